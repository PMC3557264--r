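#' Mantel consistency of a feature with the overall pattern (CM)
#'
#' Pearson correlation between the upper triangles of the feature's {0,1,2}
#' distance matrix and the overall distance matrix, assessed by a Mantel
#' permutation test: languages are randomly relabelled (rows and columns of
#' the feature matrix permuted simultaneously) \code{n_perm} times.  With the
#' add-one convention p = (1 + #\{permutations with r >= r_obs\}) /
#' (n_perm + 1), the consistency score is CM = 1 - p, so high CM means the
#' observed correlation is rarely matched by chance.
#'
#' @param table a \linkS4class{TypologyTable}.
#' @param f feature id.
#' @param n_perm number of permutations (>= 1).
#' @param seed integer seed for the permutations.
#' @param overall optional precomputed \code{\link{overallDistanceMatrix}}
#'   (saves recomputation when scoring many features).
#' @return CM in [0, 1], or \code{NA} (with a warning) when either matrix has
#'   zero variance.
#' @export
mantelConsistency <- function(table, f, n_perm = 999, seed = 1L, overall = NULL) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (is.null(overall)) overall <- suppressMessages(overallDistanceMatrix(table))
  df <- featureDistanceMatrix(table, f)
  ut <- upper.tri(df)
  x <- df[ut]; y <- overall[ut]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant distance matrix for feature ", f, "; CM undefined")
    return(NA_real_)
  }
  r_obs <- stats::cor(x, y)
  n <- nrow(df)
  set.seed(seed)
  hits <- 0L
  for (b in seq_len(n_perm)) {
    idx <- sample.int(n)
    r_p <- stats::cor(df[idx, idx][ut], y)
    if (!is.na(r_p) && r_p >= r_obs) hits <- hits + 1L
  }
  1 - (1 + hits) / (n_perm + 1)
}

# excesses d(a,c) + d(c,b) - d(a,b) for triplet index matrix (rows: a, b, c)
.tripletExcess <- function(d, trip) {
  d[cbind(trip[, 1], trip[, 3])] + d[cbind(trip[, 3], trip[, 2])] -
    d[cbind(trip[, 1], trip[, 2])]
}

#' Coherence consistency of a feature (CC)
#'
#' The excess of a language pair (a, b) through a third language c under a
#' distance matrix M is E_M(a,b|c) = M(a,c) + M(c,b) - M(a,b), the extra
#' distance of the detour; it is non-negative for the {0,1,2} per-feature rule
#' and for complete-table averages (pairwise-complete averaging over attested
#' features can dip slightly below zero).  CC(f) is the ratio of the summed
#' feature-matrix excesses
#' to the summed overall-matrix excesses over a seeded uniform sample of
#' \code{n_triplets} ordered triplets of distinct languages (all triplets when
#' fewer exist).  A feature whose distance matrix equals the overall matrix
#' has CC = 1.
#'
#' @inheritParams mantelConsistency
#' @param n_triplets triplet sample size.
#' @return CC >= 0, or \code{NA} when the overall excesses sum to zero.
#' @export
coherenceConsistency <- function(table, f, n_triplets = 1e5, seed = 1L, overall = NULL) {
  n <- ncol(table)
  if (n < 3) stop("need at least 3 languages")
  if (is.null(overall)) overall <- suppressMessages(overallDistanceMatrix(table))
  df <- featureDistanceMatrix(table, f)
  total <- as.double(n) * (n - 1) * (n - 2)
  if (total <= n_triplets) {
    idx <- seq_len(n)
    trip <- as.matrix(expand.grid(a = idx, b = idx, c = idx))
    trip <- trip[trip[, 1] != trip[, 2] & trip[, 1] != trip[, 3] & trip[, 2] != trip[, 3], , drop = FALSE]
  } else {
    set.seed(seed)
    a <- sample.int(n, n_triplets, replace = TRUE)
    b <- sample.int(n, n_triplets, replace = TRUE)
    cc <- sample.int(n, n_triplets, replace = TRUE)
    ok <- a != b & a != cc & b != cc
    while (any(!ok)) {  # redraw clashing triplets
      m <- sum(!ok)
      a[!ok] <- sample.int(n, m, replace = TRUE)
      b[!ok] <- sample.int(n, m, replace = TRUE)
      cc[!ok] <- sample.int(n, m, replace = TRUE)
      ok <- a != b & a != cc & b != cc
    }
    trip <- cbind(a, b, cc)
  }
  num <- sum(.tripletExcess(df, trip))
  den <- sum(.tripletExcess(overall, trip))
  if (den == 0) return(NA_real_)
  num / den
}

#' Rank consistency of a feature (CR)
#'
#' For a reference language l, the rank of l' is the number of other
#' languages strictly closer to l than l' is, under the overall distance
#' matrix.  For each language l with an attested value and a non-empty set
#' S_l of other languages sharing that value, the summed ranks of S_l are
#' rescaled between the minimum and maximum sums achievable by any |S_l|
#' languages, and CR(f) is the mean of these scores: 0 when co-valued
#' languages are always the nearest neighbours, 1 when they are always the
#' farthest.  Downstream comparison uses -CR (low CR = consistent = stable).
#'
#' @inheritParams mantelConsistency
#' @return CR in [0, 1], or \code{NA} when no language yields a defined score
#'   (e.g. a constant feature whose co-valued set covers all languages).
#' @export
rankConsistency <- function(table, f, overall = NULL) {
  n <- ncol(table)
  if (n < 3) stop("need at least 3 languages")
  if (is.null(overall)) overall <- suppressMessages(overallDistanceMatrix(table))
  v <- .featureRow(table, f)
  att <- which(!is.na(v))
  if (length(att) < 2) stop("feature ", f, " attested for fewer than 2 languages")
  scores <- c()
  for (l in att) {
    S <- att[att != l & v[att] == v[l]]
    if (length(S) == 0) next
    others <- setdiff(seq_len(n), l)
    dvec <- overall[others, l]
    rks <- vapply(dvec, function(x) sum(dvec < x), 0L)  # strict "<", ties don't count
    srt <- sort(rks)
    k <- length(S)
    m_l <- sum(srt[seq_len(k)])
    M_l <- sum(srt[seq.int(length(srt) - k + 1, length(srt))])
    if (M_l == m_l) next
    s <- sum(rks[match(S, others)])
    scores <- c(scores, (s - m_l) / (M_l - m_l))
  }
  if (length(scores) == 0) return(NA_real_)
  mean(scores)
}

#' All three consistency scores for a set of features
#'
#' Convenience wrapper computing CM, CC and CR against a single shared
#' overall distance matrix.
#'
#' @inheritParams mantelConsistency
#' @param features feature ids to score (default: all).
#' @param n_triplets triplet sample size for CC.
#' @return data.frame with columns feature_id, cm, cc, cr, n_perm,
#'   n_triplets, seed.
#' @export
consistencyScores <- function(table, features = featureIds(table),
                              n_perm = 999, n_triplets = 1e5, seed = 1L) {
  overall <- suppressMessages(overallDistanceMatrix(table))
  res <- lapply(seq_along(features), function(i) {
    f <- features[i]
    data.frame(feature_id = f,
               cm = suppressWarnings(mantelConsistency(table, f, n_perm, seed + i, overall = overall)),
               cc = coherenceConsistency(table, f, n_triplets, seed + i, overall = overall),
               cr = tryCatch(rankConsistency(table, f, overall = overall),
                             error = function(e) NA_real_),
               n_perm = n_perm, n_triplets = n_triplets, seed = seed)
  })
  do.call(rbind, res)
}
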