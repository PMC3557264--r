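#' Build a family tree from a genealogical classification
#'
#' Turns the family -> genus -> language classification into a rooted tree
#' with unit branch lengths: genera become internal nodes under the family
#' root, languages become tips.  A genus containing a single language attaches
#' that tip directly under the root with one unit edge.
#'
#' @param classification data.frame with columns \code{language_id},
#'   \code{family}, \code{genus} (e.g. \code{as.data.frame(languageData(x))}).
#' @param family_id the family to build.
#' @return an \code{ape::phylo} rooted tree whose tip labels are language
#'   ids.
#' @export
taxonomyToTree <- function(classification, family_id) {
  cl <- classification[classification$family == family_id, , drop = FALSE]
  if (nrow(cl) < 3) stop("family ", family_id, " has fewer than 3 languages; rate not estimable")
  ids <- as.character(cl$language_id)
  if (any(grepl("[(),:;'\\s]", ids, perl = TRUE)))
    stop("language ids must not contain Newick metacharacters or whitespace")
  parts <- vapply(split(ids, as.character(cl$genus)), function(tips) {
    if (length(tips) == 1) paste0(tips, ":1")
    else paste0("(", paste0(tips, ":1", collapse = ","), "):1")
  }, "")
  tree <- ape::read.tree(text = paste0("(", paste(parts, collapse = ","), ");"))
  tree$family_id <- family_id
  tree
}

#' Minimum number of state changes on a tree (parsimony)
#'
#' Uniform-cost Sankoff dynamic programming over the rooted tree (equivalent
#' to Fitch counting on binary trees, and valid on multifurcations): the
#' minimum number of unordered state changes needed to produce the attested
#' tip values.  Missing tips are wildcards that can take any state for free.
#'
#' @param tree an \code{ape::phylo} tree.
#' @param tip_values named character vector (names = tip labels) of states,
#'   \code{NA} = missing.
#' @return integer minimum number of changes, or \code{NA} when fewer than
#'   two tips are attested.
#' @export
fitchMinChanges <- function(tree, tip_values) {
  states <- sort(unique(stats::na.omit(tip_values[tree$tip.label])))
  vals <- tip_values[tree$tip.label]
  if (sum(!is.na(vals)) < 2) return(NA_integer_)
  k <- length(states)
  if (k == 1) return(0L)
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  cost <- matrix(0, k, n_node)
  for (i in seq_len(n_tip)) {
    if (!is.na(vals[i])) {
      cost[, i] <- Inf
      cost[match(vals[i], states), i] <- 0
    }
  }
  tr <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(tr$edge))) {
    parent <- tr$edge[e, 1]; child <- tr$edge[e, 2]
    cmin <- min(cost[, child])
    cost[, parent] <- cost[, parent] + pmin(cost[, child], cmin + 1)
  }
  root <- n_tip + 1L
  as.integer(min(cost[, root]))
}

# transition probabilities of the k-state symmetric Markov model
.mkP <- function(k, rate, t) {
  e <- exp(-k * rate * t / (k - 1))
  off <- (1 - e) / k
  same <- 1 / k + (k - 1) / k * e
  list(same = same, off = off)
}

#' Log-likelihood of tip states under the symmetric k-state Markov model
#'
#' Pruning (post-order conditional likelihoods) under the Mk model with
#' transition probability P(i -> j | t) = 1/k - (1/k) exp(-k r t/(k-1)) for
#' i != j, a uniform root prior, and missing tips contributing a vector of
#' ones.  Conditional likelihood vectors are rescaled at each node, with the
#' log scale factor accumulated, so long trees do not underflow.
#'
#' @param tree an \code{ape::phylo} tree with branch lengths.
#' @param tip_values named character vector of tip states (\code{NA} =
#'   missing).
#' @param k number of states (>= 2); states beyond those attested are allowed.
#' @param rate the substitution rate (>= 0).
#' @param states optional state labels fixing the mapping of values to the k
#'   states; defaults to the sorted attested values, padded as needed.
#' @return the log-likelihood.
#' @export
mkLikelihood <- function(tree, tip_values, k, rate, states = NULL) {
  if (rate < 0) stop("rate must be >= 0")
  if (k < 2) stop("k must be >= 2")
  vals <- tip_values[tree$tip.label]
  if (is.null(states)) {
    states <- sort(unique(stats::na.omit(vals)))
    if (length(states) > k) stop("more attested states than k")
    if (length(states) < k) states <- c(states, paste0(".s", seq_len(k - length(states))))
  }
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  L <- matrix(1, k, n_node)
  for (i in seq_len(n_tip)) {
    if (!is.na(vals[i])) {
      L[, i] <- 0
      L[match(vals[i], states), i] <- 1
    }
  }
  logscale <- 0
  tr <- ape::reorder.phylo(tree, "postorder")
  el <- tr$edge.length
  done <- rep(FALSE, n_node)
  for (e in seq_len(nrow(tr$edge))) {
    parent <- tr$edge[e, 1]; child <- tr$edge[e, 2]
    p <- .mkP(k, rate, el[e])
    lc <- L[, child]
    s <- sum(lc)
    contrib <- p$off * s + (p$same - p$off) * lc
    L[, parent] <- L[, parent] * contrib
    if (e == nrow(tr$edge) || tr$edge[e + 1, 1] != parent) {
      m <- max(L[, parent])
      if (m > 0 && m < 1e-100) { L[, parent] <- L[, parent] / m; logscale <- logscale + log(m) }
    }
  }
  root <- n_tip + 1L
  log(mean(L[, root])) + logscale
}

#' Maximum-likelihood Mk rate for one feature on one tree
#'
#' Maximises \code{\link{mkLikelihood}} over the rate by bracketed scalar
#' optimisation on [0, r_max], comparing the interior optimum against both
#' boundaries.
#'
#' @inheritParams mkLikelihood
#' @param r_max upper bound of the rate search (default 100).
#' @param tol optimisation tolerance.
#' @return list with \code{ml_rate}, \code{loglik}, \code{boundary}
#'   (\code{"none"}, \code{"lower"} or \code{"upper"}),
#'   \code{n_tips_attested}.
#' @export
mkRateML <- function(tree, tip_values, k, r_max = 100, tol = 1e-6) {
  vals <- tip_values[tree$tip.label]
  n_att <- sum(!is.na(vals))
  if (n_att < 3) stop("need >=3 attested tips")
  ll <- function(r) mkLikelihood(tree, tip_values, k, r)
  opt <- stats::optimize(ll, c(0, r_max), maximum = TRUE, tol = tol)
  cand <- rbind(c(0, ll(0)), c(opt$maximum, opt$objective), c(r_max, ll(r_max)))
  best <- cand[which.max(cand[, 2]), ]
  boundary <- if (best[1] <= tol) "lower" else if (best[1] >= r_max - tol) "upper" else "none"
  rate <- if (boundary == "lower") 0 else best[1]
  list(ml_rate = rate, loglik = best[2], boundary = boundary,
       n_tips_attested = n_att)
}

#' Cross-family aggregated phylogenetic stability (method D)
#'
#' For each sufficiently large family a taxonomy tree is built and each
#' feature's rate of change is estimated by Mk maximum likelihood and/or by
#' parsimony (minimum changes divided by attested tips).  Within each family
#' and estimator, features are ranked from fast- to slow-changing and the
#' ranks rescaled to [0, 1] (1 = most stable).  The agreed score is the first
#' principal component of the feature x (family, estimator) rank matrix
#' (missing entries mean-imputed per feature; mean rank as fallback when the
#' PCA is degenerate), oriented so that higher = more stable.
#'
#' @param table a \linkS4class{TypologyTable} with family and genus metadata.
#' @param method \code{"both"} (default), \code{"ml"} or \code{"parsimony"}.
#' @param min_family_size smallest family (number of languages) used.
#' @param r_max,tol passed to \code{\link{mkRateML}}.
#' @return data.frame with \code{feature_id}, \code{score} (NA when the
#'   feature is estimable in fewer than 2 families) and \code{n_families}.
#' @export
dediuStability <- function(table, method = c("both", "ml", "parsimony"),
                           min_family_size = 10, r_max = 100, tol = 1e-6) {
  method <- match.arg(method)
  estimators <- if (method == "both") c("ml", "parsimony") else method
  ld <- as.data.frame(languageData(table))
  fam_sizes <- table(ld$family)
  fams <- names(fam_sizes)[fam_sizes >= max(3, min_family_size)]
  if (length(fams) < 2) stop("need >=2 families of size >= ", min_family_size)
  fids <- featureIds(table)
  vals <- featureValues(table)
  rank_cols <- list()
  fam_count <- setNames(rep(0L, length(fids)), fids)
  for (fam in fams) {
    tree <- taxonomyToTree(ld, fam)
    in_fam <- languageIds(table) %in% tree$tip.label
    rates <- matrix(NA_real_, length(fids), length(estimators),
                    dimnames = list(fids, estimators))
    for (i in seq_along(fids)) {
      tv <- vals[i, in_fam]
      names(tv) <- languageIds(table)[in_fam]
      att <- stats::na.omit(tv)
      if (length(att) < 3) next
      kf <- length(unique(att))
      if ("parsimony" %in% estimators) {
        mc <- fitchMinChanges(tree, tv)
        rates[i, "parsimony"] <- mc / length(att)
      }
      if ("ml" %in% estimators) {
        rates[i, "ml"] <- if (kf < 2) 0 else mkRateML(tree, tv, k = kf, r_max = r_max, tol = tol)$ml_rate
      }
    }
    est_here <- rowSums(!is.na(rates)) > 0
    fam_count[est_here] <- fam_count[est_here] + 1L
    for (est in estimators) {
      r <- rates[, est]
      ok <- !is.na(r)
      if (sum(ok) < 2) next
      rk <- rep(NA_real_, length(r))
      rr <- rank(-r[ok])                      # high rank = low rate = stable
      rk[ok] <- (rr - 1) / (sum(ok) - 1)
      rank_cols[[paste(fam, est, sep = ".")]] <- rk
    }
  }
  if (length(rank_cols) == 0) stop("no family produced rate estimates")
  R <- do.call(cbind, rank_cols)
  rownames(R) <- fids
  usable <- fam_count >= 2
  score <- rep(NA_real_, length(fids))
  Ru <- R[usable, , drop = FALSE]
  row_ok <- rowSums(!is.na(Ru)) > 0
  # mean-impute remaining gaps per feature, then correlation PCA
  Ri <- Ru
  rm_ <- rowMeans(Ri, na.rm = TRUE)
  for (j in seq_len(ncol(Ri))) {
    na <- is.na(Ri[, j])
    Ri[na, j] <- rm_[na]
  }
  keep_col <- apply(Ri[row_ok, , drop = FALSE], 2, stats::sd) > 0
  s <- NULL
  if (ncol(Ri) >= 2 && sum(keep_col) >= 2 && sum(row_ok) > 2) {
    pc <- try(stats::prcomp(Ri[row_ok, keep_col, drop = FALSE],
                            center = TRUE, scale. = TRUE), silent = TRUE)
    if (!inherits(pc, "try-error")) {
      s <- pc$x[, 1]
      if (stats::cor(s, rowMeans(Ri[row_ok, keep_col, drop = FALSE])) < 0) s <- -s
    }
  }
  if (is.null(s)) s <- rowMeans(Ru[row_ok, , drop = FALSE], na.rm = TRUE)  # degenerate PCA
  score[usable][row_ok] <- s
  data.frame(feature_id = fids, score = score,
             n_families = as.integer(fam_count), stringsAsFactors = FALSE)
}
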