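#' Convert raw method scores to relative ranks in [0, 1]
#'
#' Ranks (average-rank ties) are computed over all non-missing entries and
#' mapped by (r - r_min) / (r_max - r_min), so the most unstable covered
#' feature gets 0.0 and the most stable 1.0; missing entries stay missing.
#'
#' @param raw_scores numeric vector of per-feature scores for one method,
#'   oriented higher = more stable.
#' @return numeric vector of the same length with values in [0, 1] or
#'   \code{NA}.
#' @examples
#' toRelativeRanks(c(3.2, 7.1, 9.9))   # 0.0 0.5 1.0
#' @export
toRelativeRanks <- function(raw_scores) {
  ok <- !is.na(raw_scores)
  if (sum(ok) < 2) stop("need at least 2 non-missing values")
  r <- rank(raw_scores[ok])
  if (max(r) == min(r)) stop("constant scores cannot be ranked")
  out <- rep(NA_real_, length(raw_scores))
  names(out) <- names(raw_scores)
  out[ok] <- (r - min(r)) / (max(r) - min(r))
  out
}

#' Features covered by every method
#'
#' @param matrix a \linkS4class{StabilityMatrix}.
#' @return feature ids with a non-missing rank for every method, in ascending
#'   feature id order.
#' @export
sharedFeatureSubset <- function(matrix) {
  rk <- rankMatrix(matrix)
  ids <- featureIds(matrix)
  sort(ids[rowSums(is.na(rk)) == 0])
}

#' Comparison-stage rank coordinates over a feature subset
#'
#' The cross-method comparison re-ranks each method within the chosen subset
#' and normalises the rank r (average-rank ties) as r / n, so each method
#' becomes a point in the unit cube indexed by the subset features.  Set
#' \code{rerank = FALSE} to use the stored rank values unchanged.
#'
#' @param matrix a \linkS4class{StabilityMatrix}.
#' @param subset feature ids (default: \code{\link{sharedFeatureSubset}}).
#' @param rerank recompute ranks within the subset (default) or keep stored
#'   ranks.
#' @return numeric matrix, features (rows, named by feature id) x methods.
#' @export
comparisonRanks <- function(matrix, subset = sharedFeatureSubset(matrix),
                            rerank = TRUE) {
  rk <- rankMatrix(matrix)
  sel <- match(subset, featureIds(matrix))
  if (anyNA(sel)) stop("subset contains unknown feature ids")
  x <- rk[sel, , drop = FALSE]
  rownames(x) <- as.character(subset)
  if (!rerank) return(x)
  apply(x, 2, function(v) rank(v) / length(v))
}

#' Pairwise correlations between methods over a feature subset
#'
#' Pearson's r and Spearman's rho with two-sided p-values for every method
#' pair, pairwise complete.  Constant columns yield \code{NA} cells.
#'
#' @inheritParams comparisonRanks
#' @return list of symmetric matrices \code{pearson}, \code{spearman},
#'   \code{p_pearson}, \code{p_spearman} with unit diagonal (p = 0 on the
#'   diagonal of the p matrices).
#' @export
pairwiseCorrelations <- function(matrix, subset = sharedFeatureSubset(matrix)) {
  if (length(subset) < 3) stop("need at least 3 features")
  x <- comparisonRanks(matrix, subset, rerank = FALSE)
  m <- ncol(x)
  out <- replicate(4, diag(1, m, m), simplify = FALSE)
  names(out) <- c("pearson", "spearman", "p_pearson", "p_spearman")
  out$p_pearson[] <- out$p_spearman[] <- 0
  diag(out$p_pearson) <- diag(out$p_spearman) <- 0
  for (i in seq_len(m - 1)) for (j in seq.int(i + 1, m)) {
    ok <- stats::complete.cases(x[, i], x[, j])
    xi <- x[ok, i]; xj <- x[ok, j]
    if (stats::sd(xi) == 0 || stats::sd(xj) == 0) {
      out$pearson[i, j] <- out$pearson[j, i] <- NA
      out$spearman[i, j] <- out$spearman[j, i] <- NA
      out$p_pearson[i, j] <- out$p_pearson[j, i] <- NA
      out$p_spearman[i, j] <- out$p_spearman[j, i] <- NA
      next
    }
    pe <- stats::cor.test(xi, xj, method = "pearson")
    sp <- suppressWarnings(stats::cor.test(xi, xj, method = "spearman", exact = FALSE))
    out$pearson[i, j] <- out$pearson[j, i] <- unname(pe$estimate)
    out$spearman[i, j] <- out$spearman[j, i] <- unname(sp$estimate)
    out$p_pearson[i, j] <- out$p_pearson[j, i] <- pe$p.value
    out$p_spearman[i, j] <- out$p_spearman[j, i] <- sp$p.value
  }
  meths <- methodIds(matrix)
  out <- lapply(out, function(mm) { dimnames(mm) <- list(meths, meths); mm })
  out
}

#' Flag features that are regression outliers for several method pairs
#'
#' For every unordered method pair, both directional OLS fits of one rank
#' column on the other are examined; a feature counts for the pair when its
#' externally studentized residual exceeds \code{resid_threshold} in either
#' direction.  Features flagged in at least \code{min_pairs} pairs are
#' returned.
#'
#' @inheritParams comparisonRanks
#' @param resid_threshold absolute externally studentized residual cut-off.
#' @param min_pairs minimum number of method pairs a feature must be flagged
#'   in.
#' @return sorted vector of flagged feature ids (possibly empty), with the
#'   per-feature pair counts as attribute \code{"pair_counts"}.
#' @export
flagOutlierFeatures <- function(matrix, subset = sharedFeatureSubset(matrix),
                                resid_threshold = 2.5, min_pairs = 3) {
  if (resid_threshold <= 0 || min_pairs <= 0) stop("thresholds must be positive")
  x <- comparisonRanks(matrix, subset)
  m <- ncol(x)
  cnt <- setNames(numeric(nrow(x)), rownames(x))
  for (i in seq_len(m - 1)) for (j in seq.int(i + 1, m)) {
    hits <- function(y, z) {
      fit <- stats::lm(y ~ z)
      # an essentially perfect fit has no outliers, only numerical noise
      if (stats::sd(stats::resid(fit)) < 1e-8 * stats::sd(y))
        return(rep(FALSE, length(y)))
      r <- abs(stats::rstudent(fit))
      !is.na(r) & r > resid_threshold
    }
    cnt <- cnt + (hits(x[, i], x[, j]) | hits(x[, j], x[, i]))
  }
  nm <- names(cnt)[cnt >= min_pairs]
  num <- suppressWarnings(as.numeric(nm))
  flagged <- if (length(nm) && anyNA(num)) sort(nm) else sort(num)
  attr(flagged, "pair_counts") <- cnt
  flagged
}

#' Euclidean distances between methods in rank space
#'
#' Each method is a point whose coordinates are its comparison-stage relative
#' ranks over the subset features; distances are plain Euclidean.
#'
#' @inheritParams comparisonRanks
#' @return symmetric method x method distance matrix with zero diagonal.
#' @export
methodDistances <- function(matrix, subset = sharedFeatureSubset(matrix),
                            rerank = TRUE) {
  if (length(subset) < 2) stop("need at least 2 features")
  x <- comparisonRanks(matrix, subset, rerank = rerank)
  as.matrix(stats::dist(t(x)))
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Double-centring plus eigendecomposition of a symmetric distance matrix,
#' delegated to \code{stats::cmdscale}; coordinates are centred and
#' eigenvalues are returned for inspection.
#'
#' @param distance_matrix symmetric non-negative matrix.
#' @param dims number of output dimensions.
#' @return list with \code{points} (n x dims) and \code{eig}.
#' @export
classicalMDS <- function(distance_matrix, dims = 2) {
  if (!isSymmetric(unname(as.matrix(distance_matrix))))
    stop("distance matrix must be symmetric")
  if (all(distance_matrix == 0)) {
    n <- nrow(as.matrix(distance_matrix))
    return(list(points = matrix(0, n, dims,
                                dimnames = list(rownames(as.matrix(distance_matrix)), NULL)),
                eig = rep(0, n)))
  }
  fit <- stats::cmdscale(stats::as.dist(distance_matrix), k = dims, eig = TRUE)
  list(points = fit$points, eig = fit$eig)
}

#' Null distribution of method distances from random points
#'
#' Draws \code{n_sets} sets of \code{n_points} i.i.d. uniform points in
#' [0, 1]^dim and records each set's minimum, mean and maximum pairwise
#' distance; observed statistics are compared by add-one one-sided empirical
#' p-values (smaller than expected).
#'
#' @param observed named numeric vector with elements \code{min},
#'   \code{mean}, \code{max} (e.g. from \code{\link{methodDistances}}).
#' @param n_points points per set (number of method columns compared).
#' @param dim dimensionality (number of subset features).
#' @param n_sets number of random sets.
#' @param seed integer seed.
#' @return list with \code{p} (p-values per statistic) and \code{null}
#'   (matrix of null summaries: mean, sd and quantiles per statistic).
#' @export
randomPointNull <- function(observed, n_points, dim, n_sets = 10000, seed = 1L) {
  if (n_sets < 1) stop("n_sets must be >= 1")
  stopifnot(all(c("min", "mean", "max") %in% names(observed)))
  set.seed(seed)
  stats_mat <- matrix(NA_real_, n_sets, 3, dimnames = list(NULL, c("min", "mean", "max")))
  for (b in seq_len(n_sets)) {
    pts <- matrix(stats::runif(n_points * dim), n_points, dim)
    d <- stats::dist(pts)
    stats_mat[b, ] <- c(min(d), mean(d), max(d))
  }
  p <- vapply(c("min", "mean", "max"), function(s)
    .empiricalP(stats_mat[, s], observed[[s]], "le"), 0)
  null <- apply(stats_mat, 2, function(v)
    c(mean = mean(v), sd = stats::sd(v), stats::quantile(v, c(0.025, 0.5, 0.975))))
  list(p = p, null = null)
}

#' Principal components agreement between methods
#'
#' Correlation-matrix PCA (columns standardised) of the stored stability
#' ranks over the subset features.  The first component captures what all
#' methods agree on; its sign is fixed so the loadings of an all-method
#' agreement pattern are positive (positive correlation with the row means).
#'
#' @inheritParams comparisonRanks
#' @param exclude features to drop before the analysis (e.g. flagged
#'   outliers).
#' @return list with \code{loadings} (methods x PCs), \code{pct_variance},
#'   \code{scores} (features x PCs, rownames = feature ids).
#' @export
pcaAgreement <- function(matrix, subset = sharedFeatureSubset(matrix),
                         exclude = NULL) {
  subset <- setdiff(subset, exclude)
  x <- comparisonRanks(matrix, subset, rerank = FALSE)
  if (nrow(x) <= ncol(x)) stop("need more features than methods")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) stop("constant column(s): ",
                          paste(colnames(x)[sds == 0], collapse = ", "))
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  pct <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  flip <- sign(stats::cor(pc$x[, 1], rowMeans(scale(x))))
  if (flip < 0) { pc$x[, 1] <- -pc$x[, 1]; pc$rotation[, 1] <- -pc$rotation[, 1] }
  list(loadings = pc$rotation, pct_variance = pct, scores = pc$x)
}

#' Per-feature disagreement between methods (IQR) with a permutation null
#'
#' For each subset feature the IQR and range of its comparison-stage ranks
#' across methods measure how much the methods disagree about it.  The null
#' is built by independently permuting each method's rank column across the
#' subset features \code{n_randomizations} times and pooling all per-feature
#' IQRs; each feature gets two one-sided add-one empirical p-values (IQR
#' smaller / larger than expected), Holm-corrected within each side.
#'
#' @inheritParams comparisonRanks
#' @param n_randomizations number of column permutations.
#' @param seed integer seed.
#' @param qtype quantile convention: 5 (h = np + 1/2, the default) or 7
#'   (h = 1 + (n-1)p).
#' @return list with \code{table} (data.frame: feature_id, iqr, range, p_low,
#'   p_high, p_low_holm, p_high_holm), \code{null_mean}, \code{null_sd},
#'   \code{qtype}.
#' @export
iqrDisagreement <- function(matrix, subset = sharedFeatureSubset(matrix),
                            n_randomizations = 10000, seed = 1L, qtype = 5) {
  if (length(subset) < 3) stop("need at least 3 features")
  x <- comparisonRanks(matrix, subset)
  n <- nrow(x); m <- ncol(x)
  obs_iqr <- .rowIQRs(x, qtype)
  obs_range <- apply(x, 1, max) - apply(x, 1, min)
  set.seed(seed)
  big <- matrix(NA_real_, n * n_randomizations, m)
  for (j in seq_len(m)) {
    idx <- as.vector(replicate(n_randomizations, sample.int(n)))
    big[, j] <- x[idx, j]
  }
  null_iqr <- .rowIQRs(big, qtype)
  null_sorted <- sort(null_iqr)
  N <- length(null_sorted)
  # add-one one-sided empirical p-values via binary search on the pooled null
  p_low <- (1 + findInterval(obs_iqr, null_sorted)) / (N + 1)
  p_high <- (1 + (N - findInterval(obs_iqr, null_sorted, left.open = TRUE))) / (N + 1)
  fid <- suppressWarnings(as.numeric(rownames(x)))
  if (anyNA(fid)) fid <- rownames(x)
  tab <- data.frame(feature_id = fid,
                    iqr = obs_iqr, range = obs_range,
                    p_low = p_low, p_high = p_high,
                    p_low_holm = stats::p.adjust(p_low, "holm"),
                    p_high_holm = stats::p.adjust(p_high, "holm"))
  list(table = tab, null_mean = mean(null_iqr), null_sd = stats::sd(null_iqr),
       qtype = qtype)
}

#' One-way ANOVA of agreed stability across WALS areas
#'
#' Tests whether the per-feature agreed stability scores (typically PC1 of
#' \code{\link{pcaAgreement}}) differ between feature domains, with Tukey HSD
#' post-hoc pairwise comparisons.  Areas with fewer than two features are
#' dropped with a warning.
#'
#' @param scores numeric vector of per-feature scores.
#' @param areas character vector of area codes, same length.
#' @return list with \code{F}, \code{p}, \code{tukey} (data.frame of pairwise
#'   comparisons sorted by adjusted p), \code{n_groups}.
#' @export
areaAnova <- function(scores, areas) {
  stopifnot(length(scores) == length(areas))
  keep <- !is.na(scores) & !is.na(areas)
  scores <- scores[keep]; areas <- as.character(areas[keep])
  sizes <- table(areas)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    warning("dropping areas with <2 features: ", paste(small, collapse = ", "))
    ok <- !(areas %in% small)
    scores <- scores[ok]; areas <- areas[ok]
  }
  if (length(unique(areas)) < 2) stop("need >=2 areas with >=2 features")
  df <- data.frame(score = scores, area = factor(areas))
  fit <- stats::aov(score ~ area, data = df)
  s <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$area
  tk <- data.frame(pair = rownames(tk), tk, row.names = NULL, check.names = FALSE)
  tk <- tk[order(tk[["p adj"]]), ]
  list(F = s[["F value"]][1], p = s[["Pr(>F)"]][1], tukey = tk,
       n_groups = nlevels(df$area))
}

#' Run the full cross-method comparison
#'
#' Orchestrates the comparison stage on a \linkS4class{StabilityMatrix}:
#' shared subset, pairwise correlations (with and without outliers), outlier
#' flags, method distances + classical MDS + random-point null, PCA
#' agreement, per-feature IQR disagreement with permutation null and Holm
#' correction, and the area ANOVA on PC1 scores.
#'
#' @param matrix a \linkS4class{StabilityMatrix}.
#' @param n_null randomization count for the distance and IQR nulls.
#' @param seed integer seed.
#' @param resid_threshold,min_pairs outlier flagging parameters.
#' @param qtype IQR quantile convention.
#' @return a list of class \code{"ComparisonReport"}.
#' @export
runComparison <- function(matrix, n_null = 10000, seed = 1L,
                          resid_threshold = 2.5, min_pairs = 3, qtype = 5) {
  subset <- sharedFeatureSubset(matrix)
  cors <- pairwiseCorrelations(matrix, subset)
  outliers <- flagOutlierFeatures(matrix, subset, resid_threshold, min_pairs)
  cors_no_out <- pairwiseCorrelations(matrix, setdiff(subset, outliers))
  d <- methodDistances(matrix, subset)
  mds <- classicalMDS(d, 2)
  dv <- d[upper.tri(d)]
  null <- randomPointNull(c(min = min(dv), mean = mean(dv), max = max(dv)),
                          n_points = ncol(d), dim = length(subset),
                          n_sets = n_null, seed = seed)
  pca <- pcaAgreement(matrix, subset)
  pca_no_out <- pcaAgreement(matrix, subset, exclude = outliers)
  iqr <- iqrDisagreement(matrix, subset, n_randomizations = n_null,
                         seed = seed + 1L, qtype = qtype)
  fd <- featureData(matrix)
  area <- fd$area_code[match(subset, fd$feature_id)]
  anova <- withCallingHandlers(
    areaAnova(pca$scores[, 1], area),
    warning = function(w) invokeRestart("muffleWarning"))
  out <- list(shared_feature_ids = subset,
              correlations = cors, correlations_no_outliers = cors_no_out,
              outlier_feature_ids = outliers,
              method_distance_matrix = d,
              mds = mds, null_distance = null,
              pca = pca, pca_no_outliers = pca_no_out,
              iqr = iqr, anova = anova,
              config = list(n_null = n_null, seed = seed,
                            resid_threshold = resid_threshold,
                            min_pairs = min_pairs, qtype = qtype))
  class(out) <- "ComparisonReport"
  out
}

#' @export
print.ComparisonReport <- function(x, ...) {
  cat("Cross-method stability comparison\n")
  cat("  shared features:", length(x$shared_feature_ids), "\n")
  cat("  outliers:", if (length(x$outlier_feature_ids))
    paste(x$outlier_feature_ids, collapse = ", ") else "none", "\n")
  dv <- x$method_distance_matrix[upper.tri(x$method_distance_matrix)]
  cat(sprintf("  method distances: min %.2f mean %.2f max %.2f (p_min=%.3g, p_mean=%.3g)\n",
              min(dv), mean(dv), max(dv),
              x$null_distance$p[["min"]], x$null_distance$p[["mean"]]))
  cat(sprintf("  PC1 %.1f%% of variance; first four %.1f%%\n",
              x$pca$pct_variance[1], sum(x$pca$pct_variance[1:4])))
  cat(sprintf("  mean feature IQR %.2f (null %.2f +/- %.2f)\n",
              mean(x$iqr$table$iqr), x$iqr$null_mean, x$iqr$null_sd))
  low <- x$iqr$table$feature_id[x$iqr$table$p_low_holm < 0.05]
  high <- x$iqr$table$feature_id[x$iqr$table$p_high_holm < 0.05]
  cat("  Holm-significant IQR: low =", paste(low, collapse = ", "),
      "; high =", paste(high, collapse = ", "), "\n")
  cat(sprintf("  area ANOVA: F = %.2f, p = %.4f; top Tukey pair %s (adj p = %.4f)\n",
              x$anova$F, x$anova$p, x$anova$tukey$pair[1], x$anova$tukey[["p adj"]][1]))
  invisible(x)
}
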