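#' Within- versus cross-family value sharing (metric C, method W)
#'
#' For each family with at least two attested languages, R_g is the
#' proportion of language pairs sharing the same feature value; the weighted
#' mean R_bar (default weight N_g - 1) is compared with U, the proportion of
#' same-valued pairs among all cross-family attested pairs, giving
#' w = (R_bar - U) / (1 - U): 1 when families are internally uniform while
#' unrelated languages differ, about 0 when relatedness carries no signal.
#'
#' @param table a \linkS4class{TypologyTable} whose languages carry a
#'   \code{family} column.
#' @param f feature id.
#' @param weight family weighting for R_bar: \code{"n-1"} (default),
#'   \code{"pairs"} (N_g choose 2) or \code{"n"}.
#' @return list with \code{w_metric}, \code{R_bar}, \code{U},
#'   \code{n_families}, \code{weight}; \code{w_metric} is \code{NA} when the
#'   feature is constant (U = 1).
#' @export
wichmannMetricC <- function(table, f, weight = c("n-1", "pairs", "n")) {
  weight <- match.arg(weight)
  v <- .featureRow(table, f)
  fam <- as.character(languageData(table)$family)
  att <- !is.na(v)
  v <- v[att]; fam <- fam[att]
  fam_sizes <- table(fam)
  big <- names(fam_sizes)[fam_sizes >= 2]
  if (length(big) < 2 || length(fam_sizes) < 2)
    stop("need >=2 families with >=2 attested languages for feature ", f)
  same_pairs <- function(x) {
    cnt <- table(x)
    sum(choose(cnt, 2))
  }
  Rg <- vapply(big, function(g) {
    x <- v[fam == g]
    same_pairs(x) / choose(length(x), 2)
  }, 0)
  Ng <- as.numeric(fam_sizes[big])
  wg <- switch(weight, "n-1" = Ng - 1, "pairs" = choose(Ng, 2), "n" = Ng)
  R_bar <- sum(wg * Rg) / sum(wg)
  # cross-family pairs over all attested languages, via value x family counts
  total_pairs <- choose(length(v), 2)
  within_pairs <- sum(choose(as.numeric(fam_sizes), 2))
  cross_pairs <- total_pairs - within_pairs
  same_total <- same_pairs(v)
  same_within <- sum(vapply(names(fam_sizes), function(g) same_pairs(v[fam == g]), 0))
  U <- (same_total - same_within) / cross_pairs
  w_metric <- if (U >= 1) NA_real_ else (R_bar - U) / (1 - U)
  list(w_metric = w_metric, R_bar = R_bar, U = U,
       n_families = length(big), weight = weight)
}
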