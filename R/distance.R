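#' Per-feature typological distance matrix
#'
#' Distance between two languages relative to one feature: 0 if both have the
#' same attested value, 2 if both are attested but differ, 1 if the value is
#' unattested for at least one of them.
#'
#' @param table a \linkS4class{TypologyTable}.
#' @param f a feature id present in \code{table}.
#' @return a symmetric numeric matrix (languages x languages, dimnames =
#'   language ids) with entries in {0, 1, 2} and a zero diagonal, with
#'   attribute \code{kind = "per-feature"}.
#' @seealso \code{\link{overallDistanceMatrix}}
#' @export
featureDistanceMatrix <- function(table, f) {
  v <- .featureRow(table, f)
  n <- length(v)
  att <- !is.na(v)
  d <- matrix(1, n, n, dimnames = list(names(v), names(v)))
  if (any(att)) {
    va <- v[att]
    d[att, att] <- 2 * outer(va, va, "!=")
  }
  diag(d) <- 0
  attr(d, "kind") <- "per-feature"
  d
}

#' Overall typological distance matrix
#'
#' Entry (a, b) is the mean of the per-feature distances over the features
#' attested in \emph{both} a and b (so each contribution is 0 or 2).  Pairs of
#' languages with no mutually attested feature receive the neutral value 1;
#' their count is reported in attribute \code{n_no_overlap} and via a message.
#'
#' @param table a \linkS4class{TypologyTable}.
#' @param feature_set feature ids to aggregate over; defaults to all features.
#' @return a symmetric numeric matrix with entries in [0, 2], zero diagonal,
#'   attribute \code{kind = "overall"}.
#' @export
overallDistanceMatrix <- function(table, feature_set = featureIds(table)) {
  if (length(feature_set) == 0) stop("feature_set must be non-empty")
  ids <- featureIds(table)
  if (!all(feature_set %in% ids)) stop("unknown feature(s): ",
                                       paste(setdiff(feature_set, ids), collapse = ", "))
  vals <- featureValues(table)[match(feature_set, ids), , drop = FALSE]
  n <- ncol(vals)
  sum_d <- matrix(0, n, n)
  n_att <- matrix(0L, n, n)
  for (i in seq_len(nrow(vals))) {
    v <- vals[i, ]
    att <- !is.na(v)
    if (sum(att) < 2) next
    va <- v[att]
    sum_d[att, att] <- sum_d[att, att] + 2 * outer(va, va, "!=")
    n_att[att, att] <- n_att[att, att] + 1L
  }
  d <- ifelse(n_att > 0, sum_d / pmax(n_att, 1L), 1)
  diag(d) <- 0
  no_overlap <- sum(n_att[upper.tri(n_att)] == 0)
  if (no_overlap > 0)
    message(no_overlap, " language pair(s) share no attested feature; distance set to 1")
  dimnames(d) <- list(languageIds(table), languageIds(table))
  attr(d, "kind") <- "overall"
  attr(d, "n_no_overlap") <- no_overlap
  d
}
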