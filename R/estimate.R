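#' Estimate feature stabilities with any subset of the seven methods
#'
#' Runs the requested estimators over every polymorphic feature of the table
#' and assembles a \linkS4class{StabilityMatrix}.  Native scores whose low
#' values mean stability (CR) are sign-flipped, so the \code{raw} assay is
#' always oriented higher = more stable, and the \code{rank} assay is each
#' column passed through \code{\link{toRelativeRanks}}.
#'
#' Method columns: \code{CM}, \code{CC}, \code{CR} (consistency with the
#' overall distance pattern), \code{D} (phylogenetic rate ranks), \code{P1},
#' \code{P2} (family/area homogeneity ratio, all vs accepted families),
#' \code{W} (metric C), \code{M} (transition probabilities).
#'
#' @param table a \linkS4class{TypologyTable}.
#' @param methods lower-case method ids, any of \code{c("cm","cc","cr","d",
#'   "p1","p2","w","m")}.
#' @param seed integer seed for the stochastic estimators.
#' @param n_perm,n_triplets consistency-method sampling sizes.
#' @param maslova_splits number of genus splits for M.
#' @param wichmann_weight family weight for W.
#' @param d_estimator rate estimator(s) behind D.
#' @param min_family_size smallest family used by D.
#' @return a \linkS4class{StabilityMatrix} over the polymorphic features.
#' @export
estimateStability <- function(table,
                              methods = c("cm", "cc", "cr", "d", "p1", "p2", "w", "m"),
                              seed = 1L, n_perm = 999, n_triplets = 1e5,
                              maslova_splits = 50,
                              wichmann_weight = "n-1",
                              d_estimator = "both",
                              min_family_size = 10) {
  methods <- match.arg(tolower(methods),
                       c("cm", "cc", "cr", "d", "p1", "p2", "w", "m"),
                       several.ok = TRUE)
  vals <- featureValues(table)
  poly <- apply(vals, 1, function(v) length(unique(stats::na.omit(v))) >= 2)
  fids <- featureIds(table)[poly]
  sub <- table[poly, ]
  label <- c(cm = "CM", cc = "CC", cr = "CR", d = "D", p1 = "P1", p2 = "P2",
             w = "W", m = "M")
  orientation <- c(CM = 1, CC = 1, CR = -1, D = 1, P1 = 1, P2 = 1, W = 1, M = 1)
  raw <- matrix(NA_real_, length(fids), length(methods),
                dimnames = list(fids, label[methods]))
  if (any(c("cm", "cc", "cr") %in% methods)) {
    cs <- consistencyScores(sub, n_perm = n_perm, n_triplets = n_triplets, seed = seed)
    if ("cm" %in% methods) raw[, "CM"] <- cs$cm
    if ("cc" %in% methods) raw[, "CC"] <- cs$cc
    if ("cr" %in% methods) raw[, "CR"] <- -cs$cr
  }
  if ("d" %in% methods) {
    d <- dediuStability(sub, method = d_estimator, min_family_size = min_family_size)
    raw[, "D"] <- d$score
  }
  for (i in seq_along(fids)) {
    f <- fids[i]
    if ("p1" %in% methods)
      raw[i, "P1"] <- parkvallRatio(sub, f, "all")$p_ratio
    if ("p2" %in% methods)
      raw[i, "P2"] <- parkvallRatio(sub, f, "accepted12")$p_ratio
    if ("w" %in% methods)
      raw[i, "W"] <- tryCatch(wichmannMetricC(sub, f, wichmann_weight)$w_metric,
                              error = function(e) NA_real_)
    if ("m" %in% methods)
      raw[i, "M"] <- maslovaStability(sub, f, n_splits = maslova_splits,
                                      seed = seed + 1000L * i)$stability
  }
  rank <- apply(raw, 2, function(v) {
    if (sum(!is.na(v)) >= 2 && stats::sd(v, na.rm = TRUE) > 0) toRelativeRanks(v) else v * NA
  })
  fd <- as.data.frame(featureData(sub))
  StabilityMatrix(rank, raw = raw,
                  methods = data.frame(method_id = colnames(raw),
                                       orientation = orientation[colnames(raw)]),
                  features = fd)
}
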