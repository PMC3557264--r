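`%||%` <- function(a, b) if (is.null(a)) b else a

# quantile position for the interpolation conventions supported here:
# type 5: h = n p + 1/2 ; type 7 (R default): h = 1 + (n - 1) p
.qpos <- function(n, p, qtype) {
  h <- switch(as.character(qtype),
              "5" = n * p + 0.5,
              "7" = 1 + (n - 1) * p,
              stop("unsupported quantile type: ", qtype))
  pmin(pmax(h, 1), n)
}

# row-wise IQR of a numeric matrix (no NAs), vectorised via one global sort
.rowIQRs <- function(mat, qtype = 5) {
  m <- ncol(mat)
  o <- order(row(mat), mat)
  srt <- matrix(mat[o], ncol = m, byrow = TRUE)
  q <- function(p) {
    h <- .qpos(m, p, qtype)
    lo <- floor(h)
    hi <- ceiling(h)
    srt[, lo] + (h - lo) * (srt[, hi] - srt[, lo])
  }
  q(0.75) - q(0.25)
}

# add-one empirical p-value: P(null <= obs) or P(null >= obs)
.empiricalP <- function(null, obs, side = c("le", "ge")) {
  side <- match.arg(side)
  hits <- if (side == "le") sum(null <= obs) else sum(null >= obs)
  (1 + hits) / (length(null) + 1)
}
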