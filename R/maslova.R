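#' Divergence samples of related language pairs for one feature
#'
#' The transition-probability method works on a binary feature: the
#' designated value \code{a} is the globally most frequent attested value and
#' everything else is pooled as \code{b}.  Genera with at least two attested
#' languages are randomly partitioned into \code{n_samples} disjoint groups;
#' within each group one random attested pair is drawn per genus.  Each group
#' yields a divergence rate D (proportion of pairs whose members differ) and a
#' value frequency p (share of the designated value among the sampled
#' languages).
#'
#' @param table a \linkS4class{TypologyTable} whose languages carry a
#'   \code{genus} column.
#' @param f feature id.
#' @param n_samples number of disjoint groups (default 2, the minimum that
#'   identifies the two transition probabilities).
#' @param seed integer seed.
#' @return list of samples, each a list with \code{pairs} (2-column matrix of
#'   language ids), \code{D}, \code{p}, \code{n_pairs}.
#' @export
maslovaSamples <- function(table, f, n_samples = 2, seed = 1L) {
  v <- .featureRow(table, f)
  genus <- as.character(languageData(table)$genus)
  att <- !is.na(v)
  tab <- table(v[att])
  if (length(tab) == 0) stop("feature ", f, " has no attested values")
  a_val <- names(tab)[which.max(tab)]
  usable <- names(which(tapply(att, genus, sum) >= 2))
  if (length(usable) < 2 * n_samples)
    stop("need at least ", 2 * n_samples, " genera with >=2 attested languages for feature ",
         f, "; found ", length(usable))
  set.seed(seed)
  grp <- sample(rep_len(seq_len(n_samples), length(usable)))
  ids <- languageIds(table)
  lapply(seq_len(n_samples), function(g) {
    gens <- usable[grp == g]
    pairs <- t(vapply(gens, function(gn) {
      cand <- ids[genus == gn & att]
      sample(cand, 2)
    }, character(2)))
    x1 <- v[pairs[, 1]]; x2 <- v[pairs[, 2]]
    D <- mean(x1 != x2)
    p <- mean(c(x1, x2) == a_val)
    list(pairs = pairs, D = D, p = p, n_pairs = nrow(pairs), value_a = a_val)
  })
}

#' Solve the two-lineage divergence system for transition probabilities
#'
#' Under the binary model, a pair of related languages whose common ancestor
#' carried value a differs with probability 2*alpha*(1-alpha) (exactly one
#' lineage switched), and analogously 2*beta*(1-beta) from ancestor b, so each
#' sample gives D_i = p_i * 2 alpha (1-alpha) + (1-p_i) * 2 beta (1-beta).
#' Writing u = 2 alpha (1-alpha), v = 2 beta (1-beta) makes the system linear;
#' it is solved by box-constrained least squares over (u, v) in [0, 1/2]^2 and
#' inverted taking the smaller roots, which is the solution with the smallest
#' alpha + beta.  The stability score is the expected per-unit-time
#' probability of no change, 1 - [p alpha + (1-p) beta], with p the pooled
#' frequency of the designated value.
#'
#' @param samples a list of at least two samples from
#'   \code{\link{maslovaSamples}} with distinct p values.
#' @param tol maximum acceptable root-mean-square residual of the fitted D
#'   values; larger residuals return \code{NA} rates with the residual as a
#'   diagnostic.
#' @return list with \code{alpha}, \code{beta}, \code{stability},
#'   \code{p_stationary} (beta/(alpha+beta), NA when alpha = beta = 0),
#'   \code{residual}.
#' @export
maslovaSolve <- function(samples, tol = 0.2) {
  if (length(samples) < 2) stop("need at least 2 samples")
  D <- vapply(samples, `[[`, 0, "D")
  p <- vapply(samples, `[[`, 0, "p")
  w <- vapply(samples, `[[`, 0, "n_pairs")
  if (diff(range(p)) < 1e-9)
    stop("samples have equal value frequencies; the system is underdetermined")
  obj <- function(uv) sum(w * (D - (p * uv[1] + (1 - p) * uv[2]))^2)
  fit <- stats::optim(c(0.25, 0.25), obj, method = "L-BFGS-B",
                      lower = c(0, 0), upper = c(0.5, 0.5))
  u <- fit$par[1]; v <- fit$par[2]
  resid <- sqrt(fit$value / sum(w))
  if (resid > tol) return(list(alpha = NA_real_, beta = NA_real_,
                               stability = NA_real_, p_stationary = NA_real_,
                               residual = resid))
  alpha <- (1 - sqrt(pmax(0, 1 - 2 * u))) / 2   # smaller root of 2a(1-a) = u
  beta <- (1 - sqrt(pmax(0, 1 - 2 * v))) / 2
  n_lang <- 2 * vapply(samples, `[[`, 0, "n_pairs")
  p_hat <- sum(p * n_lang) / sum(n_lang)
  list(alpha = alpha, beta = beta,
       stability = 1 - (p_hat * alpha + (1 - p_hat) * beta),
       p_stationary = if (alpha + beta > 0) beta / (alpha + beta) else NA_real_,
       residual = resid)
}

#' Transition-probability stability of a feature (method M)
#'
#' Repeats the sample-split-and-solve procedure over \code{n_splits} random
#' disjoint splits of the genera and reports the median of the valid
#' solutions, which smooths the sampling noise of individual splits.
#'
#' @inheritParams maslovaSamples
#' @param n_splits number of random genus splits.
#' @param n_samples groups per split.
#' @return list with medians \code{stability}, \code{alpha}, \code{beta} and
#'   the count \code{n_valid} of splits that produced a solution; all-NA when
#'   no split did.
#' @export
maslovaStability <- function(table, f, n_splits = 50, n_samples = 2, seed = 1L) {
  sols <- vector("list", n_splits)
  for (b in seq_len(n_splits)) {
    sols[[b]] <- tryCatch({
      s <- maslovaSamples(table, f, n_samples = n_samples, seed = seed + b)
      maslovaSolve(s)
    }, error = function(e) NULL)
  }
  ok <- !vapply(sols, is.null, TRUE)
  st <- vapply(sols[ok], `[[`, 0, "stability")
  al <- vapply(sols[ok], `[[`, 0, "alpha")
  be <- vapply(sols[ok], `[[`, 0, "beta")
  valid <- !is.na(st)
  if (!any(valid)) return(list(stability = NA_real_, alpha = NA_real_,
                               beta = NA_real_, n_valid = 0L))
  list(stability = stats::median(st[valid]), alpha = stats::median(al[valid]),
       beta = stats::median(be[valid]), n_valid = sum(valid))
}
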