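#' Configuration for a synthetic typological world
#'
#' The generator emulates the statistical structure the stability estimators
#' assume: multiple language families evolving as trees, k-state features
#' changing under per-feature Markov rates, horizontal borrowing between
#' areal neighbours, and missing-at-random attestation.  Defaults give a
#' WALS-like desk-scale world of 30 families x 4 genera x 3 languages with 40
#' features whose change rates span a 40-fold range.
#'
#' @param n_families number of independent families.
#' @param genera_per_family genera in each family.
#' @param languages_per_genus languages in each genus.
#' @param n_features number of features.
#' @param k_states integer vector the per-feature state count is sampled
#'   from.
#' @param change_rate per-feature substitution rate per unit branch length;
#'   either a vector of length \code{n_features} or \code{NULL} to sample
#'   log-uniformly from \code{rate_range}.
#' @param rate_range range for sampled change rates.
#' @param borrow_rate per-feature probability that a language replaces its
#'   value by an areal neighbour's after vertical evolution; scalar or vector.
#' @param n_areas number of areal units; areas are assigned to whole genera
#'   so families span areas.
#' @param missing_fraction i.i.d. probability that a cell is masked.
#' @param seed integer seed (required for reproducibility).
#' @return a list of class \code{"typostab_sim_config"}.
#' @export
simulationConfig <- function(n_families = 30, genera_per_family = 4,
                             languages_per_genus = 3, n_features = 40,
                             k_states = 2:5, change_rate = NULL,
                             rate_range = c(0.05, 2), borrow_rate = 0,
                             n_areas = 6, missing_fraction = 0.1, seed = 1L) {
  cfg <- list(n_families = n_families, genera_per_family = genera_per_family,
              languages_per_genus = languages_per_genus,
              n_features = n_features, k_states = k_states,
              change_rate = change_rate, rate_range = rate_range,
              borrow_rate = borrow_rate, n_areas = n_areas,
              missing_fraction = missing_fraction, seed = as.integer(seed))
  stopifnot(cfg$n_families >= 1, cfg$genera_per_family >= 1,
            cfg$languages_per_genus >= 1, cfg$n_features >= 1,
            all(cfg$k_states >= 2),
            all(cfg$borrow_rate >= 0), all(cfg$borrow_rate <= 1),
            cfg$missing_fraction >= 0, cfg$missing_fraction < 1)
  if (!is.null(cfg$change_rate)) {
    stopifnot(all(cfg$change_rate >= 0))
    if (length(cfg$change_rate) == 1)
      cfg$change_rate <- rep(cfg$change_rate, cfg$n_features)
    stopifnot(length(cfg$change_rate) == cfg$n_features)
  }
  class(cfg) <- "typostab_sim_config"
  cfg
}

# simulate one feature down a tree under the symmetric k-state model;
# returns tip states named by tip label
.simulateMk <- function(tree, k, rate) {
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  state <- integer(n_node)
  root <- n_tip + 1L
  state[root] <- sample.int(k, 1)
  tr <- ape::reorder.phylo(tree, "cladewise")   # parents before children
  for (e in seq_len(nrow(tr$edge))) {
    parent <- tr$edge[e, 1]; child <- tr$edge[e, 2]
    p <- .mkP(k, rate, tr$edge.length[e])
    s <- state[parent]
    if (stats::runif(1) < p$same) {
      state[child] <- s
    } else {
      others <- seq_len(k)[-s]
      state[child] <- others[sample.int(length(others), 1L)]
    }
  }
  setNames(state[seq_len(n_tip)], tree$tip.label)
}

# one family tree: per genus a pure-birth (Yule) crown at depth 0.5 attached
# to the family root, total tip depth 1; singleton genera attach directly
.familyTree <- function(family, genera, n_lang) {
  parts <- character(length(genera))
  tip_names <- list()
  for (g in seq_along(genera)) {
    labs <- sprintf("%s_%s_L%02d", family, genera[g], seq_len(n_lang))
    tip_names[[g]] <- labs
    if (n_lang == 1) {
      parts[g] <- paste0(labs, ":1")
    } else {
      sub <- ape::rphylo(n_lang, birth = 1, death = 0)
      depth <- max(ape::node.depth.edgelength(sub))
      sub$edge.length <- sub$edge.length * (0.5 / depth)
      sub$tip.label <- labs
      nw <- ape::write.tree(sub)
      parts[g] <- paste0(sub("\\);$", "):0.5", sub("^\\(", "(", nw)))
    }
  }
  tree <- ape::read.tree(text = paste0("(", paste(parts, collapse = ","), ");"))
  tree$family_id <- family
  tree
}

#' Simulate a typological world with known ground truth
#'
#' Per family a Yule genus structure is drawn (genus crowns at half the tip
#' depth, unit total depth); each feature evolves independently along the
#' branches under the symmetric k-state Markov model at its change rate; a
#' borrowing sweep then replaces, with the feature's borrowing probability,
#' each language's value by that of a uniformly chosen same-area language
#' (synchronously, from the pre-sweep values); finally cells are masked
#' i.i.d. at the missing fraction.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @return a \linkS4class{SimulatedWorld}.
#' @examples
#' w <- simulateWorld(simulationConfig(n_families = 4, n_features = 5, seed = 7))
#' worldTruth(w)
#' @export
simulateWorld <- function(config) {
  stopifnot(inherits(config, "typostab_sim_config"))
  set.seed(config$seed)
  n_feat <- config$n_features
  k <- if (length(config$k_states) == 1) rep(config$k_states, n_feat)
       else sample(config$k_states, n_feat, replace = TRUE)
  rate <- config$change_rate
  if (is.null(rate)) {
    lr <- log(config$rate_range)
    rate <- exp(stats::runif(n_feat, lr[1], lr[2]))
  }
  borrow <- rep_len(config$borrow_rate, n_feat)
  fams <- sprintf("Fam%02d", seq_len(config$n_families))
  genera <- sprintf("G%02d", seq_len(config$genera_per_family))
  trees <- lapply(fams, .familyTree, genera = genera,
                  n_lang = config$languages_per_genus)
  names(trees) <- fams
  lang_ids <- unlist(lapply(trees, `[[`, "tip.label"), use.names = FALSE)
  n_lang <- length(lang_ids)
  lang_fam <- rep(fams, vapply(trees, function(t) length(t$tip.label), 0L))
  lang_gen <- sub("^(Fam[0-9]+)_(G[0-9]+)_.*$", "\\1.\\2", lang_ids)
  # areas assigned to whole genera so families span areas like WALS families
  gen_units <- unique(lang_gen)
  gen_area <- setNames(sample(sprintf("A%d", seq_len(config$n_areas)),
                              length(gen_units), replace = TRUE), gen_units)
  lang_area <- unname(gen_area[lang_gen])
  values <- matrix(NA_character_, n_feat, n_lang,
                   dimnames = list(seq_len(n_feat), lang_ids))
  root_states <- integer(n_feat)
  for (f in seq_len(n_feat)) {
    tips <- do.call(c, unname(lapply(trees, .simulateMk, k = k[f], rate = rate[f])))
    tips <- tips[lang_ids]
    if (borrow[f] > 0) {
      pre <- tips
      borrowers <- which(stats::runif(n_lang) < borrow[f])
      for (b in borrowers) {
        donors <- which(lang_area == lang_area[b])
        donors <- donors[donors != b]
        if (length(donors)) tips[b] <- pre[donors[sample.int(length(donors), 1L)]]
      }
    }
    values[f, ] <- paste0("v", tips)
  }
  if (config$missing_fraction > 0) {
    mask <- matrix(stats::runif(n_feat * n_lang) < config$missing_fraction,
                   n_feat, n_lang)
    values[mask] <- NA_character_
  }
  tab <- TypologyTable(values,
                       languages = data.frame(language_id = lang_ids,
                                              family = lang_fam,
                                              genus = lang_gen,
                                              area = lang_area,
                                              stringsAsFactors = FALSE),
                       features = data.frame(feature_id = seq_len(n_feat),
                                             name = sprintf("F%02d", seq_len(n_feat))))
  truth <- data.frame(feature_id = seq_len(n_feat), k = k,
                      change_rate = rate, borrow_rate = borrow)
  methods::new("SimulatedWorld", table = tab, truth = truth, trees = trees,
               config = unclass(config))
}

#' Recovery of the simulated ground truth by stability estimates
#'
#' Spearman correlation (with p-values) of each method's stability estimate
#' with the negated true change rate and, separately, the negated borrowing
#' rate: an estimator that recovers stability should correlate positively
#' with both negations.
#'
#' @param world a \linkS4class{SimulatedWorld}.
#' @param estimates a \linkS4class{StabilityMatrix} computed on
#'   \code{worldTable(world)} (e.g. by \code{\link{estimateStability}}).
#' @return data.frame with one row per method: \code{method_id},
#'   \code{rho_change}, \code{p_change}, \code{rho_borrow}, \code{p_borrow},
#'   \code{n}.
#' @export
recoveryReport <- function(world, estimates) {
  truth <- worldTruth(world)
  raw <- rawMatrix(estimates)
  idx <- match(featureIds(estimates), truth$feature_id)
  if (anyNA(idx)) stop("estimates cover features absent from the world")
  rows <- lapply(colnames(raw), function(m) {
    est <- raw[, m]
    ok <- !is.na(est)
    res <- data.frame(method_id = m, rho_change = NA_real_, p_change = NA_real_,
                      rho_borrow = NA_real_, p_borrow = NA_real_, n = sum(ok))
    if (sum(ok) >= 3) {
      ct <- suppressWarnings(stats::cor.test(est[ok], -truth$change_rate[idx][ok],
                                             method = "spearman", exact = FALSE))
      res$rho_change <- unname(ct$estimate); res$p_change <- ct$p.value
      if (stats::sd(truth$borrow_rate[idx][ok]) > 0) {
        cb <- suppressWarnings(stats::cor.test(est[ok], -truth$borrow_rate[idx][ok],
                                               method = "spearman", exact = FALSE))
        res$rho_borrow <- unname(cb$estimate); res$p_borrow <- cb$p.value
      }
    }
    res
  })
  do.call(rbind, rows)
}
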