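# independent oracles, written directly from the definitions and kept free of
# the package's implementation paths

# overall distance: explicit double loop over pairs and features
brute_overall <- function(table, feature_set = featureIds(table)) {
  v <- featureValues(table)[match(feature_set, featureIds(table)), , drop = FALSE]
  n <- ncol(v)
  d <- matrix(0, n, n)
  for (a in seq_len(n)) for (b in seq_len(n)) {
    if (a == b) next
    both <- !is.na(v[, a]) & !is.na(v[, b])
    d[a, b] <- if (any(both)) mean(2 * (v[both, a] != v[both, b])) else 1
  }
  dimnames(d) <- list(languageIds(table), languageIds(table))
  d
}

# coherence over ALL ordered triplets, triple loop
brute_cc <- function(table, f) {
  ov <- suppressMessages(overallDistanceMatrix(table))
  df <- featureDistanceMatrix(table, f)
  n <- ncol(table)
  num <- den <- 0
  for (a in seq_len(n)) for (b in seq_len(n)) for (cc in seq_len(n)) {
    if (a == b || a == cc || b == cc) next
    num <- num + df[a, cc] + df[cc, b] - df[a, b]
    den <- den + ov[a, cc] + ov[cc, b] - ov[a, b]
  }
  num / den
}

# rank consistency straight from the definition, loops only
brute_cr <- function(table, f) {
  ov <- suppressMessages(overallDistanceMatrix(table))
  v <- featureValues(table)[match(f, featureIds(table)), ]
  n <- ncol(table)
  scores <- c()
  for (l in which(!is.na(v))) {
    S <- setdiff(which(!is.na(v) & v == v[l]), l)
    if (!length(S)) next
    rank_of <- function(lp) {
      cnt <- 0
      for (ls in seq_len(n)) if (ls != l && ov[ls, l] < ov[lp, l]) cnt <- cnt + 1
      cnt
    }
    all_r <- sapply(setdiff(seq_len(n), l), rank_of)
    s <- sum(sapply(S, rank_of))
    k <- length(S)
    m_l <- sum(sort(all_r)[1:k])
    M_l <- sum(rev(sort(all_r))[1:k])
    if (M_l == m_l) next
    scores <- c(scores, (s - m_l) / (M_l - m_l))
  }
  if (!length(scores)) return(NA_real_)
  mean(scores)
}

# exhaustive parsimony: enumerate states of internal nodes and missing tips
enum_parsimony <- function(tree, tip_values) {
  vals <- tip_values[tree$tip.label]
  states <- sort(unique(na.omit(vals)))
  k <- length(states)
  if (k == 1) return(0L)
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  free <- c(which(is.na(vals)), seq.int(n_tip + 1, n_node))
  fixed <- setNames(match(vals, states), seq_len(n_tip))
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), length(free))))
  best <- Inf
  for (g in seq_len(nrow(grid))) {
    assign_ <- rep(NA_integer_, n_node)
    assign_[seq_len(n_tip)] <- fixed
    assign_[free] <- grid[g, ]
    changes <- sum(assign_[tree$edge[, 1]] != assign_[tree$edge[, 2]])
    best <- min(best, changes)
  }
  as.integer(best)
}

# exhaustive Mk likelihood: sum over all internal-node state assignments
enum_mk_loglik <- function(tree, tip_values, k, rate) {
  vals <- tip_values[tree$tip.label]
  states <- sort(unique(na.omit(vals)))
  states <- c(states, paste0(".s", seq_len(max(0, k - length(states)))))
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  free <- c(which(is.na(vals)), seq.int(n_tip + 1, n_node))
  fixed <- match(vals, states)
  ptrans <- function(i, j, t) {
    e <- exp(-k * rate * t / (k - 1))
    if (i == j) 1 / k + (k - 1) / k * e else (1 - e) / k
  }
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), length(free))))
  total <- 0
  for (g in seq_len(nrow(grid))) {
    assign_ <- rep(NA_integer_, n_node)
    assign_[seq_len(n_tip)] <- fixed
    assign_[free] <- grid[g, ]
    lik <- 1 / k
    for (e in seq_len(nrow(tree$edge)))
      lik <- lik * ptrans(assign_[tree$edge[e, 1]], assign_[tree$edge[e, 2]],
                          tree$edge.length[e])
    total <- total + lik
  }
  log(total)
}

# random small tree, sometimes multifurcating, with a random tip state map
random_tree_instance <- function(seed, max_tips = 6, k = 2, n_missing = 1) {
  set.seed(seed)
  n <- sample(3:max_tips, 1)
  tree <- ape::rtree(n)
  tree$edge.length <- runif(nrow(tree$edge), 0.1, 1.5)
  if (runif(1) < 0.3 && n >= 4) tree <- ape::di2multi(tree, tol = 0.4)
  vals <- sample(letters[1:k], length(tree$tip.label), replace = TRUE)
  if (n_missing > 0 && length(tree$tip.label) > 2) {
    vals[sample(length(vals), min(n_missing, length(vals) - 2))] <- NA
  }
  list(tree = tree, tip_values = setNames(vals, tree$tip.label))
}
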