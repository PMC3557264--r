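classification <- data.frame(
  language_id = c("a1", "a2", "b1", "b2", "c1"),
  family = "Fam",
  genus = c("ga", "ga", "gb", "gb", "gc"),
  stringsAsFactors = FALSE)

test_that("taxonomy trees have the family-genus-language shape and round trip", {
  tree <- taxonomyToTree(classification, "Fam")
  expect_s3_class(tree, "phylo")
  expect_setequal(tree$tip.label, classification$language_id)
  expect_identical(tree$Nnode, 3L)              # root + two non-singleton genera
  expect_true(all(tree$edge.length == 1))
  # the singleton genus attaches directly under the root
  root <- length(tree$tip.label) + 1L
  c1 <- which(tree$tip.label == "c1")
  expect_identical(tree$edge[tree$edge[, 2] == c1, 1], root)
  # Newick round trip preserves the topology
  back <- ape::read.tree(text = ape::write.tree(tree))
  expect_identical(ape::dist.topo(tree, back)[1], 0)
  expect_error(taxonomyToTree(classification[1:2, ], "Fam"), "fewer than 3")
})

test_that("minimum change counts match forced cases", {
  tree <- ape::read.tree(text = "((t1:1,t2:1):1,(t3:1,t4:1):1);")
  expect_identical(fitchMinChanges(tree, c(t1 = "A", t2 = "A", t3 = "A", t4 = "A")), 0L)
  expect_identical(fitchMinChanges(tree, c(t1 = "A", t2 = "A", t3 = "B", t4 = "B")), 1L)
  expect_identical(fitchMinChanges(tree, c(t1 = "A", t2 = "B", t3 = "A", t4 = "B")), 2L)
  # missing tips are free wildcards
  expect_identical(fitchMinChanges(tree, c(t1 = "A", t2 = NA, t3 = "B", t4 = NA)), 1L)
  expect_true(is.na(fitchMinChanges(tree, c(t1 = "A", t2 = NA, t3 = NA, t4 = NA))))
  # star tree with k distinct singleton values needs k - 1 changes
  star <- ape::read.tree(text = "(s1:1,s2:1,s3:1,s4:1);")
  expect_identical(fitchMinChanges(star, c(s1 = "A", s2 = "B", s3 = "C", s4 = "D")), 3L)
})

test_that("parsimony counts equal exhaustive enumeration and an independent implementation", {
  for (seed in 1:60) {
    inst <- random_tree_instance(seed, max_tips = 6, k = sample(2:3, 1))
    got <- fitchMinChanges(inst$tree, inst$tip_values)
    if (sum(!is.na(inst$tip_values)) < 2) {
      expect_true(is.na(got)); next
    }
    expect_identical(got, enum_parsimony(inst$tree, inst$tip_values),
                     label = paste("instance", seed))
  }
  # cross-check against phangorn's Sankoff parsimony on complete binary trees
  for (seed in 61:70) {
    set.seed(seed)
    tree <- ape::rtree(6)
    vals <- setNames(sample(c("a", "b"), 6, TRUE), tree$tip.label)
    pd <- phangorn::phyDat(as.matrix(vals), type = "USER", levels = c("a", "b"))
    expect_identical(fitchMinChanges(tree, vals),
                     as.integer(phangorn::parsimony(tree, pd, method = "sankoff")))
  }
})

test_that("parsimony bounds hold on random instances", {
  for (seed in 101:140) {
    inst <- random_tree_instance(seed, max_tips = 6, k = 3, n_missing = 0)
    mc <- fitchMinChanges(inst$tree, inst$tip_values)
    n_distinct <- length(unique(na.omit(inst$tip_values)))
    expect_gte(mc, n_distinct - 1)
    expect_lte(mc, length(inst$tip_values) - 1)
  }
})

test_that("pruning likelihood matches limits and exhaustive state sums", {
  tree <- ape::read.tree(text = "((t1:1,t2:1):1,t3:1);")
  # rate 0: only the root draw is random
  expect_equal(mkLikelihood(tree, c(t1 = "A", t2 = "A", t3 = "A"), k = 2, rate = 0),
               log(1 / 2), tolerance = 1e-12)
  # saturation: every attested tip is an independent uniform draw
  expect_equal(mkLikelihood(tree, c(t1 = "A", t2 = "B", t3 = "A"), k = 2, rate = 1e4),
               3 * log(1 / 2), tolerance = 1e-6)
  # 3-tip enumeration identity
  vals <- c(t1 = "A", t2 = "B", t3 = "A")
  expect_equal(mkLikelihood(tree, vals, k = 2, rate = 0.7),
               enum_mk_loglik(tree, vals, k = 2, rate = 0.7), tolerance = 1e-12)
  # random instances, tolerance 1e-10 in log space (the full 200-instance
  # sweep runs in the acceptance suite)
  for (seed in 201:260) {
    k <- sample(2:3, 1)
    inst <- random_tree_instance(seed, max_tips = 6, k = k)
    if (sum(!is.na(inst$tip_values)) < 1) next
    rate <- runif(1, 0.05, 3)
    expect_lt(abs(mkLikelihood(inst$tree, inst$tip_values, k = k, rate = rate) -
                    enum_mk_loglik(inst$tree, inst$tip_values, k = k, rate = rate)),
              1e-10, label = paste("instance", seed))
  }
})

test_that("the ML rate is invariant under value relabelling and detects boundaries", {
  tree <- ape::read.tree(text = "((t1:1,t2:1):1,(t3:1,t4:1):1);")
  same <- mkRateML(tree, c(t1 = "A", t2 = "A", t3 = "A", t4 = "A"), k = 2)
  expect_identical(same$ml_rate, 0)
  expect_identical(same$boundary, "lower")
  r1 <- mkRateML(tree, c(t1 = "A", t2 = "B", t3 = "A", t4 = "B"), k = 2)
  r2 <- mkRateML(tree, c(t1 = "B", t2 = "A", t3 = "B", t4 = "A"), k = 2)
  expect_equal(r1$ml_rate, r2$ml_rate, tolerance = 1e-8)
})

test_that("ML rate agrees with an independent discrete-trait fitter", {
  set.seed(31)
  tree <- ape::rphylo(24, birth = 1, death = 0)
  depth <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length / depth * 2
  for (i in 1:3) {
    tips <- typostab:::.simulateMk(tree, k = 2, rate = 0.8)
    vals <- setNames(c("A", "B")[tips], names(tips))
    if (length(unique(vals)) < 2) next
    got <- mkRateML(tree, vals, k = 2)
    ref <- ape::ace(vals[tree$tip.label], tree, type = "discrete", model = "ER")
    expect_lt(abs(got$ml_rate - unname(ref$rates)) / max(got$ml_rate, 1e-6), 0.02)
  }
})

test_that("ML recovers the generating rate on 64-tip trees", {
  set.seed(8)
  tree <- ape::rphylo(64, birth = 1, death = 0)
  depth <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length / depth * 2
  rates <- vapply(1:50, function(i) {
    tips <- typostab:::.simulateMk(tree, k = 2, rate = 0.5)
    mkRateML(tree, setNames(letters[tips], names(tips)), k = 2)$ml_rate
  }, 0)
  expect_gte(median(rates), 0.35)
  expect_lte(median(rates), 0.70)
})

test_that("making a uniform clade discordant never lowers the ML rate", {
  tree <- ape::read.tree(
    text = "(((t1:1,t2:1):1,(t3:1,t4:1):1):1,((t5:1,t6:1):1,(t7:1,t8:1):1):1);")
  vals <- c(t1 = "A", t2 = "A", t3 = "A", t4 = "A",
            t5 = "B", t6 = "B", t7 = "B", t8 = "B")
  r0 <- mkRateML(tree, vals, k = 2)$ml_rate
  vals2 <- vals; vals2["t2"] <- "B"
  r1 <- mkRateML(tree, vals2, k = 2)$ml_rate
  vals3 <- vals2; vals3["t7"] <- "A"
  r2 <- mkRateML(tree, vals3, k = 2)$ml_rate
  expect_gte(r1, r0)
  expect_gte(r2, r1)
})

test_that("aggregated phylogenetic stability favours constant features and follows shared order", {
  # 3 families x 4 languages; feature 1 constant everywhere, feature 2 maximally mixed
  set.seed(5)
  v <- rbind(rep("a", 12),
             rep(c("a", "b"), 6),
             sample(c("a", "b"), 12, TRUE),
             sample(c("a", "b", "c"), 12, TRUE))
  tt <- TypologyTable(v,
                      languages = data.frame(language_id = paste0("l", 1:12),
                                             family = rep(c("F1", "F2", "F3"), each = 4),
                                             genus = rep(paste0("g", 1:6), each = 2),
                                             area = "A1"),
                      features = data.frame(feature_id = 1:4))
  d <- dediuStability(tt, min_family_size = 4)
  expect_identical(d$feature_id, 1:4)
  expect_true(all(d$n_families == 3))
  expect_identical(which.max(d$score), 1L)   # constant feature = most stable
  expect_identical(which.min(d$score), 2L)   # alternating feature = least stable
})
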