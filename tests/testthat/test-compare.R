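test_that("relative ranks rescale, tie and ignore monotone transforms as ranks should", {
  expect_identical(toRelativeRanks(c(3.2, 7.1, 9.9)), c(0, 0.5, 1))
  r <- toRelativeRanks(c(5, 5, 9))
  expect_identical(r[1], r[2])
  x <- c(0.2, 0.7, 0.4, 0.9, NA, 0.1)
  expect_identical(toRelativeRanks(x), toRelativeRanks(x^2))   # monotone on positives
  expect_identical(which(is.na(toRelativeRanks(x))), 5L)
  expect_error(toRelativeRanks(c(1, 1, 1)), "constant")
  expect_error(toRelativeRanks(c(1, NA, NA)), "non-missing")
})

test_that("the shared subset keeps only all-method features", {
  rk <- cbind(A = c(0, 0.5, 1, NA), B = c(1, 0.5, 0, 0.2))
  rownames(rk) <- 1:4
  sm <- StabilityMatrix(rk)
  expect_identical(sharedFeatureSubset(sm), c("1", "2", "3"))
  full <- StabilityMatrix(cbind(A = c(0, 1), B = c(1, 0)))
  expect_length(sharedFeatureSubset(full), 2)
})

test_that("correlations are symmetric, unit-diagonal and rank-invariant", {
  sm <- loadTable1Fixture()
  cors <- pairwiseCorrelations(sm)
  expect_true(isSymmetric(cors$spearman))
  expect_identical(unname(diag(cors$pearson)), rep(1, 8))
  # squaring a positive column leaves Spearman unchanged
  sub <- sharedFeatureSubset(sm)
  x <- comparisonRanks(sm, sub, rerank = FALSE)
  expect_equal(cor(x[, "CC"], x[, "CR"], method = "spearman"),
               cor((x[, "CC"] + 0.1)^2, x[, "CR"], method = "spearman"),
               tolerance = 1e-12)
})

test_that("collinear columns and oversized pair thresholds flag no outliers", {
  set.seed(2)
  base <- runif(30)
  rk <- cbind(A = base, B = base, C = base)
  rownames(rk) <- 1:30
  sm <- StabilityMatrix(apply(rk, 2, toRelativeRanks))
  expect_length(flagOutlierFeatures(sm, min_pairs = 1), 0)
  fix <- loadTable1Fixture()
  expect_length(flagOutlierFeatures(fix, min_pairs = 29), 0)  # more than #pairs
  expect_error(flagOutlierFeatures(fix, resid_threshold = -1), "positive")
})

test_that("method distances vanish for identical columns", {
  set.seed(4)
  v <- runif(20)
  rk <- cbind(A = v, B = v, C = rev(v))
  rownames(rk) <- 1:20
  sm <- StabilityMatrix(apply(rk, 2, toRelativeRanks))
  d <- methodDistances(sm, rerank = TRUE)
  expect_identical(unname(d["A", "B"]), 0)
  expect_gt(d["A", "C"], 0)
  expect_true(all(diag(d) == 0))
})

test_that("classical MDS embeds a 3-4-5 triangle exactly and centres coordinates", {
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3)
  fit <- classicalMDS(d, dims = 2)
  expect_equal(unname(as.matrix(dist(fit$points))), d, tolerance = 1e-9)
  expect_equal(colMeans(fit$points), c(0, 0), tolerance = 1e-12)
  # full-rank embedding reproduces any Euclidean distance matrix
  set.seed(6)
  pts <- matrix(runif(5 * 4), 5, 4)
  dd <- as.matrix(dist(pts))
  fit2 <- classicalMDS(dd, dims = 4)
  expect_equal(unname(as.matrix(dist(fit2$points))), unname(dd), tolerance = 1e-9)
  # degenerate all-zero matrix
  z <- classicalMDS(matrix(0, 3, 3), dims = 2)
  expect_true(all(z$points == 0))
})

test_that("the random-point null matches its analytic mean and floor p-value", {
  null <- randomPointNull(c(min = 0, mean = 0, max = 0), n_points = 8,
                          dim = 62, n_sets = 1000, seed = 3)
  expect_identical(unname(null$p), rep(1 / 1001, 3))      # observed 0 -> floor
  expect_lt(abs(null$null["mean", "mean"] - sqrt(62 / 6)) / sqrt(62 / 6), 0.02)
})

test_that("PCA agreement conserves variance and finds planted correlation", {
  sm <- loadTable1Fixture()
  pca <- pcaAgreement(sm)
  expect_equal(sum(pca$pct_variance), 100, tolerance = 1e-9)
  # two perfectly correlated columns among noise load PC1 most heavily
  set.seed(10)
  shared <- runif(40)
  rk <- cbind(A = shared, B = shared,
              C = runif(40), D = runif(40), E = runif(40))
  rownames(rk) <- 1:40
  sm2 <- StabilityMatrix(apply(rk, 2, toRelativeRanks))
  p2 <- pcaAgreement(sm2, subset = featureIds(sm2))
  l1 <- abs(p2$loadings[, 1])
  expect_setequal(names(sort(l1, decreasing = TRUE))[1:2], c("A", "B"))
  # constant column is reported by name
  rk3 <- cbind(A = runif(41), B = rep(0.5, 41), C = runif(41))
  rownames(rk3) <- 1:41
  sm3 <- StabilityMatrix(rk3)
  expect_error(pcaAgreement(sm3, subset = featureIds(sm3)), "B")
})

test_that("IQR disagreement p-values obey the add-one bounds and Holm monotonicity", {
  set.seed(12)
  rk <- matrix(runif(80), 20, 4, dimnames = list(1:20, c("A", "B", "C", "D")))
  sm <- StabilityMatrix(apply(rk, 2, toRelativeRanks))
  out <- iqrDisagreement(sm, subset = featureIds(sm), n_randomizations = 200, seed = 5)
  tab <- out$table
  expect_true(all(tab$p_low_holm >= tab$p_low))
  expect_true(all(tab$p_high_holm >= tab$p_high))
  # Holm adjustment is monotone non-decreasing in raw-p order
  o <- order(tab$p_low)
  expect_true(all(diff(tab$p_low_holm[o]) >= -1e-12))
  # empirical p-values live in [1/(N+1), 1]
  N <- 200 * 20
  expect_true(all(tab$p_low >= 1 / (N + 1) & tab$p_low <= 1))
  expect_true(all(tab$p_high >= 1 / (N + 1) & tab$p_high <= 1))
})

test_that("IQR of an identical-rank row is zero", {
  v <- seq(0, 1, length.out = 10)
  rk <- cbind(A = v, B = v, C = v, D = v)
  rownames(rk) <- 1:10
  sm <- StabilityMatrix(rk)
  out <- iqrDisagreement(sm, subset = featureIds(sm), n_randomizations = 50, seed = 1)
  expect_true(all(out$table$iqr == 0))
  expect_true(all(out$table$range == 0))
})

test_that("the area ANOVA reduces to the squared t statistic with two groups", {
  set.seed(14)
  s <- c(rnorm(8, 0), rnorm(8, 1))
  a <- rep(c("X", "Y"), each = 8)
  fit <- areaAnova(s, a)
  tt <- t.test(s ~ a, var.equal = TRUE)
  expect_equal(fit$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(fit$p, tt$p.value, tolerance = 1e-10)
  # identical means with internal spread: F near 0, p near 1
  s2 <- c(-1, 1, -1, 1, -1, 1)
  a2 <- rep(c("X", "Y", "Z"), each = 2)
  fit2 <- areaAnova(s2, a2)
  expect_lt(fit2$F, 1e-10)
  expect_gt(fit2$p, 0.999)
  # undersized groups are dropped with a warning
  expect_warning(areaAnova(c(s2, 5), c(a2, "W")), "dropping")
})

test_that("the comparison report is reproducible under a fixed seed", {
  sm <- loadTable1Fixture()
  r1 <- runComparison(sm, n_null = 100, seed = 11)
  r2 <- runComparison(sm, n_null = 100, seed = 11)
  expect_equal(r1[setdiff(names(r1), "config")], r2[setdiff(names(r2), "config")])
})
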