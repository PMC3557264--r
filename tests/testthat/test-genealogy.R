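# families with controllable internal structure
family_table <- function(fam_values, area = NULL) {
  v <- matrix(unlist(fam_values), nrow = 1)
  fam <- rep(names(fam_values), lengths(fam_values))
  n <- ncol(v)
  if (is.null(area)) area <- rep("A1", n)
  TypologyTable(v,
                languages = data.frame(language_id = paste0("l", seq_len(n)),
                                       family = fam, genus = fam, area = area),
                features = data.frame(feature_id = 1L))
}

test_that("metric C is 1 for uniform families and matches hand counts", {
  # three families, each internally uniform, different values across families
  tt <- family_table(list(F1 = c("a", "a", "a"), F2 = c("b", "b"), F3 = c("c", "c", "c")))
  w <- wichmannMetricC(tt, 1)
  expect_identical(w$R_bar, 1)
  expect_identical(w$w_metric, 1)
  # hand-computed toy: F1 = (a,a,b), F2 = (a,b), F3 = (b,b)
  tt2 <- family_table(list(F1 = c("a", "a", "b"), F2 = c("a", "b"), F3 = c("b", "b")))
  # R_g: F1 = 1/3, F2 = 0, F3 = 1; weights N-1: 2, 1, 1
  R_bar <- (2 * (1/3) + 1 * 0 + 1 * 1) / 4
  # cross-family pairs: F1xF2 6, F1xF3 6, F2xF3 4 = 16; same-valued:
  # F1xF2: a-a 2, b-b 1 = 3 ; F1xF3: b-b 2 ; F2xF3: b-b 2  => 7/16
  U <- 7 / 16
  w2 <- wichmannMetricC(tt2, 1)
  expect_equal(w2$R_bar, R_bar, tolerance = 1e-12)
  expect_equal(w2$U, U, tolerance = 1e-12)
  expect_equal(w2$w_metric, (R_bar - U) / (1 - U), tolerance = 1e-12)
})

test_that("metric C equals brute-force pair enumeration on random tables", {
  for (seed in 1:5) {
    set.seed(seed)
    n_fam <- 4
    vals <- lapply(seq_len(n_fam), function(i) sample(c("a", "b", "c"), 3 + i %% 2, TRUE))
    names(vals) <- paste0("F", seq_len(n_fam))
    tt <- family_table(vals)
    got <- wichmannMetricC(tt, 1)
    # brute force over all language pairs
    v <- featureValues(tt)[1, ]; fam <- as.character(languageData(tt)$family)
    same <- outer(v, v, "=="); cross <- outer(fam, fam, "!=")
    ut <- upper.tri(same)
    U <- sum(same[ut & cross]) / sum(ut & cross)
    Rg <- sapply(names(vals), function(g) {
      s <- same[fam == g, fam == g]; mean(s[upper.tri(s)])
    })
    Ng <- lengths(vals)
    R_bar <- sum((Ng - 1) * Rg) / sum(Ng - 1)
    expect_equal(got$U, U, tolerance = 1e-12)
    expect_equal(got$R_bar, R_bar, tolerance = 1e-12)
  }
})

test_that("metric C is near zero when values ignore family structure", {
  # one table, many i.i.d. features = replicates under the null
  set.seed(77)
  n_fam <- 30; n_per <- 5; n_rep <- 500
  v <- matrix(sample(c("a", "b"), n_rep * n_fam * n_per, replace = TRUE),
              n_rep, n_fam * n_per)
  tt <- TypologyTable(v,
                      languages = data.frame(language_id = paste0("l", seq_len(n_fam * n_per)),
                                             family = rep(paste0("F", 1:n_fam), each = n_per),
                                             genus = rep(paste0("F", 1:n_fam), each = n_per),
                                             area = "A1"),
                      features = data.frame(feature_id = seq_len(n_rep)))
  ws <- vapply(seq_len(n_rep), function(f) wichmannMetricC(tt, f)$w_metric, 0)
  expect_lt(abs(mean(ws)), 0.02)
})

test_that("homogeneity ratio reproduces forced examples and the brute-force sum", {
  # two areas each mixing two internally-fixed families -> h_fam 1, h_area 0.5
  tt <- family_table(list(F1 = c("a", "a"), F2 = c("b", "b"),
                          F3 = c("a", "a"), F4 = c("b", "b")),
                     area = c("X", "X", "X", "X", "Y", "Y", "Y", "Y"))
  p <- parkvallRatio(tt, 1)
  expect_identical(p$h_family, 1)
  expect_identical(p$h_area, 0.5)
  expect_identical(p$p_ratio, 2)
  # constant feature -> ratio 1
  tc <- family_table(list(F1 = c("a", "a"), F2 = c("a", "a")), area = c("X", "X", "Y", "Y"))
  expect_identical(parkvallRatio(tc, 1)$p_ratio, 1)
  # random toy vs direct sum of squared shares
  set.seed(9)
  vals <- list(F1 = sample(letters[1:3], 4, TRUE), F2 = sample(letters[1:3], 4, TRUE),
               F3 = sample(letters[1:3], 3, TRUE), F4 = sample(letters[1:3], 3, TRUE))
  area <- rep(c("X", "Y"), each = 7)
  tt2 <- family_table(vals, area = area)
  got <- parkvallRatio(tt2, 1)
  herf <- function(x) sum((table(x) / length(x))^2)
  v <- featureValues(tt2)[1, ]
  fam <- as.character(languageData(tt2)$family)
  h_f <- mean(sapply(unique(fam), function(g) herf(v[fam == g])))
  h_a <- mean(sapply(unique(area), function(g) herf(v[area == g])))
  expect_equal(got$h_family, h_f, tolerance = 1e-12)
  expect_equal(got$h_area, h_a, tolerance = 1e-12)
  expect_equal(got$p_ratio, h_f / h_a, tolerance = 1e-12)
})

test_that("the accepted-families variant restricts the family set", {
  tt <- family_table(list(`Indo-European` = c("a", "a"), Uralic = c("b", "b"),
                          Madeup = c("a", "b"), Turkic = c("a", "a")),
                     area = rep(c("X", "Y"), 4))
  all_f <- parkvallRatio(tt, 1, "all")
  acc <- parkvallRatio(tt, 1, "accepted12")
  expect_identical(all_f$n_families, 4L)
  expect_identical(acc$n_families, 3L)
  expect_gt(acc$h_family, all_f$h_family)  # the mixed made-up family is dropped
})

test_that("genealogical estimators are invariant to value relabelling and language order", {
  set.seed(13)
  vals <- list(F1 = sample(c("a", "b"), 5, TRUE), F2 = sample(c("a", "b"), 5, TRUE),
               F3 = sample(c("a", "b"), 4, TRUE))
  tt <- family_table(vals, area = rep(c("X", "Y"), length.out = 14))
  relab <- chartr("ab", "ba", featureValues(tt))
  tt2 <- TypologyTable(relab, languages = as.data.frame(languageData(tt)),
                       features = as.data.frame(featureData(tt)))
  expect_identical(wichmannMetricC(tt, 1), wichmannMetricC(tt2, 1))
  expect_identical(parkvallRatio(tt, 1)[c("p_ratio", "h_family", "h_area")],
                   parkvallRatio(tt2, 1)[c("p_ratio", "h_family", "h_area")])
  perm <- sample(ncol(tt))
  tt3 <- TypologyTable(featureValues(tt)[, perm, drop = FALSE],
                       languages = as.data.frame(languageData(tt))[perm, ],
                       features = as.data.frame(featureData(tt)))
  expect_equal(wichmannMetricC(tt3, 1)$w_metric, wichmannMetricC(tt, 1)$w_metric)
  expect_equal(parkvallRatio(tt3, 1)$p_ratio, parkvallRatio(tt, 1)$p_ratio)
})
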