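test_that("AUC matches exhaustive pair enumeration", {
  r <- roc_auc(c(1, 2, 3, 4), c(0, 1, 0, 1))
  expect_equal(r$auc, 0.75)
  expect_equal(r$auc, oracle_auc(c(1, 2, 3, 4), c(0, 1, 0, 1)))
  # perfect separation
  expect_equal(roc_auc(c(5, 6, 7, 1, 2), c(1, 1, 1, 0, 0))$auc, 1.0)
  # all ties
  allt <- roc_auc(rep(3, 8), rep(c(0, 1), 4))
  expect_equal(allt$auc, 0.5)
  expect_gt(allt$p_two_sided, 0.9)
  for (seed in 1:5) {
    set.seed(seed)
    v <- sample(1:8, 12, replace = TRUE); l <- rep(c(0, 1), 6)
    expect_equal(roc_auc(v, l)$auc, oracle_auc(v, l))
  }
  expect_error(roc_auc(1:4, rep(1, 4)), "class error")
})

test_that("AUC is tie-symmetric and invariant under monotone transforms", {
  set.seed(4)
  v <- rnorm(30); l <- rep(c(0, 1), 15)
  expect_equal(roc_auc(v, l)$auc + roc_auc(-v, l)$auc, 1)
  expect_equal(roc_auc(exp(v), l)$auc, roc_auc(v, l)$auc)
  expect_equal(roc_auc(rank(v), l)$auc, roc_auc(v, l)$auc)
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(12)
  v <- rnorm(40); l <- rep(c(0, 1), 20)
  expect_equal(roc_auc(v, l)$auc,
               as.numeric(pROC::auc(pROC::roc(l, v, quiet = TRUE, direction = "<"))))
})

test_that("exact and normal Mann-Whitney p agree within 0.01 on tie-free grids", {
  set.seed(8)
  for (n1 in c(10, 14, 20)) {
    for (rep_i in 1:3) {
      v <- sample(seq(0, 1, length.out = 2 * n1))  # tie-free
      l <- rep(c(0, 1), n1)
      pe <- roc_auc(v, l, p_method = "exact")$p_two_sided
      pn <- roc_auc(v, l, p_method = "normal")$p_two_sided
      expect_lt(abs(pe - pn), 0.01)
    }
  }
})

test_that("correlation matrices behave for monotone transforms and constants", {
  set.seed(2)
  x <- rnorm(20)
  tab <- feature_table(cbind(A = x, B = exp(x), C = -x, K = rep(1, 20)),
                       sprintf("S%d", 1:20), rep(c(0, 1), 10), "pre")
  expect_warning(cm <- correlation_matrix(tab, "spearman"), "constant")
  expect_equal(cm["A", "B"], 1)
  expect_equal(cm["A", "C"], -1)
  expect_equal(cm["A", "K"], 0)
  expect_equal(diag(cm), rep(1, 4), ignore_attr = TRUE)
  expect_equal(cm, t(cm))
  expect_identical(attr(cm, "constant_features"), "K")
})

test_that("Spearman matrix matches a hand-ranked 5-point computation", {
  # x ranks: 1 2 3 4 5 ; y values (10, 8, 9, 1, 2) -> ranks 5 3 4 1 2
  # d = (-4, -1, -1, 3, 3); rho = 1 - 6*36/(5*24) = -0.8
  tab <- feature_table(cbind(X = 1:5, Y = c(10, 8, 9, 1, 2)),
                       sprintf("S%d", 1:5), c(0, 0, 1, 1, 1), "pre")
  cm <- correlation_matrix(tab, "spearman")
  expect_equal(cm["X", "Y"], -0.8)
})

test_that("ICC(1,1) recovers the generating variance ratio", {
  expect_equal(icc(c(1, 2, 3, 4), c(1, 2, 3, 4))$icc, 1.0)
  set.seed(101)
  n <- 200
  for (frac in c(0.5, 0.9)) {
    sb <- sqrt(frac); se <- sqrt(1 - frac)
    subj <- rnorm(n, sd = sb)
    t1 <- subj + rnorm(n, sd = se); t2 <- subj + rnorm(n, sd = se)
    expect_lt(abs(icc(t1, t2)$icc - frac), 0.1)
  }
  # null: independent columns
  set.seed(102)
  expect_lt(abs(icc(rnorm(200), rnorm(200))$icc), 0.15)
  expect_error(icc(1:3, 1:4), "pairing error")
})

test_that("ICC is invariant under a common affine transform", {
  set.seed(33)
  a <- rnorm(50); b <- a + rnorm(50, sd = 0.3)
  r0 <- icc(a, b)$icc
  expect_equal(icc(3 * a - 7, 3 * b - 7)$icc, r0, tolerance = 1e-12)
  expect_identical(icc(a, b)$model, "ICC(1,1)")
  expect_identical(icc(a, b, model = "twoway_random")$model, "ICC(2,1)")
})

test_that("auc_report covers every requested feature with BH column", {
  set.seed(55)
  tab <- feature_table(matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("A", "B"))),
                       sprintf("S%d", 1:20), rep(c(0, 1), 10), "delta")
  rep <- auc_report(tab)
  expect_identical(rep$feature, c("A", "B"))
  expect_true(all(rep$p_adj_bh >= rep$p - 1e-12))
  expect_identical(unique(rep$timepoint), "delta")
})
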