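make_table <- function(mat, labels, tp = "pre") {
  feature_table(mat, sprintf("S%02d", seq_len(nrow(mat))), labels, tp)
}

test_that("delta table is cell-wise pre minus post, aligned by subject", {
  m <- matrix(c(1000, 800, 2, 3), 2, 2, dimnames = list(NULL, c("Volume", "F")))
  pre <- make_table(m, c(1, 0), "pre")
  post_m <- matrix(c(550, 790, 1, 5), 2, 2, dimnames = list(NULL, c("Volume", "F")))
  post <- make_table(post_m, c(1, 0), "post")
  # scramble post row order to force re-alignment
  post2 <- post[c(2, 1), ]
  attr(post2, "timepoint") <- "post"
  d <- delta_table(pre, post2)
  expect_equal(d$Volume, c(450, 10))
  expect_equal(d$F, c(1, -2))
  expect_identical(attr(d, "timepoint"), "delta")
  expect_equal(delta_table(pre, pre)$Volume, c(0, 0))
  bad <- make_table(matrix(1:2, 2, 1, dimnames = list(NULL, "G")), c(1, 0))
  expect_error(delta_table(pre, bad), "alignment")
})

test_that("delta volume equals the directly recomputed mask-volume difference", {
  coh <- generate_cohort(2, 2, seed = 31, grid_dim = 40, radius_range = c(5, 9))
  man <- feature_manifest(list(list(class = "size")))
  pre <- cohort_feature_table(coh, man, "pre")
  post <- cohort_feature_table(coh, man, "post")
  d <- delta_table(pre, post)
  direct <- sapply(coh, function(s) tumor_volume(s$pre$mask) - tumor_volume(s$post$mask))
  expect_equal(d$Volume, direct)
})

test_that("coefficient of variation matches hand arithmetic and its invariances", {
  expect_equal(coefficient_of_variation(c(2, 2, 2)), 0)
  expect_equal(coefficient_of_variation(c(1, 3)), sqrt(2) / 2, tolerance = 1e-12)
  x <- c(1.2, 5.4, -2, 7)
  expect_equal(coefficient_of_variation(-5 * x), coefficient_of_variation(x))
  expect_true(is.na(coefficient_of_variation(c(-1, 1))))
  expect_error(coefficient_of_variation(3), "at least 2")
})

test_that("selection keeps top-variance features and prunes duplicates", {
  set.seed(17)
  n <- 100
  base <- matrix(rnorm(n * 6), n, 6,
                 dimnames = list(NULL, paste0("F", 1:6)))
  base <- sweep(base, 2, seq(1, 3.5, by = 0.5), `*`)  # increasing variance
  base <- sweep(base, 2, rep(10, 6), `+`)
  tab <- cbind(base, Dup = base[, "F6"] * 2 + 1,       # rank-correlated copy
               Volume = rnorm(n, 500, 5), Max_Diameter = rnorm(n, 20, 0.2))
  ft <- make_table(tab, rep(c(0, 1), n / 2), "delta")
  sel <- select_features(ft, k = 7, corr_threshold = 0.95)
  expect_true(xor("Dup" %in% sel$selected, "F6" %in% sel$selected))
  expect_true(all(c("Volume", "Max_Diameter") %in% sel$selected))
  # mutually independent columns at n=100 survive pruning entirely
  set.seed(18)
  ind <- matrix(rnorm(n * 8, mean = 5), n, 8,
                dimnames = list(NULL, paste0("G", 1:8)))
  ft2 <- make_table(cbind(ind, Volume = rnorm(n, 100, 1),
                          Max_Diameter = rnorm(n, 10, 0.1)),
                    rep(c(0, 1), n / 2), "delta")
  sel2 <- select_features(ft2, k = 8)
  expect_setequal(sel2$selected, c(paste0("G", 1:8), "Volume", "Max_Diameter"))
  # no surviving pair above the threshold
  cm <- abs(cor(as.matrix(ft[, setdiff(sel$selected, c("Volume", "Max_Diameter"))]),
                method = "spearman"))
  diag(cm) <- 0
  expect_lt(max(cm), 0.95)
  expect_error(select_features(ft, k = 0), "parameter error")
})

test_that("selection is invariant to feature column order", {
  set.seed(23)
  m <- matrix(rnorm(50 * 5, mean = 3), 50, 5, dimnames = list(NULL, paste0("F", 1:5)))
  ft <- make_table(m, rep(c(0, 1), 25), "delta")
  perm <- m[, c(4, 2, 5, 1, 3)]
  ftp <- make_table(perm, rep(c(0, 1), 25), "delta")
  expect_identical(select_features(ft, k = 3)$selected,
                   select_features(ftp, k = 3)$selected)
})

test_that("always-include features appear even with uncompetitive variance", {
  set.seed(5)
  m <- cbind(matrix(rnorm(40 * 3, mean = 2, sd = 5), 40, 3,
                    dimnames = list(NULL, paste0("F", 1:3))),
             Volume = rnorm(40, 1000, 0.01), Max_Diameter = rnorm(40, 30, 0.001))
  ft <- make_table(m, rep(c(0, 1), 20), "delta")
  sel <- select_features(ft, k = 2)
  expect_true(all(c("Volume", "Max_Diameter") %in% sel$selected))
  expect_length(sel$selected, 4)
})
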