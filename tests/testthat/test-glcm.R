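test_that("the 1D toy row reproduces the hand-enumerated matrix", {
  vol <- image_volume(array(c(1, 1, 2, 3), dim = c(4, 1, 1)), c(1, 1, 1))
  msk <- lesion_mask(array(1, dim = c(4, 1, 1)), c(1, 1, 1))
  P <- compute_glcm(vol, msk, 1, c(1, 0, 0), glcm_config(n_levels = 3))
  # pair multiset {(1,1),(1,2),(2,3)} plus transpose, 6 counts total
  expected <- matrix(c(2, 1, 0, 1, 0, 1, 0, 1, 0) / 6, 3, 3)
  expect_equal(unclass(P), expected, ignore_attr = TRUE)
})

test_that("co-occurrence matrices are normalized and symmetric when configured", {
  for (seed in 1:3) {
    pr <- toy_pair(seed, dim = c(5, 5, 5))
    P <- compute_glcm(pr$image, pr$mask, 1, c(1, 1, 0), glcm_config(n_levels = 8))
    expect_true(all(P >= 0))
    expect_equal(sum(P), 1)
    expect_equal(P, t(P))
  }
})

test_that("there are exactly 13 pairwise non-antiparallel directions", {
  dirs <- glcm_directions()
  expect_identical(dim(dirs), c(13L, 3L))
  for (i in 1:12) for (j in (i + 1):13) {
    expect_false(all(dirs[i, ] == dirs[j, ]) || all(dirs[i, ] == -dirs[j, ]))
  }
})

test_that("IMC1 is zero under marginal independence and MCC hits known values", {
  px <- c(0.5, 0.3, 0.2); py <- c(0.1, 0.6, 0.3)
  P <- outer(px, py)
  st <- glcm_statistics(P)
  expect_equal(st[["IMC1"]], 0, tolerance = 1e-12)
  # 2x2 diagonal matrix: Q has eigenvalues {1, 1} -> MCC = 1
  st2 <- glcm_statistics(matrix(c(0.5, 0, 0, 0.5), 2, 2))
  expect_equal(st2[["MCC"]], 1)
})

test_that("MCC stays within [0, 1] and degenerate matrices never yield NaN", {
  for (seed in 1:10) {
    set.seed(seed)
    P <- matrix(runif(16), 4, 4); P <- (P + t(P)); P <- P / sum(P)
    st <- glcm_statistics(P)
    expect_true(all(is.finite(st)))
    expect_gte(st[["MCC"]], 0); expect_lte(st[["MCC"]], 1)
  }
  # single occupied grey level
  P1 <- matrix(0, 4, 4); P1[2, 2] <- 1
  st1 <- glcm_statistics(P1)
  expect_true(all(is.finite(st1)))
  expect_equal(st1[["MCC"]], 1)
  expect_equal(st1[["IMC1"]], 0)
  expect_equal(st1[["Contrast"]], 0)
})

test_that("constant images give zero contrast and zero directional range", {
  img <- image_volume(array(42, dim = c(5, 5, 5)), c(1, 1, 1))
  msk <- lesion_mask(array(1, dim = c(5, 5, 5)), c(1, 1, 1))
  expect_equal(glcm_feature(img, msk, "Contrast", 1, "mean"), 0)
  expect_equal(glcm_feature(img, msk, "Entropy", 1, "range"), 0)
})

test_that("directional aggregation equals the mean of per-direction oracles", {
  pr <- toy_pair(5, dim = c(4, 4, 1))
  dirs <- glcm_directions()
  vals <- sapply(seq_len(nrow(dirs)), function(k) {
    P <- oracle_glcm(pr$image, pr$mask, 1, dirs[k, ], 8)
    if (is.null(P)) { st <- glcm_statistics(matrix(0, 8, 8)); return(0) }
    oracle_glcm_stats(P)[["Contrast"]]
  })
  expect_equal(glcm_feature(pr$image, pr$mask, "Contrast", 1, "mean",
                            glcm_config(n_levels = 8)),
               mean(vals), tolerance = 1e-12)
})

test_that("vectorized matrices match brute-force pair enumeration on toy volumes", {
  dirs <- glcm_directions()
  for (seed in 1:4) {
    pr <- toy_pair(seed + 100, dim = c(6, 6, 6))
    for (d in c(1, 4)) for (k in c(1, 5, 10, 13)) {
      Po <- oracle_glcm(pr$image, pr$mask, d, dirs[k, ], 8)
      Pv <- compute_glcm(pr$image, pr$mask, d, dirs[k, ], glcm_config(n_levels = 8))
      if (is.null(Po)) {
        expect_true(isTRUE(attr(Pv, "degenerate")))
      } else {
        expect_equal(unclass(Pv), Po, tolerance = 1e-12, ignore_attr = TRUE)
      }
    }
  }
})
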