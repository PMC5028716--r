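test_that("noise-free ball phantom voxelizes to the analytic sphere volume", {
  ph <- ball_phantom(6, spacing = 1, dim = 40)
  expect_lt(abs(tumor_volume(ph$mask) - 4 / 3 * pi * 6^3) / (4 / 3 * pi * 6^3), 0.05)
})

test_that("rendering is deterministic and interior voxels sit on the plateau", {
  p <- lesion_params(radii = c(7, 6, 5), bumpiness = 0.2, margin_width = 1)
  a <- render_lesion(p, 1, 48, seed = 5)
  b <- render_lesion(p, 1, 48, seed = 5)
  expect_identical(a$image$data, b$image$data)
  expect_identical(a$mask$data, b$mask$data)
  # with texture and noise off, deep-interior voxels equal lesion_hu
  p0 <- lesion_params(radii = c(7, 7, 7), bumpiness = 0, texture_sigma = 0,
                      noise_sigma = 0, margin_width = 1)
  r <- render_lesion(p0, 1, 48, seed = 1)
  ctr <- (dim(r$image$data) + 1) / 2
  deep <- r$image$data[(ctr[1] - 2):(ctr[1] + 2), (ctr[2] - 2):(ctr[2] + 2), ctr[3]]
  expect_true(all(abs(deep - p0$lesion_hu) < 0.5))
  bg <- r$image$data[1:3, 1:3, 1:3]
  expect_true(all(abs(bg - p0$parenchyma_hu) < 0.5))
})

test_that("a lesion larger than the grid is rejected", {
  p <- lesion_params(radii = c(30, 30, 30))
  expect_error(render_lesion(p, 1, 48, seed = 1), "geometry error")
})

test_that("cohort generation is seed-reproducible with the requested labels", {
  c1 <- generate_cohort(3, 2, seed = 9, grid_dim = 40, radius_range = c(5, 9))
  c2 <- generate_cohort(3, 2, seed = 9, grid_dim = 40, radius_range = c(5, 9))
  expect_identical(
    lapply(c1, function(s) s$pre$image$data),
    lapply(c2, function(s) s$pre$image$data))
  expect_identical(sapply(c1, `[[`, "label"), c(1L, 1L, 1L, 0L, 0L))
  c0 <- generate_cohort(0, 3, seed = 4, grid_dim = 40, radius_range = c(5, 9))
  expect_true(all(sapply(c0, `[[`, "label") == 0L))
})

test_that("mutant lesions shrink more than wild-type under the response model", {
  coh <- generate_cohort(8, 8, seed = 7, grid_dim = 56, radius_range = c(5, 12))
  ratio <- sapply(coh, function(s) tumor_volume(s$post$mask) / tumor_volume(s$pre$mask))
  lab <- sapply(coh, `[[`, "label")
  expect_lt(mean(ratio[lab == 1]), mean(ratio[lab == 0]))
})

test_that("test-retest pairs share geometry up to sub-voxel shift and noise", {
  tr1 <- generate_test_retest(3, seed = 11, grid_dim = 40, radius_range = c(5, 9))
  tr2 <- generate_test_retest(3, seed = 11, grid_dim = 40, radius_range = c(5, 9))
  expect_identical(tr1[[2]]$scan2$image$data, tr2[[2]]$scan2$image$data)
  # volumes nearly unchanged between the two scans of a pair
  v1 <- sapply(tr1, function(p) tumor_volume(p$scan1$mask))
  v2 <- sapply(tr1, function(p) tumor_volume(p$scan2$mask))
  expect_true(all(abs(v1 - v2) / v1 < 0.05))
})

test_that("zero noise and zero shift reproduce an identical scan", {
  p <- lesion_params(radii = c(6, 6, 6), noise_sigma = 0)
  model <- deltarad:::make_lesion_model(p, 3)
  s1 <- deltarad:::render_lesion_impl(model, 1, 40)
  s2 <- deltarad:::render_lesion_impl(model, 1, 40, shift = c(0, 0, 0))
  expect_identical(s1$image$data, s2$image$data)
  expect_identical(s1$mask$data, s2$mask$data)
})

test_that("delta volume separates the labels across seeds at study scale", {
  # default response model, 20 + 20 subjects: the delta-volume AUC should
  # clear 0.9 in at least 19 of 20 seeds
  hits <- sum(sapply(1:20, function(seed) {
    coh <- generate_cohort(20, 20, seed = seed)
    dv <- sapply(coh, function(s) tumor_volume(s$pre$mask) - tumor_volume(s$post$mask))
    lab <- sapply(coh, `[[`, "label")
    roc_auc(dv, lab)$auc >= 0.9
  }))
  expect_gte(hits, 19)
})

test_that("wider rendered margins yield flatter fitted sigmoid slopes", {
  slopes <- sapply(c(0.5, 1, 2), function(w) {
    p <- lesion_params(radii = c(6, 6, 6), bumpiness = 0, texture_sigma = 0,
                       noise_sigma = 0, margin_width = w)
    r <- render_lesion(p, 1, 48, seed = 1)
    sigmoid_margin_features(r$image, r$mask, sigmoid_config(5, 0.5, 60))[[2]]
  })
  expect_true(all(diff(slopes) < 0))
})
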