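test_that("NIfTI and NRRD round-trips preserve data, spacing and origin", {
  set.seed(42)
  a <- array(rnorm(10 * 10 * 10, sd = 100), dim = c(10, 10, 10))
  v <- image_volume(a, c(1.25, 0.7, 0.7), origin = c(-12, 3.5, 40))
  for (ext in c(".nii", ".nii.gz", ".nrrd")) {
    f <- withr::local_tempfile(fileext = ext)
    write_volume(v, f)
    b <- read_volume(f)
    expect_identical(b$data, v$data, label = ext)
    expect_identical(b$spacing, v$spacing, label = ext)
    expect_identical(b$origin, v$origin, label = ext)
  }
})

test_that("NIfTI and NRRD encodings of the same array read back equal", {
  set.seed(7)
  v <- image_volume(array(rnorm(64), dim = c(4, 4, 4)), c(2, 1, 0.5))
  f1 <- withr::local_tempfile(fileext = ".nii.gz")
  f2 <- withr::local_tempfile(fileext = ".nrrd")
  write_volume(v, f1); write_volume(v, f2)
  b1 <- read_volume(f1); b2 <- read_volume(f2)
  expect_identical(b1$data, b2$data)
  expect_identical(b1$spacing, b2$spacing)
  expect_identical(b1$origin, b2$origin)
})

test_that("non-3D payloads and bad headers are rejected with clear errors", {
  f4 <- withr::local_tempfile(fileext = ".nii")
  RNifti::writeNifti(RNifti::asNifti(array(0, dim = c(4, 4, 4, 2))), f4)
  expect_error(read_volume(f4), "dimensionality error")
  fbad <- withr::local_tempfile(fileext = ".nrrd")
  writeLines(c("NRRD0004", "dimension: 2", "sizes: 3 3", "encoding: raw", ""), fbad)
  expect_error(read_volume(fbad), "dimensionality error")
  ftxt <- withr::local_tempfile(fileext = ".nrrd")
  writeLines("not a header", ftxt)
  expect_error(read_volume(ftxt), "format error")
  expect_error(read_volume(withr::local_tempfile(fileext = ".png")), "file not found|format error")
})

test_that("validate_pair passes matched pairs and names the mismatched field", {
  pr <- toy_pair(1)
  expect_silent(out <- validate_pair(pr$image, pr$mask))
  expect_identical(out$image, pr$image)
  m_short <- lesion_mask(pr$mask$data[, , 1:5], pr$mask$spacing)
  expect_error(validate_pair(pr$image, m_short), "shape")
  m_sp <- lesion_mask(pr$mask$data, c(1, 1, 1.5))
  expect_error(validate_pair(pr$image, m_sp), "spacing")
  m_or <- lesion_mask(pr$mask$data, c(1, 1, 1), origin = c(0, 0, 1))
  expect_error(validate_pair(pr$image, m_or), "origin")
  m_empty <- lesion_mask(array(0, dim(pr$mask$data)), c(1, 1, 1))
  expect_error(validate_pair(pr$image, m_empty), "degenerate")
})

test_that("isotropic resampling preserves lesion volume and mask binarity", {
  ph <- ball_phantom(6, spacing = 1, dim = 40)
  # identity when target equals the current isotropic spacing
  same <- resample_isotropic(ph$image, ph$mask, 1.0)
  expect_identical(same$image$data, ph$image$data)
  # downsampling to 0.5 mm: volume within 5 %
  fine <- resample_isotropic(ph$image, ph$mask, 0.5)
  expect_equal(fine$image$spacing, rep(0.5, 3))
  v0 <- tumor_volume(ph$mask); v1 <- tumor_volume(fine$mask)
  expect_lt(abs(v1 - v0) / v0, 0.05)
  expect_true(all(fine$mask$data %in% c(0, 1)))
  # world extent preserved to within one voxel
  ext0 <- (dim(ph$image$data) - 1) * ph$image$spacing
  ext1 <- (dim(fine$image$data) - 1) * fine$image$spacing
  expect_true(all(abs(ext0 - ext1) <= 0.5 + 1e-9))
  expect_error(resample_isotropic(ph$image, ph$mask, 0), "positive")
})

test_that("anisotropic input resamples onto an isotropic grid", {
  set.seed(3)
  a <- array(rnorm(12 * 16 * 8), dim = c(12, 16, 8))
  m <- array(0, dim(a)); m[4:9, 5:12, 3:6] <- 1
  v <- image_volume(a, c(0.7, 0.7, 1.25)); msk <- lesion_mask(m, c(0.7, 0.7, 1.25))
  rs <- resample_isotropic(v, msk, 0.7)
  expect_equal(rs$image$spacing, rep(0.7, 3))
  v0 <- tumor_volume(msk)
  expect_lt(abs(tumor_volume(rs$mask) - v0) / v0, 0.25)
})

test_that("cohort manifest CSV round-trips through write_cohort/read_cohort", {
  ph1 <- ball_phantom(5, dim = 32); ph2 <- ball_phantom(6, dim = 32)
  coh <- list(subject_study("A", 1, ph1, ph2), subject_study("B", 0, ph2, ph1))
  d <- withr::local_tempdir()
  manifest <- write_cohort(coh, d)
  back <- read_cohort(manifest)
  expect_length(back, 2)
  expect_identical(back[[1]]$subject_id, "A")
  expect_identical(back[[1]]$label, 1L)
  expect_identical(back[[2]]$pre$image$data, ph2$image$data)
  expect_identical(back[[1]]$post$mask$data, ph2$mask$data)
})
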