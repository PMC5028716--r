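test_that("the default manifest expands to 183 unique names", {
  nms <- manifest_feature_names(default_manifest())
  expect_length(nms, 183)
  expect_false(anyDuplicated(nms) > 0)
  expect_true(all(c("Volume", "Max_Diameter", "Boundary_Radius_Std",
                    "Shape_SI6", "Sigmoid-Slope-Mean-d5", "Laws_Energy-10",
                    "Gabor_Energy-dir135-w3", "GLCM_IMC1-mean-d1",
                    "GLCM_MCC-mean-d4") %in% nms))
})

test_that("extraction follows the manifest exactly and is deterministic", {
  ph <- ball_phantom(6, dim = 40)
  vol_only <- feature_manifest(list(list(class = "size")))
  fv <- extract_features(ph$image, ph$mask, vol_only)
  expect_identical(names(fv), c("Volume", "Max_Diameter", "Boundary_Radius_Std"))
  expect_equal(fv[["Volume"]], tumor_volume(ph$mask))
  r <- render_lesion(lesion_params(radii = c(6, 5, 7)), 1, 48, seed = 12)
  small <- feature_manifest(list(
    list(class = "size"),
    list(class = "laws", ids = c(1, 11)),
    list(class = "glcm", statistics = c("Contrast", "MCC"), distances = 1,
         aggregations = "mean", n_levels = 16)))
  f1 <- extract_features(r$image, r$mask, small)
  f2 <- extract_features(r$image, r$mask, small)
  expect_identical(f1, f2)
  expect_true(all(is.finite(f1)))
})

test_that("manifest YAML round-trips", {
  m <- default_manifest()
  f <- withr::local_tempfile(fileext = ".yaml")
  write_manifest(m, f)
  back <- read_manifest(f)
  expect_identical(manifest_feature_names(back), manifest_feature_names(m))
})

test_that("mask-only features ignore intensity; energies are degree-2 homogeneous", {
  r <- render_lesion(lesion_params(radii = c(6, 5, 7), bumpiness = 0.2), 1, 48,
                     seed = 4)
  man <- feature_manifest(list(
    list(class = "size"),
    list(class = "shape_index", smoothing_sigma = 1.5),
    list(class = "laws", ids = c(3, 12))))
  f1 <- extract_features(r$image, r$mask, man)
  shifted <- image_volume(r$image$data * 5 + 30, r$image$spacing)
  f2 <- extract_features(shifted, r$mask, man)
  mask_only <- c("Volume", "Max_Diameter", "Boundary_Radius_Std",
                 paste0("Shape_SI", 1:9))
  expect_equal(f1[mask_only], f2[mask_only])
  # zero-mean Laws kernels kill the +30 offset; gain enters squared
  en <- setdiff(names(f1), mask_only)
  expect_equal(f2[en], 25 * f1[en], tolerance = 1e-8)
})

test_that("whole-voxel translation of volume and mask leaves features unchanged", {
  r <- render_lesion(lesion_params(radii = c(5, 5, 5), bumpiness = 0.1), 1, 44,
                     seed = 6)
  shift_arr <- function(a, s) {
    d <- dim(a); out <- array(a[1], d)
    out[(1 + s):d[1], (1 + s):d[2], (1 + s):d[3]] <-
      a[1:(d[1] - s), 1:(d[2] - s), 1:(d[3] - s)]
    out
  }
  man <- feature_manifest(list(
    list(class = "size"),
    list(class = "laws", ids = c(1, 14)),
    list(class = "glcm", statistics = c("Entropy", "IMC1"), distances = c(1, 4),
         aggregations = c("mean", "range"), n_levels = 16)))
  f1 <- extract_features(r$image, r$mask, man)
  f2 <- extract_features(
    image_volume(shift_arr(r$image$data, 3), r$image$spacing),
    lesion_mask(shift_arr(r$mask$data, 3), r$mask$spacing), man)
  expect_equal(f1, f2, tolerance = 1e-10)
})

test_that("extraction failures name the offending feature class", {
  ph <- ball_phantom(5, dim = 32)
  bad <- structure(list(entries = list(list(class = "laws", ids = 99))),
                   class = "feature_manifest")
  expect_error(extract_features(ph$image, ph$mask, bad), "laws")
})
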