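#' Parameters of a synthetic CT lesion phantom
#'
#' Describes one lesion as a perturbed ellipsoid with a sigmoid density
#' transition into lung parenchyma, a stationary correlated random-field
#' texture inside the lesion, and additive scan noise.
#'
#' @param radii length-3 positive vector, ellipsoid semi-axes in mm.
#' @param bumpiness amplitude of the low-order angular surface perturbation,
#'   as a fraction of the local radius (0 = perfect ellipsoid).
#' @param lesion_hu plateau intensity inside the lesion (HU).
#' @param parenchyma_hu background lung intensity (HU).
#' @param margin_width width of the sigmoid lesion-margin transition in mm
#'   (approximately the 12-88 percent distance of the logistic profile).
#' @param texture_sigma standard deviation (HU) of the intralesional
#'   correlated texture field.
#' @param texture_corr_len correlation length (mm) of the texture field.
#' @param noise_sigma standard deviation (HU) of i.i.d. additive scan noise.
#' @return A `lesion_params` list.
#' @export
lesion_params <- function(radii = c(8, 8, 8), bumpiness = 0.15,
                          lesion_hu = 30, parenchyma_hu = -780,
                          margin_width = 1.0, texture_sigma = 40,
                          texture_corr_len = 2.0, noise_sigma = 20) {
  stopifnot(length(radii) == 3, all(radii > 0), margin_width > 0,
            noise_sigma >= 0, texture_corr_len > 0, texture_sigma >= 0,
            bumpiness >= 0)
  structure(list(radii = as.numeric(radii), bumpiness = bumpiness,
                 lesion_hu = lesion_hu, parenchyma_hu = parenchyma_hu,
                 margin_width = margin_width, texture_sigma = texture_sigma,
                 texture_corr_len = texture_corr_len, noise_sigma = noise_sigma),
            class = "lesion_params")
}

#' Mutation-dependent treatment-response model
#'
#' Post-treatment lesions are re-rendered with per-axis radii scaled by
#' `ratio^(1/3)` where `ratio` (post/pre volume) is drawn from a label-
#' specific log-normal law. Mutant (label 1) lesions additionally get a
#' widened margin and a smoother (longer correlation length) texture,
#' emulating the regressing, blurring-margin phenotype of responders.
#'
#' @param mutant_volume_ratio,wt_volume_ratio length-2 vectors
#'   `c(meanlog, sdlog)` of the post/pre volume-ratio log-normal for
#'   mutants and wild-type subjects. Defaults give a mean ratio of about
#'   0.57 (mutant) versus 0.98 (wild-type).
#' @param mutant_margin_widening multiplicative factor on `margin_width`
#'   post-treatment for mutants.
#' @param mutant_texture_smoothing multiplicative factor on
#'   `texture_corr_len` post-treatment for mutants.
#' @return A `response_model` list.
#' @export
response_model <- function(mutant_volume_ratio = c(meanlog = log(0.55), sdlog = 0.25),
                           wt_volume_ratio = c(meanlog = log(0.98), sdlog = 0.08),
                           mutant_margin_widening = 1.6,
                           mutant_texture_smoothing = 1.5) {
  stopifnot(mutant_margin_widening > 0, mutant_texture_smoothing > 0,
            mutant_volume_ratio[2] >= 0, wt_volume_ratio[2] >= 0)
  structure(list(mutant_volume_ratio = mutant_volume_ratio,
                 wt_volume_ratio = wt_volume_ratio,
                 mutant_margin_widening = mutant_margin_widening,
                 mutant_texture_smoothing = mutant_texture_smoothing),
            class = "response_model")
}

## A lesion "model" is the continuous description shared across renders of
## the same physical lesion: the angular surface-perturbation coefficients
## and the white-noise texture seed. Rendering voxelizes it on a grid.
make_lesion_model <- function(params, seed) {
  set.seed(seed)
  list(params = params,
       perturb_coefs = stats::runif(6, -1, 1),
       texture_seed = sample.int(2^31 - 2, 1),
       noise_seed = sample.int(2^31 - 2, 1))
}

# Band-limited angular perturbation (degree <= 3 direction harmonics,
# at most 4 lobes around any great circle), |f| <= 1.
angular_perturbation <- function(ux, uy, uz, coefs) {
  terms <- cbind(2 * ux * uy, 2 * uy * uz, 2 * ux * uz,
                 ux^2 - uy^2, (3 * uz^2 - 1) / 2,
                 ux * (ux^2 - 3 * uy^2))
  s <- sum(abs(coefs))
  if (s < 1e-12) return(rep(0, length(ux)))
  as.vector(terms %*% coefs) / s
}

render_lesion_impl <- function(model, grid_spacing, grid_dim, shift = c(0, 0, 0),
                               noise_seed = model$noise_seed) {
  p <- model$params
  spacing <- rep(grid_spacing, 3)
  d <- as.integer(grid_dim)
  if (length(d) == 1L) d <- rep(d, 3L)
  centre <- (d - 1) / 2 * spacing + shift
  if (any(p$radii + p$margin_width + 5 > (d - 1) / 2 * spacing))
    stop("geometry error: lesion (radius + margin + 5 mm context) exceeds the grid",
         call. = FALSE)
  gx <- (seq_len(d[1]) - 1) * spacing[1] - centre[1]
  gy <- (seq_len(d[2]) - 1) * spacing[2] - centre[2]
  gz <- (seq_len(d[3]) - 1) * spacing[3] - centre[3]
  X <- array(gx, d)
  Y <- aperm(array(gy, d[c(2, 1, 3)]), c(2, 1, 3))
  Z <- aperm(array(gz, d[c(3, 2, 1)]), c(3, 2, 1))
  r <- sqrt(X^2 + Y^2 + Z^2)
  r0 <- pmax(r, 1e-9)
  ux <- X / r0; uy <- Y / r0; uz <- Z / r0
  # directional ellipsoid radius
  Re <- 1 / sqrt((ux / p$radii[1])^2 + (uy / p$radii[2])^2 + (uz / p$radii[3])^2)
  if (p$bumpiness > 0) {
    f <- angular_perturbation(as.vector(ux), as.vector(uy), as.vector(uz),
                              model$perturb_coefs)
    Re <- Re * (1 + p$bumpiness * array(f, d))
  }
  dist <- r - Re                      # signed distance proxy (mm, >0 outside)
  mask <- dist <= 0
  img <- p$parenchyma_hu + (p$lesion_hu - p$parenchyma_hu) *
    stats::plogis(-4 * dist / p$margin_width)
  if (p$texture_sigma > 0) {
    set.seed(model$texture_seed)
    wn <- array(stats::rnorm(prod(d)), d)
    tex <- gaussian_smooth3d(wn, p$texture_corr_len, spacing)
    sdt <- stats::sd(tex)
    if (sdt > 0) tex <- tex / sdt * p$texture_sigma
    if (any(abs(shift) > 0)) {
      # the texture grid is anchored to the lesion: sample it at the
      # lesion-frame coordinates (X, Y, Z) so it translates rigidly
      tex_origin <- -(d - 1) / 2 * spacing
      pts <- cbind(as.vector(X), as.vector(Y), as.vector(Z))
      tv <- interp_trilinear(tex, spacing, tex_origin, pts)
      nb <- is.na(tv)
      if (any(nb))
        tv[nb] <- interp_nearest_clamped(tex, spacing, tex_origin, pts[nb, , drop = FALSE])
      tex <- array(tv, d)
    }
    img <- img + tex * mask
  }
  if (p$noise_sigma > 0) {
    set.seed(noise_seed)
    img <- img + array(stats::rnorm(prod(d), sd = p$noise_sigma), d)
  }
  list(image = image_volume(img, spacing),
       mask = lesion_mask(mask * 1, spacing))
}

#' Render a single lesion phantom
#'
#' Voxelizes the continuous lesion model on an isotropic grid: parenchyma
#' plateau, sigmoid radial margin of width `margin_width`, intralesional
#' Gaussian random-field texture, and i.i.d. scan noise. Deterministic
#' given `seed`.
#'
#' @param params a [lesion_params()].
#' @param grid_spacing isotropic voxel size, mm.
#' @param grid_dim scalar or length-3 grid size in voxels.
#' @param seed integer seed.
#' @return `list(image =, mask =)`.
#' @export
render_lesion <- function(params, grid_spacing = 1.0, grid_dim = 64, seed = 1) {
  model <- make_lesion_model(params, seed)
  render_lesion_impl(model, grid_spacing, grid_dim)
}

sample_base_params <- function(base_params, radius_range) {
  p <- base_params
  p$radii <- stats::runif(3, radius_range[1], radius_range[2])
  p
}

#' Generate a paired baseline/follow-up cohort
#'
#' Each subject receives sampled lesion parameters (semi-axes uniform on
#' `radius_range` by default); the follow-up lesion is the same continuous
#' lesion re-rendered with radii scaled by `ratio^(1/3)` drawn from the
#' label's volume-ratio law, and (for mutants) a widened margin and
#' smoothed texture, per the [response_model()].
#'
#' @param n_mutant,n_wt subject counts per label.
#' @param base_params template [lesion_params()]; radii are resampled per
#'   subject.
#' @param response a [response_model()].
#' @param seed integer seed; the whole cohort is a pure function of it.
#' @param grid_spacing,grid_dim grid geometry passed to the renderer.
#' @param radius_range length-2 vector, mm, for per-axis radius sampling.
#' @return List of [subject_study()] objects, mutants first.
#' @export
generate_cohort <- function(n_mutant = 20, n_wt = 20,
                            base_params = lesion_params(),
                            response = response_model(), seed = 1,
                            grid_spacing = 1.0, grid_dim = 64,
                            radius_range = c(5, 15)) {
  if (n_mutant + n_wt < 2) stop("need at least 2 subjects", call. = FALSE)
  set.seed(seed)
  labels <- c(rep(1L, n_mutant), rep(0L, n_wt))
  sub_seeds <- sample.int(2^31 - 2, length(labels))
  ratios <- ifelse(labels == 1L,
                   stats::rlnorm(length(labels), response$mutant_volume_ratio[1],
                                 response$mutant_volume_ratio[2]),
                   stats::rlnorm(length(labels), response$wt_volume_ratio[1],
                                 response$wt_volume_ratio[2]))
  lapply(seq_along(labels), function(i) {
    set.seed(sub_seeds[i])
    pre_params <- sample_base_params(base_params, radius_range)
    noise_seed_post <- sample.int(2^31 - 2, 1)
    model <- make_lesion_model(pre_params, sample.int(2^31 - 2, 1))
    pre <- render_lesion_impl(model, grid_spacing, grid_dim)
    post_params <- pre_params
    post_params$radii <- pre_params$radii * ratios[i]^(1 / 3)
    if (labels[i] == 1L) {
      post_params$margin_width <- pre_params$margin_width * response$mutant_margin_widening
      post_params$texture_corr_len <- pre_params$texture_corr_len * response$mutant_texture_smoothing
    }
    post_model <- model
    post_model$params <- post_params
    post <- render_lesion_impl(post_model, grid_spacing, grid_dim,
                               noise_seed = noise_seed_post)
    subject_study(sprintf("S%03d", i), labels[i], pre, post)
  })
}

#' Generate same-day test--retest scan pairs
#'
#' Each pair shares the lesion geometry, plateaus and texture field; the
#' second scan differs only by an independent noise realization and a
#' rigid sub-voxel translation (uniform on half a voxel per axis) applied
#' to the continuous model before voxelization.
#'
#' @inheritParams generate_cohort
#' @param n number of pairs (>= 2).
#' @return List of `list(subject_id =, scan1 =, scan2 =)` entries, each scan
#'   a `list(image =, mask =)`.
#' @export
generate_test_retest <- function(n = 20, base_params = lesion_params(), seed = 1,
                                 grid_spacing = 1.0, grid_dim = 64,
                                 radius_range = c(5, 15)) {
  if (n < 2) stop("need at least 2 test-retest pairs", call. = FALSE)
  set.seed(seed)
  sub_seeds <- sample.int(2^31 - 2, n)
  lapply(seq_len(n), function(i) {
    set.seed(sub_seeds[i])
    params <- sample_base_params(base_params, radius_range)
    shift <- stats::runif(3, -0.5, 0.5) * grid_spacing
    noise_seed2 <- sample.int(2^31 - 2, 1)
    model <- make_lesion_model(params, sample.int(2^31 - 2, 1))
    scan1 <- render_lesion_impl(model, grid_spacing, grid_dim)
    scan2 <- render_lesion_impl(model, grid_spacing, grid_dim, shift = shift,
                                noise_seed = noise_seed2)
    list(subject_id = sprintf("R%03d", i), scan1 = scan1, scan2 = scan2)
  })
}
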