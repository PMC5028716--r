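#' Sigmoid margin-profile configuration
#'
#' Controls the sampling lines drawn orthogonally through the lesion
#' surface and the logistic model fitted to the density profile along
#' each line, `f(t) = B + A / (1 + exp(-s (t - t0)))` with `t` in mm,
#' positive outward.
#'
#' @param half_length_mm line half-length in mm (the line spans
#'   `[-half_length_mm, +half_length_mm]` about the surface voxel).
#' @param step_mm sampling step along the line (must not exceed the
#'   smallest voxel spacing when used; default 0.5 mm).
#' @param max_lines at most this many surface voxels get a line (an evenly
#'   spaced deterministic subsample in array order); keeps the per-lesion
#'   cost bounded on large surfaces.
#' @param smoothing_sigma Gaussian scale (mm) used to estimate outward
#'   surface normals from the mask indicator.
#' @return A `sigmoid_config` list.
#' @export
sigmoid_config <- function(half_length_mm = 5, step_mm = 0.5, max_lines = 100,
                           smoothing_sigma = 1.5) {
  stopifnot(half_length_mm > 0, step_mm > 0, max_lines >= 1)
  structure(list(half_length_mm = half_length_mm, step_mm = step_mm,
                 max_lines = as.integer(max_lines),
                 smoothing_sigma = smoothing_sigma),
            class = "sigmoid_config")
}

# Fit f(t) = B + A/(1+exp(-s(t-t0))) by least squares; returns NULL when
# the fit does not converge. Constant profiles short-circuit to A = 0.
fit_sigmoid_profile <- function(t, y, half_length) {
  if (stats::sd(y) < 1e-9) {
    return(list(B = mean(y), A = 0, s = 0, t0 = 0))
  }
  n_out <- max(1L, ceiling(0.2 * length(y)))
  B0 <- mean(y[order(t, decreasing = TRUE)[seq_len(n_out)]])  # outermost 20 %
  A0 <- mean(y[order(t)[seq_len(n_out)]]) - B0                # inner - outer
  if (abs(A0) < 1e-9) A0 <- if (mean(y) >= B0) 1 else -1
  # profile runs inside -> outside, so the logistic must decay toward B0:
  # s and A share... the step from B (t -> -Inf) to B + A (t -> +Inf) must
  # equal outer - inner, hence initialize with A pointing outward.
  start <- list(B = B0 + A0, A = -A0, s = 4 / half_length, t0 = 0)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ B + A / (1 + exp(-s * (t - t0))),
                      start = start,
                      lower = c(B = -Inf, A = -Inf, s = -100, t0 = -half_length),
                      upper = c(B = Inf, A = Inf, s = 100, t0 = half_length),
                      control = minpack.lm::nls.lm.control(maxiter = 100)),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  as.list(stats::coef(fit))
}

#' Sigmoid lesion-margin features
#'
#' For an evenly spaced subsample of surface voxels, a sampling line is
#' drawn through the voxel along the outward surface normal (estimated
#' from the Gaussian-smoothed mask indicator) and the image is sampled
#' trilinearly at `step_mm` over `[-half_length_mm, +half_length_mm]`
#' (negative = inside). A logistic curve
#' `f(t) = B + A / (1 + exp(-s (t - t0)))` is fitted to each profile by
#' least squares. Per line, the offset is the mid-transition density
#' `B + A/2` (HU), the slope is the maximum density change rate
#' `|s * A| / 4` (HU/mm), and the amplitude is `|A|` (HU); the features
#' are the means over all fitted lines. Lines leaving the volume or
#' failing to converge are skipped and counted.
#'
#' @inheritParams laws_energy
#' @param config a [sigmoid_config()].
#' @return Named vector `Sigmoid-Offset-Mean-d<h>`, `Sigmoid-Slope-Mean-d<h>`,
#'   `Sigmoid-Amplitude-Mean-d<h>` with attributes `n_lines` (fitted) and
#'   `n_skipped`.
#' @export
sigmoid_margin_features <- function(volume, mask, config = sigmoid_config()) {
  validate_pair(volume, mask)
  if (config$step_mm > min(volume$spacing) + 1e-9)
    stop("step_mm must not exceed the smallest voxel spacing", call. = FALSE)
  d <- dim(mask$data)
  phi <- gaussian_smooth3d(mask$data, config$smoothing_sigma, mask$spacing)
  surf <- surface_voxels(mask$data)
  idx <- which(surf, arr.ind = TRUE)
  if (nrow(idx) > config$max_lines) {
    idx <- idx[round(seq(1, nrow(idx), length.out = config$max_lines)), , drop = FALSE]
  }
  interior <- idx[, 1] > 1 & idx[, 1] < d[1] & idx[, 2] > 1 & idx[, 2] < d[2] &
    idx[, 3] > 1 & idx[, 3] < d[3]
  idx <- idx[interior, , drop = FALSE]
  ts <- seq(-config$half_length_mm, config$half_length_mm, by = config$step_mm)
  offs <- slopes <- amps <- numeric(0)
  n_skipped <- sum(!interior)
  if (nrow(idx) > 0) {
    de <- field_derivatives(phi, mask$spacing, idx)
    # phi is high inside, so -grad(phi) points outward
    nrm <- -de$g / pmax(sqrt(rowSums(de$g^2)), 1e-12)
    world <- sweep(sweep(idx - 1, 2, mask$spacing, `*`), 2, mask$origin, `+`)
    for (i in seq_len(nrow(idx))) {
      pts <- cbind(world[i, 1] + ts * nrm[i, 1],
                   world[i, 2] + ts * nrm[i, 2],
                   world[i, 3] + ts * nrm[i, 3])
      y <- interp_trilinear(volume$data, volume$spacing, volume$origin, pts)
      if (anyNA(y)) { n_skipped <- n_skipped + 1L; next }
      fit <- fit_sigmoid_profile(ts, y, config$half_length_mm)
      if (is.null(fit)) { n_skipped <- n_skipped + 1L; next }
      offs <- c(offs, fit$B + fit$A / 2)
      slopes <- c(slopes, abs(fit$s * fit$A) / 4)
      amps <- c(amps, abs(fit$A))
    }
  }
  if (length(offs) == 0)
    stop("margin undefined: no usable sampling line could be fitted", call. = FALSE)
  h <- config$half_length_mm
  out <- c(mean(offs), mean(slopes), mean(amps))
  names(out) <- sprintf("Sigmoid-%s-Mean-d%g", c("Offset", "Slope", "Amplitude"), h)
  attr(out, "n_lines") <- length(offs)
  attr(out, "n_skipped") <- n_skipped
  out
}
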