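#' Gabor filter parameters
#'
#' An in-plane Gabor filter: an oriented Gaussian envelope modulated by a
#' sinusoid. Orientation is measured in degrees within the axial plane and
#' wavelength in pixels, matching the 2D acquisition geometry of axial CT.
#'
#' @param orientation_deg orientation in `[0, 180)` degrees.
#' @param wavelength_px sinusoid wavelength in pixels (>= 2).
#' @param bandwidth spatial-frequency bandwidth in octaves; sets the
#'   Gaussian envelope width (default 1 octave).
#' @return A `gabor_params` list.
#' @export
gabor_params <- function(orientation_deg, wavelength_px, bandwidth = 1) {
  if (wavelength_px < 2) stop("wavelength_px must be >= 2", call. = FALSE)
  orientation_deg <- orientation_deg %% 180
  structure(list(orientation_deg = orientation_deg,
                 wavelength_px = wavelength_px, bandwidth = bandwidth),
            class = "gabor_params")
}

# Envelope sigma (pixels) from wavelength and octave bandwidth.
gabor_sigma <- function(params) {
  b <- params$bandwidth
  params$wavelength_px / pi * sqrt(log(2) / 2) * (2^b + 1) / (2^b - 1)
}

# Separable decomposition of the real (even) isotropic-envelope Gabor
# kernel: g(x,y) = e^{-(x^2+y^2)/2s^2} cos(ax + by)
#               = Cx(x) Cy(y) - Sx(x) Sy(y).
gabor_terms <- function(params) {
  s <- gabor_sigma(params)
  th <- params$orientation_deg * pi / 180
  a <- 2 * pi * cos(th) / params$wavelength_px
  b <- 2 * pi * sin(th) / params$wavelength_px
  r <- max(1L, ceiling(3 * s))
  t <- (-r):r
  env <- exp(-0.5 * (t / s)^2)
  list(list(vx = env * cos(a * t), vy = env * cos(b * t), coef = 1),
       list(vx = env * sin(a * t), vy = env * sin(b * t), coef = -1))
}

# Dense kernel (for inspection/tests).
gabor_kernel <- function(params) {
  tm <- gabor_terms(params)
  outer(tm[[1]]$vx, tm[[1]]$vy) - outer(tm[[2]]$vx, tm[[2]]$vy)
}

#' Gabor texture energy of a lesion
#'
#' Filters every axial slice with the real part of the requested Gabor
#' filter (reflect-padded) and returns the sum of squared responses over
#' lesion voxels.
#'
#' @inheritParams laws_energy
#' @param params a [gabor_params()].
#' @return Non-negative scalar energy (HU^2).
#' @export
gabor_energy <- function(volume, mask, params) {
  validate_pair(volume, mask)
  tm <- gabor_terms(params)
  margin <- (length(tm[[1]]$vx) - 1L) %/% 2L
  cr <- crop_reflect(volume$data, mask$data > 0, margin = margin)
  resp <- conv_terms_inplane(cr$data, tm)
  sum(resp[cr$mask]^2)
}

# Several Gabor energies with one crop at the largest margin.
gabor_energy_all <- function(volume, mask, param_list) {
  terms <- lapply(param_list, gabor_terms)
  margin <- max(vapply(terms, function(t) (length(t[[1]]$vx) - 1L) %/% 2L, integer(1)))
  cr <- crop_reflect(volume$data, mask$data > 0, margin = margin)
  vapply(terms, function(t) sum(conv_terms_inplane(cr$data, t)[cr$mask]^2), numeric(1))
}
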