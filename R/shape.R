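## Surface/shape descriptors computed from the mask alone. All distances
## are in world mm; anisotropic spacing is respected throughout.

# Logical array of surface voxels: foreground with at least one of the six
# face neighbours background (volume border counts as background).
surface_voxels <- function(mask_data) {
  m <- mask_data > 0
  d <- dim(m)
  pad <- array(FALSE, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- m
  nb <- pad[1:d[1], 2:(d[2] + 1), 2:(d[3] + 1)] &
    pad[3:(d[1] + 2), 2:(d[2] + 1), 2:(d[3] + 1)] &
    pad[2:(d[1] + 1), 1:d[2], 2:(d[3] + 1)] &
    pad[2:(d[1] + 1), 3:(d[2] + 2), 2:(d[3] + 1)] &
    pad[2:(d[1] + 1), 2:(d[2] + 1), 1:d[3]] &
    pad[2:(d[1] + 1), 2:(d[2] + 1), 3:(d[3] + 2)]
  m & !nb
}

# World-mm coordinates (voxel centres) of the TRUE entries of a logical array.
voxel_world_coords <- function(logical_array, spacing, origin) {
  w <- which(logical_array, arr.ind = TRUE)
  sweep(sweep(w - 1, 2, spacing, `*`), 2, origin, `+`)
}

#' Tumor volume
#'
#' Foreground voxel count times the voxel volume.
#'
#' @param mask a [lesion_mask()].
#' @return Volume in mm^3.
#' @export
tumor_volume <- function(mask) {
  stopifnot(inherits(mask, "lesion_mask"))
  n <- sum(mask$data > 0)
  if (n < 1) stop("degenerate lesion: empty mask", call. = FALSE)
  n * prod(mask$spacing)
}

#' Maximum 3D diameter
#'
#' Largest Euclidean distance (mm) between any two surface-voxel centres.
#' Computed blockwise so large surfaces stay within memory.
#'
#' @param mask a [lesion_mask()].
#' @return Diameter in mm (0 for a single-voxel mask).
#' @export
max_diameter <- function(mask) {
  stopifnot(inherits(mask, "lesion_mask"))
  if (sum(mask$data > 0) < 1) stop("degenerate lesion: empty mask", call. = FALSE)
  pts <- voxel_world_coords(surface_voxels(mask$data), mask$spacing, mask$origin)
  n <- nrow(pts)
  if (n < 2) return(0)
  best <- -1
  bi <- bj <- 1L
  block <- 512L
  for (i0 in seq(1L, n, by = block)) {
    ii <- i0:min(n, i0 + block - 1L)
    d2 <- outer(pts[ii, 1], pts[, 1], `-`)^2 +
      outer(pts[ii, 2], pts[, 2], `-`)^2 +
      outer(pts[ii, 3], pts[, 3], `-`)^2
    m <- max(d2)
    if (m > best) {
      best <- m
      w <- which(d2 == m, arr.ind = TRUE)[1, ]
      bi <- ii[w[1]]; bj <- w[2]
    }
  }
  # recompute the winning pair's distance directly
  sqrt(sum((pts[bi, ] - pts[bj, ])^2))
}

#' Boundary radius standard deviation
#'
#' Population standard deviation (mm) of the distances from the lesion's
#' foreground centroid to every surface-voxel centre. Zero for a perfect
#' sphere.
#'
#' @param mask a [lesion_mask()].
#' @return Scalar mm (0 for a single-voxel mask).
#' @export
boundary_radius_std <- function(mask) {
  stopifnot(inherits(mask, "lesion_mask"))
  if (sum(mask$data > 0) < 1) stop("degenerate lesion: empty mask", call. = FALSE)
  ctr <- colMeans(voxel_world_coords(mask$data > 0, mask$spacing, mask$origin))
  pts <- voxel_world_coords(surface_voxels(mask$data), mask$spacing, mask$origin)
  r <- sqrt(rowSums(sweep(pts, 2, ctr)^2))
  sqrt(mean((r - mean(r))^2))
}

# Gradient and Hessian of a 3D scalar field at given voxel indices
# (central differences, spacing-aware). idx is an n x 3 1-based matrix at
# least one voxel away from every border.
field_derivatives <- function(phi, spacing, idx) {
  at <- function(dx, dy, dz) phi[cbind(idx[, 1] + dx, idx[, 2] + dy, idx[, 3] + dz)]
  h <- spacing
  g <- cbind((at(1, 0, 0) - at(-1, 0, 0)) / (2 * h[1]),
             (at(0, 1, 0) - at(0, -1, 0)) / (2 * h[2]),
             (at(0, 0, 1) - at(0, 0, -1)) / (2 * h[3]))
  c0 <- at(0, 0, 0)
  H <- list(
    xx = (at(1, 0, 0) - 2 * c0 + at(-1, 0, 0)) / h[1]^2,
    yy = (at(0, 1, 0) - 2 * c0 + at(0, -1, 0)) / h[2]^2,
    zz = (at(0, 0, 1) - 2 * c0 + at(0, 0, -1)) / h[3]^2,
    xy = (at(1, 1, 0) - at(1, -1, 0) - at(-1, 1, 0) + at(-1, -1, 0)) / (4 * h[1] * h[2]),
    xz = (at(1, 0, 1) - at(1, 0, -1) - at(-1, 0, 1) + at(-1, 0, -1)) / (4 * h[1] * h[3]),
    yz = (at(0, 1, 1) - at(0, 1, -1) - at(0, -1, 1) + at(0, -1, -1)) / (4 * h[2] * h[3]))
  list(g = g, H = H)
}

# Principal curvatures (kappa1 >= kappa2) of the implicit level surface of
# phi at the given voxels, signed so that a convex lesion (phi high inside)
# has positive curvatures. Vectorized closed forms for mean and Gaussian
# curvature of an implicit surface.
implicit_curvatures <- function(phi, spacing, idx) {
  de <- field_derivatives(phi, spacing, idx)
  gx <- de$g[, 1]; gy <- de$g[, 2]; gz <- de$g[, 3]
  H <- de$H
  g2 <- gx^2 + gy^2 + gz^2
  gn <- sqrt(g2)
  trH <- H$xx + H$yy + H$zz
  gHg <- gx * (H$xx * gx + H$xy * gy + H$xz * gz) +
    gy * (H$xy * gx + H$yy * gy + H$yz * gz) +
    gz * (H$xz * gx + H$yz * gy + H$zz * gz)
  # adjugate(H) quadratic form
  axx <- H$yy * H$zz - H$yz^2
  ayy <- H$xx * H$zz - H$xz^2
  azz <- H$xx * H$yy - H$xy^2
  axy <- H$xz * H$yz - H$xy * H$zz
  axz <- H$xy * H$yz - H$xz * H$yy
  ayz <- H$xy * H$xz - H$yz * H$xx
  gAg <- gx * (axx * gx + axy * gy + axz * gz) +
    gy * (axy * gx + ayy * gy + ayz * gz) +
    gz * (axz * gx + ayz * gy + azz * gz)
  ok <- gn > 1e-8
  Hm <- Kg <- rep(NA_real_, length(gn))
  # mean curvature w.r.t. the normal +grad(phi); phi is high inside the
  # lesion, so grad points inward and this convention makes a ball positive
  Hm[ok] <- (gHg[ok] - g2[ok] * trH[ok]) / (2 * gn[ok]^3)
  Kg[ok] <- gAg[ok] / g2[ok]^2
  disc <- pmax(Hm^2 - Kg, 0)
  list(k1 = Hm + sqrt(disc), k2 = Hm - sqrt(disc), valid = ok)
}

#' Shape-index surface fractions
#'
#' The mask indicator is Gaussian-smoothed at `smoothing_sigma` (mm) and
#' the principal curvatures `k1 >= k2` of its implicit level surface are
#' evaluated at every surface voxel. The shape index
#' `s = 1/2 + (1/pi) * atan2(k1 + k2, k1 - k2)` maps local geometry to
#' `[0, 1]` (0 = spherical cup, 0.5 = saddle, 1 = spherical cap/dome, with
#' the saddle-ridge range falling in bin 6). The feature vector `SI1..SI9`
#' is the fraction of surface voxels in each of 9 equal-width bins; the
#' fractions sum to 1. Surface voxels with vanishing gradient (flat or
#' degenerate surface) fall back to the central saddle bin.
#'
#' @param mask a [lesion_mask()].
#' @param smoothing_sigma Gaussian smoothing scale in mm.
#' @return Named numeric vector `Shape_SI1..Shape_SI9` summing to 1.
#' @export
shape_index_features <- function(mask, smoothing_sigma = 1.5) {
  stopifnot(inherits(mask, "lesion_mask"))
  if (sum(mask$data > 0) < 1) stop("degenerate lesion: empty mask", call. = FALSE)
  d <- dim(mask$data)
  phi <- gaussian_smooth3d(mask$data, smoothing_sigma, mask$spacing)
  surf <- surface_voxels(mask$data)
  idx <- which(surf, arr.ind = TRUE)
  # derivatives need a 1-voxel interior margin
  inner <- idx[, 1] > 1 & idx[, 1] < d[1] & idx[, 2] > 1 & idx[, 2] < d[2] &
    idx[, 3] > 1 & idx[, 3] < d[3]
  s <- rep(0.5, nrow(idx))  # flat-surface fallback: central bin
  if (any(inner)) {
    cv <- implicit_curvatures(phi, mask$spacing, idx[inner, , drop = FALSE])
    si <- ifelse(cv$valid & (abs(cv$k1) + abs(cv$k2)) > 1e-9,
                 0.5 + atan2(cv$k1 + cv$k2, cv$k1 - cv$k2) / pi, 0.5)
    s[inner] <- si
  }
  bin <- pmin(9L, floor(pmin(pmax(s, 0), 1) * 9) + 1L)
  frac <- tabulate(bin, nbins = 9L) / length(bin)
  stats::setNames(frac, paste0("Shape_SI", 1:9))
}
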