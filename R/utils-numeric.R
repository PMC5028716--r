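## Internal numerical helpers: reflected indexing, separable convolution,
## Gaussian smoothing, trilinear interpolation. All array code assumes
## dimension order (x, y, z) with axial slices along the third dimension.

# Half-sample symmetric ("reflect") index vector of length n + 2*h into 1:n.
reflect_indices <- function(n, h) {
  if (h == 0L) return(seq_len(n))
  if (n == 1L) return(rep(1L, n + 2L * h))
  left <- rev(seq_len(min(h, n)))
  right <- rev(rev(seq_len(n))[seq_len(min(h, n))])
  # for h > n fall back to cycling the reflection (rare, tiny arrays)
  while (length(left) < h) left <- c(rev(seq_len(min(h - length(left), n))), left)
  while (length(right) < h) right <- c(right, rev(rev(seq_len(n))[seq_len(min(h - length(right), n))]))
  c(left, seq_len(n), right)
}

# 1D convolution (correlation orientation) along dimension `dim` of a 3D
# array, reflect-padded, output same shape. Kernel length must be odd.
conv1d_dim <- function(a, kernel, dim) {
  L <- length(kernel)
  h <- (L - 1L) %/% 2L
  d <- dim(a)
  idx <- reflect_indices(d[dim], h)
  pad <- switch(dim,
    a[idx, , , drop = FALSE],
    a[, idx, , drop = FALSE],
    a[, , idx, drop = FALSE])
  out <- array(0, d)
  n <- d[dim]
  for (k in seq_len(L)) {
    sl <- k:(k + n - 1L)
    out <- out + kernel[k] * switch(dim,
      pad[sl, , , drop = FALSE],
      pad[, sl, , drop = FALSE],
      pad[, , sl, drop = FALSE])
  }
  out
}

# Separable in-plane (x, y) filtering of every axial slice: response to the
# rank-1 kernel outer(vx, vy), correlation orientation, reflect boundary.
conv_sep_inplane <- function(a, vx, vy) {
  conv1d_dim(conv1d_dim(a, vx, 1L), vy, 2L)
}

# In-plane response to a sum of rank-1 terms: terms is a list of
# list(vx =, vy =, coef =).
conv_terms_inplane <- function(a, terms) {
  out <- array(0, dim(a))
  for (t in terms) out <- out + t$coef * conv_sep_inplane(a, t$vx, t$vy)
  out
}

gaussian_kernel_1d <- function(sigma_vox) {
  if (sigma_vox <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma_vox))
  k <- exp(-0.5 * ((-r):r / sigma_vox)^2)
  k / sum(k)
}

# Isotropic-in-mm Gaussian smoothing of a 3D array on an anisotropic grid.
gaussian_smooth3d <- function(a, sigma_mm, spacing) {
  for (d in 1:3) {
    k <- gaussian_kernel_1d(sigma_mm / spacing[d])
    if (length(k) > 1L) a <- conv1d_dim(a, k, d)
  }
  a
}

# Trilinear interpolation of `a` (grid: voxel centers at
# origin + (index - 1) * spacing, world mm) at an n x 3 matrix of points.
# Points outside the grid get NA.
interp_trilinear <- function(a, spacing, origin, pts) {
  d <- dim(a)
  cx <- (pts[, 1] - origin[1]) / spacing[1]
  cy <- (pts[, 2] - origin[2]) / spacing[2]
  cz <- (pts[, 3] - origin[3]) / spacing[3]
  out <- rep(NA_real_, nrow(pts))
  ok <- cx >= 0 & cx <= d[1] - 1 & cy >= 0 & cy <= d[2] - 1 & cz >= 0 & cz <= d[3] - 1
  if (!any(ok)) return(out)
  cx <- cx[ok]; cy <- cy[ok]; cz <- cz[ok]
  x0 <- pmin(floor(cx), d[1] - 2); x0 <- pmax(x0, 0)
  y0 <- pmin(floor(cy), d[2] - 2); y0 <- pmax(y0, 0)
  z0 <- pmin(floor(cz), d[3] - 2); z0 <- pmax(z0, 0)
  if (d[1] == 1L) x0 <- rep(0, length(cx))
  if (d[2] == 1L) y0 <- rep(0, length(cy))
  if (d[3] == 1L) z0 <- rep(0, length(cz))
  fx <- cx - x0; fy <- cy - y0; fz <- cz - z0
  at <- function(ix, iy, iz) a[cbind(pmin(ix, d[1] - 1) + 1L, pmin(iy, d[2] - 1) + 1L, pmin(iz, d[3] - 1) + 1L)]
  v <- at(x0, y0, z0) * (1 - fx) * (1 - fy) * (1 - fz) +
    at(x0 + 1, y0, z0) * fx * (1 - fy) * (1 - fz) +
    at(x0, y0 + 1, z0) * (1 - fx) * fy * (1 - fz) +
    at(x0 + 1, y0 + 1, z0) * fx * fy * (1 - fz) +
    at(x0, y0, z0 + 1) * (1 - fx) * (1 - fy) * fz +
    at(x0 + 1, y0, z0 + 1) * fx * (1 - fy) * fz +
    at(x0, y0 + 1, z0 + 1) * (1 - fx) * fy * fz +
    at(x0 + 1, y0 + 1, z0 + 1) * fx * fy * fz
  out[ok] <- v
  out
}

# Nearest-neighbour lookup at world points; NA outside.
interp_nearest <- function(a, spacing, origin, pts) {
  d <- dim(a)
  ix <- round((pts[, 1] - origin[1]) / spacing[1]) + 1
  iy <- round((pts[, 2] - origin[2]) / spacing[2]) + 1
  iz <- round((pts[, 3] - origin[3]) / spacing[3]) + 1
  out <- rep(NA_real_, nrow(pts))
  ok <- ix >= 1 & ix <= d[1] & iy >= 1 & iy <= d[2] & iz >= 1 & iz <= d[3]
  out[ok] <- a[cbind(ix[ok], iy[ok], iz[ok])]
  out
}

# Bounding box of TRUE voxels, expanded by `margin` voxels and extracted
# with reflected indexing at the array border. Returns the sub-array plus
# the logical sub-mask aligned with it.
crop_reflect <- function(a, mask, margin) {
  d <- dim(a)
  w <- which(mask, arr.ind = TRUE)
  lo <- apply(w, 2, min); hi <- apply(w, 2, max)
  idx <- vector("list", 3)
  for (k in 1:3) {
    rng <- (lo[k] - margin):(hi[k] + margin)
    # reflect out-of-range indices at the borders (half-sample symmetric)
    rng <- ifelse(rng < 1L, 1L - rng, rng)
    rng <- ifelse(rng > d[k], 2L * d[k] + 1L - rng, rng)
    rng <- pmin(pmax(rng, 1L), d[k])
    idx[[k]] <- rng
  }
  sub <- a[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  # mask voxels only inside the original bbox (reflected border voxels are
  # image context, never lesion)
  subm <- array(FALSE, dim(sub))
  subm[margin + seq_len(hi[1] - lo[1] + 1L),
       margin + seq_len(hi[2] - lo[2] + 1L),
       margin + seq_len(hi[3] - lo[3] + 1L)] <-
    mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]
  list(data = sub, mask = subm)
}

# Entropy helper: -sum p log p with 0 log 0 = 0 (natural log).
neg_entropy_sum <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}
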