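# Shared fixtures (generated in code) and independent brute-force oracles.

# Noise-free digitized ball phantom.
ball_phantom <- function(radius_mm, spacing = 1, dim = 48, margin_width = 1) {
  render_lesion(lesion_params(radii = rep(radius_mm, 3), bumpiness = 0,
                              texture_sigma = 0, noise_sigma = 0,
                              margin_width = margin_width),
                grid_spacing = spacing, grid_dim = dim, seed = 1)
}

# Small random image/mask pair for oracle comparisons.
toy_pair <- function(seed, dim = c(6, 6, 6), p_mask = 0.7) {
  set.seed(seed)
  img <- image_volume(array(rnorm(prod(dim), sd = 50), dim), c(1, 1, 1))
  repeat {
    m <- array(as.numeric(runif(prod(dim)) < p_mask), dim)
    if (sum(m) >= 4) break
  }
  list(image = img, mask = lesion_mask(m, c(1, 1, 1)))
}

# --- brute-force GLCM oracle: explicit loops over voxels and pairs -------

oracle_glcm <- function(vol, msk, distance, direction, n_levels, symmetric = TRUE) {
  d <- dim(vol$data)
  v <- vol$data[msk$data > 0]
  lo <- min(v); hi <- max(v)
  qz <- function(x) if (hi <= lo) 1L else min(n_levels, floor((x - lo) / (hi - lo) * n_levels) + 1L)
  off <- direction * distance
  P <- matrix(0, n_levels, n_levels)
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    if (msk$data[x, y, z] <= 0) next
    x2 <- x + off[1]; y2 <- y + off[2]; z2 <- z + off[3]
    if (x2 < 1 || x2 > d[1] || y2 < 1 || y2 > d[2] || z2 < 1 || z2 > d[3]) next
    if (msk$data[x2, y2, z2] <= 0) next
    i <- qz(vol$data[x, y, z]); j <- qz(vol$data[x2, y2, z2])
    P[i, j] <- P[i, j] + 1
  }
  if (symmetric) P <- P + t(P)
  if (sum(P) == 0) return(NULL)
  P / sum(P)
}

# Naive loop-based co-occurrence statistics (independent of the package's
# vectorized implementation; only eigen() is shared as a base primitive).
oracle_glcm_stats <- function(P) {
  n <- nrow(P)
  px <- py <- numeric(n)
  for (i in 1:n) for (j in 1:n) { px[i] <- px[i] + P[i, j]; py[j] <- py[j] + P[i, j] }
  mux <- sum((1:n) * px); muy <- sum((1:n) * py)
  sdx <- sqrt(sum(((1:n) - mux)^2 * px)); sdy <- sqrt(sum(((1:n) - muy)^2 * py))
  en <- ct <- hom <- dis <- ent <- vr <- cor_num <- 0
  psum <- numeric(2 * n); pdiff <- numeric(n)
  HXY1 <- HXY2 <- 0
  for (i in 1:n) for (j in 1:n) {
    p <- P[i, j]
    en <- en + p^2; ct <- ct + (i - j)^2 * p
    hom <- hom + p / (1 + (i - j)^2); dis <- dis + abs(i - j) * p
    if (p > 0) ent <- ent - p * log(p)
    vr <- vr + (i - mux)^2 * p
    cor_num <- cor_num + i * j * p
    psum[i + j] <- psum[i + j] + p
    pdiff[abs(i - j) + 1] <- pdiff[abs(i - j) + 1] + p
    if (p > 0 && px[i] * py[j] > 0) HXY1 <- HXY1 - p * log(px[i] * py[j])
    if (px[i] * py[j] > 0) HXY2 <- HXY2 - px[i] * py[j] * log(px[i] * py[j])
  }
  sa <- sum(seq_along(psum) * psum)
  sv <- sum((seq_along(psum) - sa)^2 * psum)
  se <- -sum(psum[psum > 0] * log(psum[psum > 0]))
  mu_d <- sum((0:(n - 1)) * pdiff)
  dv <- sum(((0:(n - 1)) - mu_d)^2 * pdiff)
  de <- -sum(pdiff[pdiff > 0] * log(pdiff[pdiff > 0]))
  HX <- -sum(px[px > 0] * log(px[px > 0]))
  HY <- -sum(py[py > 0] * log(py[py > 0]))
  imc1 <- if (max(HX, HY) > 0) (ent - HXY1) / max(HX, HY) else 0
  imc2 <- sqrt(max(0, 1 - exp(-2 * (HXY2 - ent))))
  corr <- if (sdx > 0 && sdy > 0) (cor_num - mux * muy) / (sdx * sdy) else 0
  # MCC via explicit Q construction
  ki <- which(px > 0); kj <- which(py > 0)
  mcc <- if (length(ki) < 2 || length(kj) < 2) 1 else {
    Q <- matrix(0, length(ki), length(ki))
    for (a in seq_along(ki)) for (b in seq_along(ki)) {
      s <- 0
      for (c in seq_along(kj))
        s <- s + P[ki[a], kj[c]] * P[ki[b], kj[c]] / (px[ki[a]] * py[kj[c]])
      Q[a, b] <- s
    }
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    sqrt(min(1, max(0, ev[2])))
  }
  c(Energy = en, Contrast = ct, Correlation = corr, Variance = vr,
    Homogeneity = hom, SumAverage = sa, SumVariance = sv, SumEntropy = se,
    Entropy = ent, DifferenceVariance = dv, DifferenceEntropy = de,
    IMC1 = imc1, IMC2 = imc2, MCC = mcc, Dissimilarity = dis)
}

# Exhaustive O(n^2) maximum pairwise distance between surface voxel centres.
oracle_max_diameter <- function(msk) {
  surf <- deltarad:::surface_voxels(msk$data)
  w <- which(surf, arr.ind = TRUE)
  pts <- sweep(sweep(w - 1, 2, msk$spacing, `*`), 2, msk$origin, `+`)
  best <- 0
  if (nrow(pts) >= 2)
    for (i in 1:(nrow(pts) - 1)) for (j in (i + 1):nrow(pts))
      best <- max(best, sum((pts[i, ] - pts[j, ])^2))
  sqrt(best)
}

# Direct loop recomputation of the boundary-radius standard deviation.
oracle_boundary_radius_std <- function(msk) {
  w_all <- which(msk$data > 0, arr.ind = TRUE)
  ctr <- colMeans(sweep(sweep(w_all - 1, 2, msk$spacing, `*`), 2, msk$origin, `+`))
  surf <- deltarad:::surface_voxels(msk$data)
  w <- which(surf, arr.ind = TRUE)
  r <- numeric(nrow(w))
  for (i in seq_len(nrow(w)))
    r[i] <- sqrt(sum(((w[i, ] - 1) * msk$spacing + msk$origin - ctr)^2))
  sqrt(mean((r - mean(r))^2))
}

# Exhaustive pair-counting AUC: fraction of (pos, neg) pairs won, ties 1/2.
oracle_auc <- function(values, labels) {
  pos <- values[labels == 1]; neg <- values[labels == 0]
  s <- 0
  for (a in pos) for (b in neg) s <- s + (a > b) + 0.5 * (a == b)
  s / (length(pos) * length(neg))
}
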