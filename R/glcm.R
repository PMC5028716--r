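#' Grey-level co-occurrence configuration
#'
#' @param n_levels number of equal-width grey-level bins over the lesion's
#'   intensity range (default 32).
#' @param distances integer voxel-pair distances (default `c(1, 4)`); the
#'   offset used for a direction is `distance * direction`, so distance is
#'   measured in the Chebyshev sense along each of the 13 unique 3D
#'   directions.
#' @param symmetric if `TRUE` (default) the matrix is symmetrized by adding
#'   its transpose before normalization.
#' @return A `glcm_config` list.
#' @export
glcm_config <- function(n_levels = 32, distances = c(1, 4), symmetric = TRUE) {
  if (n_levels < 2) stop("n_levels must be >= 2", call. = FALSE)
  structure(list(n_levels = as.integer(n_levels),
                 distances = as.integer(distances), symmetric = symmetric),
            class = "glcm_config")
}

#' The 13 unique 3D co-occurrence directions
#'
#' Offsets `(dx, dy, dz)` covering every pair of 26-connected neighbours
#' once (no antiparallel duplicates).
#'
#' @return A 13 x 3 integer matrix.
#' @export
glcm_directions <- function() {
  m <- rbind(
    c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
    c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1),
    c(0, 1, 1), c(0, 1, -1),
    c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1))
  storage.mode(m) <- "integer"
  m
}

# Quantize intensities inside the mask into n_levels equal-width bins over
# the mask's [min, max]; background voxels are NA.
quantize_mask <- function(volume_data, mask_logical, n_levels) {
  q <- array(NA_integer_, dim(volume_data))
  v <- volume_data[mask_logical]
  lo <- min(v); hi <- max(v)
  if (hi <= lo) {
    q[mask_logical] <- 1L
  } else {
    q[mask_logical] <- pmin(n_levels, floor((v - lo) / (hi - lo) * n_levels) + 1L)
  }
  q
}

glcm_from_quantized <- function(q, offset, n_levels, symmetric = TRUE) {
  d <- dim(q)
  if (any(abs(offset) >= d)) return(NULL)  # offset leaves the grid entirely
  src <- lapply(1:3, function(k) {
    o <- offset[k]
    if (o >= 0) seq_len(d[k] - o) else seq(1 - o, d[k])
  })
  dst <- lapply(1:3, function(k) src[[k]] + offset[k])
  qi <- q[src[[1]], src[[2]], src[[3]], drop = FALSE]
  qj <- q[dst[[1]], dst[[2]], dst[[3]], drop = FALSE]
  ok <- !is.na(qi) & !is.na(qj)
  if (!any(ok)) return(NULL)
  counts <- tabulate((qi[ok] - 1L) * n_levels + qj[ok], nbins = n_levels^2)
  P <- matrix(counts, n_levels, n_levels, byrow = TRUE)
  if (symmetric) P <- P + t(P)
  P / sum(P)
}

#' Compute one normalized co-occurrence matrix
#'
#' Intensities inside the mask are quantized into `n_levels` equal-width
#' bins over the lesion's intensity range, then pairs
#' `(i at x, j at x + distance * direction)` with both endpoints in the
#' mask are counted, optionally symmetrized, and normalized to sum 1.
#'
#' @inheritParams laws_energy
#' @param distance integer voxel distance.
#' @param direction integer length-3 offset, one of [glcm_directions()].
#' @param config a [glcm_config()].
#' @return A normalized `n_levels x n_levels` matrix, with attribute
#'   `degenerate = TRUE` when no valid voxel pair exists (matrix of zeros
#'   with a single 1 would be meaningless; callers use the statistic
#'   fallbacks).
#' @export
compute_glcm <- function(volume, mask, distance, direction, config = glcm_config()) {
  validate_pair(volume, mask)
  q <- quantize_mask(volume$data, mask$data > 0, config$n_levels)
  P <- glcm_from_quantized(q, as.integer(direction) * as.integer(distance),
                           config$n_levels, config$symmetric)
  if (is.null(P)) {
    P <- matrix(0, config$n_levels, config$n_levels)
    attr(P, "degenerate") <- TRUE
  }
  P
}

#' Statistics of a normalized co-occurrence matrix
#'
#' Computes the supported co-occurrence statistic set: angular second
#' moment (`Energy`), `Contrast`, `Correlation`, `Variance`, `Homogeneity`
#' (inverse difference moment), `SumAverage`, `SumVariance`, `SumEntropy`,
#' `Entropy`, `DifferenceVariance`, `DifferenceEntropy`, the informational
#' measures of correlation `IMC1` and `IMC2`, the maximum correlation
#' coefficient `MCC`, and `Dissimilarity`. Natural logarithms throughout;
#' `0 log 0 = 0`.
#'
#' Degenerate matrices never yield `NaN`: with a single occupied grey
#' level, `Correlation` falls back to 0, `IMC1` to 0 (its entropy
#' denominator vanishes) and `MCC` to 1 (the rank-deficient limit).
#'
#' @param P normalized co-occurrence matrix (entries sum to 1).
#' @return Named numeric vector of the 15 statistics.
#' @export
glcm_statistics <- function(P) {
  n <- nrow(P)
  if (isTRUE(attr(P, "degenerate")) || sum(P) <= 0) {
    out <- stats::setNames(numeric(15), glcm_statistic_names())
    out["MCC"] <- 1
    return(out)
  }
  i <- row(P); j <- col(P)
  px <- rowSums(P); py <- colSums(P)
  lev <- seq_len(n)
  mux <- sum(lev * px); muy <- sum(lev * py)
  sdx <- sqrt(sum((lev - mux)^2 * px)); sdy <- sqrt(sum((lev - muy)^2 * py))
  dif <- abs(i - j)
  # p_{x+y}(k), k = 2..2n ; p_{x-y}(k), k = 0..n-1
  psum <- vapply(2:(2 * n), function(k) sum(P[i + j == k]), numeric(1))
  pdiff <- vapply(0:(n - 1), function(k) sum(P[dif == k]), numeric(1))
  ks <- 2:(2 * n); kd <- 0:(n - 1)
  sa <- sum(ks * psum)
  mu_d <- sum(kd * pdiff)
  HXY <- neg_entropy_sum(P)
  HX <- neg_entropy_sum(px); HY <- neg_entropy_sum(py)
  pxpy <- outer(px, py)
  nz <- P > 0 & pxpy > 0
  HXY1 <- -sum(P[nz] * log(pxpy[nz]))
  nz2 <- pxpy > 0
  HXY2 <- -sum(pxpy[nz2] * log(pxpy[nz2]))
  imc1 <- if (max(HX, HY) > 0) (HXY - HXY1) / max(HX, HY) else 0
  imc2 <- sqrt(max(0, 1 - exp(-2 * (HXY2 - HXY))))
  corr <- if (sdx > 0 && sdy > 0) (sum(i * j * P) - mux * muy) / (sdx * sdy) else 0
  c(Energy = sum(P^2),
    Contrast = sum((i - j)^2 * P),
    Correlation = corr,
    Variance = sum((i - mux)^2 * P),
    Homogeneity = sum(P / (1 + (i - j)^2)),
    SumAverage = sa,
    SumVariance = sum((ks - sa)^2 * psum),
    SumEntropy = neg_entropy_sum(psum),
    Entropy = HXY,
    DifferenceVariance = sum((kd - mu_d)^2 * pdiff),
    DifferenceEntropy = neg_entropy_sum(pdiff),
    IMC1 = imc1,
    IMC2 = imc2,
    MCC = glcm_mcc(P, px, py),
    Dissimilarity = sum(dif * P))
}

# Maximum correlation coefficient: sqrt of the second-largest eigenvalue of
# Q(i,j) = sum_k p(i,k) p(j,k) / (px(i) py(k)), restricted to occupied
# levels; clamped to [0, 1].
glcm_mcc <- function(P, px = rowSums(P), py = colSums(P)) {
  keep_i <- px > 0; keep_j <- py > 0
  Pk <- P[keep_i, keep_j, drop = FALSE]
  if (nrow(Pk) < 2L || ncol(Pk) < 2L) return(1)
  Q <- (Pk / px[keep_i]) %*% t(Pk / rep(py[keep_j], each = nrow(Pk)))
  ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
  sqrt(min(1, max(0, ev[2])))
}

glcm_statistic_names <- function() {
  c("Energy", "Contrast", "Correlation", "Variance", "Homogeneity",
    "SumAverage", "SumVariance", "SumEntropy", "Entropy",
    "DifferenceVariance", "DifferenceEntropy", "IMC1", "IMC2", "MCC",
    "Dissimilarity")
}

#' Aggregated directional co-occurrence feature
#'
#' Computes one statistic on the co-occurrence matrix of each of the 13
#' directions at the given distance and aggregates across directions.
#'
#' @inheritParams compute_glcm
#' @param statistic one of [glcm_statistic_names()].
#' @param aggregation `"mean"`, `"std"` (population) or `"range"`.
#' @return Scalar feature value.
#' @export
glcm_feature <- function(volume, mask, statistic, distance,
                         aggregation = c("mean", "std", "range"),
                         config = glcm_config()) {
  aggregation <- match.arg(aggregation)
  if (!statistic %in% glcm_statistic_names())
    stop("unknown co-occurrence statistic '", statistic, "'", call. = FALSE)
  validate_pair(volume, mask)
  q <- quantize_mask(volume$data, mask$data > 0, config$n_levels)
  dirs <- glcm_directions()
  vals <- vapply(seq_len(nrow(dirs)), function(k) {
    P <- glcm_from_quantized(q, dirs[k, ] * as.integer(distance),
                             config$n_levels, config$symmetric)
    if (is.null(P)) {
      P <- matrix(0, config$n_levels, config$n_levels)
      attr(P, "degenerate") <- TRUE
    }
    glcm_statistics(P)[[statistic]]
  }, numeric(1))
  aggregate_directional(vals, aggregation)
}

aggregate_directional <- function(vals, aggregation) {
  switch(aggregation,
         mean = mean(vals),
         std = sqrt(mean((vals - mean(vals))^2)),
         range = diff(range(vals)))
}

# All statistics x distances x aggregations in one pass (13 matrices per
# distance, statistics computed once per matrix).
glcm_features_all <- function(volume, mask, statistics, distances, aggregations,
                              config = glcm_config()) {
  q_full <- quantize_mask(volume$data, mask$data > 0, config$n_levels)
  dirs <- glcm_directions()
  out <- c()
  for (d in distances) {
    stat_by_dir <- vapply(seq_len(nrow(dirs)), function(k) {
      P <- glcm_from_quantized(q_full, dirs[k, ] * as.integer(d),
                               config$n_levels, config$symmetric)
      if (is.null(P)) {
        P <- matrix(0, config$n_levels, config$n_levels)
        attr(P, "degenerate") <- TRUE
      }
      glcm_statistics(P)[statistics]
    }, numeric(length(statistics)))
    if (is.null(dim(stat_by_dir))) stat_by_dir <- matrix(stat_by_dir, nrow = 1)
    for (s_i in seq_along(statistics)) for (ag in aggregations) {
      nm <- sprintf("GLCM_%s-%s-d%d", statistics[s_i], ag, d)
      out[nm] <- aggregate_directional(stat_by_dir[s_i, ], ag)
    }
  }
  out
}
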