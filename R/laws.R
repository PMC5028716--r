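## Laws 1D basis vectors (length 5): Level, Edge, Spot, Ripple, Wave.
## Only L5 has a nonzero coefficient sum; every kernel involving E5, S5,
## R5 or W5 is therefore zero-mean.
laws_basis <- function() {
  list(L = c(1, 4, 6, 4, 1),
       E = c(-1, -2, 0, 2, 1),
       S = c(-1, 0, 2, 0, -1),
       R = c(1, -4, 6, -4, 1),
       W = c(-1, 2, 0, -2, 1))
}

#' Build the 14-filter Laws texture bank
#'
#' The bank contains the 10 symmetrized cross-products
#' `(outer(u, v) + outer(v, u)) / 2` for unordered pairs of distinct basis
#' vectors, ordered lexicographically by the basis order (L, E, S, R, W)
#' -- LE, LS, LR, LW, ES, ER, EW, SR, SW, RW, ids 1--10 -- followed by the
#' 4 zero-mean self-products EE, SS, RR, WW (ids 11--14). The pure-level
#' kernel LL is excluded because it is not zero-mean. Each entry carries
#' the dense 5x5 kernel and its separable decomposition.
#'
#' @return A list of class `laws_filter_bank`: elements have `id`, `name`,
#'   `kernel` (5x5 matrix) and `terms` (separable rank-1 terms).
#' @export
build_laws_filters <- function() {
  b <- laws_basis()
  nm <- names(b)
  bank <- list()
  for (i in 1:4) for (j in (i + 1):5) {
    u <- b[[i]]; v <- b[[j]]
    bank[[length(bank) + 1L]] <- list(
      name = paste0(nm[i], "5", nm[j], "5"),
      kernel = (outer(u, v) + outer(v, u)) / 2,
      terms = list(list(vx = u, vy = v, coef = 0.5),
                   list(vx = v, vy = u, coef = 0.5)))
  }
  for (k in 2:5) {
    v <- b[[k]]
    bank[[length(bank) + 1L]] <- list(
      name = paste0(nm[k], "5", nm[k], "5"),
      kernel = outer(v, v),
      terms = list(list(vx = v, vy = v, coef = 1)))
  }
  for (i in seq_along(bank)) bank[[i]]$id <- i
  structure(bank, class = "laws_filter_bank")
}

#' Laws texture energy of a lesion
#'
#' Filters every axial slice with the requested 5x5 Laws kernel
#' (reflect-padded, correlation orientation), squares the response, and
#' sums over lesion voxels.
#'
#' @param volume an [image_volume()].
#' @param mask the companion [lesion_mask()].
#' @param filter_id integer 1--14, see [build_laws_filters()].
#' @param bank optionally a prebuilt filter bank.
#' @return Non-negative scalar energy (HU^2).
#' @export
laws_energy <- function(volume, mask, filter_id, bank = build_laws_filters()) {
  validate_pair(volume, mask)
  if (!filter_id %in% seq_along(bank))
    stop("filter_id must be in 1..", length(bank), call. = FALSE)
  cr <- crop_reflect(volume$data, mask$data > 0, margin = 2L)
  resp <- conv_terms_inplane(cr$data, bank[[filter_id]]$terms)
  sum(resp[cr$mask]^2)
}

# All 14 Laws energies at once (shared crop).
laws_energy_all <- function(volume, mask, bank = build_laws_filters()) {
  cr <- crop_reflect(volume$data, mask$data > 0, margin = 2L)
  vapply(bank, function(f) {
    sum(conv_terms_inplane(cr$data, f$terms)[cr$mask]^2)
  }, numeric(1))
}
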