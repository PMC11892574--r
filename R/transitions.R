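#' Directional apparent diffusion coefficient
#'
#' Evaluates the diffusivity of a tensor along a unit direction as the
#' quadratic form `n' D n` (mm^2/s), clamped below at zero: noisy tensor
#' fits can produce slightly negative directional values that have no
#' physical meaning.
#'
#' @param tensor symmetric 3x3 matrix, or its 6 unique components in
#'   `(Dxx, Dxy, Dxz, Dyy, Dyz, Dzz)` order, mm^2/s.
#' @param direction length-3 unit vector (tolerance 1e-6 on the norm).
#' @return Nonnegative scalar, mm^2/s.
#' @examples
#' directional_adc(diag(3) * 1e-3, c(1, 0, 0))  # 1e-3 for any direction
#' @export
directional_adc <- function(tensor, direction) {
  if (length(tensor) == 6L) {
    tensor <- matrix(c(tensor[1], tensor[2], tensor[3],
                       tensor[2], tensor[4], tensor[5],
                       tensor[3], tensor[5], tensor[6]), 3L, 3L)
  }
  stopifnot(identical(dim(tensor), c(3L, 3L)))
  n <- as.numeric(direction)
  if (abs(sqrt(sum(n^2)) - 1) > 1e-6)
    stop("direction must be a unit vector")
  max(0, drop(n %*% tensor %*% n))
}

# 6 x n matrix turning packed tensor components into quadratic forms:
# adc[, j] = comps %*% quad_coeffs[, j] = n_j' D n_j
quad_form_coeffs <- function(directions) {
  apply(directions, 1L, function(n)
    c(n[1]^2, 2 * n[1] * n[2], 2 * n[1] * n[3],
      n[2]^2, 2 * n[2] * n[3], n[3]^2))
}

#' Transition-probability matrix over the 26-neighborhood
#'
#' For every eligible white-matter voxel i, evaluates the directional ADC
#' toward each of its 26 neighbors and converts the gated values into step
#' probabilities `W_ij = m_ij * ADC_ij / sum_j m_ij * ADC_ij`. The gate
#' coefficient `m_ij` is 1 only when neighbor j is an eligible white-matter
#' voxel and satisfies the distance rule of the requested mode: walking
#' toward the tumor nullifies directions with `d_j > d_i`; walking away
#' nullifies `d_j < d_i`. Equal-distance neighbors stay eligible in both
#' modes, which lets trajectories wander along a distance stratum. Gated
#' ADC values below `adc_floor` are raised to the floor so that no eligible
#' voxel with a valid descent direction becomes a dead end on noisy
#' tensors; at typical white-matter diffusivities (~1e-3 mm^2/s) the floor
#' is negligible. Rows of voxels with no admissible neighbor are all zero
#' (terminal).
#'
#' @param tensors a [tensor_field()].
#' @param dm a [compute_distance_map()] result on the same grid.
#' @param mode `"toward_tumor"` or `"away_from_tumor"`.
#' @param adc_floor minimum gated directional ADC, mm^2/s (default 1e-6).
#' @return An object of class `transition_weights`: list with `W` (nvox x
#'   26 probabilities), `adc` (clamped, un-floored directional ADC), `m`
#'   (0/1 gates), `nb` (nvox x 26 row index of each neighbor, 0 if not
#'   eligible), `vox` (linear voxel index per row), `d` (distance per row),
#'   `mode`, `grid`, `nbhd`.
#' @export
build_transition_matrix <- function(tensors, dm,
                                    mode = c("toward_tumor", "away_from_tumor"),
                                    adc_floor = 1e-6) {
  mode <- match.arg(mode)
  grid <- validate_grids(list(tensors, dm$grid))
  nbhd <- neighborhood_model(26L)
  vox <- eligible_voxels(dm)
  nvox <- length(vox)
  if (nvox == 0L) stop("no eligible white-matter voxels")
  shape <- grid$shape

  row_of <- integer(prod(shape))
  row_of[vox] <- seq_len(nvox)

  ijk <- arrayInd(vox, shape)
  dvec <- dm$d[vox]

  n_dir <- nrow(nbhd$offsets)
  nb <- matrix(0L, nvox, n_dir)
  dnb <- matrix(NA_integer_, nvox, n_dir)
  for (j in seq_len(n_dir)) {
    p <- ijk + matrix(nbhd$offsets[j, ], nvox, 3L, byrow = TRUE)
    ok <- p[, 1] >= 1L & p[, 1] <= shape[1] &
          p[, 2] >= 1L & p[, 2] <= shape[2] &
          p[, 3] >= 1L & p[, 3] <= shape[3]
    lin <- rep(0L, nvox)
    lin[ok] <- (p[ok, 3] - 1L) * shape[1] * shape[2] +
               (p[ok, 2] - 1L) * shape[1] + p[ok, 1]
    r <- rep(0L, nvox)
    r[ok] <- row_of[lin[ok]]
    nb[, j] <- r
    has <- r > 0L
    dnb[has, j] <- dvec[r[has]]
  }

  m <- nb > 0L
  if (mode == "toward_tumor") m <- m & !is.na(dnb) & dnb <= dvec
  else                        m <- m & !is.na(dnb) & dnb >= dvec

  comps <- matrix(tensors$values, prod(shape), 6L)[vox, , drop = FALSE]
  adc <- pmax(comps %*% quad_form_coeffs(nbhd$directions), 0)

  w <- matrix(0, nvox, n_dir)
  w[m] <- pmax(adc[m], adc_floor)
  rs <- rowSums(w)
  pos <- rs > 0
  w[pos, ] <- w[pos, , drop = FALSE] / rs[pos]

  structure(list(W = w, adc = adc, m = m * 1L, nb = nb, vox = vox,
                 d = dvec, mode = mode, grid = grid, nbhd = nbhd,
                 adc_floor = adc_floor),
            class = "transition_weights")
}

#' @export
print.transition_weights <- function(x, ...) {
  cat(sprintf("<transition_weights %s: %d voxels x %d directions, %d terminal rows>\n",
              x$mode, nrow(x$W), ncol(x$W), sum(rowSums(x$W) == 0)))
  invisible(x)
}
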