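# shift a logical array by an integer offset, padding with FALSE
shift_logical <- function(a, off) {
  d <- dim(a)
  out <- array(FALSE, dim = d)
  src <- dst <- vector("list", 3L)
  for (ax in 1:3) {
    o <- off[ax]
    if (o >= 0) {
      src[[ax]] <- seq_len(d[ax] - o)
      dst[[ax]] <- src[[ax]] + o
    } else {
      src[[ax]] <- seq(1L - o, d[ax])
      dst[[ax]] <- src[[ax]] + o
    }
    if (length(src[[ax]]) == 0L) return(out)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <-
    a[src[[1]], src[[2]], src[[3]]]
  out
}

dilate_mask <- function(a, nbhd) {
  out <- array(FALSE, dim = dim(a))
  for (j in seq_len(nrow(nbhd$offsets)))
    out <- out | shift_logical(a, nbhd$offsets[j, ])
  out
}

#' Step-distance map to the tumor border
#'
#' Labels every white-matter voxel with the minimal number of single-voxel
#' steps needed to reach the tumor, moving only inside the white-matter
#' mask. Voxels adjacent to the tumor get distance 1, their unlabeled
#' white-matter neighbors 2, and so on, until no further white-matter voxel
#' can be labeled. "Distance" is a pure step count through the white-matter
#' labyrinth — a diagonal step also counts 1 — not a straight-line length.
#' White-matter components not connected to the tumor are marked
#' unreachable (-1) and are excluded from all downstream analysis. Voxels
#' covered by both masks are treated as tumor.
#'
#' @param wm white-matter [binary_mask()].
#' @param tumor tumor [binary_mask()] on the same grid.
#' @param connectivity neighborhood used for one step (default 26, matching
#'   the 26 transition directions).
#' @return An object of class `distance_map`: list with `d` (integer array;
#'   `NA` outside the white matter, `-1` for unreachable white matter,
#'   otherwise steps >= 1), `d_max`, `grid`, `connectivity`.
#' @export
compute_distance_map <- function(wm, tumor, connectivity = 26L) {
  grid <- validate_grids(list(wm, tumor))
  if (!any(tumor$values)) stop("tumor mask is empty")
  if (!any(wm$values)) stop("white-matter mask is empty")
  nbhd <- neighborhood_model(connectivity)
  wmx <- wm$values & !tumor$values  # overlap resolved in favor of tumor
  d <- array(NA_integer_, dim = grid$shape)
  frontier <- tumor$values
  labeled <- array(FALSE, dim = grid$shape)
  k <- 0L
  repeat {
    new <- dilate_mask(frontier, nbhd) & wmx & !labeled
    if (!any(new)) break
    k <- k + 1L
    d[new] <- k
    labeled <- labeled | new
    frontier <- new
  }
  if (k == 0L)
    stop("no white-matter voxel adjacent to the tumor: distance map undefined")
  d[wmx & !labeled] <- -1L
  structure(list(d = d, d_max = k, grid = grid,
                 connectivity = as.integer(connectivity)),
            class = "distance_map")
}

#' @export
print.distance_map <- function(x, ...) {
  n_fin <- sum(x$d >= 1L, na.rm = TRUE)
  n_unr <- sum(x$d == -1L, na.rm = TRUE)
  cat(sprintf("<distance_map %s: %d eligible voxels, d_max = %d, %d unreachable>\n",
              paste(x$grid$shape, collapse = "x"), n_fin, x$d_max, n_unr))
  invisible(x)
}

#' Voxels eligible for analysis
#'
#' Returns the linear array indices of white-matter voxels with a finite
#' step distance to the tumor. These define the analysis domain for the
#' transition matrices, the trajectories and the output maps; unreachable
#' white matter is excluded.
#'
#' @param dm a [compute_distance_map()] result.
#' @return Sorted integer vector of linear voxel indices.
#' @export
eligible_voxels <- function(dm) {
  stopifnot(inherits(dm, "distance_map"))
  which(!is.na(dm$d) & dm$d >= 1L)
}

#' Export a distance map as a scalar volume
#'
#' Unreachable white matter is coded -1 and voxels outside the white
#' matter NaN, so the map can be written with [write_volume()].
#'
#' @param dm a `distance_map`.
#' @return A [scalar_map()] named `"distance"`.
#' @export
distance_as_map <- function(dm) {
  vals <- array(as.numeric(dm$d), dim = dm$grid$shape)
  vals[is.na(dm$d)] <- NaN
  scalar_map(vals, dm$grid, name = "distance")
}
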