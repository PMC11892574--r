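#' Voxel neighborhood model
#'
#' Enumerates the neighbor offsets of a voxel on the 3-D lattice together
#' with the matching unit direction vectors. The full 26-neighborhood (all
#' nonzero offsets in \{-1,0,1\}^3) is the default used throughout the
#' pipeline: the same 26 directions define the transition matrices and the
#' step-distance labeling, so "one step" means the same thing in every stage.
#'
#' @param connectivity 6, 18 or 26. 6 keeps face neighbors only, 18 adds
#'   edge neighbors, 26 adds corner neighbors.
#' @return An object of class `neighborhood_model`: a list with
#'   `offsets` (n x 3 integer matrix), `directions` (n x 3, unit rows),
#'   `opposite` (integer vector, `opposite[j]` indexes `-offsets[j, ]`) and
#'   `connectivity`.
#' @examples
#' nb <- neighborhood_model()
#' nrow(nb$offsets)  # 26
#' @export
neighborhood_model <- function(connectivity = 26L) {
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("connectivity must be 6, 18 or 26")
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(abs(g)) > 0L, , drop = FALSE]
  ord <- rowSums(abs(g))  # 1 = face, 2 = edge, 3 = corner
  keep <- switch(as.character(connectivity),
                 "6"  = ord == 1L,
                 "18" = ord <= 2L,
                 "26" = rep(TRUE, nrow(g)))
  offsets <- g[keep, , drop = FALSE]
  storage.mode(offsets) <- "integer"
  dimnames(offsets) <- NULL
  nrm <- sqrt(rowSums(offsets^2))
  directions <- offsets / nrm
  # index of the negated offset, needed to pair toward/away directions
  key <- function(m) paste(m[, 1], m[, 2], m[, 3])
  opposite <- match(key(-offsets), key(offsets))
  structure(list(offsets = offsets, directions = directions,
                 opposite = opposite, connectivity = connectivity),
            class = "neighborhood_model")
}
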