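# Shared fixture builders and independent oracles. Everything is generated
# in code; no data files.

# A straight 1-voxel-wide corridor along +x ending at a tumor block.
# Returns masks on an (len+4) x 7 x 7 grid with corridor distances 1..len.
corridor_masks <- function(len = 5L, width = 1L) {
  shape <- c(len + 4L, 7L, 7L)
  g <- voxel_grid(shape, c(1, 1, 1))
  tum <- array(FALSE, dim = shape)
  tum[1:2, 3:5, 3:5] <- TRUE
  wm <- array(FALSE, dim = shape)
  ys <- 4:(3L + width)
  wm[3:(2L + len), ys, ys] <- TRUE
  list(wm = binary_mask(wm, g), tumor = binary_mask(tum, g), grid = g)
}

# Constant (isotropic or x-aligned anisotropic) tensor field on a grid.
uniform_tensors <- function(grid, lambda_par = 1e-3, lambda_perp = lambda_par) {
  shape <- grid$shape
  comps <- array(0, dim = c(shape, 6L))
  comps[, , , 1] <- lambda_par
  comps[, , , 4] <- lambda_perp
  comps[, , , 6] <- lambda_perp
  tensor_field(comps, grid)
}

# Brute-force unit-weight shortest-path oracle for the distance map,
# independent of the package BFS: igraph::distances on the voxel
# adjacency graph, seeded at tumor-adjacent white-matter voxels.
oracle_distance <- function(wm_vals, tumor_vals, connectivity = 26L) {
  shape <- dim(wm_vals)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  offs <- offs[rowSums(abs(offs)) <= c(1L, 2L, 3L)[match(connectivity, c(6L, 18L, 26L))], ,
               drop = FALSE]
  wmx <- wm_vals & !tumor_vals
  idx <- which(wmx)
  n <- length(idx)
  d_out <- array(NA_integer_, dim = shape)
  if (n == 0L) return(d_out)
  rank_of <- integer(prod(shape))
  rank_of[idx] <- seq_len(n)
  ijk <- arrayInd(idx, shape)
  edges <- NULL
  seed <- logical(n)
  for (r in seq_len(nrow(offs))) {
    p <- ijk + matrix(offs[r, ], n, 3L, byrow = TRUE)
    ok <- p[, 1] >= 1 & p[, 1] <= shape[1] & p[, 2] >= 1 & p[, 2] <= shape[2] &
          p[, 3] >= 1 & p[, 3] <= shape[3]
    lin <- (p[ok, 3] - 1L) * shape[1] * shape[2] + (p[ok, 2] - 1L) * shape[1] + p[ok, 1]
    to <- rank_of[lin]
    here <- which(ok)
    inwm <- to > 0L
    edges <- rbind(edges, cbind(here[inwm], to[inwm]))
    seed[here[tumor_vals[lin]]] <- TRUE
  }
  if (!any(seed)) stop("oracle: no white-matter voxel adjacent to tumor")
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (!is.null(edges) && nrow(edges) > 0L) {
    keep <- edges[, 1] < edges[, 2]
    g <- igraph::add_edges(g, t(edges[keep, , drop = FALSE]))
  }
  dmat <- igraph::distances(g, v = which(seed))
  dmin <- apply(dmat, 2L, min) + 1
  dv <- rep(-1L, n)
  fin <- is.finite(dmin)
  dv[fin] <- as.integer(dmin[fin])
  d_out[idx] <- dv
  d_out
}

# Random co-registered mask pair on a small grid, with one white-matter
# voxel forced adjacent to the tumor so the distance map is defined.
random_mask_pair <- function(shape, p_wm = 0.45) {
  g <- voxel_grid(shape, c(1, 1, 1))
  tum <- array(FALSE, dim = shape)
  c0 <- pmax(pmin(sapply(shape, function(s) sample.int(s, 1)), shape - 1L), 2L)
  r <- sample(1:2, 1)
  for (dx in -r:r) for (dy in -r:r) for (dz in -r:r) {
    p <- c0 + c(dx, dy, dz)
    if (all(p >= 1L) && all(p <= shape) && sum(c(dx, dy, dz)^2) <= r^2)
      tum[p[1], p[2], p[3]] <- TRUE
  }
  wm <- array(stats::runif(prod(shape)) < p_wm, dim = shape)
  adj <- c0 + c(r + 1L, 0L, 0L)
  adj <- pmin(pmax(adj, 1L), shape)
  wm[adj[1], adj[2], adj[3]] <- TRUE
  list(wm = binary_mask(wm, g), tumor = binary_mask(tum, g))
}

# Bare profile object for operating directly on sample sequences.
raw_profile <- function(values, x = seq_along(values),
                        voxel = seq_along(values)) {
  structure(list(x = as.numeric(x), raw = as.numeric(values),
                 smoothed = NULL, voxel = as.integer(voxel),
                 trajectory_id = 1L),
            class = "trajectory_profile")
}

# A 2-voxel-wide corridor (2x2 cross-section) with a tumor slab at x = 1:2,
# so d = x - 2 on every cross-section voxel; tensors anisotropic along x.
wide_corridor_bundle <- function(len = 12L, lambda_par = 1.7e-3,
                                 lambda_perp = 0.3e-3) {
  shape <- c(len + 4L, 7L, 7L)
  g <- voxel_grid(shape, c(1, 1, 1))
  tum <- array(FALSE, dim = shape)
  tum[1:2, 4:5, 4:5] <- TRUE
  wm <- array(FALSE, dim = shape)
  wm[3:(2L + len), 4:5, 4:5] <- TRUE
  tens <- uniform_tensors(g, lambda_par, lambda_perp)
  list(wm = binary_mask(wm, g), tumor = binary_mask(tum, g), tensors = tens,
       grid = g)
}
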