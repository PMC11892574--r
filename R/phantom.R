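#' Synthetic phantom specification
#'
#' Describes a lattice-native test phantom: a white-matter geometry around
#' a spherical tumor, a diffusion-tensor field aligned with the local
#' corridor axis, and a parametric map that either carries a planted
#' gradient zone around the tumor (glioblastoma mode: perifocal
#' infiltration fades with distance) or is flat outside the tumor
#' (metastasis mode: pure vasogenic edema, no infiltrative component),
#' plus additive Gaussian noise.
#'
#' @param grid_shape integer triple (default 40x40x40).
#' @param voxel_size mm triple (default 2.5 isotropic, a typical DKI grid).
#' @param geometry `"labyrinth"` (randomized connected corridor maze,
#'   emulating the labyrinthine white matter), `"corridor"` (one straight
#'   tube to the tumor) or `"shell"` (solid white-matter ball).
#' @param tumor_radius,edema_radius voxels; the enhancing core and the
#'   perifocal shell (`edema_radius >= tumor_radius`).
#' @param mode `"glioblastoma"` or `"metastasis"`.
#' @param lambda_parallel,lambda_perp tensor eigenvalues, mm^2/s (defaults
#'   1.7e-3 along the corridor axis, 0.3e-3 across — healthy white-matter
#'   values).
#' @param map_baseline,map_contrast parametric-map baseline and planted
#'   ramp height, map units.
#' @param gradient_extent steps of the distance map over which the planted
#'   ramp decays outward from the tumor border (glioblastoma mode).
#' @param noise_sigma additive Gaussian noise sd, map units.
#' @param seed integer seed; the same seed yields a bit-identical phantom.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(40L, 40L, 40L),
                         voxel_size = c(2.5, 2.5, 2.5),
                         geometry = c("labyrinth", "corridor", "shell"),
                         tumor_radius = 4, edema_radius = 7,
                         mode = c("glioblastoma", "metastasis"),
                         lambda_parallel = 1.7e-3, lambda_perp = 0.3e-3,
                         map_baseline = 1.0, map_contrast = 0.5,
                         gradient_extent = 5L, noise_sigma = 0.05,
                         seed = 1L) {
  geometry <- match.arg(geometry)
  mode <- match.arg(mode)
  stopifnot(edema_radius >= tumor_radius, tumor_radius >= 1,
            lambda_parallel > 0, lambda_perp > 0, noise_sigma >= 0,
            gradient_extent >= 1)
  structure(list(grid_shape = as.integer(grid_shape),
                 voxel_size = as.numeric(voxel_size),
                 geometry = geometry, tumor_radius = tumor_radius,
                 edema_radius = edema_radius, mode = mode,
                 lambda_parallel = lambda_parallel,
                 lambda_perp = lambda_perp,
                 map_baseline = map_baseline, map_contrast = map_contrast,
                 gradient_extent = as.integer(gradient_extent),
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "phantom_spec")
}

ball_mask <- function(shape, center, radius) {
  i <- array(rep(seq_len(shape[1]), times = shape[2] * shape[3]), dim = shape)
  j <- array(rep(rep(seq_len(shape[2]), each = shape[1]), times = shape[3]),
             dim = shape)
  k <- array(rep(seq_len(shape[3]), each = shape[1] * shape[2]), dim = shape)
  (i - center[1])^2 + (j - center[2])^2 + (k - center[3])^2 <= radius^2
}

# carve a straight voxel segment between two lattice points (axis-aligned
# or diagonal with equal per-axis extents), recording the segment axis
carve_segment <- function(env, from, to) {
  delta <- to - from
  n <- max(abs(delta))
  step <- delta / n
  u <- step / sqrt(sum(step^2))
  for (t in 0:n) {
    p <- round(from + t * step)
    env$wm[p[1], p[2], p[3]] <- TRUE
    env$ux[p[1], p[2], p[3]] <- u[1]
    env$uy[p[1], p[2], p[3]] <- u[2]
    env$uz[p[1], p[2], p[3]] <- u[3]
  }
}

# randomized-Prim spanning tree over a coarse node lattice (6-connected),
# corridors carved between tree-adjacent nodes
carve_labyrinth <- function(env, shape, center, spacing = 3L) {
  ax <- lapply(1:3, function(a) {
    lo <- center[a] - spacing * ((center[a] - 2L) %/% spacing)
    seq(lo, shape[a] - 1L, by = spacing)
  })
  nodes <- as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]]))
  nn <- nrow(nodes)
  key <- paste(nodes[, 1], nodes[, 2], nodes[, 3])
  idx_of <- function(p) match(paste(p[1], p[2], p[3]), key)
  root <- idx_of(center)
  if (is.na(root)) root <- which.min(colSums((t(nodes) - center)^2))
  in_tree <- logical(nn)
  in_tree[root] <- TRUE
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1)) * spacing
  # frontier edges: candidate (tree-node, outside-node) pairs
  frontier <- list()
  push_edges <- function(i) {
    for (r in seq_len(nrow(offs))) {
      q <- nodes[i, ] + offs[r, ]
      j <- idx_of(q)
      if (!is.na(j) && !in_tree[j])
        frontier[[length(frontier) + 1L]] <<- c(i, j)
    }
  }
  push_edges(root)
  while (length(frontier) > 0L) {
    pickr <- sample.int(length(frontier), 1L)
    e <- frontier[[pickr]]
    frontier[[pickr]] <- frontier[[length(frontier)]]
    frontier[[length(frontier)]] <- NULL
    if (in_tree[e[2]]) next
    in_tree[e[2]] <- TRUE
    carve_segment(env, nodes[e[1], ], nodes[e[2], ])
    push_edges(e[2])
  }
}

finish_phantom <- function(env, spec, grid, tumor_vals, truth_fun) {
  shape <- spec$grid_shape
  wm_vals <- env$wm & !tumor_vals
  if (!any(wm_vals)) stop("phantom geometry has no white matter")
  wm <- binary_mask(wm_vals, grid)
  tumor <- binary_mask(tumor_vals, grid)

  # tensors: lambda_perp * I + (lambda_parallel - lambda_perp) * u u'
  lp <- spec$lambda_parallel
  lq <- spec$lambda_perp
  ux <- env$ux; uy <- env$uy; uz <- env$uz
  none <- wm_vals & (ux == 0 & uy == 0 & uz == 0)
  ux[none] <- 1  # voxels carved without an axis default to +x
  dl <- lp - lq
  comps <- array(0, dim = c(shape, 6L))
  comps[, , , 1] <- lq + dl * ux * ux
  comps[, , , 2] <- dl * ux * uy
  comps[, , , 3] <- dl * ux * uz
  comps[, , , 4] <- lq + dl * uy * uy
  comps[, , , 5] <- dl * uy * uz
  comps[, , , 6] <- lq + dl * uz * uz
  tensors <- tensor_field(comps, grid)

  dm <- compute_distance_map(wm, tumor)
  vals <- array(spec$map_baseline, dim = shape)
  truth_vals <- array(FALSE, dim = shape)
  if (spec$mode == "glioblastoma") {
    tr <- truth_fun(dm)
    vals <- vals + tr$ramp
    truth_vals <- tr$truth
  }
  if (spec$noise_sigma > 0)
    vals <- vals + array(stats::rnorm(prod(shape), 0, spec$noise_sigma),
                         dim = shape)
  pmap <- scalar_map(vals, grid, name = "synthetic")
  list(wm = wm, tumor = tumor, tensors = tensors, pmap = pmap,
       truth = binary_mask(truth_vals, grid), distance = dm, spec = spec)
}

ramp_from_distance <- function(dm, spec, where = NULL) {
  d <- dm$d
  ramp <- array(0, dim = dim(d))
  fin <- !is.na(d) & d >= 1L
  if (!is.null(where)) fin <- fin & where
  d0 <- if (is.null(where)) 1L else min(d[fin])
  ramp[fin] <- spec$map_contrast *
    pmax(0, 1 - (d[fin] - d0) / spec$gradient_extent)
  list(ramp = ramp, truth = ramp > 0)
}

#' Build a synthetic phantom
#'
#' Constructs the white-matter and tumor masks, the axis-aligned tensor
#' field and the parametric map described by a [phantom_spec()], together
#' with the planted-truth mask (voxels carrying the planted gradient ramp;
#' empty in metastasis mode). In glioblastoma mode the map rises by
#' `map_contrast` at the tumor border and decays linearly to baseline over
#' `gradient_extent` steps of the internal distance map.
#'
#' @param spec a [phantom_spec()].
#' @return List with `wm`, `tumor` ([binary_mask()]), `tensors`
#'   ([tensor_field()]), `pmap` ([scalar_map()]), `truth` (planted-gradient
#'   [binary_mask()]), `distance` (the internal `distance_map`), `spec`.
#' @export
make_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  shape <- spec$grid_shape
  grid <- voxel_grid(shape, spec$voxel_size)
  center <- (shape + 1L) %/% 2L
  tumor_vals <- ball_mask(shape, center, spec$tumor_radius)
  env <- new.env()
  env$wm <- array(FALSE, dim = shape)
  env$ux <- array(0, dim = shape)
  env$uy <- array(0, dim = shape)
  env$uz <- array(0, dim = shape)
  if (spec$geometry == "corridor") {
    carve_segment(env, c(center[1], center[2], center[3]),
                  c(shape[1] - 2L, center[2], center[3]))
  } else if (spec$geometry == "shell") {
    rad <- min(shape) %/% 2L - 2L
    sh <- ball_mask(shape, center, rad)
    idx <- which(sh)
    ijk <- arrayInd(idx, shape)
    v <- sweep(ijk, 2L, center)
    nrm <- sqrt(rowSums(v^2))
    nrm[nrm == 0] <- 1
    env$wm <- sh
    env$ux[idx] <- v[, 1] / nrm
    env$uy[idx] <- v[, 2] / nrm
    env$uz[idx] <- v[, 3] / nrm
  } else {
    carve_labyrinth(env, shape, center)
  }
  out <- finish_phantom(env, spec, grid, tumor_vals,
                        function(dm) ramp_from_distance(dm, spec))
  if (!any(out$distance$d == 1L, na.rm = TRUE))
    stop("phantom geometry disconnected: tumor not adjacent to white matter")
  out
}

#' Two-slice crossing phantom
#'
#' Emulates an invasion path that no single axial slice can show: two
#' planar corridor systems on different slices are joined by an oblique
#' bridge, and (in glioblastoma mode) the gradient ramp is planted only on
#' the bridge path. Inspecting either slice alone shows flat corridors;
#' trajectory profiles that traverse the bridge cross the planted
#' gradient.
#'
#' @param spec a [phantom_spec()]; `geometry` is ignored.
#' @return Same bundle as [make_phantom()].
#' @export
make_two_slice_crossing_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  shape <- spec$grid_shape
  if (any(shape < 24L)) stop("two-slice phantom needs a grid of at least 24 voxels per axis")
  grid <- voxel_grid(shape, spec$voxel_size)
  cx <- (shape[1] + 1L) %/% 2L
  cy <- (shape[2] + 1L) %/% 2L
  z1 <- shape[3] %/% 3L
  z2 <- (2L * shape[3]) %/% 3L
  center <- c(cx, cy, z1)
  tumor_vals <- ball_mask(shape, center, spec$tumor_radius)
  env <- new.env()
  env$wm <- array(FALSE, dim = shape)
  env$ux <- array(0, dim = shape)
  env$uy <- array(0, dim = shape)
  env$uz <- array(0, dim = shape)
  # zone 1: crossing corridors in slice z1
  carve_segment(env, c(2L, cy, z1), c(shape[1] - 1L, cy, z1))
  carve_segment(env, c(cx, 2L, z1), c(cx, shape[2] - 1L, z1))
  # oblique bridge from the zone-1 corridor up to slice z2
  bx0 <- cx + spec$tumor_radius + 2L
  dz <- z2 - z1
  carve_segment(env, c(bx0, cy, z1), c(bx0 + dz, cy, z2))
  bridge <- array(FALSE, dim = shape)
  for (t in 0:dz) bridge[bx0 + t, cy, z1 + t] <- TRUE
  # zone 2: crossing corridors in slice z2
  bx1 <- bx0 + dz
  carve_segment(env, c(2L, cy, z2), c(shape[1] - 1L, cy, z2))
  carve_segment(env, c(bx1, 2L, z2), c(bx1, shape[2] - 1L, z2))
  out <- finish_phantom(env, spec, grid, tumor_vals,
                        function(dm) ramp_from_distance(dm, spec,
                                                        where = bridge))
  out$bridge <- binary_mask(bridge & out$wm$values, grid)
  out
}
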