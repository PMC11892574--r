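#' Accumulate per-voxel gradient statistics over profiles
#'
#' For each trajectory profile, every distinct voxel it visits increments
#' the per-voxel trajectory count `q` once; a voxel increments the rising
#' count `p_up` when any of its samples in that profile lies inside a
#' significant rising segment, and `p_down` likewise for falling segments.
#' A voxel can increment both counts from one trajectory when it lies in
#' segments of both kinds.
#'
#' @param profiles list of smoothed profiles, each carrying a `segments`
#'   element as returned by [detect_gradient_segments()].
#' @param dm the `distance_map` defining the grid.
#' @return An object of class `voxel_gradient_stats`: list with integer
#'   arrays-as-vectors `p_up`, `p_down`, `q` (length `prod(shape)`), and
#'   `grid`.
#' @export
accumulate_stats <- function(profiles, dm) {
  grid <- dm$grid
  nvol <- prod(grid$shape)
  q <- integer(nvol)
  p_up <- integer(nvol)
  p_down <- integer(nvol)
  for (p in profiles) {
    seg <- p$segments
    if (is.null(seg)) stop("profile without segment labels")
    n <- length(p$raw)
    up <- logical(n)
    down <- logical(n)
    sig <- seg[seg$significant, , drop = FALSE]
    if (nrow(sig) > 0L) {
      for (i in seq_len(nrow(sig))) {
        span <- sig$start[i]:sig$end[i]
        if (sig$direction[i] == "rising") up[span] <- TRUE
        else down[span] <- TRUE
      }
    }
    uvox <- unique(p$voxel)
    q[uvox] <- q[uvox] + 1L
    if (any(up)) {
      u <- unique(p$voxel[up])
      p_up[u] <- p_up[u] + 1L
    }
    if (any(down)) {
      u <- unique(p$voxel[down])
      p_down[u] <- p_down[u] + 1L
    }
  }
  structure(list(p_up = p_up, p_down = p_down, q = q, grid = grid),
            class = "voxel_gradient_stats")
}

#' Percentage gradient maps from accumulated statistics
#'
#' Elementwise `100 * P / Q`, reported separately for rising and falling
#' gradients; voxels with no trajectory (`q = 0`) are NaN and excluded.
#' The two maps are independent — a voxel lying in both a rising and a
#' falling significant segment contributes to both, so their sum may
#' exceed 100.
#'
#' @param stats a [accumulate_stats()] result.
#' @param map_name label of the source parametric map.
#' @return An object of class `gradient_map`: list with `up_pct` and
#'   `down_pct` (3-D arrays, values in \[0, 100\] or NaN), `map_name`,
#'   `grid`.
#' @export
compute_gradient_map <- function(stats, map_name = "other") {
  shape <- stats$grid$shape
  pct <- function(p) {
    v <- rep(NaN, length(stats$q))
    pos <- stats$q > 0L
    v[pos] <- 100 * p[pos] / stats$q[pos]
    array(v, dim = shape)
  }
  structure(list(up_pct = pct(stats$p_up), down_pct = pct(stats$p_down),
                 map_name = map_name, grid = stats$grid),
            class = "gradient_map")
}

#' @export
print.gradient_map <- function(x, ...) {
  fin <- is.finite(x$up_pct)
  cat(sprintf(
    "<gradient_map '%s': %d voxels, mean up %.1f%%, mean down %.1f%%>\n",
    x$map_name, sum(fin), mean(x$up_pct[fin]), mean(x$down_pct[fin])))
  invisible(x)
}

profile_one_map <- function(ts, pmap, dm, smoothing) {
  profiles <- vector("list", length(ts$trajectories))
  for (i in seq_along(ts$trajectories)) {
    p <- extract_profile(ts$trajectories[[i]], pmap, dm, id = i)
    p <- smooth_profile(p, smoothing)
    p$segments <- detect_gradient_segments(p, smoothing)
    profiles[[i]] <- p
  }
  profiles
}

#' Map tumor invasion from diffusion MRI volumes
#'
#' The full pipeline: validates that all volumes share one grid, labels the
#' white matter by step distance to the tumor border, builds the
#' toward-tumor and away-from-tumor transition matrices from the tensor
#' field, generates the pseudorandom trajectory set under the
#' coverage-driven scheduler, and — reusing the same trajectories for
#' every parametric map — extracts profiles, median-smooths them, detects
#' significant rising/falling gradient segments and aggregates them into
#' the per-voxel percentage maps `100 * P / Q`.
#'
#' @param wm white-matter [binary_mask()].
#' @param tumor tumor [binary_mask()].
#' @param tensors a [tensor_field()] (mm^2/s).
#' @param pmaps a single [scalar_map()] or a (preferably named) list of
#'   them; each gets its own output gradient map from the shared
#'   trajectory set.
#' @param walk a [walk_config()].
#' @param smoothing a [smoothing_config()].
#' @param keep_profiles retain the per-trajectory profiles of each map in
#'   the result (memory-heavy; default FALSE).
#' @return An object of class `invasion_map`: list with `maps` (named list
#'   of [compute_gradient_map()] results), `distance` (`distance_map`),
#'   `trajectories` (`trajectory_set`), `stats` (per-map
#'   `voxel_gradient_stats`), `walk`, `smoothing`, `call`; plus `profiles`
#'   when requested.
#' @examples
#' ph <- make_phantom(phantom_spec(grid_shape = c(20, 20, 20),
#'                                 geometry = "corridor", tumor_radius = 3,
#'                                 noise_sigma = 0, seed = 1))
#' fit <- invasion_map(ph$wm, ph$tumor, ph$tensors, list(MK = ph$pmap),
#'                     walk = walk_config(min_coverage = 10, seed = 1))
#' fit
#' @export
invasion_map <- function(wm, tumor, tensors, pmaps,
                         walk = walk_config(), smoothing = smoothing_config(),
                         keep_profiles = FALSE) {
  if (inherits(pmaps, "scalar_map")) pmaps <- list(pmaps)
  if (is.null(names(pmaps)))
    names(pmaps) <- vapply(pmaps, function(p) p$name, character(1))
  validate_grids(c(list(wm, tumor, tensors), pmaps))
  dm <- compute_distance_map(wm, tumor)
  tw_t <- build_transition_matrix(tensors, dm, "toward_tumor")
  tw_a <- build_transition_matrix(tensors, dm, "away_from_tumor")
  ts <- generate_trajectory_set(tw_t, tw_a, dm, walk)
  maps <- list()
  stats <- list()
  kept <- list()
  for (nm in names(pmaps)) {
    profiles <- profile_one_map(ts, pmaps[[nm]], dm, smoothing)
    st <- accumulate_stats(profiles, dm)
    maps[[nm]] <- compute_gradient_map(st, map_name = nm)
    stats[[nm]] <- st
    if (keep_profiles) kept[[nm]] <- profiles
  }
  out <- list(maps = maps, distance = dm, trajectories = ts, stats = stats,
              walk = walk, smoothing = smoothing, call = match.call())
  if (keep_profiles) out$profiles <- kept
  structure(out, class = "invasion_map")
}

#' @export
print.invasion_map <- function(x, ...) {
  cat("Tumor invasion map\n")
  cat(sprintf("  grid:          %s voxels\n",
              paste(x$distance$grid$shape, collapse = " x ")))
  cat(sprintf("  eligible WM:   %d voxels, d_max = %d steps\n",
              length(x$trajectories$vox), x$distance$d_max))
  cat(sprintf("  trajectories:  %d (min coverage %d, %d cycles, %d failed segments)\n",
              length(x$trajectories$trajectories), min(x$trajectories$coverage),
              x$trajectories$n_cycles, x$trajectories$n_failed))
  for (nm in names(x$maps)) {
    g <- x$maps[[nm]]
    fin <- is.finite(g$up_pct)
    cat(sprintf("  map %-8s mean up %5.1f%%, mean down %5.1f%%\n",
                paste0(nm, ":"), mean(g$up_pct[fin]), mean(g$down_pct[fin])))
  }
  invisible(x)
}

#' @export
summary.invasion_map <- function(object, ...) {
  ts <- object$trajectories
  per_map <- do.call(rbind, lapply(names(object$maps), function(nm) {
    g <- object$maps[[nm]]
    fin <- is.finite(g$up_pct)
    data.frame(map = nm,
               mean_up_pct = mean(g$up_pct[fin]),
               max_up_pct = max(g$up_pct[fin]),
               mean_down_pct = mean(g$down_pct[fin]),
               max_down_pct = max(g$down_pct[fin]))
  }))
  out <- list(n_eligible = length(ts$vox), d_max = object$distance$d_max,
              n_trajectories = length(ts$trajectories),
              min_coverage = min(ts$coverage),
              median_coverage = stats::median(ts$coverage),
              n_failed = ts$n_failed, per_map = per_map)
  class(out) <- "summary.invasion_map"
  out
}

#' @export
print.summary.invasion_map <- function(x, ...) {
  cat(sprintf("eligible voxels: %d   d_max: %d steps\n", x$n_eligible, x$d_max))
  cat(sprintf("trajectories: %d   coverage min/median: %d/%g   failed segments: %d\n",
              x$n_trajectories, x$min_coverage, x$median_coverage, x$n_failed))
  print(x$per_map, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Plot an axial slice of a gradient map
#'
#' @param x an `invasion_map`.
#' @param map name or index of the parametric map (default first).
#' @param which `"up"` or `"down"`.
#' @param slice axial (third-axis) slice index; defaults to the slice with
#'   the most finite voxels.
#' @param ... passed to [graphics::image()].
#' @return `x`, invisibly.
#' @export
plot.invasion_map <- function(x, map = 1L, which = c("up", "down"),
                              slice = NULL, ...) {
  which <- match.arg(which)
  g <- x$maps[[map]]
  vol <- if (which == "up") g$up_pct else g$down_pct
  if (is.null(slice))
    slice <- which.max(apply(is.finite(vol), 3L, sum))
  graphics::image(vol[, , slice], zlim = c(0, 100),
                  col = grDevices::hcl.colors(64, "Inferno"),
                  main = sprintf("%s %s%% (slice %d)", g$map_name, which, slice),
                  useRaster = TRUE, ...)
  invisible(x)
}

#' Write pipeline outputs to a directory
#'
#' Writes `<map>_up_pct.nii.gz` and `<map>_down_pct.nii.gz` per parametric
#' map (float32, NaN-excluded voxels), optionally the distance and coverage
#' volumes, and a JSON run report (configuration echo, trajectory counts,
#' wall time).
#'
#' @param fit an [invasion_map()] result.
#' @param dir output directory (created if missing).
#' @param save_distance,save_coverage also write the distance / coverage
#'   volumes.
#' @return Character vector of files written, invisibly.
#' @export
write_invasion_map <- function(fit, dir, save_distance = FALSE,
                               save_coverage = FALSE) {
  stopifnot(inherits(fit, "invasion_map"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (nm in names(fit$maps)) {
    g <- fit$maps[[nm]]
    up <- file.path(dir, paste0(nm, "_up_pct.nii.gz"))
    dn <- file.path(dir, paste0(nm, "_down_pct.nii.gz"))
    write_volume(scalar_map(g$up_pct, g$grid, paste0(nm, "_up_pct")), up)
    write_volume(scalar_map(g$down_pct, g$grid, paste0(nm, "_down_pct")), dn)
    files <- c(files, up, dn)
  }
  if (save_distance) {
    f <- file.path(dir, "distance.nii.gz")
    write_volume(distance_as_map(fit$distance), f)
    files <- c(files, f)
  }
  if (save_coverage) {
    f <- file.path(dir, "coverage.nii.gz")
    write_volume(coverage_as_map(fit$trajectories), f)
    files <- c(files, f)
  }
  report <- list(
    maps = names(fit$maps),
    n_trajectories = length(fit$trajectories$trajectories),
    min_coverage = min(fit$trajectories$coverage),
    n_failed_segments = fit$trajectories$n_failed,
    d_max = fit$distance$d_max,
    walk = unclass(fit$walk),
    smoothing = unclass(fit$smoothing),
    files = files)
  rf <- file.path(dir, "run_report.json")
  jsonlite::write_json(report, rf, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  invisible(c(files, rf))
}
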