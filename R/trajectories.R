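#' Random-walk configuration
#'
#' Holds the trajectory-generation settings. The shipped defaults are the
#' method's operating constants: every eligible voxel must be covered by at
#' least 100 trajectories before generation stops, and a trajectory may
#' take at most 12 consecutive steps without getting closer to the tumor
#' before its next step is forced downhill.
#'
#' @param min_coverage minimum trajectories through every eligible voxel
#'   (default 100).
#' @param stall_limit maximum consecutive equal-distance steps (default 12).
#' @param seed optional integer seed; when non-NULL, [generate_trajectory_set()]
#'   seeds R's RNG so runs are bit-reproducible.
#' @param max_cycles safety bound on scheduler cycles (default 1000).
#' @param max_steps safety bound on steps per walk segment (default 1e6).
#' @return A list of class `walk_config`.
#' @export
walk_config <- function(min_coverage = 100L, stall_limit = 12L, seed = NULL,
                        max_cycles = 1000L, max_steps = 1000000L) {
  stopifnot(min_coverage >= 1L, stall_limit >= 1L, max_cycles >= 1L)
  structure(list(min_coverage = as.integer(min_coverage),
                 stall_limit = as.integer(stall_limit),
                 seed = if (!is.null(seed)) as.integer(seed),
                 max_cycles = as.integer(max_cycles),
                 max_steps = as.integer(max_steps)),
            class = "walk_config")
}

row_for_voxel <- function(tw, voxel) {
  r <- match(voxel, tw$vox)
  if (is.na(r)) stop("start voxel is not an eligible white-matter voxel")
  r
}

#' Walk one trajectory segment toward the tumor
#'
#' Starting at an eligible voxel, repeatedly samples the next step from the
#' toward-tumor transition row of the current voxel until a voxel at
#' distance 1 (the tumor margin) is entered. A run of `stall_limit`
#' consecutive steps at unchanged distance forces the next draw onto
#' strictly-decreasing-distance neighbors (renormalized), so walks cannot
#' wander a stratum indefinitely.
#'
#' @param start linear voxel index of the start (must be eligible).
#' @param tw_toward toward-mode [build_transition_matrix()] result.
#' @param dm the matching `distance_map`.
#' @param cfg a [walk_config()].
#' @return List with `voxels` (linear indices, start first), `d`,
#'   `reached_margin`, `failed`.
#' @export
walk_toward_tumor <- function(start, tw_toward, dm, cfg = walk_config()) {
  stopifnot(tw_toward$mode == "toward_tumor")
  r <- row_for_voxel(tw_toward, start)
  res <- walk_toward_cpp(r, tw_toward$W, tw_toward$nb, tw_toward$d,
                         cfg$stall_limit, cfg$max_steps)
  rows <- res$path
  list(voxels = tw_toward$vox[rows], rows = rows, d = tw_toward$d[rows],
       reached_margin = res$reached_margin, failed = res$failed)
}

#' Walk one trajectory segment away from the tumor
#'
#' Samples steps under the away-mode matrix (directions toward smaller
#' distance nullified) until the walk reaches a voxel with an all-zero row
#' (a local distance maximum) or has taken `stall_limit` consecutive
#' equal-distance steps. Always returns at least the start voxel.
#'
#' @inheritParams walk_toward_tumor
#' @param tw_away away-mode [build_transition_matrix()] result.
#' @return List with `voxels`, `d`.
#' @export
walk_away_from_tumor <- function(start, tw_away, cfg = walk_config()) {
  stopifnot(tw_away$mode == "away_from_tumor")
  r <- row_for_voxel(tw_away, start)
  res <- walk_away_cpp(r, tw_away$W, tw_away$nb, tw_away$d,
                       cfg$stall_limit, cfg$max_steps)
  rows <- res$path
  list(voxels = tw_away$vox[rows], rows = rows, d = tw_away$d[rows])
}

#' Generate the full pseudorandom trajectory set
#'
#' Runs the coverage-driven scheduler until every eligible voxel lies on at
#' least `cfg$min_coverage` trajectories. The first cycle starts
#' trajectories from uncovered voxels, working from the most distant
#' stratum (`d_max`) toward the tumor and exhausting each stratum before
#' moving on. Later cycles revisit each stratum from far to near and start
#' new trajectories from the voxels with the lowest current coverage.
#' A start not at `d_max` is stitched from two segments sharing the start
#' voxel: one walked toward the tumor and one walked away from it; the
#' stored trajectory runs continuously from the far end to the tumor
#' margin, then is oriented tumor-first for profiling. Each trajectory
#' increments a voxel's coverage at most once, even if it revisits the
#' voxel. Failed toward-segments are discarded and regenerated (counted in
#' `n_failed`).
#'
#' @param tw_toward,tw_away the two [build_transition_matrix()] results.
#' @param dm the matching `distance_map`.
#' @param cfg a [walk_config()]; `cfg$seed`, when set, seeds the single RNG
#'   stream driving scheduling and step draws.
#' @return An object of class `trajectory_set`: list with `trajectories`
#'   (each: `voxels` linear indices oriented tumor-first, `d`, `start`,
#'   `n_toward` length of the toward part, `reached_margin`, `stitched`),
#'   `coverage` (integer per eligible row), `vox`, `d`, `n_failed`,
#'   `n_cycles`, `grid`.
#' @export
generate_trajectory_set <- function(tw_toward, tw_away, dm,
                                    cfg = walk_config()) {
  stopifnot(tw_toward$mode == "toward_tumor",
            tw_away$mode == "away_from_tumor",
            identical(tw_toward$vox, tw_away$vox))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  vox <- tw_toward$vox
  nvox <- length(vox)
  if (nvox == 0L) stop("no eligible voxels")
  dvec <- tw_toward$d
  d_max <- dm$d_max
  strata <- lapply(seq_len(d_max), function(k) which(dvec == k))
  coverage <- integer(nvox)
  n_failed <- 0L
  trajectories <- vector("list", 0L)
  ntraj <- 0L

  launch <- function(row) {
    # retry failed toward-segments; with the ADC floor they should not occur
    for (try in 1:5) {
      tow <- walk_toward_cpp(row, tw_toward$W, tw_toward$nb, tw_toward$d,
                             cfg$stall_limit, cfg$max_steps)
      if (!tow$failed) break
      n_failed <<- n_failed + 1L
    }
    if (tow$failed)
      stop("toward-segment from voxel ", vox[row],
           " failed repeatedly: no admissible step (corrupt transition matrix?)")
    stitched <- dvec[row] < d_max
    if (stitched) {
      awy <- walk_away_cpp(row, tw_away$W, tw_away$nb, tw_away$d,
                           cfg$stall_limit, cfg$max_steps)
      away_rows <- awy$path
    } else away_rows <- row
    # oriented tumor-first: reversed toward part, then the away part
    rows <- c(rev(tow$path), away_rows[-1L])
    ntraj <<- ntraj + 1L
    trajectories[[ntraj]] <<- list(
      voxels = vox[rows], d = dvec[rows], start = vox[row],
      n_toward = length(tow$path), reached_margin = tow$reached_margin,
      stitched = stitched && length(away_rows) > 1L)
    u <- unique(rows)
    coverage[u] <<- coverage[u] + 1L
    invisible(NULL)
  }

  pick <- function(cand) cand[sample.int(length(cand), 1L)]

  # cycle 1: exhaust uncovered voxels stratum by stratum, far to near
  for (k in rev(seq_len(d_max))) {
    repeat {
      zc <- strata[[k]][coverage[strata[[k]]] == 0L]
      if (length(zc) == 0L) break
      launch(pick(zc))
    }
  }
  cycle <- 1L
  while (min(coverage) < cfg$min_coverage) {
    cycle <- cycle + 1L
    if (cycle > cfg$max_cycles)
      stop("coverage target not reached within max_cycles (pathological geometry?)")
    for (k in rev(seq_len(d_max))) {
      s <- strata[[k]]
      if (length(s) == 0L) next
      cmin <- min(coverage[s])
      if (cmin >= cfg$min_coverage) next
      targets <- s[coverage[s] == cmin]
      for (row in targets[sample.int(length(targets))]) launch(row)
    }
  }

  structure(list(trajectories = trajectories[seq_len(ntraj)],
                 coverage = coverage, vox = vox, d = dvec,
                 n_failed = n_failed, n_cycles = cycle,
                 grid = tw_toward$grid),
            class = "trajectory_set")
}

#' @export
print.trajectory_set <- function(x, ...) {
  cat(sprintf(
    "<trajectory_set: %d trajectories over %d voxels, coverage %d..%d, %d cycles, %d failed segments>\n",
    length(x$trajectories), length(x$vox), min(x$coverage), max(x$coverage),
    x$n_cycles, x$n_failed))
  invisible(x)
}

#' Coverage as a scalar volume
#'
#' Per-voxel count of distinct trajectories passing through each eligible
#' voxel; NaN elsewhere.
#'
#' @param ts a `trajectory_set`.
#' @return A [scalar_map()] named `"coverage"`.
#' @export
coverage_as_map <- function(ts) {
  vals <- array(NaN, dim = ts$grid$shape)
  vals[ts$vox] <- as.numeric(ts$coverage)
  scalar_map(vals, ts$grid, name = "coverage")
}
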