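#' Profile smoothing and significance settings
#'
#' @param filter_order sliding median window length in samples (default 6,
#'   the shipped operating value; the median of an even-length window is
#'   the mean of its two central order statistics).
#' @param significance_k multiplier on the robust per-profile noise scale
#'   used to flag a gradient segment as significant (default 3).
#' @param absolute_threshold optional amplitude threshold in map units that
#'   overrides the scale-free rule, for calibrated maps.
#' @return A list of class `smoothing_config`.
#' @export
smoothing_config <- function(filter_order = 6L, significance_k = 3.0,
                             absolute_threshold = NULL) {
  stopifnot(filter_order >= 1L, significance_k > 0)
  structure(list(filter_order = as.integer(filter_order),
                 significance_k = significance_k,
                 absolute_threshold = absolute_threshold),
            class = "smoothing_config")
}

#' Extract a parametric profile along a trajectory
#'
#' Samples the parametric map at every voxel of an oriented trajectory
#' (tumor margin first), yielding the map value as a function of the step
#' distance to the tumor border. Samples at equal distance (wandering
#' within a stratum) are retained so every visited voxel carries a sample.
#'
#' @param traj one trajectory from [generate_trajectory_set()] (oriented
#'   tumor-first, with `voxels` and `d`).
#' @param pmap a [scalar_map()] on the trajectory's grid.
#' @param dm the matching `distance_map` (grid consistency check).
#' @param id trajectory identifier stored in the profile.
#' @return An object of class `trajectory_profile`: list with `x` (steps to
#'   the tumor border, non-decreasing), `raw`, `smoothed` (NULL until
#'   [smooth_profile()]), `voxel` (linear index per sample),
#'   `trajectory_id`.
#' @export
extract_profile <- function(traj, pmap, dm, id = NA_integer_) {
  validate_grids(list(pmap, dm$grid))
  raw <- pmap$values[traj$voxels]
  if (any(!is.finite(raw)))
    stop("non-finite parametric value on the trajectory path")
  structure(list(x = as.numeric(traj$d), raw = as.numeric(raw),
                 smoothed = NULL, voxel = traj$voxels,
                 trajectory_id = as.integer(id)),
            class = "trajectory_profile")
}

#' Median-smooth a profile
#'
#' Applies a sliding median of window `filter_order` over the sample
#' sequence, suppressing isolated noise spikes while preserving monotone
#' trends. Windows truncate at the profile ends; a profile shorter than the
#' window is smoothed with the largest window that fits.
#'
#' @param p a [extract_profile()] result.
#' @param cfg a [smoothing_config()].
#' @return The profile with `smoothed` filled in.
#' @export
smooth_profile <- function(p, cfg = smoothing_config()) {
  stopifnot(inherits(p, "trajectory_profile"))
  p$smoothed <- sliding_median_cpp(p$raw, cfg$filter_order)
  p$filter_order <- cfg$filter_order
  p
}

# Local extrema of a sequence, plateaus collapsed to their midpoint.
# Returns sample indices including both endpoints; NULL for flat sequences.
profile_extrema <- function(y) {
  n <- length(y)
  if (n < 2L) return(NULL)
  r <- rle(y)
  m <- length(r$values)
  if (m < 2L) return(NULL)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  mids <- (starts + ends) %/% 2L
  v <- r$values
  idx <- 1L  # first sample is always a boundary extremum
  if (m > 2L) {
    s <- sign(diff(v))
    turns <- which(s[-1L] != s[-(m - 1L)]) + 1L  # runs where slope flips
    idx <- c(idx, mids[turns])
  }
  c(idx, n)
}

#' Detect monotone gradient segments on a smoothed profile
#'
#' Labels the local minima and maxima of the smoothed profile (plateaus
#' collapse to their midpoint; the profile endpoints count as extrema) and
#' forms the alternating rising/falling monotone segments between
#' consecutive extrema. Direction is reported relative to the tumor: a
#' `"rising"` segment is one where the parameter increases as the tumor
#' border is approached (the profile is oriented tumor-first, so rising
#' means the smoothed value falls with increasing distance), which is the
#' sign an invasion map highlights — the parameter elevated toward the
#' infiltrated border. A segment is significant when its amplitude
#' exceeds the threshold: `absolute_threshold` when given, otherwise
#' `significance_k * 1.4826 * median(|raw - smoothed|)` computed over this
#' profile — a robust estimate of the profile's own noise scale, which
#' makes the rule scale-free across parametric maps with different units.
#'
#' @param p a smoothed profile.
#' @param cfg a [smoothing_config()].
#' @return A `data.frame` with one row per segment: `start`, `end` (sample
#'   indices), `direction` (`"rising"`/`"falling"`, with respect to
#'   increasing distance from the tumor), `amplitude`, `significant`; plus
#'   attribute `"threshold"`.
#' @export
detect_gradient_segments <- function(p, cfg = smoothing_config()) {
  stopifnot(inherits(p, "trajectory_profile"))
  if (is.null(p$smoothed)) stop("profile must be smoothed first")
  y <- p$smoothed
  ex <- profile_extrema(y)
  thr <- if (!is.null(cfg$absolute_threshold)) cfg$absolute_threshold
         else cfg$significance_k * 1.4826 * stats::median(abs(p$raw - y))
  if (is.null(ex) || length(ex) < 2L) {
    out <- data.frame(start = integer(0), end = integer(0),
                      direction = character(0), amplitude = numeric(0),
                      significant = logical(0))
    attr(out, "threshold") <- thr
    return(out)
  }
  k <- length(ex) - 1L
  start <- ex[-length(ex)]
  end <- ex[-1L]
  dy <- y[end] - y[start]
  # dy < 0 in tumor-first orientation = value grows toward the tumor
  out <- data.frame(start = start, end = end,
                    direction = ifelse(dy < 0, "rising", "falling"),
                    amplitude = abs(dy),
                    significant = abs(dy) > thr)
  attr(out, "threshold") <- thr
  out
}

#' Plot a profile in the raw + smoothed style
#'
#' Raw samples against distance to the tumor border, the median-smoothed
#' profile on top, local extrema of the smoothed curve marked.
#'
#' @param x a smoothed `trajectory_profile`.
#' @param cfg a [smoothing_config()] used for extremum marking.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.trajectory_profile <- function(x, cfg = smoothing_config(), ...) {
  graphics::plot(x$x, x$raw, type = "l", col = "red",
                 xlab = "distance to tumor border (steps)",
                 ylab = "parametric value", ...)
  if (!is.null(x$smoothed)) {
    graphics::lines(x$x, x$smoothed, col = "blue", lwd = 2)
    ex <- profile_extrema(x$smoothed)
    if (!is.null(ex))
      graphics::points(x$x[ex], x$smoothed[ex], pch = 17, col = "black")
  }
  invisible(x)
}
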