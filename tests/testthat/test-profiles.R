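test_that("profiles sample the map along the oriented trajectory", {
  cm <- corridor_masks(len = 6L)
  tens <- uniform_tensors(cm$grid, 1e-3)
  dm <- compute_distance_map(cm$wm, cm$tumor)
  tw_t <- build_transition_matrix(tens, dm, "toward_tumor")
  tw_a <- build_transition_matrix(tens, dm, "away_from_tumor")
  ts <- generate_trajectory_set(tw_t, tw_a, dm,
                                walk_config(min_coverage = 3L, seed = 1L))

  const <- scalar_map(array(2.5, cm$grid$shape), cm$grid)
  ramp <- scalar_map(array(NaN, cm$grid$shape), cm$grid)
  ramp$values[!is.na(dm$d)] <- dm$d[!is.na(dm$d)]

  for (tr in ts$trajectories) {
    pc <- extract_profile(tr, const, dm)
    expect_true(all(pc$raw == 2.5))
    pr <- extract_profile(tr, ramp, dm)
    expect_identical(pr$raw, pr$x)        # identity ramp: value equals x
    expect_identical(pr$x[1], 1)          # oriented: tumor margin first
    expect_true(all(diff(pr$x) >= 0))
  }

  bad <- scalar_map(array(NaN, cm$grid$shape), cm$grid)
  expect_error(extract_profile(ts$trajectories[[1]], bad, dm), "non-finite")
})

test_that("sliding median matches the direct order-statistics oracle", {
  set.seed(8)
  for (n in c(3L, 7L, 30L)) {
    v <- rnorm(n)
    p <- smooth_profile(raw_profile(v), smoothing_config(filter_order = 6L))
    # oracle: explicit window [i-2, i+3] truncated, stats::median
    oracle <- vapply(seq_len(n), function(i)
      stats::median(v[max(1, i - 2):min(n, i + 3)]), numeric(1))
    expect_equal(p$smoothed, oracle)
  }
  # constant profiles are unchanged
  pc <- smooth_profile(raw_profile(rep(3, 10)), smoothing_config())
  expect_identical(pc$smoothed, rep(3, 10))
})

test_that("an isolated impulse on a ramp is rejected by the median filter", {
  v <- as.numeric(0:20)
  v[11] <- v[11] + 10
  p <- smooth_profile(raw_profile(v), smoothing_config(filter_order = 6L))
  # smoothed value at the impulse stays within the local ramp values
  window <- (0:20)[8:14]
  expect_true(p$smoothed[11] >= min(window) && p$smoothed[11] <= max(window))
  expect_lt(abs(p$smoothed[11] - 10), 2)
})

test_that("extrema partition the profile into alternating monotone segments", {
  # zigzag with plateaus: extrema at the plateau midpoints
  v <- c(0, 1, 2, 3, 3, 3, 2, 1, 0, 1, 2, 2, 1, 0)
  p <- raw_profile(v)
  p$smoothed <- v  # analyze the sequence as-is
  seg <- detect_gradient_segments(p, smoothing_config(absolute_threshold = 0.5))
  expect_identical(seg$start[1], 1L)
  expect_identical(seg$end[nrow(seg)], length(v))
  # interior extrema: plateau 3,3,3 at samples 4:6 -> midpoint 5;
  # minimum at 9; plateau 2,2 at 11:12 -> midpoint 11
  expect_identical(seg$end[-nrow(seg)], c(5L, 9L, 11L))
  # segments tile the profile and alternate direction
  expect_identical(seg$start[-1], seg$end[-nrow(seg)])
  expect_true(all(seg$direction[-1] != seg$direction[-nrow(seg)]))
  # amplitudes are the extremum-to-extremum differences
  expect_equal(seg$amplitude, c(3, 3, 2, 2))
  expect_true(all(seg$significant))
})

test_that("direction is reported relative to the tumor border", {
  # value falling with distance = rising toward the tumor
  fall <- raw_profile(seq(10, 0, length.out = 21))
  fall$smoothed <- fall$raw
  sf <- detect_gradient_segments(fall, smoothing_config(absolute_threshold = 1))
  expect_identical(nrow(sf), 1L)
  expect_identical(sf$direction, "rising")
  expect_true(sf$significant)

  rise <- raw_profile(seq(0, 10, length.out = 21))
  rise$smoothed <- rise$raw
  sr <- detect_gradient_segments(rise, smoothing_config(absolute_threshold = 1))
  expect_identical(sr$direction, "falling")
})

test_that("a noiseless monotone ramp yields one significant segment", {
  p <- smooth_profile(raw_profile(seq(5, 0, length.out = 30)),
                      smoothing_config())
  seg <- detect_gradient_segments(p, smoothing_config())
  expect_identical(nrow(seg), 1L)
  expect_true(seg$significant)
  # flat profiles produce no segments at all
  pf <- smooth_profile(raw_profile(rep(1, 20)), smoothing_config())
  expect_identical(nrow(detect_gradient_segments(pf, smoothing_config())), 0L)
})

test_that("pure-noise profiles rarely show significant segments", {
  set.seed(314)
  cfg <- smoothing_config()
  hits <- replicate(400, {
    p <- smooth_profile(raw_profile(rnorm(60)), cfg)
    any(detect_gradient_segments(p, cfg)$significant)
  })
  # Monte-Carlo false-positive rate of the k = 3 robust threshold at this
  # length is ~7-8%; assert it stays a small minority
  expect_lt(mean(hits), 0.15)
})

test_that("raising the significance multiplier never adds significant segments", {
  set.seed(21)
  v <- cumsum(rnorm(80)) + seq(0, 4, length.out = 80)
  p <- smooth_profile(raw_profile(v), smoothing_config())
  counts <- vapply(c(0.5, 1, 2, 3, 5, 8), function(k) {
    sum(detect_gradient_segments(p, smoothing_config(significance_k = k))$significant)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("short profiles are smoothed with the largest window that fits", {
  p <- smooth_profile(raw_profile(c(1, 5, 100)), smoothing_config())
  expect_identical(p$smoothed, rep(5, 3))  # median over all 3 samples
  p1 <- smooth_profile(raw_profile(7), smoothing_config())
  expect_identical(p1$smoothed, 7)
})

test_that("the absolute threshold overrides the scale-free rule", {
  p <- smooth_profile(raw_profile(seq(0, 2, length.out = 25)),
                      smoothing_config())
  hi <- detect_gradient_segments(p, smoothing_config(absolute_threshold = 5))
  lo <- detect_gradient_segments(p, smoothing_config(absolute_threshold = 0.5))
  expect_false(any(hi$significant))
  expect_true(all(lo$significant))
})
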