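setup_corridor <- function(len = 5L) {
  cm <- corridor_masks(len = len)
  tens <- uniform_tensors(cm$grid, 1e-3)
  dm <- compute_distance_map(cm$wm, cm$tumor)
  list(cm = cm, dm = dm,
       toward = build_transition_matrix(tens, dm, "toward_tumor"),
       away = build_transition_matrix(tens, dm, "away_from_tumor"))
}

test_that("forced moves walk a 1-wide corridor straight to the margin", {
  s <- setup_corridor(5L)
  start <- which(s$dm$d == 5L)
  seg <- walk_toward_tumor(start, s$toward, s$dm)
  expect_identical(seg$d, 5:1)
  expect_true(seg$reached_margin)
  expect_false(seg$failed)

  # start already at the margin: single-voxel segment
  seg1 <- walk_toward_tumor(which(s$dm$d == 1L), s$toward, s$dm)
  expect_identical(seg1$d, 1L)
  expect_true(seg1$reached_margin)
})

test_that("away segments climb to the corridor end and stop", {
  s <- setup_corridor(6L)
  seg <- walk_away_from_tumor(which(s$dm$d == 3L), s$away)
  expect_identical(seg$d, 3:6)  # forced moves up to the local maximum

  # a start whose away row is all-zero stays a single voxel
  seg2 <- walk_away_from_tumor(which(s$dm$d == 6L), s$away)
  expect_identical(seg2$d, 6L)
})

test_that("ineligible starts are rejected", {
  s <- setup_corridor(4L)
  expect_error(walk_toward_tumor(1L, s$toward, s$dm), "eligible")
})

test_that("the scheduler reaches the coverage target on a small corridor", {
  s <- setup_corridor(7L)
  cfg <- walk_config(min_coverage = 5L, seed = 11L)
  ts <- generate_trajectory_set(s$toward, s$away, s$dm, cfg)
  expect_true(all(ts$coverage >= 5L))
  expect_identical(ts$n_failed, 0L)
  # every trajectory stays inside the eligible set
  el <- eligible_voxels(s$dm)
  for (tr in ts$trajectories) expect_true(all(tr$voxels %in% el))
})

test_that("trajectory generation is deterministic in the seed", {
  ph <- make_phantom(phantom_spec(grid_shape = c(14, 14, 14),
                                  tumor_radius = 3, seed = 4))
  dm <- ph$distance
  tw_t <- build_transition_matrix(ph$tensors, dm, "toward_tumor")
  tw_a <- build_transition_matrix(ph$tensors, dm, "away_from_tumor")
  cfg <- walk_config(min_coverage = 10L, seed = 99L)
  ts1 <- generate_trajectory_set(tw_t, tw_a, dm, cfg)
  ts2 <- generate_trajectory_set(tw_t, tw_a, dm, cfg)
  expect_identical(ts1$trajectories, ts2$trajectories)
  expect_identical(ts1$coverage, ts2$coverage)
  ts3 <- generate_trajectory_set(tw_t, tw_a, dm,
                                 walk_config(min_coverage = 10L, seed = 100L))
  expect_false(identical(ts1$trajectories, ts3$trajectories))
})

test_that("stitched trajectories are unimodal with the minimum at the tumor end", {
  ph <- make_phantom(phantom_spec(grid_shape = c(14, 14, 14),
                                  tumor_radius = 3, seed = 4))
  dm <- ph$distance
  tw_t <- build_transition_matrix(ph$tensors, dm, "toward_tumor")
  tw_a <- build_transition_matrix(ph$tensors, dm, "away_from_tumor")
  ts <- generate_trajectory_set(tw_t, tw_a, dm,
                                walk_config(min_coverage = 10L, seed = 5L))
  any_stitched <- FALSE
  for (tr in ts$trajectories) {
    # oriented tumor-first: the toward part (reversed) never decreases,
    # and the appended away part never decreases either
    expect_true(all(diff(tr$d) >= 0))
    if (tr$reached_margin) expect_identical(tr$d[1], 1L)
    nt <- tr$n_toward
    expect_true(all(diff(tr$d[seq_len(nt)]) >= 0))
    if (length(tr$d) > nt) {
      expect_true(all(diff(tr$d[nt:length(tr$d)]) >= 0))
      any_stitched <- any_stitched || tr$stitched
    }
    # consecutive voxels are 26-neighbors
    ijk <- arrayInd(tr$voxels, dm$grid$shape)
    steps <- abs(diff(ijk))
    expect_true(all(steps <= 1L) && all(rowSums(steps) > 0L))
  }
  expect_true(any_stitched)
  # coverage counts each trajectory once per distinct voxel
  recount <- integer(length(ts$vox))
  rk <- integer(prod(dm$grid$shape)); rk[ts$vox] <- seq_along(ts$vox)
  for (tr in ts$trajectories) {
    u <- rk[unique(tr$voxels)]
    recount[u] <- recount[u] + 1L
  }
  expect_identical(recount, ts$coverage)
})

test_that("single-step frequencies follow the transition row", {
  wc <- wide_corridor_bundle(len = 8L)
  dm <- compute_distance_map(wc$wm, wc$tumor)
  tw_t <- build_transition_matrix(wc$tensors, dm, "toward_tumor")
  start <- which(dm$d == 4L)[1]
  i <- match(start, tw_t$vox)
  p <- tw_t$W[i, ]
  set.seed(42)
  n <- 2000L
  counts <- numeric(length(p))
  for (k in seq_len(n)) {
    seg <- walk_toward_tumor(start, tw_t, dm)
    step <- arrayInd(seg$voxels[2], dm$grid$shape) -
            arrayInd(seg$voxels[1], dm$grid$shape)
    j <- which(tw_t$nbhd$offsets[, 1] == step[1] &
               tw_t$nbhd$offsets[, 2] == step[2] &
               tw_t$nbhd$offsets[, 3] == step[3])
    counts[j] <- counts[j] + 1
  }
  phat <- counts / n
  se <- sqrt(p * (1 - p) / n)
  expect_true(all(abs(phat - p) <= 3 * se + 1e-12))
  expect_true(all(phat[p == 0] == 0))
})
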