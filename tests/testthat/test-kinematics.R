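cfg <- run_config()

test_that("leg_speed converts displacement to mm/s and clips at zero", {
  ## uniform 1 px/frame at 60 fps, 0.01 mm/px -> 0.6 mm/s
  legs <- lapply(stats::setNames(seq_along(leg_ids), leg_ids), function(i) {
    cbind(x = as.numeric(1:30), y = rep(i, 30))
  })
  tr <- leg_track_table(legs, fps = 60, mm_per_px = 0.01)
  vel <- leg_speed(tr, cfg)
  for (l in leg_ids) {
    expect_equal(vel$speed[[l]], rep(0.6, 29), tolerance = 1e-9)
  }
  ## stationary leg -> all zero
  legs$T1L[, "x"] <- 5
  legs$T1L[, "y"] <- 5
  tr2 <- leg_track_table(legs, fps = 60, mm_per_px = 0.01)
  expect_equal(leg_speed(tr2, cfg)$speed$T1L, rep(0, 29))
  ## too-short track errors with guidance
  short <- lapply(legs, function(m) m[1:4, ])
  expect_error(leg_speed(leg_track_table(short, 60, 0.01), cfg), "window")
})

test_that("speed peaks fall inside true swing intervals", {
  g <- simulate_gait(gait_params(seed = 7, noise_sd = 0.2))
  vel <- leg_speed(g$track, cfg)
  hits <- misses <- 0
  for (l in leg_ids) {
    v <- vel$speed[[l]]
    tr <- g$truth$swings[[l]]
    ## each local peak above half max should lie in a true swing
    th <- 0.5 * max(v)
    peaks <- which(diff(sign(diff(v))) == -2) + 1L
    peaks <- peaks[v[peaks] >= th]
    inside <- logical(length(peaks))
    for (i in seq_along(peaks)) {
      inside[i] <- any(tr$start < peaks[i] & peaks[i] <= tr$end)
    }
    hits <- hits + sum(inside); misses <- misses + sum(!inside)
  }
  expect_gte(hits / (hits + misses), 0.99)
})

test_that("segmentation matches the brute-force threshold oracle on clean pulses", {
  ## square pulses 0.07 s every 0.2 s at 100 fps
  onsets <- seq(0.1, 1.9, by = 0.2)
  v <- pulse_train(onsets, 0.07, fps = 100, total_s = 2.2)
  speed <- stats::setNames(rep(list(v), 6), leg_ids)
  vel <- make_velocity_series(speed, fps = 100)
  s <- segment_swings(vel, cfg)
  th_hi <- cfg$swing_threshold_frac * quantile(v, 0.95, names = FALSE)
  oracle <- oracle_threshold_runs(v, th_hi)
  d <- s$swings$T1L
  expect_equal(nrow(d), nrow(oracle))
  expect_equal(d$start, unname(oracle[, "start"]))
  expect_equal(d$end, unname(oracle[, "end"]))
  ## onsets within one frame of the true pulse times
  expect_true(all(abs(d$onset_s - onsets) <= 1 / 100))
  expect_true(all(abs(d$offset_s - (onsets + 0.07)) <= 1 / 100))
  ## all-zero trace: no swings, not an error
  z <- make_velocity_series(stats::setNames(rep(list(rep(0, 100)), 6),
                                            leg_ids), 100)
  expect_equal(nrow(segment_swings(z, cfg)$swings$T1L), 0L)
})

test_that("swing/stance durations and duty cycles follow their definitions", {
  on <- list()
  for (l in leg_ids) on[[l]] <- c(0.03, 0.25)
  s <- make_swing_series(on, dur_s = 0.07, fps = 100, n_samples = 40)
  ## stance = next start - previous end = 0.25 - 0.10
  expect_equal(stance_durations(s)$T1L, 0.15, tolerance = 1e-12)
  expect_equal(swing_durations(s)$T2R, c(0.07, 0.07), tolerance = 1e-12)
  ## single swing -> no stances
  on1 <- on; on1$T3L <- 0.1
  s1 <- make_swing_series(on1, 0.07, 100, 40)
  expect_length(stance_durations(s1)$T3L, 0)
  ## duty: swing 0.05 s, period 0.2 -> 0.25/0.75; duties always sum to 1
  on2 <- lapply(on, function(x) seq(0, 0.8, by = 0.2))
  s2 <- make_swing_series(on2, 0.05, 100, 100)
  d <- duty_cycles(s2, period = 0.2)
  expect_equal(d$swing_duty, rep(0.25, 3), tolerance = 1e-9)
  expect_equal(d$stance_duty, rep(0.75, 3), tolerance = 1e-9)
  expect_equal(d$swing_duty + d$stance_duty, rep(1, 3))
})

test_that("cycle period is the reciprocal mean swing-onset rate", {
  on <- lapply(stats::setNames(leg_ids, leg_ids),
               function(l) seq(0, 1.8, by = 0.2))
  s <- make_swing_series(on, 0.07, 100, 200)
  expect_equal(cycle_period(s), 0.2, tolerance = 1e-12)
  on7 <- lapply(on, function(x) seq(0, 6.3, by = 0.7))
  s7 <- make_swing_series(on7, 0.07, 100, 700)
  expect_equal(cycle_period(s7), 0.7, tolerance = 1e-12)
})

test_that("slow-mode stance stretches while swing stays constant", {
  g <- simulate_gait(gait_params(period = 0.7, n_cycles = 8, seed = 4))
  s <- segment_swings(leg_speed(g$track, cfg), cfg)
  st <- unlist(stance_durations(s))
  sw <- unlist(swing_durations(s))
  expect_lt(abs(mean(st) - 0.63), 0.015)   # 1 frame + estimator slack
  expect_lt(abs(mean(sw) - 0.07), 0.01)
})

test_that("stride length is the net tip displacement over each swing", {
  legs <- lapply(stats::setNames(seq_along(leg_ids), leg_ids), function(i) {
    x <- c(rep(0, 10), seq(0, 120, length.out = 8), rep(120, 12))
    cbind(x = x, y = rep(i, 30))
  })
  tr <- leg_track_table(legs, fps = 100, mm_per_px = 0.01)
  on <- lapply(stats::setNames(leg_ids, leg_ids), function(l) 0.10)
  s <- make_swing_series(on, 0.07, 100, 29)
  sl <- stride_length(tr, s)
  expect_equal(sl$T1L, 1.2, tolerance = 0.01)   # 120 px * 0.01 mm/px
  ## zero-length interval -> 0 mm
  s0 <- s
  s0$swings$T1L$end <- s0$swings$T1L$start + 1L
  s0$swings$T1L$start <- s0$swings$T1L$start
  sl0 <- stride_length(tr, s0)
  expect_lt(sl0$T1L, 0.2)
})

test_that("stride length grows linearly with speed in the generator", {
  speeds <- seq(1, 4, length.out = 8)
  stride <- vapply(speeds, function(v) {
    g <- simulate_gait(gait_params(speed = v, seed = 21, n_cycles = 8))
    s <- segment_swings(leg_speed(g$track, cfg), cfg)
    mean(unlist(stride_length(g$track, s)))
  }, numeric(1))
  expect_gt(stats::cor(speeds, stride)^2, 0.9)
})

test_that("intra- and intersegmental phases recover constructed offsets", {
  base <- seq(0, 1.8, by = 0.2)
  on <- list(T3L = base, T3R = base,
             T2L = base + 0.2 / 3, T2R = base + 0.2 / 3,
             T1L = base + 0.4 / 3, T1R = base + 0.4 / 3)
  s <- make_swing_series(on, 0.07, 100, 220)
  intra <- intrasegmental_phase(s, 0.2)
  expect_equal(unname(intra), c(0, 0, 0), tolerance = 1e-9)
  inter <- intersegmental_phase(s, 0.2)
  expect_equal(inter[["T2L"]], 120, tolerance = 1e-6)
  expect_equal(inter[["T1L"]], 240, tolerance = 1e-6)
  ## anchor onto itself -> 0
  self <- intersegmental_phase(s, 0.2, anchor = "T3L", targets = "T3L")
  expect_equal(self[["T3L"]], 0, tolerance = 1e-9)
  ## right shifted by half a period -> 180 deg intrasegmental
  on2 <- on
  on2$T3R <- base + 0.1
  s2 <- make_swing_series(on2, 0.07, 100, 220)
  expect_equal(abs(intrasegmental_phase(s2, 0.2)[["T3"]]), 180,
               tolerance = 1e-6)
  ## a leg with no swings flags the segment as undefined
  on3 <- on
  on3$T1R <- numeric()
  s3 <- make_swing_series(on3, 0.07, 100, 220)
  expect_true(is.na(intrasegmental_phase(s3, 0.2)[["T1"]]))
})

test_that("phase estimates are invariant to global time shift and spatial scale", {
  g <- simulate_gait(gait_params(seed = 9, intraseg_jitter_sd = 5))
  s <- segment_swings(leg_speed(g$track, cfg), cfg)
  per <- cycle_period(s)
  inter <- intersegmental_phase(s, per)
  intra <- intrasegmental_phase(s, per)

  ## global time shift of all onsets
  sh <- s
  sh$swings <- lapply(s$swings, function(d) {
    d$onset_s <- d$onset_s + 1.23; d$offset_s <- d$offset_s + 1.23; d
  })
  expect_equal(intersegmental_phase(sh, per), inter, tolerance = 1e-9)
  expect_equal(intrasegmental_phase(sh, per), intra, tolerance = 1e-9)

  ## doubling the spatial scale (same pixel data, double mm/px) leaves
  ## period, duties and phases unchanged
  tr2 <- leg_track_table(g$track$legs, fps = g$track$fps,
                         mm_per_px = 2 * g$track$mm_per_px)
  s2 <- segment_swings(leg_speed(tr2, cfg), cfg)
  expect_equal(cycle_period(s2), per, tolerance = 1e-9)
  expect_equal(intersegmental_phase(s2, per), inter, tolerance = 1e-9)
  expect_equal(duty_cycles(s2, per), duty_cycles(s, per), tolerance = 1e-9)
})

test_that("parameter recovery holds across seeded simulations at defaults", {
  per_err <- sw_err <- it2 <- it1 <- intra <- numeric(0)
  for (seed in 1:8) {
    g <- simulate_gait(gait_params(seed = seed))
    s <- segment_swings(leg_speed(g$track, cfg), cfg)
    per <- cycle_period(s)
    per_err <- c(per_err, abs(per - 0.2) / 0.2)
    sw_err <- c(sw_err, abs(mean(unlist(swing_durations(s))) - 0.07))
    ip <- intersegmental_phase(s, per)
    it2 <- c(it2, abs(ip[["T2L"]] - 120))
    it1 <- c(it1, abs(ip[["T1L"]] - 240))
    intra <- c(intra, abs(intrasegmental_phase(s, per)))
  }
  expect_lte(median(per_err), 0.02)
  expect_lte(median(sw_err), 1 / 100)      # one frame at 100 fps
  expect_lte(median(it2), 5)
  expect_lte(median(it1), 5)
  expect_lte(median(intra), 5)
})
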