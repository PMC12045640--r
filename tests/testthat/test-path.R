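straight_track <- function(n = 100, step = 2, fps = 30, scale = 0.05,
                           angle = 180) {
  centroid_track(x = step * (0:(n - 1)), y = rep(0, n),
                 angle_deg = rep(angle, n), fps = fps, mm_per_px = scale)
}

test_that("instantaneous velocity converts steps to mm/s", {
  ## 0.1 mm/frame at 30 fps -> 3 mm/s
  ct <- straight_track(n = 50, step = 2, fps = 30, scale = 0.05)
  expect_equal(instantaneous_velocity(ct), rep(3, 49), tolerance = 1e-12)
  still <- centroid_track(rep(1, 20), rep(1, 20), rep(180, 20), 30, 0.05)
  expect_equal(instantaneous_velocity(still), rep(0, 19))
})

test_that("state classification partitions frames and flags headsweeps", {
  ang <- c(180, 215, 150, 145, 212, 175)
  ct <- centroid_track(x = cumsum(rep(1, 6)), y = rep(0, 6), angle_deg = ang,
                       fps = 30, mm_per_px = 0.05)
  st <- classify_states(ct)
  expect_equal(st$state, c("straight", "bent", "straight", "bent", "bent",
                           "straight"))
  expect_equal(st$headsweep, c("none", "L", "R", "R", "L", "none"))
  ## still overrides angle
  ct2 <- centroid_track(rep(0, 5), rep(0, 5), c(180, 215, 90, 300, 150),
                        30, 0.05)
  expect_true(all(classify_states(ct2)$state == "still"))
  ## exactly one state per frame always
  set.seed(2)
  ct3 <- centroid_track(cumsum(stats::rnorm(200)), cumsum(stats::rnorm(200)),
                        stats::runif(200, 0, 360), 30, 0.05)
  st3 <- classify_states(ct3)
  expect_true(all(st3$state %in% c("straight", "bent", "still")))
  expect_equal(nrow(st3), 200L)
})

test_that("generator state labels agree with the classifier definitions", {
  sim <- simulate_path(path_params(seed = 5, headsweep_rate = 0.2,
                                   backtrack_rate = 0.02, pause_prob = 0.01))
  st <- classify_states(sim$track)
  ## identical definitional rules; boundary frames may differ by the
  ## one-frame velocity convention
  expect_gt(mean(st$state == sim$truth$labels$state), 0.98)
})

test_that("headsweep bias testing is exact and calibrated", {
  b <- headsweep_bias(10, 10)
  expect_equal(b$estimate, 0.5)
  expect_gt(b$p, 0.99)
  expect_lt(headsweep_bias(20, 0)$p, 0.001)
  expect_error(headsweep_bias(0, 0), "no headsweep")
  set.seed(12)
  rej <- mean(replicate(500, {
    l <- stats::rbinom(1, 60, 0.5)
    headsweep_bias(l, 60 - l)$p < 0.05
  }))
  expect_lt(abs(rej - 0.05), 0.035)        # exact test is mildly conservative
})

test_that("curviness is 1 for lines, pi/2 for semicircles, and invariant", {
  expect_equal(curviness(straight_track()), 1, tolerance = 1e-9)
  th <- seq(0, pi, length.out = 1001)
  semi <- cbind(cos(th), sin(th))
  expect_equal(curviness(semi), pi / 2, tolerance = 1e-3)
  ## rotation / translation / scaling invariance
  rot <- function(m, a) m %*% matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2)
  expect_equal(curviness(7 * rot(semi, 1.1) + 3), curviness(semi),
               tolerance = 1e-9)
  set.seed(3)
  rw <- cbind(cumsum(stats::rnorm(500)), cumsum(stats::rnorm(500)))
  expect_gte(curviness(rw), 1)
  ## brute-force polyline check
  expect_equal(curviness(rw),
               sum(sqrt(rowSums(diff(rw)^2))) /
                 sqrt(sum((rw[500, ] - rw[1, ])^2)),
               tolerance = 1e-12)
  loop <- centroid_track(c(0, 1, 1, 0, 0), c(0, 0, 1, 1, 0), rep(180, 5),
                         30, 1)
  expect_error(curviness(loop), "zero net displacement")
})

test_that("angle histograms bin every 10 degrees and conserve counts", {
  ct <- straight_track(n = 64)
  h <- angle_histogram(ct)
  expect_equal(nrow(h), 36L)
  expect_equal(sum(h$count), 64L)
  expect_equal(h$count[h$bin_start == 180], 64L)
  ## uniform angles are flat (chi-square not rejected at alpha = 0.01)
  set.seed(6)
  hu <- angle_histogram(stats::runif(1e4, 0, 360))
  expect_equal(sum(hu$count), 1e4)
  expect_gt(stats::chisq.test(hu$count)$p.value, 0.01)
})

test_that("total distance sums steps and scales with the spatial calibration", {
  ct <- straight_track(n = 11, step = 2, scale = 0.05)
  expect_equal(total_distance(ct), 10 * 2 * 0.05, tolerance = 1e-12)
  ct2 <- straight_track(n = 11, step = 2, scale = 0.1)
  expect_equal(total_distance(ct2), 2 * total_distance(ct), tolerance = 1e-12)
})

test_that("a constructed turn-reverse-turn sequence yields one episode", {
  fps <- 30
  seg <- function(n, vx, ang) list(n = n, vx = vx, ang = ang)
  parts <- list(seg(60, 2, 180), seg(15, 0.5, 215), seg(30, -1.2, 180),
                seg(15, 0.5, 145), seg(60, 2, 180))
  x <- cumsum(unlist(lapply(parts, function(p) rep(p$vx / fps, p$n))))
  ang <- unlist(lapply(parts, function(p) rep(p$ang, p$n)))
  ct <- centroid_track(x, rep(0, length(x)), ang, fps = fps, mm_per_px = 1)
  ep <- detect_backtrack_redirect(ct)
  expect_equal(nrow(ep), 1L)
  expect_equal(ep$first_side, "L")
  expect_equal(ep$back_disp_mm, 30 * 1.2 / fps, tolerance = 0.1)
  ## straight constant-velocity paths yield no episodes
  expect_equal(nrow(detect_backtrack_redirect(straight_track(300))), 0L)
  ## mirror reflection flips the direction label
  ct_m <- centroid_track(x, rep(0, length(x)), 360 - ang, fps = fps,
                         mm_per_px = 1)
  ep_m <- detect_backtrack_redirect(ct_m)
  expect_equal(ep_m$first_side, "R")
})

test_that("episode detection is sensitive and specific on labelled paths", {
  tp <- fp <- n_true <- 0
  for (seed in 1:8) {
    sim <- simulate_path(path_params(seed = seed, backtrack_rate = 0.025,
                                     headsweep_rate = 0.05, duration = 120))
    det <- detect_backtrack_redirect(sim$track)
    tru <- sim$truth$episodes
    n_true <- n_true + nrow(tru)
    if (nrow(det) == 0) next
    matched_det <- logical(nrow(det))
    for (k in seq_len(nrow(tru))) {
      ov <- det$start < tru$end[k] & det$end > tru$start[k]
      if (any(ov)) {
        tp <- tp + 1
        matched_det[ov] <- TRUE
      }
    }
    fp <- fp + sum(!matched_det)
  }
  expect_gt(n_true, 10)
  expect_gte(tp / n_true, 0.9)
  expect_lte(fp / max(tp + fp, 1), 0.1)
})

test_that("path summaries assemble per-animal metrics", {
  sim <- simulate_path(path_params(seed = 9, headsweep_rate = 0.15))
  ps <- path_summary(sim$track)
  expect_equal(nrow(ps), 1L)
  expect_equal(ps$pct_straight + ps$pct_bent + ps$pct_still, 100,
               tolerance = 1e-9)
  expect_gt(ps$mean_velocity_mm_s, 1)
  expect_gte(ps$curviness, 1)
})
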