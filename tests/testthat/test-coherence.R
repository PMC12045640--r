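test_that("plateau rules match a brute-force enumeration oracle", {
  freq <- seq(0.2, 10, by = 0.2)
  ## single peak
  p1 <- exp(-(freq - 5)^2)
  expect_equal(fundamental_from_spectrum(freq, p1, 0.05),
               oracle_plateau(freq, p1, 0.05))
  ## equal-power plateau 4.6-5.4 -> middle bin 5.0
  p2 <- rep(0.1, length(freq))
  p2[freq >= 4.59 & freq <= 5.41] <- 1
  expect_equal(fundamental_from_spectrum(freq, p2, 0.05), 5.0)
  expect_equal(oracle_plateau(freq, p2, 0.05), 5.0)
  ## two adjacent equal plateaus (3-4 and 5-6) -> middle of the higher block
  p3 <- rep(0.1, length(freq))
  p3[freq >= 2.99 & freq <= 4.01] <- 1
  p3[freq >= 4.99 & freq <= 6.01] <- 1
  expect_equal(fundamental_from_spectrum(freq, p3, 0.05), 5.6)
  expect_equal(oracle_plateau(freq, p3, 0.05), 5.6)
  ## randomised spectra agree with the oracle
  set.seed(31)
  for (i in 1:25) {
    p <- stats::runif(length(freq))
    expect_equal(fundamental_from_spectrum(freq, p, 0.1),
                 oracle_plateau(freq, p, 0.1))
  }
  ## flat zero spectrum -> undefined
  expect_true(is.na(fundamental_from_spectrum(freq, rep(0, length(freq)))))
})

test_that("a pure tone lands on its own frequency bin", {
  fs <- 60
  x <- sin(2 * pi * 5 * (0:599) / fs)
  expect_equal(fundamental_frequency(x, fs = fs), 5, tolerance = fs / 600)
})

test_that("coherence identities: self, delay, amplitude scaling, antisymmetry", {
  fs <- 100
  t <- (0:799) / fs
  cfg <- run_config(n_obs = 4)
  x <- sin(2 * pi * 5 * t) + 0.05 * sin(2 * pi * 11 * t)
  mt <- multitaper_coherence(x, x, fs, cfg, f0 = 5)
  expect_equal(mt$magnitude, 1, tolerance = 1e-9)
  expect_equal(mt$phase_at_f0, 0, tolerance = 1e-9)
  expect_true(all(mt$coherence >= 0 & mt$coherence <= 1 + 1e-12))

  ## quarter-period delay of the second signal -> -90 deg at f0
  xs <- sin(2 * pi * 5 * t)
  y <- sin(2 * pi * 5 * (t - 0.05))
  mtd <- multitaper_coherence(xs, y, fs, cfg, f0 = 5)
  expect_equal(mtd$phase_at_f0, -90, tolerance = 2)

  ## amplitude scaling leaves magnitude untouched
  mts <- multitaper_coherence(3.7 * xs, 0.2 * y, fs, cfg, f0 = 5)
  expect_equal(mts$magnitude, mtd$magnitude, tolerance = 1e-9)

  ## phase antisymmetry
  mtr <- multitaper_coherence(y, xs, fs, cfg, f0 = 5)
  expect_equal(mtr$phase_at_f0, -mtd$phase_at_f0, tolerance = 1e-6)

  ## segment-length guard
  expect_error(multitaper_coherence(x[1:20], x[1:20], fs,
                                    run_config(n_obs = 10)),
               "fewer")
})

test_that("boxcar multitaper equals the averaged-periodogram oracle", {
  set.seed(5)
  fs <- 50
  x <- stats::rnorm(400)
  y <- stats::rnorm(400)
  R <- 4
  L <- 100
  cfg <- run_config(n_obs = R, n_tapers = 1, time_bandwidth = 1)
  box <- matrix(1 / sqrt(L), nrow = L, ncol = 1)
  mt <- multitaper_coherence(x, y, fs, cfg, tapers = box)
  or <- oracle_boxcar_coherence(x, y, R)
  ## the DC bin is degenerate after per-segment demeaning; compare the rest
  expect_equal(mt$coherence[-1], or$coherence[-1], tolerance = 1e-6)
  expect_equal(mt$phase_deg[-1], or$phase_deg[-1], tolerance = 1e-6)
})

test_that("the analytic threshold follows its closed form and monotonicity", {
  cfg <- run_config()
  ## R = 10, K = 5 -> dof = 100
  expect_equal(coherence_threshold(cfg, dof = 100),
               sqrt(1 - 0.05^(1 / 49)), tolerance = 1e-12)
  ## alpha -> 1 drives the threshold to 0
  expect_lt(coherence_threshold(cfg, dof = 40, alpha = 1 - 1e-12), 1e-4)
  ## strictly decreasing in dof (more tapers)
  ths <- vapply(c(8, 20, 40, 100, 400), function(d)
    coherence_threshold(cfg, dof = d), numeric(1))
  expect_true(all(diff(ths) < 0))
  expect_error(coherence_threshold(cfg, dof = 2), "dof")
})

test_that("false-positive rate on independent noise calibrates to alpha", {
  ## moderate replication here; the acceptance suite runs the full design
  set.seed(99)
  cfg <- run_config(n_obs = 5, n_tapers = 4, time_bandwidth = 2.5)
  thr <- coherence_threshold(cfg, dof = 40)
  hits <- 0
  nrep <- 300
  for (i in seq_len(nrep)) {
    mt <- multitaper_coherence(stats::rnorm(320), stats::rnorm(320), 1, cfg)
    hits <- hits + (mt$coherence[17] >= thr)
  }
  expect_equal(hits / nrep, 0.05, tolerance = 0.03)
})

test_that("all legs cohere with the anchor in clean fast gait", {
  g <- simulate_gait(gait_params(seed = 13))
  res <- leg_coherence(g$track, run_config())
  expect_equal(nrow(res), 5L)
  expect_equal(res$f0[1], 5, tolerance = 0.5)
  expect_true(all(res$significant))
  expect_equal(coherent_leg_fraction(res), 100)
  expect_true(all(res$dof == 2 * 4 * 7))   # 4 s of trace, 1 s segments, K = 7
  ## contralateral anchor pair is fully coherent at zero phase
  expect_equal(res$phase_deg[res$leg == "T1R"], 0, tolerance = 2)
  ## one intersegmental step of the wave separates T2 from the anchor
  expect_equal(abs(res$phase_deg[res$leg == "T2L"]), 120, tolerance = 15)
})

test_that("dropout and jitter erode coherence with the anchor", {
  cfgc <- run_config(n_tapers = 3, time_bandwidth = 2, n_obs = 1)
  frac <- function(skip, seeds = 1:6) {
    mean(vapply(seeds, function(sd_) {
      g <- simulate_gait(gait_params(
        seed = sd_, skip_prob = skip, intraseg_jitter_sd = 10,
        noise_sd = 0.1 * peak_swing_speed(gait_params())))
      coherent_leg_fraction(leg_coherence(g$track, cfgc))
    }, numeric(1)))
  }
  expect_gt(frac(0), frac(0.3))
})
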