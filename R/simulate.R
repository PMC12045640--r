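# Synthetic gait, pygopod-event and exploration-path generator.
#
# The gait model is the bilaterally symmetric posterior-to-anterior wave
# observed in walking larvae: metathoracic (T3) legs initiate each cycle,
# meso- (T2) and prothoracic (T1) segments follow with a fixed
# intersegmental phase lag (default 120 deg each), and left/right legs of a
# segment swing together up to Gaussian intrasegmental jitter. Swing
# duration is constant; speed is modulated through the cycle period
# (stance), mirroring the constant-swing/variable-stance phenomenology of
# real larvae.

#' Gait generator parameters
#'
#' Defaults describe fast straight walking: cycle period 0.2 s, swing
#' duration 0.07 s, 120 deg posterior-to-anterior intersegmental lag,
#' bilateral synchrony (zero jitter), no swing dropout, mean forward speed
#' 1.8 mm/s. Slow walking is emulated by a larger `period` with the same
#' `swing_duration`, plus nonzero `skip_prob` and `intraseg_jitter_sd`.
#'
#' @param period Cycle period T, s.
#' @param swing_duration Swing duration, s (< `period`).
#' @param interseg_lag Intersegmental phase lag T3->T2 and T2->T1, degrees.
#' @param intraseg_jitter_sd SD of per-onset timing jitter, degrees of cycle.
#' @param skip_prob Probability that a scheduled swing is dropped, in [0, 1).
#' @param speed Mean forward speed of the body, mm/s.
#' @param stride_gain Stride length per unit speed, s (stride =
#'   `stride_gain * speed`); `NULL` uses `period` so each leg recovers the
#'   body advance per cycle.
#' @param noise_sd SD of white velocity noise per coordinate, mm/s.
#' @param pygopod_prob Probability that a swing onset triggers a pygopod
#'   plant event.
#' @param pygopod_jitter_sd SD of plant-event timing relative to its swing
#'   onset, s.
#' @param fps Frame rate of the emitted track, frames/s (`fps * period >= 4`).
#' @param n_cycles Number of gait cycles to simulate.
#' @param mm_per_px Spatial scale of the emitted pixel coordinates.
#' @param seed Integer seed; the whole simulation uses one seeded generator.
#' @param animal_id Identifier for the emitted track.
#' @return An object of class `gait_params` (validated list).
#' @export
gait_params <- function(period = 0.2, swing_duration = 0.07,
                        interseg_lag = 120, intraseg_jitter_sd = 0,
                        skip_prob = 0, speed = 1.8, stride_gain = NULL,
                        noise_sd = 0, pygopod_prob = 0.1,
                        pygopod_jitter_sd = 0.02, fps = 100, n_cycles = 20,
                        mm_per_px = 0.01, seed = 1, animal_id = "sim") {
  if (swing_duration >= period) {
    stop_wavegait("swing_duration must be < period",
                  class = "wavegait_param_error")
  }
  if (skip_prob < 0 || skip_prob >= 1) {
    stop_wavegait("skip_prob must lie in [0, 1)", class = "wavegait_param_error")
  }
  if (fps * period < 4) {
    stop_wavegait("fps * period must be >= 4 (cycle too coarse to sample)",
                  class = "wavegait_param_error")
  }
  structure(as.list(environment()), class = "gait_params")
}

## Peak leg-tip speed of the half-sine swing pulse, mm/s.
#' Peak swing speed implied by a gait parameter set
#' @param params A [gait_params()] object.
#' @return Peak leg-tip speed during swing, mm/s.
#' @export
peak_swing_speed <- function(params) {
  stride <- (params$stride_gain %||% params$period) * params$speed
  pi * stride / (2 * params$swing_duration)
}

#' Simulate six-leg wave-gait trajectories with ground truth
#'
#' Leg `k` of segment s swings at `t = n*T + phase_s/360*T + jitter` with
#' `phase_T3 = 0`, `phase_T2 = interseg_lag`, `phase_T1 = 2*interseg_lag`;
#' left and right legs of a segment are identical up to jitter. Scheduled
#' swings are dropped independently with `skip_prob`. The leg tip is
#' stationary in the lab frame during stance and translates forward by one
#' stride during swing following a half-sine velocity pulse (smooth, zero
#' at both endpoints, analytic peak speed). White Gaussian velocity noise
#' (`noise_sd`, per coordinate) emulates tracking error. Each emitted swing
#' onset triggers a pygopod plant event with probability `pygopod_prob`,
#' jittered by `N(0, pygopod_jitter_sd)` seconds.
#'
#' @param params A [gait_params()] object.
#' @return A list with elements `track` ([leg_track_table()]), `events`
#'   ([plant_events()], provenance `"simulated"`) and `truth`, a list of
#'   per-leg true swing tables (`onset_s`, `offset_s`, `start`, `end`),
#'   true `period`, per-leg `phase_deg`, and an `events` tibble
#'   (`time_s`, `frame`, `leg`, `onset_s`).
#' @export
simulate_gait <- function(params) {
  stopifnot(inherits(params, "gait_params"))
  p <- params
  if (!is.null(p$seed)) set.seed(p$seed)
  T <- p$period
  fps <- p$fps
  duration <- p$n_cycles * T
  n_frames <- as.integer(ceiling(duration * fps)) + 1L
  stride <- (p$stride_gain %||% T) * p$speed
  jitter_sd_s <- p$intraseg_jitter_sd / 360 * T

  phase <- c(T3 = 0, T2 = p$interseg_lag, T1 = 2 * p$interseg_lag)
  home_x <- c(T1 = 2, T2 = 1, T3 = 0)           # mm along body axis
  home_y <- c(L = 0.5, R = -0.5)                # mm lateral

  t_frames <- (seq_len(n_frames) - 1L) / fps
  legs <- vector("list", 6L)
  names(legs) <- LEG_IDS
  truth_sw <- vector("list", 6L)
  names(truth_sw) <- LEG_IDS

  for (leg in LEG_IDS) {
    seg <- segment_of(leg)
    sched <- (seq_len(p$n_cycles) - 1L) * T + phase[[seg]] / 360 * T
    jit <- stats::rnorm(length(sched), 0, jitter_sd_s)
    keep <- stats::runif(length(sched)) >= p$skip_prob
    onsets <- sched + jit
    ok <- keep & onsets >= 0 & (onsets + p$swing_duration) <= duration
    onsets <- sort(onsets[ok])
    offsets <- onsets + p$swing_duration

    ## analytic position: each swing contributes stride * smooth step;
    ## completed swings via findInterval, in-flight swings touch only the
    ## frames inside the swing window
    pos <- stride * findInterval(t_frames + 1e-12, onsets + p$swing_duration)
    for (o in onsets) {
      i_lo <- as.integer(floor(o * fps + 1e-9)) + 2L
      i_hi <- min(as.integer(ceiling((o + p$swing_duration) * fps - 1e-9)),
                  n_frames - 1L) + 1L
      if (i_hi < i_lo) next
      tt <- t_frames[i_lo:i_hi]
      u <- pmin(pmax((tt - o) / p$swing_duration, 0), 1)
      ## subtract exactly where findInterval above already counted the
      ## completed swing (same comparison, same tolerance)
      done <- tt + 1e-12 >= o + p$swing_duration
      pos[i_lo:i_hi] <- pos[i_lo:i_hi] +
        stride * ((1 - cos(pi * u)) / 2 - done)
    }
    x_mm <- home_x[[seg]] + pos
    y_mm <- rep(home_y[[side_of(leg)]], n_frames)
    if (p$noise_sd > 0) {
      ## white velocity noise along the direction of motion (the body axis)
      x_mm <- x_mm + cumsum(stats::rnorm(n_frames, 0, p$noise_sd)) / fps
    }
    legs[[leg]] <- cbind(x = x_mm / p$mm_per_px, y = y_mm / p$mm_per_px)
    ## integer frame labels use the majority-overlap rule: a frame is a
    ## swing frame when most of it falls inside the swing interval
    truth_sw[[leg]] <- tibble::tibble(
      onset_s = onsets, offset_s = offsets,
      start = as.integer(round(onsets * fps)),
      end = as.integer(round(offsets * fps)))
  }

  ## pygopod plant events tied to emitted swing onsets (fixed leg order for
  ## reproducibility)
  ev <- do.call(rbind, lapply(LEG_IDS, function(leg) {
    on <- truth_sw[[leg]]$onset_s
    if (!length(on)) return(NULL)
    hit <- stats::runif(length(on)) < p$pygopod_prob
    if (!any(hit)) return(NULL)
    t_ev <- on[hit] + stats::rnorm(sum(hit), 0, p$pygopod_jitter_sd)
    data.frame(time_s = t_ev, leg = leg, onset_s = on[hit])
  }))
  if (is.null(ev)) {
    ev <- data.frame(time_s = numeric(), leg = character(), onset_s = numeric())
  }
  ev$frame <- as.integer(round(ev$time_s * fps))
  ev <- ev[ev$frame >= 0L & ev$frame < n_frames, , drop = FALSE]
  ev <- ev[order(ev$time_s), , drop = FALSE]
  ev_frames <- sort(unique(ev$frame))

  track <- leg_track_table(legs, fps = fps, mm_per_px = p$mm_per_px,
                           animal_id = p$animal_id)
  events <- plant_events(ev_frames, fps = fps, n_frames = n_frames,
                         provenance = "simulated")
  truth <- list(
    swings = truth_sw, period = T, swing_duration = p$swing_duration,
    phase_deg = vapply(LEG_IDS, function(l) phase[[segment_of(l)]],
                       numeric(1)),
    events = tibble::as_tibble(ev[, c("time_s", "frame", "leg", "onset_s")]),
    params = p)
  list(track = track, events = events, truth = truth)
}

#' Path generator parameters
#'
#' Defaults describe the 2-min free-exploration assay: mean speed 1.8 mm/s,
#' sparse headsweeps, rare pauses, and backtrack-and-redirect episodes
#' lasting 3-6 s.
#'
#' @param mean_speed Overall mean instantaneous speed, mm/s; the assembled
#'   profile (episodes included) is normalised to this mean.
#' @param headsweep_rate Headsweep episodes per second.
#' @param headsweep_magnitude Peak body-angle excursion from 180 deg during
#'   a headsweep, degrees (> 30 so the 210/150 deg thresholds are crossed).
#' @param backtrack_rate Backtrack-and-redirect episodes per second.
#' @param backtrack_duration Length-2 range (s) of episode durations,
#'   drawn uniformly.
#' @param pause_prob Expected pauses per second (pause length 0.3-1 s).
#' @param heading_sd Heading diffusion, deg per sqrt(s); 0 gives a
#'   geometrically straight baseline path.
#' @param duration Total simulated time, s.
#' @param fps Frame rate, frames/s.
#' @param mm_per_px Spatial scale of the emitted pixel coordinates.
#' @param seed Integer seed.
#' @param animal_id Identifier for the emitted track.
#' @return An object of class `path_params`.
#' @export
path_params <- function(mean_speed = 1.8, headsweep_rate = 0.1,
                        headsweep_magnitude = 60, backtrack_rate = 0.01,
                        backtrack_duration = c(3, 6), pause_prob = 0.005,
                        heading_sd = 0, duration = 120, fps = 30,
                        mm_per_px = 0.05, seed = 1, animal_id = "simpath") {
  if (duration <= 0) {
    stop_wavegait("duration must be > 0", class = "wavegait_param_error")
  }
  if (any(c(headsweep_rate, backtrack_rate, pause_prob) < 0)) {
    stop_wavegait("rates must be >= 0", class = "wavegait_param_error")
  }
  if (length(backtrack_duration) != 2L ||
      backtrack_duration[1] > backtrack_duration[2]) {
    stop_wavegait("backtrack_duration must be an increasing length-2 range",
                  class = "wavegait_param_error")
  }
  structure(as.list(environment()), class = "path_params")
}

## Draw n_ep non-overlapping [start, end] second intervals inside
## [pad, duration - pad], greedily dropping overlaps.
place_episodes <- function(n_ep, dur_fun, duration, occupied, pad = 1) {
  out <- NULL
  if (n_ep <= 0) return(list(ep = out, occupied = occupied))
  starts <- sort(stats::runif(n_ep, pad, max(pad, duration - pad)))
  for (s in starts) {
    d <- dur_fun()
    e <- s + d
    if (e > duration - pad) next
    clash <- FALSE
    if (!is.null(occupied) && nrow(occupied)) {
      clash <- any(s < occupied[, 2] + 0.5 & e > occupied[, 1] - 0.5)
    }
    if (clash) next
    occupied <- rbind(occupied, c(s, e))
    out <- rbind(out, c(s, e))
  }
  list(ep = out, occupied = occupied)
}

#' Simulate a 2-D exploration path with ground-truth labels
#'
#' A constant-speed heading walk carrying three kinds of injected episodes:
#' headsweeps (smooth body-angle excursions beyond the 210/150 deg
#' thresholds with a concurrent turn), pauses (speed 0), and
#' backtrack-and-redirect episodes (turn to one side, visible backwards
#' displacement along the prior heading at ~180 deg body angle, then a
#' contralateral turn and resumed forward motion). Every frame carries a
#' ground-truth behavioural state (straight/bent/still, by the same angle
#' and speed definitions the classifier uses), a headsweep side flag and a
#' backtrack episode id.
#'
#' @param params A [path_params()] object.
#' @return A list with `track` ([centroid_track()]) and `truth`, a list of
#'   a per-frame label tibble (`frame`, `state`, `headsweep`,
#'   `backtrack_id`) and an `episodes` tibble (`id`, `start`, `end`,
#'   `first_side`, `duration_s`, `back_disp_mm`).
#' @export
simulate_path <- function(params) {
  stopifnot(inherits(params, "path_params"))
  p <- params
  if (!is.null(p$seed)) set.seed(p$seed)
  fps <- p$fps
  n <- as.integer(round(p$duration * fps))
  dt <- 1 / fps

  speed <- rep(p$mean_speed, n)        # mm/s, signed along heading
  dev <- rep(0, n)                     # body-angle deviation from 180 deg
  turn <- rep(0, n)                    # heading increment per frame, deg
  hs_flag <- rep("none", n)
  bt_id <- rep(NA_integer_, n)
  frozen <- rep(FALSE, n)              # frames where heading is held fixed

  if (p$heading_sd > 0) {
    turn <- turn + stats::rnorm(n, 0, p$heading_sd * sqrt(dt))
  }

  occupied <- matrix(numeric(0), ncol = 2)

  ## --- backtrack-and-redirect episodes (placed first; they are longest)
  n_bt <- stats::rpois(1L, p$backtrack_rate * p$duration)
  pl <- place_episodes(n_bt, function() stats::runif(1, p$backtrack_duration[1],
                                                     p$backtrack_duration[2]),
                       p$duration, occupied, pad = 1.5)
  occupied <- pl$occupied
  episodes <- NULL
  if (!is.null(pl$ep)) {
    for (i in seq_len(nrow(pl$ep))) {
      s <- pl$ep[i, 1]; e <- pl$ep[i, 2]; d <- e - s
      side <- sample(c(1, -1), 1L)      # +1 = left (angle above 180)
      f0 <- as.integer(round(s * fps)) + 1L
      n1 <- max(3L, as.integer(round(0.25 * d * fps)))  # first turn
      n2 <- max(3L, as.integer(round(0.50 * d * fps)))  # backwards run
      n3 <- max(3L, as.integer(round(0.25 * d * fps)))  # contralateral turn
      i1 <- f0:(f0 + n1 - 1L)
      i2 <- (f0 + n1):(f0 + n1 + n2 - 1L)
      i3 <- (f0 + n1 + n2):(f0 + n1 + n2 + n3 - 1L)
      if (max(i3) > n) next
      dev[i1] <- side * 45 * sin(pi * seq_len(n1) / (n1 + 1L))
      speed[i1] <- p$mean_speed * 0.3
      turn[i1] <- turn[i1] + side * 30 / n1
      dev[i2] <- 0
      speed[i2] <- -0.6 * p$mean_speed          # backwards along heading
      frozen[i2] <- TRUE
      dev[i3] <- -side * 45 * sin(pi * seq_len(n3) / (n3 + 1L))
      speed[i3] <- p$mean_speed * 0.3
      turn[i3] <- turn[i3] - side * 30 / n3
      idx <- c(i1, i2, i3)
      bt_id[idx] <- i
      hs_flag[i1][abs(dev[i1]) >= 30] <- if (side > 0) "L" else "R"
      hs_flag[i3][abs(dev[i3]) >= 30] <- if (side > 0) "R" else "L"
      episodes <- rbind(episodes, data.frame(
        id = i, start = f0 - 1L, end = max(i3),  # 0-based half-open
        first_side = if (side > 0) "L" else "R", duration_s = d,
        back_disp_mm = 0.6 * p$mean_speed * n2 * dt))
    }
  }

  ## --- plain headsweeps
  n_hs <- stats::rpois(1L, p$headsweep_rate * p$duration)
  pl <- place_episodes(n_hs, function() stats::runif(1, 0.5, 1.5),
                       p$duration, occupied)
  occupied <- pl$occupied
  if (!is.null(pl$ep)) {
    for (i in seq_len(nrow(pl$ep))) {
      s <- pl$ep[i, 1]; e <- pl$ep[i, 2]
      side <- sample(c(1, -1), 1L)
      idx <- (as.integer(round(s * fps)) + 1L):(as.integer(round(e * fps)))
      idx <- idx[idx >= 1L & idx <= n]
      if (length(idx) < 3L) next
      prof <- sin(pi * seq_along(idx) / (length(idx) + 1L))
      dev[idx] <- side * p$headsweep_magnitude * prof
      speed[idx] <- p$mean_speed * 0.5
      turn[idx] <- turn[idx] + side * 0.5 * p$headsweep_magnitude / length(idx)
      hs_flag[idx][abs(dev[idx]) >= 30] <- if (side > 0) "L" else "R"
    }
  }

  ## --- pauses
  n_pa <- stats::rpois(1L, p$pause_prob * p$duration)
  pl <- place_episodes(n_pa, function() stats::runif(1, 0.3, 1),
                       p$duration, occupied)
  if (!is.null(pl$ep)) {
    for (i in seq_len(nrow(pl$ep))) {
      idx <- (as.integer(round(pl$ep[i, 1] * fps)) + 1L):
        (as.integer(round(pl$ep[i, 2] * fps)))
      idx <- idx[idx >= 1L & idx <= n]
      speed[idx] <- 0
      dev[idx] <- 0
    }
  }

  ## --- normalise so the overall mean |speed| equals mean_speed (the
  ## reported "mean instantaneous velocity" includes slow episodes)
  m <- mean(abs(speed))
  if (m > 0) {
    sc <- p$mean_speed / m
    speed <- speed * sc
    if (!is.null(episodes)) {
      episodes$back_disp_mm <- episodes$back_disp_mm * sc
    }
  }

  ## --- integrate heading and position
  heading <- rep(0, n)
  h <- 0
  for (i in seq_len(n)) {
    if (!frozen[i]) h <- h + turn[i]
    heading[i] <- h
  }
  hr <- heading * pi / 180
  vx <- speed * cos(hr) * dt
  vy <- speed * sin(hr) * dt
  x_mm <- cumsum(c(0, vx[-n]))
  y_mm <- cumsum(c(0, vy[-n]))
  angle <- 180 + dev

  state <- ifelse(abs(speed) <= 1e-9, "still",
                  ifelse(abs(angle - 180) <= 30, "straight", "bent"))

  track <- centroid_track(x_mm / p$mm_per_px, y_mm / p$mm_per_px, angle,
                          fps = fps, mm_per_px = p$mm_per_px,
                          animal_id = p$animal_id)
  labels <- tibble::tibble(frame = seq_len(n) - 1L, state = state,
                           headsweep = hs_flag, backtrack_id = bt_id)
  truth <- list(labels = labels,
                episodes = tibble::as_tibble(
                  episodes %||% data.frame(id = integer(), start = integer(),
                                           end = integer(),
                                           first_side = character(),
                                           duration_s = numeric(),
                                           back_disp_mm = numeric())),
                params = p)
  list(track = track, truth = truth)
}
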