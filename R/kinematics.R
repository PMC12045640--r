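# Leg kinematics: velocity traces, swing/stance segmentation, cycle
# period, durations, duty cycles, stride lengths and phase relationships.

#' Smoothed leg-tip speed traces
#'
#' Forward-difference speed `||d(x, y)|| * fps * mm_per_px` (mm/s) per leg,
#' Savitzky-Golay low-pass filtered and clipped at zero. Sample `i`
#' (0-based) describes motion during frame interval `[i, i+1)`, so each
#' trace has `n_frames - 1` samples.
#'
#' @param track A [leg_track_table()].
#' @param cfg A [run_config()]; `sg_window`/`sg_order` control smoothing.
#' @return An object of class `velocity_series`: per-leg speed vectors plus
#'   smoothing metadata (`fps`, `window`, `order`).
#' @export
leg_speed <- function(track, cfg = run_config()) {
  stopifnot(inherits(track, "leg_tracks"))
  w <- sg_window_for(cfg, track$fps)
  if (track$n_frames - 1L < w) {
    stop_wavegait("track too short for SG window ", w,
                  "; use a smaller sg_window", class = "wavegait_length_error")
  }
  raw <- lapply(track$legs, function(m) {
    sqrt(diff(m[, "x"])^2 + diff(m[, "y"])^2) * track$fps * track$mm_per_px
  })
  speed <- lapply(raw, function(d) {
    pmax(signal::sgolayfilt(d, p = cfg$sg_order, n = w), 0)
  })
  structure(list(speed = speed, raw = raw, fps = track$fps, window = w,
                 order = cfg$sg_order, animal_id = track$animal_id),
            class = "velocity_series")
}

#' @export
print.velocity_series <- function(x, ...) {
  cat(sprintf("<velocity_series> %d legs x %d samples @ %g fps (SG %d/%d)\n",
              length(x$speed), length(x$speed[[1]]), x$fps, x$window, x$order))
  invisible(x)
}

## Hysteresis segmentation of one speed trace. Candidate runs come from
## the smoothed trace (robust detection); boundary timing is then refined
## on the raw trace, which is free of the smoother's pulse widening: from
## each smoothed-run boundary the exit-threshold crossing of the raw trace
## is located searching inward (smoothing only ever widens a unimodal
## pulse) and linearly interpolated to sub-frame precision. Integer frame
## bounds are the rounded refined times.
segment_one <- function(v, raw, fps, frac, min_frames) {
  th_hi <- frac * stats::quantile(v, 0.95, names = FALSE)
  empty <- tibble::tibble(start = integer(), end = integer(),
                          onset_s = numeric(), offset_s = numeric())
  if (!is.finite(th_hi) || th_hi <= 0) return(empty)
  th_lo <- th_hi / 2
  runs <- logical_runs(v >= th_lo)
  if (!nrow(runs)) return(empty)
  keep <- vapply(seq_len(nrow(runs)), function(i) {
    max(v[runs[i, 1]:runs[i, 2]]) >= th_hi &&
      (runs[i, 2] - runs[i, 1] + 1L) >= min_frames
  }, logical(1))
  runs <- runs[keep, , drop = FALSE]
  if (!nrow(runs)) return(empty)

  onset_s <- offset_s <- numeric(nrow(runs))
  start_f <- end_f <- integer(nrow(runs))
  for (i in seq_len(nrow(runs))) {
    a <- runs[i, 1]; b <- runs[i, 2]
    ## first/last raw sample at or above th_lo within the smoothed run
    inside <- which(raw[a:b] >= th_lo)
    if (length(inside)) {
      ja <- a + inside[1L] - 1L
      jb <- a + inside[length(inside)] - 1L
      ## exit-threshold crossing by linear interpolation (sub-frame)
      s_on <- ja
      if (ja > 1L && raw[ja - 1L] < th_lo) {
        s_on <- ja - (raw[ja] - th_lo) / (raw[ja] - raw[ja - 1L])
      }
      s_off <- jb
      if (jb < length(raw) && raw[jb + 1L] < th_lo) {
        s_off <- jb + (raw[jb] - th_lo) / (raw[jb] - raw[jb + 1L])
      }
    } else {
      s_on <- a; s_off <- b
    }
    ## sample j covers frames [j-1, j); its midpoint time is (j - 0.5)/fps.
    ## Integer frame labels follow the majority-overlap rule (round).
    onset_s[i] <- (s_on - 0.5) / fps
    offset_s[i] <- (s_off - 0.5) / fps
    start_f[i] <- as.integer(max(round(s_on - 0.5), 0))
    end_f[i] <- as.integer(min(max(round(s_off - 0.5), start_f[i] + 1),
                               length(v)))
  }
  tibble::tibble(start = start_f, end = end_f,
                 onset_s = onset_s, offset_s = offset_s)
}

#' Segment speed traces into swing and stance phases
#'
#' Swings are maximal runs where the smoothed speed stays at or above the
#' exit threshold and reaches the entry threshold at least once
#' (hysteresis): entry `theta_hi = swing_threshold_frac x` the per-leg
#' robust peak (95th percentile speed), exit `theta_lo = theta_hi / 2`.
#' Runs shorter than `max(2 frames, min_swing_s)` are discarded. Stance is
#' the complement. An all-zero trace yields an empty series, not an error.
#'
#' @param vel A `velocity_series` from [leg_speed()].
#' @param cfg A [run_config()].
#' @return An object of class `swing_series`: per-leg tibbles with integer
#'   half-open frame intervals `[start, end)` and interpolated sub-frame
#'   `onset_s`/`offset_s` times.
#' @export
segment_swings <- function(vel, cfg = run_config()) {
  stopifnot(inherits(vel, "velocity_series"))
  min_frames <- max(2L, as.integer(round(cfg$min_swing_s * vel$fps)))
  raw <- vel$raw %||% vel$speed
  swings <- lapply(names(vel$speed), function(lg) {
    segment_one(vel$speed[[lg]], raw[[lg]], fps = vel$fps,
                frac = cfg$swing_threshold_frac, min_frames = min_frames)
  })
  names(swings) <- names(vel$speed)
  structure(list(swings = swings, fps = vel$fps,
                 n_samples = length(vel$speed[[1]]),
                 animal_id = vel$animal_id),
            class = "swing_series")
}

#' @export
print.swing_series <- function(x, ...) {
  n <- vapply(x$swings, nrow, integer(1))
  cat(sprintf("<swing_series> %s: %s swings per leg @ %g fps\n",
              x$animal_id, paste(n, collapse = "/"), x$fps))
  invisible(x)
}

## Build a swing_series directly from interval tables (used for simulated
## ground truth and constructed fixtures).
#' Construct a swing series from interval tables
#'
#' @param swings Named list (all six leg ids) of data frames with columns
#'   `start`, `end` (0-based half-open frames) and optionally `onset_s`,
#'   `offset_s`.
#' @param fps Frame rate.
#' @param n_samples Length of the underlying velocity clock.
#' @param animal_id Identifier.
#' @return A `swing_series`.
#' @export
swing_series <- function(swings, fps, n_samples, animal_id = "animal") {
  swings <- lapply(swings[LEG_IDS], function(d) {
    d <- as.data.frame(d)
    if (is.null(d$onset_s)) d$onset_s <- d$start / fps
    if (is.null(d$offset_s)) d$offset_s <- d$end / fps
    stopifnot(all(d$end > d$start), !is.unsorted(d$start))
    if (nrow(d) > 1L && any(d$start[-1L] < d$end[-nrow(d)])) {
      stop_wavegait("swing intervals must be disjoint and sorted",
                    class = "wavegait_type_error")
    }
    tibble::as_tibble(d[, c("start", "end", "onset_s", "offset_s")])
  })
  structure(list(swings = swings, fps = fps, n_samples = as.integer(n_samples),
                 animal_id = animal_id),
            class = "swing_series")
}

#' Per-leg swing durations
#'
#' Swing duration is the time between swing start and swing stop
#' (interpolated sub-frame times), seconds.
#'
#' @param s A `swing_series`.
#' @return Named list of numeric vectors, one per leg.
#' @export
swing_durations <- function(s) {
  stopifnot(inherits(s, "swing_series"))
  lapply(s$swings, function(d) d$offset_s - d$onset_s)
}

#' Per-leg stance durations
#'
#' For consecutive swings i, i+1 of a leg, stance is the gap
#' `start[i+1] - end[i]` in seconds. Legs with fewer than two swings yield
#' an empty vector.
#'
#' @param s A `swing_series`.
#' @return Named list of numeric vectors, one per leg.
#' @export
stance_durations <- function(s) {
  stopifnot(inherits(s, "swing_series"))
  lapply(s$swings, function(d) {
    if (nrow(d) < 2L) return(numeric())
    d$onset_s[-1L] - d$offset_s[-nrow(d)]
  })
}

#' Per-animal cycle period
#'
#' Each leg's cycle frequency is its mean swing-onset rate
#' `(n_onsets - 1) / (last - first onset)`; the animal's period is the
#' reciprocal of the mean per-leg frequency (1 over average cycle
#' frequency).
#'
#' @param s A `swing_series`.
#' @return Cycle period in seconds, or `NA` if no leg has >= 2 swings.
#' @export
cycle_period <- function(s) {
  stopifnot(inherits(s, "swing_series"))
  freqs <- vapply(s$swings, function(d) {
    if (nrow(d) < 2L) return(NA_real_)
    (nrow(d) - 1L) / (d$onset_s[nrow(d)] - d$onset_s[1L])
  }, numeric(1))
  if (all(is.na(freqs))) return(NA_real_)
  1 / mean(freqs, na.rm = TRUE)
}

#' Per-segment swing and stance duty cycles
#'
#' Swing duty is the mean swing duration of a segment's legs over the
#' animal's cycle period; stance duty is its complement (stance is defined
#' as the complement of swing), so the two sum to 1 by construction.
#'
#' @param s A `swing_series`.
#' @param period Cycle period in seconds (> 0), e.g. from [cycle_period()].
#' @return A tibble with columns `segment`, `swing_duty`, `stance_duty`.
#' @export
duty_cycles <- function(s, period) {
  stopifnot(inherits(s, "swing_series"), is.finite(period), period > 0)
  sw <- swing_durations(s)
  rows <- lapply(SEGMENTS, function(seg) {
    d <- unlist(sw[paste0(seg, c("L", "R"))], use.names = FALSE)
    sd_ <- if (length(d)) mean(d) / period else NA_real_
    tibble::tibble(segment = seg, swing_duty = sd_, stance_duty = 1 - sd_)
  })
  do.call(rbind, rows)
}

#' Per-swing stride lengths
#'
#' Net leg-tip displacement from swing start to swing end, in mm. (The
#' alternative reading of stride length, body advance per cycle, is not
#' implemented; see the methods vignette.)
#'
#' @param track The [leg_track_table()] the swings were segmented from.
#' @param s A `swing_series` on the same frame clock.
#' @return Named list of numeric vectors (mm), one value per swing.
#' @export
stride_length <- function(track, s) {
  stopifnot(inherits(track, "leg_tracks"), inherits(s, "swing_series"))
  out <- lapply(LEG_IDS, function(leg) {
    d <- s$swings[[leg]]
    if (!nrow(d)) return(numeric())
    m <- track$legs[[leg]]
    i0 <- pmin(pmax(d$start, 0L), track$n_frames - 1L) + 1L
    i1 <- pmin(pmax(d$end, 0L), track$n_frames - 1L) + 1L
    as.numeric(sqrt((m[i1, "x"] - m[i0, "x"])^2 +
                      (m[i1, "y"] - m[i0, "y"])^2)) * track$mm_per_px
  })
  names(out) <- LEG_IDS
  out
}

## Pair each reference onset with its nearest onset in `other`; ties break
## to the earlier onset. Returns signed time differences other - ref.
nearest_onset_diff <- function(ref, other) {
  if (!length(ref) || !length(other)) return(numeric())
  vapply(ref, function(t0) {
    d <- other - t0
    i <- which.min(abs(d) - 1e-12 * (d < 0))  # tie -> earlier onset
    d[i]
  }, numeric(1))
}

#' Intrasegmental (left-right) phase difference per segment
#'
#' For each left-leg swing onset the nearest right-leg onset is found
#' (ties to the earlier one); the time difference is mapped to degrees of
#' the cycle (`360 * dt / period`), wrapped to `[-180, 180)`, and the
#' segment value is the circular mean of the absolute differences.
#'
#' @param s A `swing_series`.
#' @param period Cycle period, seconds.
#' @return Named numeric vector (`T1`, `T2`, `T3`) in degrees; `NA` where a
#'   leg of the segment has no swings.
#' @export
intrasegmental_phase <- function(s, period) {
  stopifnot(inherits(s, "swing_series"), is.finite(period), period > 0)
  out <- vapply(SEGMENTS, function(seg) {
    l <- s$swings[[paste0(seg, "L")]]$onset_s
    r <- s$swings[[paste0(seg, "R")]]$onset_s
    d <- nearest_onset_diff(l, r)
    if (!length(d)) return(NA_real_)
    circ_mean_deg(abs(wrap180(360 * d / period)))
  }, numeric(1))
  names(out) <- SEGMENTS
  out
}

#' Intersegmental phase relative to an anchor leg
#'
#' For each anchor onset the next onset of the target leg is taken; the
#' delay is mapped to degrees of the cycle and the circular mean reported
#' in `[0, 360)`. Negative phase would mean temporally earlier; with the
#' next-onset convention values lie in `[0, 360)`.
#'
#' @param s A `swing_series`.
#' @param period Cycle period, seconds.
#' @param anchor Anchor leg id (default `"T3L"`, the wave origin).
#' @param targets Target leg ids (default the left legs of the other
#'   segments).
#' @return Named numeric vector of phases in degrees, `[0, 360)`.
#' @export
intersegmental_phase <- function(s, period, anchor = "T3L",
                                 targets = setdiff(c("T3L", "T2L", "T1L"),
                                                   anchor)) {
  stopifnot(inherits(s, "swing_series"), is.finite(period), period > 0)
  a <- s$swings[[anchor]]$onset_s
  out <- vapply(targets, function(leg) {
    b <- s$swings[[leg]]$onset_s
    if (!length(a) || !length(b)) return(NA_real_)
    d <- vapply(a, function(t0) {
      nxt <- b[b >= t0 - 1e-12]
      if (!length(nxt)) NA_real_ else min(nxt) - t0
    }, numeric(1))
    d <- d[is.finite(d)]
    if (!length(d)) return(NA_real_)
    wrap360(circ_mean_deg(wrap360(360 * d / period)))
  }, numeric(1))
  names(out) <- targets
  out
}

#' One-row-per-animal kinematics summary
#'
#' Runs the full kinematics chain (speed, segmentation, period, durations,
#' duty cycles, strides, phases) and returns tidy tables.
#'
#' @param track A [leg_track_table()].
#' @param cfg A [run_config()].
#' @return A list of tibbles: `intervals` (one row per animal/leg/swing),
#'   `legs` (per-leg means), `segments` (per-segment durations, duties,
#'   intrasegmental phase), and `animal` (period, intersegmental phases).
#' @export
gait_summary <- function(track, cfg = run_config()) {
  vel <- leg_speed(track, cfg)
  s <- segment_swings(vel, cfg)
  period <- cycle_period(s)
  sw <- swing_durations(s)
  st <- stance_durations(s)
  strides <- stride_length(track, s)

  intervals <- do.call(rbind, lapply(LEG_IDS, function(lg) {
    d <- s$swings[[lg]]
    if (!nrow(d)) return(NULL)
    tibble::tibble(animal = track$animal_id, leg = lg,
                   cycle = seq_len(nrow(d)), start = d$start, end = d$end,
                   onset_s = d$onset_s, offset_s = d$offset_s,
                   swing_s = d$offset_s - d$onset_s,
                   stride_mm = strides[[lg]])
  }))
  legs <- do.call(rbind, lapply(LEG_IDS, function(lg) {
    tibble::tibble(animal = track$animal_id, leg = lg,
                   n_swings = nrow(s$swings[[lg]]),
                   mean_swing_s = if (length(sw[[lg]])) mean(sw[[lg]]) else NA,
                   mean_stance_s = if (length(st[[lg]])) mean(st[[lg]]) else NA,
                   mean_stride_mm = if (length(strides[[lg]]))
                     mean(strides[[lg]]) else NA)
  }))
  duties <- if (is.finite(period)) duty_cycles(s, period) else
    tibble::tibble(segment = SEGMENTS, swing_duty = NA_real_,
                   stance_duty = NA_real_)
  intra <- if (is.finite(period)) intrasegmental_phase(s, period) else
    stats::setNames(rep(NA_real_, 3L), SEGMENTS)
  segments <- tibble::tibble(
    animal = track$animal_id, segment = duties$segment,
    swing_duty = duties$swing_duty, stance_duty = duties$stance_duty,
    intraseg_phase_deg = intra[duties$segment])
  inter <- if (is.finite(period)) intersegmental_phase(s, period) else
    c(T2L = NA_real_, T1L = NA_real_)
  animal <- tibble::tibble(animal = track$animal_id, cycle_period_s = period,
                           interseg_T2_deg = inter[["T2L"]],
                           interseg_T1_deg = inter[["T1L"]])
  list(intervals = tibble::as_tibble(intervals), legs = legs,
       segments = segments, animal = animal, swings = s)
}
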