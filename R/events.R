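# Pygopod plant-event analysis: alignment to leg-swing initiations,
# Freedman-Diaconis binning, planting rate, event-triggered velocity
# averages and correlations.

#' Align plant events to the closest leg-swing initiation
#'
#' For each pygopod plant event, the signed offset (seconds; positive =
#' event after swing initiation) to the globally closest swing onset over
#' all six legs, recording the leg and thoracic segment of that swing.
#'
#' @param events A [plant_events()] list on the same frame clock as `s`, or
#'   a numeric vector of event times in seconds (e.g. continuous simulated
#'   ground-truth times).
#' @param s A `swing_series`.
#' @return A tibble with one row per event: `event_s`, `offset_s`, `leg`,
#'   `segment` (plus `event_frame` when `events` is a [plant_events()]).
#' @export
align_events_to_swings <- function(events, s) {
  stopifnot(inherits(s, "swing_series"))
  onset <- unlist(lapply(LEG_IDS, function(l) s$swings[[l]]$onset_s))
  leg <- rep(LEG_IDS, vapply(LEG_IDS, function(l) nrow(s$swings[[l]]),
                             integer(1)))
  if (!length(onset)) {
    stop_wavegait("no swings available to align events against",
                  class = "wavegait_undefined_result")
  }
  o <- order(onset)
  onset <- onset[o]
  leg <- leg[o]
  if (inherits(events, "plant_events")) {
    t_ev <- events$frames / events$fps
    frames <- events$frames
  } else {
    t_ev <- as.numeric(events)
    frames <- NULL
  }
  ## nearest onset via the sorted-insertion neighbours
  pos <- findInterval(t_ev, onset)
  lo <- pmax(pos, 1L)
  hi <- pmin(pos + 1L, length(onset))
  idx <- ifelse(abs(t_ev - onset[lo]) <= abs(onset[hi] - t_ev), lo, hi)
  out <- tibble::tibble(event_s = t_ev, offset_s = t_ev - onset[idx],
                        leg = leg[idx], segment = segment_of(leg[idx]))
  if (!is.null(frames)) out <- cbind(tibble::tibble(event_frame = frames), out)
  tibble::as_tibble(out)
}

#' Freedman-Diaconis histogram bin width
#'
#' `width = 2 * IQR(values) / n^(1/3)`. When the IQR is zero (degenerate
#' distribution), falls back to range-based binning with a Sturges bin
#' count, `width = diff(range) / (log2(n) + 1)` (0 when all values are
#' identical).
#'
#' @param values Numeric sample, `n >= 2`.
#' @return Bin width, same units as `values`.
#' @export
fd_bin_width <- function(values) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 2L) {
    stop_wavegait("need at least 2 values for a bin width",
                  class = "wavegait_param_error")
  }
  iqr <- stats::IQR(values)
  if (iqr > 0) return(2 * iqr / n^(1 / 3))
  diff(range(values)) / (log2(n) + 1)   # Sturges-count fallback
}

#' Histogram of event-to-swing offsets with FD bins
#'
#' Bin edges are centred on zero offset so the mode of a phase-locked
#' distribution falls in the central bin. Counts are normalised to sum
#' to 1.
#'
#' @param alignment Output of [align_events_to_swings()].
#' @param bin_width Bin width, s; default [fd_bin_width()] of the offsets.
#' @return A list with `breaks`, a tibble `bins` (`mid`, `count`,
#'   `density`), and `bin_width`.
#' @export
offset_histogram <- function(alignment, bin_width = NULL) {
  off <- alignment$offset_s
  bw <- bin_width %||% fd_bin_width(off)
  if (!is.finite(bw) || bw <= 0) bw <- max(diff(range(off)), 1e-6)
  k <- ceiling((max(abs(off)) + bw / 2) / bw)
  breaks <- seq(-k * bw - bw / 2, k * bw + bw / 2, by = bw)
  counts <- as.integer(table(cut(off, breaks, right = FALSE)))
  tib <- tibble::tibble(mid = breaks[-length(breaks)] + bw / 2,
                        count = counts, density = counts / sum(counts))
  list(breaks = breaks, bins = tib, bin_width = bw)
}

#' Pygopod planting rate
#'
#' Number of plant events over total tracked time; normalises event counts
#' for variable video lengths.
#'
#' @param events A [plant_events()] list.
#' @param tracked_time Total tracked time, seconds (> 0); default the full
#'   record length.
#' @return Rate in Hz.
#' @export
plant_rate <- function(events, tracked_time = NULL) {
  stopifnot(inherits(events, "plant_events"))
  tt <- tracked_time %||% (events$n_frames / events$fps)
  if (!is.finite(tt) || tt <= 0) {
    stop_wavegait("tracked_time must be > 0", class = "wavegait_param_error")
  }
  length(events$frames) / tt
}

#' Event-triggered average of body velocity
#'
#' Extracts the instantaneous velocity on `[-w, +w]` around each plant
#' event, drops events whose window exceeds the record, averages across
#' events, and normalises by the mean velocity over all included windows
#' (so a constant velocity gives a flat trace at 1).
#'
#' @param vel Per-frame body velocity, mm/s (e.g. from
#'   [instantaneous_velocity()]).
#' @param events A [plant_events()] list on the same clock.
#' @param window Half-width `w` of the window, seconds.
#' @param fps Frame rate of `vel`; defaults to `events$fps`.
#' @param normalise `"mean"` divides the averaged trace by the mean
#'   velocity over all included windows; `"zscore"` centres and scales it
#'   instead.
#' @return A list with `lag_s` (symmetric about 0), `mean_velocity`
#'   (normalised), `n_events` used, and the per-event matrix `windows`.
#' @export
event_triggered_velocity <- function(vel, events, window = 1, fps = NULL,
                                     normalise = c("mean", "zscore")) {
  normalise <- match.arg(normalise)
  stopifnot(inherits(events, "plant_events"))
  fps <- fps %||% events$fps
  vel <- as.numeric(vel)
  w <- as.integer(round(window * fps))
  if (2L * w + 1L > length(vel)) {
    stop_wavegait("window longer than the record", class = "wavegait_param_error")
  }
  centre <- events$frames + 1L            # 1-based index into vel
  ok <- centre - w >= 1L & centre + w <= length(vel)
  centre <- centre[ok]
  if (!length(centre)) {
    stop_wavegait("no events with a complete window",
                  class = "wavegait_undefined_result")
  }
  win <- t(vapply(centre, function(c0) vel[(c0 - w):(c0 + w)],
                  numeric(2L * w + 1L)))
  avg <- colMeans(win)
  if (normalise == "mean") {
    norm <- mean(win)
    if (norm > 0) avg <- avg / norm
  } else {
    s <- stats::sd(win)
    avg <- if (s > 0) (avg - mean(win)) / s else avg - mean(win)
  }
  list(lag_s = ((-w):w) / fps, mean_velocity = avg, n_events = length(centre),
       windows = win)
}

#' Squared Pearson correlation with significance
#'
#' @param x,y Finite numeric samples, `n >= 3`.
#' @return A list with `r2` and the two-sided `p` value.
#' @export
pearson_r2 <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    stop_wavegait("need paired samples of length >= 3",
                  class = "wavegait_param_error")
  }
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop_wavegait("samples must be finite", class = "wavegait_param_error")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop_wavegait("zero variance: correlation undefined",
                  class = "wavegait_undefined_result")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r2 = unname(ct$estimate)^2, p = ct$p.value)
}
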