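#' Leg-tip trajectory table
#'
#' Container for per-frame (x, y) positions of the six thoracic leg tips
#' (`T1L`, `T1R`, `T2L`, `T2R`, `T3L`, `T3R`), together with the frame rate
#' and spatial scale needed to convert pixel coordinates to mm and seconds.
#' Frames are 0-based; all downstream intervals are half-open `[start, end)`
#' in frames.
#'
#' @param legs Named list of two-column numeric matrices (or data frames)
#'   with columns `x`, `y` in pixels, one per leg id; all of equal length
#'   (>= 2 frames), no missing values.
#' @param fps Frames per second (> 0).
#' @param mm_per_px Spatial scale, mm per pixel (> 0).
#' @param animal_id Identifier carried through to tidy outputs.
#' @return An object of class `leg_tracks`.
#' @export
leg_track_table <- function(legs, fps, mm_per_px, animal_id = "animal") {
  if (!is.list(legs) || is.null(names(legs))) {
    stop_wavegait("`legs` must be a named list of coordinate matrices",
                  class = "wavegait_type_error")
  }
  if (!setequal(names(legs), LEG_IDS)) {
    stop_wavegait("expected 6 legs named ", paste(LEG_IDS, collapse = ", "),
                  class = "wavegait_type_error")
  }
  legs <- lapply(legs[LEG_IDS], function(m) {
    m <- as.matrix(as.data.frame(m)[, c("x", "y")])
    storage.mode(m) <- "double"
    m
  })
  n <- unique(vapply(legs, nrow, integer(1)))
  if (length(n) != 1L || n < 2L) {
    stop_wavegait("all legs must share the same length >= 2 frames",
                  class = "wavegait_type_error")
  }
  if (any(!vapply(legs, function(m) all(is.finite(m)), logical(1)))) {
    stop_wavegait("leg coordinates contain missing/non-finite values ",
                  "(gaps are an ingestion error)", class = "wavegait_type_error")
  }
  stopifnot(is.numeric(fps), fps > 0, is.numeric(mm_per_px), mm_per_px > 0)
  structure(
    list(legs = legs, fps = as.numeric(fps), mm_per_px = as.numeric(mm_per_px),
         n_frames = as.integer(n), animal_id = as.character(animal_id)),
    class = "leg_tracks")
}

#' @export
print.leg_tracks <- function(x, ...) {
  cat(sprintf("<leg_tracks> %s: 6 legs x %d frames @ %g fps, %g mm/px\n",
              x$animal_id, x$n_frames, x$fps, x$mm_per_px))
  invisible(x)
}

#' @export
as.data.frame.leg_tracks <- function(x, ...) {
  out <- do.call(rbind, lapply(LEG_IDS, function(l) {
    data.frame(animal = x$animal_id, leg = l, frame = seq_len(x$n_frames) - 1L,
               x = x$legs[[l]][, "x"], y = x$legs[[l]][, "y"])
  }))
  rownames(out) <- NULL
  out
}

#' Body-centroid track
#'
#' Per-frame body position (pixels) and body-bending angle in degrees, where
#' 180 deg is a straight body, larger angles bend left and smaller bend
#' right (the FIMTrack-style convention).
#'
#' @param x,y Numeric position vectors in pixels (length >= 2).
#' @param angle_deg Body bending angle per frame, degrees; finite.
#' @param fps Frames per second (> 0).
#' @param mm_per_px Spatial scale, mm per pixel (> 0).
#' @param animal_id Identifier carried through to tidy outputs.
#' @return An object of class `centroid_track`.
#' @export
centroid_track <- function(x, y, angle_deg, fps, mm_per_px,
                           animal_id = "animal") {
  n <- length(x)
  if (n < 2L || length(y) != n || length(angle_deg) != n) {
    stop_wavegait("x, y and angle_deg must share length >= 2",
                  class = "wavegait_type_error")
  }
  if (!all(is.finite(x)) || !all(is.finite(y)) || !all(is.finite(angle_deg))) {
    stop_wavegait("centroid track contains non-finite values",
                  class = "wavegait_type_error")
  }
  stopifnot(fps > 0, mm_per_px > 0)
  structure(
    list(x = as.numeric(x), y = as.numeric(y), angle_deg = as.numeric(angle_deg),
         fps = as.numeric(fps), mm_per_px = as.numeric(mm_per_px),
         n_frames = as.integer(n), animal_id = as.character(animal_id)),
    class = "centroid_track")
}

#' @export
print.centroid_track <- function(x, ...) {
  cat(sprintf("<centroid_track> %s: %d frames @ %g fps (%.1f s), %g mm/px\n",
              x$animal_id, x$n_frames, x$fps, x$n_frames / x$fps, x$mm_per_px))
  invisible(x)
}

#' @export
as.data.frame.centroid_track <- function(x, ...) {
  data.frame(animal = x$animal_id, frame = seq_len(x$n_frames) - 1L,
             x = x$x, y = x$y, angle_deg = x$angle_deg)
}

#' Pygopod plant-event list
#'
#' Strictly increasing 0-based frame indices of pygopod planting events
#' (visible extension of the paired terminal abdominal appendages into the
#' substrate), on the same frame clock as the associated leg-track table.
#'
#' @param frames Strictly increasing integer vector of 0-based event frames.
#' @param fps Frames per second of the shared clock.
#' @param n_frames Total frames of the associated record; events must lie in
#'   `[0, n_frames)`.
#' @param provenance `"observed"` for manual annotations, `"simulated"` for
#'   generator ground truth.
#' @return An object of class `plant_events`.
#' @export
plant_events <- function(frames, fps, n_frames, provenance = "observed") {
  frames <- as.integer(frames)
  if (any(diff(frames) <= 0L)) {
    stop_wavegait("event frames must be strictly increasing",
                  class = "wavegait_type_error")
  }
  if (length(frames) && (min(frames) < 0L || max(frames) >= n_frames)) {
    stop_wavegait("event frames outside track bounds [0, ", n_frames, ")",
                  class = "wavegait_type_error")
  }
  structure(list(frames = frames, fps = as.numeric(fps),
                 n_frames = as.integer(n_frames),
                 provenance = match.arg(provenance, c("observed", "simulated"))),
            class = "plant_events")
}

#' @export
print.plant_events <- function(x, ...) {
  cat(sprintf("<plant_events> %d events over %d frames @ %g fps (%s)\n",
              length(x$frames), x$n_frames, x$fps, x$provenance))
  invisible(x)
}

#' Analysis run configuration
#'
#' Bundles the tunable parameters of the pipeline: Savitzky-Golay smoothing,
#' swing segmentation thresholds, spectral plateau tolerance, multitaper
#' coherence settings (significance level `alpha`, tapers `K`, observations
#' `R`, time-bandwidth `NW`; degrees of freedom are `2*R*K`), the
#' event-triggered-average window and the histogram binning rule.
#'
#' @param sg_window Savitzky-Golay window length in frames (odd, >
#'   `sg_order`); `NULL` selects `max(5, odd(0.05 s * fps))` at run time.
#' @param sg_order Savitzky-Golay polynomial order.
#' @param swing_threshold_frac Entry threshold for swing segmentation as a
#'   fraction of the per-leg robust (95th percentile) peak speed; the exit
#'   threshold is half of it.
#' @param min_swing_s Minimum swing duration in seconds; runs shorter than
#'   `max(2 frames, min_swing_s)` are discarded. Default 0 (i.e. 2 frames).
#' @param plateau_tol Relative tolerance defining a spectral power plateau.
#' @param alpha Significance level for the coherence threshold, in (0, 1).
#' @param n_tapers Number of DPSS tapers `K` (>= 1).
#' @param time_bandwidth DPSS time-bandwidth product `NW` (requires
#'   `n_tapers <= 2*NW - 1`).
#' @param n_obs Number of observations `R` (non-overlapping segments);
#'   `NULL` derives it from `segment_s`.
#' @param segment_s Segment length in seconds when `n_obs` is `NULL`.
#' @param event_window_s Half-width of the event-triggered-average window, s.
#' @param hist_rule Histogram bin-width rule identifier (`"fd"`).
#' @param seed Optional integer seed recorded in run manifests.
#' @return An object of class `run_config` (a validated list).
#' @export
run_config <- function(sg_window = NULL, sg_order = 2L,
                       swing_threshold_frac = 0.3, min_swing_s = 0,
                       plateau_tol = 0.05, alpha = 0.05, n_tapers = 7L,
                       time_bandwidth = 4, n_obs = NULL, segment_s = 1,
                       event_window_s = 1, hist_rule = "fd", seed = NULL) {
  if (!(alpha > 0 && alpha < 1)) {
    stop_wavegait("alpha must lie in (0, 1)", class = "wavegait_config_error")
  }
  if (n_tapers < 1L) {
    stop_wavegait("n_tapers (K) must be >= 1", class = "wavegait_config_error")
  }
  if (!is.null(n_obs) && n_obs < 1L) {
    stop_wavegait("n_obs (R) must be >= 1", class = "wavegait_config_error")
  }
  if (n_tapers > 2 * time_bandwidth - 1) {
    stop_wavegait("n_tapers must be <= 2*time_bandwidth - 1",
                  class = "wavegait_config_error")
  }
  if (!is.null(sg_window)) {
    if (sg_window %% 2L == 0L || sg_window <= sg_order) {
      stop_wavegait("sg_window must be odd and > sg_order",
                    class = "wavegait_config_error")
    }
  }
  structure(list(sg_window = sg_window, sg_order = as.integer(sg_order),
                 swing_threshold_frac = swing_threshold_frac,
                 min_swing_s = min_swing_s, plateau_tol = plateau_tol,
                 alpha = alpha, n_tapers = as.integer(n_tapers),
                 time_bandwidth = time_bandwidth, n_obs = n_obs,
                 segment_s = segment_s, event_window_s = event_window_s,
                 hist_rule = match.arg(hist_rule, "fd"), seed = seed),
            class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-22s %s\n", nm,
                if (is.null(x[[nm]])) "<auto>" else format(x[[nm]])))
  }
  invisible(x)
}

## Resolve the SG window for a given frame rate.
sg_window_for <- function(cfg, fps) {
  cfg$sg_window %||% odd_at_least(0.05 * fps, 5L)
}
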