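# Pipeline driver: subcommands over the module functions, tidy-table
# outputs and a deterministic run manifest.

write_tidy <- function(df, path) {
  utils::write.csv(as.data.frame(df), path, row.names = FALSE, quote = FALSE)
  path
}

write_manifest <- function(out_dir, subcommand, cfg, seed, outputs) {
  manifest <- list(
    tool = "wavegait", version = as.character(utils::packageVersion("wavegait")),
    subcommand = subcommand, seed = seed,
    config = Filter(Negate(is.null), unclass(cfg)),
    outputs = basename(unlist(outputs)))
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  path
}

#' Run a pipeline subcommand end to end
#'
#' Thin driver around the analysis modules: reads the delimited-text
#' inputs, runs one analysis stage and writes tidy CSV result tables plus
#' a JSON run manifest (config, seed, version) to `out_dir`. Deterministic
#' given `seed`.
#'
#' Subcommands: `simulate` (gait + path generator; writes trajectory
#' tables, events and ground truth), `gait` (per-leg kinematics),
#' `coherence` (anchor-leg coherence table), `cycles` (T3->T1 cycle
#' extraction and report), `events` (plant-event alignment, rate,
#' triggered average), `path` (behavioural states, episodes, summary).
#'
#' @param subcommand One of `simulate`, `gait`, `coherence`, `cycles`,
#'   `events`, `path`.
#' @param out_dir Output directory (created if absent).
#' @param cfg A [run_config()].
#' @param track_path Manual-Tracking leg table (gait/coherence/cycles/
#'   events).
#' @param centroid_path FIMTrack-style centroid table (path; optional for
#'   events).
#' @param events_path Plant-event frame list (events).
#' @param fps,mm_per_px Acquisition metadata for the inputs.
#' @param leg_order Leg id per ascending track number, for
#'   [read_manual_track()].
#' @param seed Integer seed for `simulate`.
#' @param anchor Anchor leg for `coherence`.
#' @return Invisibly, a named list of written file paths.
#' @export
run_pipeline <- function(subcommand, out_dir, cfg = run_config(),
                         track_path = NULL, centroid_path = NULL,
                         events_path = NULL, fps = 100, mm_per_px = 0.01,
                         leg_order = LEG_IDS, seed = 1, anchor = "T1L") {
  subcommand <- match.arg(subcommand, c("simulate", "gait", "coherence",
                                        "cycles", "events", "path"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  need <- function(path, what) {
    if (is.null(path) || !file.exists(path)) {
      stop_wavegait("missing required input (", what, "): ",
                    path %||% "<not supplied>", class = "wavegait_io_error")
    }
    path
  }
  outputs <- list()
  o <- function(name) file.path(out_dir, name)

  if (subcommand == "simulate") {
    g <- simulate_gait(gait_params(seed = seed, fps = fps,
                                   mm_per_px = mm_per_px))
    p <- simulate_path(path_params(seed = seed))
    outputs$track <- write_manual_track(g$track, o("legs.csv"))
    outputs$events <- write_plant_events(g$events, o("plant_events.csv"))
    truth_sw <- do.call(rbind, lapply(LEG_IDS, function(l)
      cbind(leg = l, as.data.frame(g$truth$swings[[l]]))))
    outputs$gait_truth <- write_tidy(truth_sw, o("gait_truth.csv"))
    outputs$centroid <- write_centroid_track(p$track, o("centroid.csv"))
    outputs$path_truth <- write_tidy(p$truth$labels, o("path_truth.csv"))
  } else if (subcommand == "path") {
    ct <- read_centroid_track(need(centroid_path, "centroid table"),
                              fps = fps, mm_per_px = mm_per_px)
    outputs$states <- write_tidy(classify_states(ct), o("states.csv"))
    outputs$episodes <- write_tidy(detect_backtrack_redirect(ct),
                                   o("backtrack_episodes.csv"))
    outputs$summary <- write_tidy(path_summary(ct), o("path_summary.csv"))
    outputs$angles <- write_tidy(angle_histogram(ct), o("angle_histogram.csv"))
  } else {
    track <- read_manual_track(need(track_path, "leg track table"),
                               fps = fps, mm_per_px = mm_per_px,
                               leg_order = leg_order)
    if (subcommand == "gait") {
      gs <- gait_summary(track, cfg)
      outputs$intervals <- write_tidy(gs$intervals, o("swing_intervals.csv"))
      outputs$legs <- write_tidy(gs$legs, o("leg_summary.csv"))
      outputs$segments <- write_tidy(gs$segments, o("segment_summary.csv"))
      outputs$animal <- write_tidy(gs$animal, o("animal_summary.csv"))
    } else if (subcommand == "coherence") {
      res <- leg_coherence(track, cfg, anchor = anchor)
      outputs$coherence <- write_tidy(res, o("coherence.csv"))
    } else if (subcommand == "cycles") {
      gs <- gait_summary(track, cfg)
      cyc <- extract_t3_to_t1_cycles(gs$swings)
      st <- unlist(stance_durations(gs$swings), use.names = FALSE)
      fp <- filter_pauses(st)
      report <- tibble::tibble(
        animal = track$animal_id, n_cycles = nrow(cyc),
        extracted_pct = extraction_fraction(
          cyc, (track$n_frames - 1L) / track$fps),
        n_stances_discarded = length(fp$discarded))
      outputs$cycles <- write_tidy(cyc, o("walk_cycles.csv"))
      outputs$report <- write_tidy(report, o("extraction_report.csv"))
    } else if (subcommand == "events") {
      ev <- read_plant_events(need(events_path, "plant-event list"),
                              fps = track$fps, n_frames = track$n_frames)
      gs <- gait_summary(track, cfg)
      ali <- align_events_to_swings(ev, gs$swings)
      outputs$alignment <- write_tidy(ali, o("event_alignment.csv"))
      hist <- offset_histogram(ali)
      outputs$histogram <- write_tidy(hist$bins, o("offset_histogram.csv"))
      rate <- tibble::tibble(animal = track$animal_id,
                             plant_rate_hz = plant_rate(ev))
      outputs$rate <- write_tidy(rate, o("plant_rate.csv"))
      if (!is.null(centroid_path)) {
        ct <- read_centroid_track(centroid_path, fps = track$fps,
                                  mm_per_px = mm_per_px)
        eta <- event_triggered_velocity(instantaneous_velocity(ct), ev,
                                        window = cfg$event_window_s)
        outputs$triggered <- write_tidy(
          tibble::tibble(lag_s = eta$lag_s, mean_velocity = eta$mean_velocity),
          o("triggered_average.csv"))
      }
    }
  }
  outputs$manifest <- write_manifest(out_dir, subcommand, cfg, seed, outputs)
  invisible(outputs)
}
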