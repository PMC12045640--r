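# Reading and writing the delimited-text trajectory dialects.

## Autodetect comma vs whitespace delimited text with a one-line header.
read_delim_auto <- function(path) {
  if (!file.exists(path)) {
    stop_wavegait("cannot read input file: ", path, class = "wavegait_io_error")
  }
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                    strip.white = TRUE, comment.char = "")
}

match_column <- function(df, patterns, what, path) {
  nms <- tolower(names(df))
  for (p in patterns) {
    hit <- which(grepl(p, nms))
    if (length(hit)) return(hit[1L])
  }
  stop_wavegait("missing required column '", what, "' in ", path,
                class = "wavegait_io_error")
}

#' Read a Manual-Tracking leg trajectory table
#'
#' Parses the Fiji Manual Tracking dialect: delimited text (comma or
#' whitespace, autodetected) with a one-line header and one row per
#' (track, slice) giving track number, slice (frame) and x, y pixel
#' coordinates. Exactly six distinct tracks are required and the caller
#' supplies the leg identity of each track via `leg_order`, since tracking
#' order is operator-defined.
#'
#' @param path Path to the delimited text file.
#' @param fps Frame rate of the source video, frames/s.
#' @param mm_per_px Spatial scale of the source video, mm per pixel.
#' @param leg_order Character vector of six leg ids giving the leg tracked
#'   as the 1st, 2nd, ... track number in ascending order. Default assumes
#'   tracks were recorded `T1L, T1R, T2L, T2R, T3L, T3R`.
#' @param animal_id Identifier carried through to outputs.
#' @return A [leg_track_table()] with frames re-indexed 0-based.
#' @export
read_manual_track <- function(path, fps, mm_per_px, leg_order = LEG_IDS,
                              animal_id = "animal") {
  df <- read_delim_auto(path)
  ci <- c(track = match_column(df, c("^track"), "track", path),
          slice = match_column(df, c("^slice$", "slice", "^frame"), "slice", path),
          x = match_column(df, c("^x$", "^x\\b", "x"), "x", path),
          y = match_column(df, c("^y$", "^y\\b", "y"), "y", path))
  track <- as.integer(df[[ci["track"]]])
  slice <- as.integer(df[[ci["slice"]]])
  xs <- as.numeric(df[[ci["x"]]])
  ys <- as.numeric(df[[ci["y"]]])

  tracks <- sort(unique(track))
  if (length(tracks) != 6L) {
    stop_wavegait("expected 6 legs (tracks), found ", length(tracks), " in ",
                  path, class = "wavegait_io_error")
  }
  if (!setequal(leg_order, LEG_IDS) || length(leg_order) != 6L) {
    stop_wavegait("leg_order must be a permutation of ",
                  paste(LEG_IDS, collapse = ", "), class = "wavegait_io_error")
  }
  legs <- vector("list", 6L)
  names(legs) <- leg_order
  for (i in seq_along(tracks)) {
    sel <- track == tracks[i]
    sl <- slice[sel]
    o <- order(sl)
    sl <- sl[o]
    if (anyDuplicated(sl)) {
      d <- sl[duplicated(sl)][1L]
      stop_wavegait("duplicate entry at track ", tracks[i], " slice ", d,
                    class = "wavegait_io_error")
    }
    gaps <- which(diff(sl) != 1L)
    if (length(gaps)) {
      stop_wavegait("gap at track ", tracks[i], " slice ", sl[gaps[1L]] + 1L,
                    class = "wavegait_io_error")
    }
    legs[[leg_order[i]]] <- cbind(x = xs[sel][o], y = ys[sel][o])
  }
  lens <- vapply(legs, nrow, integer(1))
  if (length(unique(lens)) != 1L) {
    stop_wavegait("tracks have unequal lengths (", paste(lens, collapse = ", "),
                  ") in ", path, class = "wavegait_io_error")
  }
  leg_track_table(legs, fps = fps, mm_per_px = mm_per_px, animal_id = animal_id)
}

#' Write a leg trajectory table in the Manual-Tracking dialect
#'
#' Inverse of [read_manual_track()]: tracks are numbered 1..6 in the order
#' given by `leg_order`, slices are 1-based. Coordinates are written with
#' enough precision for an exact text round-trip.
#'
#' @param x A [leg_track_table()].
#' @param path Output path.
#' @param leg_order Leg id per ascending track number.
#' @return `path`, invisibly.
#' @export
write_manual_track <- function(x, path, leg_order = LEG_IDS) {
  stopifnot(inherits(x, "leg_tracks"))
  rows <- do.call(rbind, lapply(seq_along(leg_order), function(i) {
    m <- x$legs[[leg_order[i]]]
    data.frame(track = i, slice = seq_len(nrow(m)), x = m[, "x"], y = m[, "y"])
  }))
  utils::write.table(format(rows, digits = 15, scientific = FALSE,
                            trim = TRUE),
                     path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a FIMTrack-style centroid track
#'
#' Delimited text with a one-line header and columns frame, x, y and body
#' bending angle (degrees, 180 = straight). The frame column must be
#' contiguous and monotone increasing.
#'
#' @inheritParams read_manual_track
#' @return A [centroid_track()] on a 0-based frame clock.
#' @export
read_centroid_track <- function(path, fps, mm_per_px, animal_id = "animal") {
  df <- read_delim_auto(path)
  ci <- c(frame = match_column(df, c("^frame", "^slice"), "frame", path),
          x = match_column(df, c("^x$", "^x\\b", "^mom_x", "x"), "x", path),
          y = match_column(df, c("^y$", "^y\\b", "^mom_y", "y"), "y", path),
          angle = match_column(df, c("angle", "bend"), "angle", path))
  fr <- as.integer(df[[ci["frame"]]])
  if (any(diff(fr) <= 0L)) {
    stop_wavegait("frame column not monotone increasing in ", path,
                  class = "wavegait_io_error")
  }
  if (any(diff(fr) != 1L)) {
    stop_wavegait("frame gap after frame ", fr[which(diff(fr) != 1L)[1L]],
                  " in ", path, class = "wavegait_io_error")
  }
  centroid_track(as.numeric(df[[ci["x"]]]), as.numeric(df[[ci["y"]]]),
                 as.numeric(df[[ci["angle"]]]), fps = fps,
                 mm_per_px = mm_per_px, animal_id = animal_id)
}

#' Write a centroid track
#' @param x A [centroid_track()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_centroid_track <- function(x, path) {
  stopifnot(inherits(x, "centroid_track"))
  df <- data.frame(frame = seq_len(x$n_frames) - 1L, x = x$x, y = x$y,
                   angle_deg = x$angle_deg)
  utils::write.table(format(df, digits = 15, scientific = FALSE, trim = TRUE),
                     path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a plant-event frame list
#'
#' One 0-based frame index per line (or a delimited file with a `frame`
#' column header).
#'
#' @param path Input path.
#' @param fps Frame rate of the shared clock.
#' @param n_frames Length of the associated record, frames.
#' @return A [plant_events()] object.
#' @export
read_plant_events <- function(path, fps, n_frames) {
  if (!file.exists(path)) {
    stop_wavegait("cannot read input file: ", path, class = "wavegait_io_error")
  }
  first <- readLines(path, n = 1L)
  frames <- if (grepl("[A-Za-z]", first)) {
    df <- read_delim_auto(path)
    as.integer(df[[match_column(df, c("^frame"), "frame", path)]])
  } else {
    as.integer(scan(path, quiet = TRUE))
  }
  plant_events(sort(unique(frames)), fps = fps, n_frames = n_frames,
               provenance = "observed")
}

#' Write a plant-event frame list
#' @param x A [plant_events()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_plant_events <- function(x, path) {
  stopifnot(inherits(x, "plant_events"))
  writeLines(c("frame", as.character(x$frames)), path)
  invisible(path)
}

#' Read a key-value configuration file
#'
#' Lines of `key = value` (or `key: value`); `#` starts a comment. Values
#' are coerced to numeric where possible and mapped onto [run_config()]
#' fields; unknown keys are an error.
#'
#' @param path Input path.
#' @return A [run_config()].
#' @export
read_config <- function(path) {
  if (!file.exists(path)) {
    stop_wavegait("cannot read config file: ", path, class = "wavegait_io_error")
  }
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*[=:]\\s*")
  bad <- lengths(kv) != 2L
  if (any(bad)) {
    stop_wavegait("malformed config line: '", lines[bad][1L], "'",
                  class = "wavegait_io_error")
  }
  keys <- vapply(kv, `[[`, "", 1L)
  vals <- vapply(kv, `[[`, "", 2L)
  allowed <- names(formals(run_config))
  unknown <- setdiff(keys, allowed)
  if (length(unknown)) {
    stop_wavegait("unknown config key(s): ", paste(unknown, collapse = ", "),
                  class = "wavegait_io_error")
  }
  args <- lapply(vals, function(v) {
    n <- suppressWarnings(as.numeric(v))
    if (is.na(n)) v else n
  })
  names(args) <- keys
  do.call(run_config, args)
}
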