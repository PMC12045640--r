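# Whole-animal path metrics and behavioural-state analysis.

#' Instantaneous centroid velocity
#'
#' `||d position|| * fps * mm_per_px`, mm/s. Sample `i` (0-based)
#' describes motion during frame interval `[i, i+1)`; the trace has
#' `n_frames - 1` samples.
#'
#' @param c A [centroid_track()].
#' @return Numeric vector of speeds, mm/s.
#' @export
instantaneous_velocity <- function(c) {
  stopifnot(inherits(c, "centroid_track"))
  sqrt(diff(c$x)^2 + diff(c$y)^2) * c$fps * c$mm_per_px
}

#' Classify frames into straight / bent / still behavioural states
#'
#' A frame is `still` when speed is at or below `tol_vel` (a literal
#' 0 mm/s never occurs in floating point); otherwise `straight` when the
#' body angle is within `tol_angle` of 180 deg and `bent` otherwise. The
#' default `tol_angle = 30` makes straight = (150, 210) deg so that "bent"
#' coincides with the headsweep thresholds. Headsweep flags are assigned
#' independently of the three-state label: left when angle >= 210 deg,
#' right when angle <= 150 deg.
#'
#' @param c A [centroid_track()].
#' @param tol_angle Half-width of the straight band around 180 deg.
#' @param tol_vel Still speed tolerance, mm/s.
#' @return A tibble with one row per frame: `frame`, `speed_mm_s`,
#'   `angle_deg`, `state`, `headsweep` (`"L"`, `"R"`, `"none"`). The last
#'   frame inherits the final speed sample.
#' @export
classify_states <- function(c, tol_angle = 30, tol_vel = 0.05) {
  stopifnot(inherits(c, "centroid_track"))
  v <- instantaneous_velocity(c)
  v <- c(v, v[length(v)])               # label all n frames
  ang <- c$angle_deg
  state <- ifelse(v <= tol_vel, "still",
                  ifelse(abs(ang - 180) <= tol_angle, "straight", "bent"))
  hs <- ifelse(ang >= 210, "L", ifelse(ang <= 150, "R", "none"))
  tibble::tibble(frame = seq_len(c$n_frames) - 1L, speed_mm_s = v,
                 angle_deg = ang, state = state, headsweep = hs)
}

#' Count headsweep episodes per side
#'
#' Maximal runs of headsweep-flagged frames count as one episode each.
#'
#' @param states Output of [classify_states()].
#' @return Named integer vector `c(left = , right = )`.
#' @export
headsweep_counts <- function(states) {
  runs_of <- function(side) {
    r <- rle(states$headsweep == side)
    sum(r$values)
  }
  c(left = runs_of("L"), right = runs_of("R"))
}

#' Test for a left/right headsweep bias
#'
#' Tests whether the proportion of left headsweeps differs from 0.5 (the
#' null of the intercept-only binomial model), using the exact binomial
#' test, which remains well behaved when all events fall on one side.
#'
#' @param left,right Non-negative event counts, `left + right >= 1`.
#' @return A list with `estimate` (left proportion) and two-sided `p`.
#' @export
headsweep_bias <- function(left, right) {
  n <- left + right
  if (n < 1L) {
    stop_wavegait("no headsweep events to test", class = "wavegait_param_error")
  }
  bt <- stats::binom.test(left, n, p = 0.5)
  list(estimate = left / n, p = bt$p.value)
}

## Unit heading vectors from a trailing displacement window of `w` frames.
trailing_heading <- function(x, y, w) {
  n <- length(x)
  hx <- hy <- rep(NA_real_, n)
  idx <- (w + 1L):n
  dx <- x[idx] - x[idx - w]
  dy <- y[idx] - y[idx - w]
  len <- sqrt(dx^2 + dy^2)
  ok <- len > 0
  hx[idx[ok]] <- dx[ok] / len[ok]
  hy[idx[ok]] <- dy[ok] / len[ok]
  list(hx = hx, hy = hy)
}

#' Detect backtrack-and-redirect episodes
#'
#' A three-stage state machine over frames: (i) a headsweep to one side;
#' (ii) a run of frames whose displacement projected on the pre-episode
#' heading is negative while the body is near straight
#' (`|angle - 180| <= tol_angle`), accumulating at least
#' `min_back_disp_mm` of backwards displacement over at least
#' `min_back_s`; (iii) a headsweep to the opposite side. All three must
#' fall within `max_window_s`. The reference heading is the direction of
#' the `heading_window_s` displacement preceding the first headsweep and
#' is frozen for the whole episode.
#'
#' @param c A [centroid_track()].
#' @param tol_angle Straightness tolerance during the backwards run, deg.
#' @param heading_window_s Length of the trailing window defining the
#'   pre-episode heading, s.
#' @param min_back_s Minimum duration of the backwards run, s.
#' @param min_back_disp_mm Minimum backwards displacement, mm.
#' @param max_window_s Maximum span of a whole episode, s.
#' @return A tibble with one row per episode: `start`, `end` (0-based
#'   half-open frames), `first_side`, `back_disp_mm`, `duration_s`.
#' @export
detect_backtrack_redirect <- function(c, tol_angle = 30,
                                      heading_window_s = 0.5,
                                      min_back_s = 0.3,
                                      min_back_disp_mm = 0.3,
                                      max_window_s = 10) {
  stopifnot(inherits(c, "centroid_track"))
  fps <- c$fps
  n <- c$n_frames
  states <- classify_states(c, tol_angle = tol_angle)
  hs <- states$headsweep
  hw <- max(2L, as.integer(round(heading_window_s * fps)))
  head_ref <- trailing_heading(c$x, c$y, hw)
  dx <- diff(c$x) * c$mm_per_px
  dy <- diff(c$y) * c$mm_per_px

  hs_runs <- logical_runs(hs != "none")
  empty <- tibble::tibble(start = integer(), end = integer(),
                          first_side = character(), back_disp_mm = numeric(),
                          duration_s = numeric())
  if (nrow(hs_runs) < 2L) return(empty)
  run_side <- vapply(seq_len(nrow(hs_runs)), function(i)
    hs[hs_runs[i, 1]], character(1))

  max_w <- as.integer(round(max_window_s * fps))
  min_back <- max(2L, as.integer(round(min_back_s * fps)))

  out <- NULL
  i <- 1L
  while (i < nrow(hs_runs)) {
    a1 <- hs_runs[i, 1]; b1 <- hs_runs[i, 2]; side1 <- run_side[i]
    ref_i <- max(a1 - 1L, 1L)
    rx <- head_ref$hx[ref_i]; ry <- head_ref$hy[ref_i]
    matched <- FALSE
    if (is.finite(rx)) {
      lim <- min(n - 1L, a1 + max_w)
      ## backwards displacement per velocity sample, projected on frozen
      ## heading, gated on near-straight body angle
      seg <- b1:(lim - 1L)
      if (length(seg) >= min_back) {
        proj <- dx[seg] * rx + dy[seg] * ry
        straight <- abs(c$angle_deg[seg] - 180) <= tol_angle
        back <- proj < 0 & straight
        br <- logical_runs(back)
        if (nrow(br)) {
          lens <- br[, 2] - br[, 1] + 1L
          disp <- vapply(seq_len(nrow(br)), function(k)
            -sum(proj[br[k, 1]:br[k, 2]]), numeric(1))
          cand <- which(lens >= min_back & disp >= min_back_disp_mm)
          if (length(cand)) {
            k <- cand[1L]
            back_end <- seg[br[k, 2]]
            ## contralateral headsweep after the backwards run
            nxt <- which(hs_runs[, 1] > back_end &
                           hs_runs[, 1] <= a1 + max_w &
                           run_side != side1)
            nxt <- nxt[nxt > i]
            if (length(nxt)) {
              j <- nxt[1L]
              out <- rbind(out, data.frame(
                start = a1 - 1L, end = hs_runs[j, 2],
                first_side = side1, back_disp_mm = disp[k],
                duration_s = (hs_runs[j, 2] - a1 + 1L) / fps))
              i <- j + 1L
              matched <- TRUE
            }
          }
        }
      }
    }
    if (!matched) i <- i + 1L
  }
  if (is.null(out)) return(empty)
  tibble::as_tibble(out)
}

#' Path curviness (tortuosity)
#'
#' Total path length over net displacement; 1 for a straight path, pi/2
#' for a semicircular arc. Invariant to rotation, translation and uniform
#' scaling.
#'
#' @param c A [centroid_track()] (or a two-column matrix of coordinates).
#' @return Scalar >= 1. A path with zero net displacement signals a
#'   `wavegait_undefined_result` error.
#' @export
curviness <- function(c) {
  if (inherits(c, "centroid_track")) {
    x <- c$x; y <- c$y
  } else {
    m <- as.matrix(c); x <- m[, 1]; y <- m[, 2]
  }
  net <- sqrt((x[length(x)] - x[1])^2 + (y[length(y)] - y[1])^2)
  if (net == 0) {
    stop_wavegait("zero net displacement: curviness undefined",
                  class = "wavegait_undefined_result")
  }
  sum(sqrt(diff(x)^2 + diff(y)^2)) / net
}

#' Body-angle histogram
#'
#' Counts of per-frame body angles in fixed-width bins over `[0, 360)`
#' degrees (default every 10 deg).
#'
#' @param c A [centroid_track()] (or a numeric vector of angles).
#' @param bin Bin width, degrees.
#' @return A tibble with `bin_start`, `bin_mid`, `count`.
#' @export
angle_histogram <- function(c, bin = 10) {
  ang <- if (inherits(c, "centroid_track")) c$angle_deg else as.numeric(c)
  ang <- wrap360(ang)
  breaks <- seq(0, 360, by = bin)
  counts <- as.integer(table(cut(ang, breaks, right = FALSE,
                                 include.lowest = FALSE)))
  tibble::tibble(bin_start = breaks[-length(breaks)],
                 bin_mid = breaks[-length(breaks)] + bin / 2, count = counts)
}

#' Total distance travelled
#'
#' Sum of per-frame step lengths, mm.
#'
#' @param c A [centroid_track()].
#' @return Distance in mm.
#' @export
total_distance <- function(c) {
  stopifnot(inherits(c, "centroid_track"))
  sum(sqrt(diff(c$x)^2 + diff(c$y)^2)) * c$mm_per_px
}

#' Per-animal path summary
#'
#' @param c A [centroid_track()].
#' @param tol_angle,tol_vel Passed to [classify_states()].
#' @return A one-row tibble: mean velocity, total distance, curviness,
#'   percent time straight/bent/still, headsweep counts.
#' @export
path_summary <- function(c, tol_angle = 30, tol_vel = 0.05) {
  states <- classify_states(c, tol_angle, tol_vel)
  hs <- headsweep_counts(states)
  curv <- tryCatch(curviness(c), error = function(e) NA_real_)
  tibble::tibble(
    animal = c$animal_id,
    mean_velocity_mm_s = mean(instantaneous_velocity(c)),
    total_distance_mm = total_distance(c),
    curviness = curv,
    pct_straight = 100 * mean(states$state == "straight"),
    pct_bent = 100 * mean(states$state == "bent"),
    pct_still = 100 * mean(states$state == "still"),
    headsweeps_left = hs[["left"]], headsweeps_right = hs[["right"]])
}
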