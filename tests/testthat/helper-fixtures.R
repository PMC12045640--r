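# Fixture builders and independent brute-force oracles shared across tests.

leg_ids <- c("T1L", "T1R", "T2L", "T2R", "T3L", "T3R")

## Write a Manual-Tracking dialect fixture: 6 tracks x n slices.
write_track_fixture <- function(path, n = 10, tracks = 1:6, drop = NULL,
                                dup = NULL, sep = ",") {
  rows <- do.call(rbind, lapply(tracks, function(tr) {
    data.frame(track = tr, slice = 1:n, x = tr * 100 + (1:n),
               y = tr * 10 + 0.5 * (1:n))
  }))
  if (!is.null(drop)) {
    rows <- rows[!(rows$track == drop[1] & rows$slice == drop[2]), ]
  }
  if (!is.null(dup)) {
    rows <- rbind(rows, rows[rows$track == dup[1] & rows$slice == dup[2], ])
  }
  header <- paste(c("track", "slice", "x", "y"), collapse = sep)
  body <- apply(rows, 1, paste, collapse = sep)
  writeLines(c(header, body), path)
  path
}

## Build a velocity_series directly from a named list of speed traces
## (raw = speed: no smoothing), for estimator tests on constructed pulses.
make_velocity_series <- function(speed, fps) {
  structure(list(speed = speed, raw = speed, fps = fps, window = NA_integer_,
                 order = NA_integer_, animal_id = "fixture"),
            class = "velocity_series")
}

## Square pulse train: value `amp` during each [on, on + dur) second window.
pulse_train <- function(onsets_s, dur_s, fps, total_s, amp = 10) {
  n <- round(total_s * fps)
  v <- numeric(n)
  for (o in onsets_s) {
    i <- which((seq_len(n) - 0.5) / fps >= o &
                 (seq_len(n) - 0.5) / fps < o + dur_s)
    v[i] <- amp
  }
  v
}

## Six-leg swing series from per-leg onset vectors (seconds).
make_swing_series <- function(onsets, dur_s, fps, n_samples) {
  sw <- lapply(leg_ids, function(l) {
    on <- sort(onsets[[l]])
    data.frame(start = as.integer(round(on * fps)),
               end = as.integer(round((on + dur_s) * fps)),
               onset_s = on, offset_s = on + dur_s)
  })
  names(sw) <- leg_ids
  swing_series(sw, fps = fps, n_samples = n_samples)
}

## Oracle: single-threshold run segmentation (brute force, no hysteresis).
oracle_threshold_runs <- function(v, th) {
  above <- v >= th
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values] - 1L, end = ends[r$values])
}

## Oracle: plateau-rule peak selection by explicit enumeration.
oracle_plateau <- function(freq, power, tol) {
  cut <- (1 - tol) * max(power)
  above <- power >= cut
  blocks <- list()
  i <- 1
  while (i <= length(above)) {
    if (above[i]) {
      j <- i
      while (j < length(above) && above[j + 1]) j <- j + 1
      blocks[[length(blocks) + 1]] <- i:j
      i <- j + 1
    } else i <- i + 1
  }
  scores <- vapply(blocks, function(b) max(power[b]), numeric(1))
  best <- which(scores >= max(power) * (1 - 1e-12))
  b <- blocks[[best[length(best)]]]
  len <- length(b)
  mid <- b[(len - 1) %/% 2 + 1 + (len %% 2 == 0)]
  freq[mid]
}

## Oracle: averaged-periodogram (boxcar, K = 1) coherence, plain loops.
oracle_boxcar_coherence <- function(x, y, R) {
  L <- floor(length(x) / R)
  nyq <- L %/% 2 + 1
  Sxx <- Syy <- numeric(nyq)
  Sxy <- complex(real = numeric(nyq))
  for (r in seq_len(R)) {
    idx <- ((r - 1) * L + 1):(r * L)
    xs <- x[idx] - mean(x[idx])
    ys <- y[idx] - mean(y[idx])
    X <- fft(xs)[1:nyq]
    Y <- fft(ys)[1:nyq]
    Sxx <- Sxx + Mod(X)^2
    Syy <- Syy + Mod(Y)^2
    Sxy <- Sxy + Conj(X) * Y
  }
  list(coherence = Mod(Sxy) / sqrt(Sxx * Syy),
       phase_deg = Arg(Sxy) * 180 / pi)
}

## Oracle: Freedman-Diaconis width from first principles.
oracle_fd <- function(x) {
  q <- unname(quantile(x, c(0.25, 0.75)))
  2 * (q[2] - q[1]) * length(x)^(-1 / 3)
}

## Frame-wise swing/stance agreement between predicted and true intervals.
frame_agreement <- function(pred, truth, n) {
  lab <- function(tbl) {
    l <- rep(FALSE, n)
    for (k in seq_len(nrow(tbl))) {
      i0 <- max(tbl$start[k] + 1L, 1L)
      i1 <- min(tbl$end[k], n)
      if (i1 >= i0) l[i0:i1] <- TRUE
    }
    l
  }
  mean(lab(pred) == lab(truth))
}
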