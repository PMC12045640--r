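# Spectral analysis: fundamental-frequency selection with plateau rules,
# DPSS multitaper coherence and the analytic significance threshold.

## Cache DPSS tapers per (n, nw, k); the eigen decomposition is cheap but
## called inside Monte-Carlo loops.
.dpss_cache <- new.env(parent = emptyenv())

#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Computed from the classical symmetric tridiagonal formulation (diagonal
#' `((n-1-2i)/2)^2 cos(2 pi W)`, off-diagonal `i (n-i) / 2`, `W = nw/n`),
#' whose top eigenvectors are the most spectrally concentrated sequences.
#' Tapers are unit-norm, ordered by decreasing concentration.
#'
#' @param n Taper length, samples.
#' @param nw Time-bandwidth product (requires `k <= 2*nw - 1`).
#' @param k Number of tapers.
#' @return An `n x k` matrix, one taper per column.
#' @export
dpss_tapers <- function(n, nw, k) {
  stopifnot(n >= 8, k >= 1, k <= max(1, floor(2 * nw - 1)))
  key <- paste(n, nw, k, sep = "_")
  hit <- .dpss_cache[[key]]
  if (!is.null(hit)) return(hit)
  i <- 0:(n - 1)
  w <- nw / n
  A <- matrix(0, n, n)
  diag(A) <- ((n - 1 - 2 * i) / 2)^2 * cos(2 * pi * w)
  off <- (1:(n - 1)) * (n - (1:(n - 1))) / 2
  A[cbind(1:(n - 1), 2:n)] <- off
  A[cbind(2:n, 1:(n - 1))] <- off
  V <- eigen(A, symmetric = TRUE)$vectors[, seq_len(k), drop = FALSE]
  V <- apply(V, 2, function(v) v / sqrt(sum(v^2)))
  .dpss_cache[[key]] <- V
  V
}

#' Fundamental frequency from a power spectrum with plateau rules
#'
#' Selects the frequency with greatest power density, with explicit
#' handling of plateau ambiguity: bins with power within `plateau_tol`
#' (relative) of the maximum form plateaus (maximal contiguous blocks);
#' the middle bin of the winning plateau is returned, and when two blocks
#' tie for maximum power the higher-frequency block is used. The DC bin is
#' excluded before calling this.
#'
#' @param freq Increasing frequency grid, Hz (DC excluded).
#' @param power Non-negative power per bin.
#' @param plateau_tol Relative tolerance; a bin belongs to the plateau set
#'   when `power >= (1 - plateau_tol) * max(power)`.
#' @return The selected frequency, Hz; `NA` for a flat zero spectrum.
#' @export
fundamental_from_spectrum <- function(freq, power, plateau_tol = 0.05) {
  stopifnot(length(freq) == length(power), !is.unsorted(freq))
  pmax_ <- max(power)
  if (!is.finite(pmax_) || pmax_ <= 0) return(NA_real_)
  above <- power >= (1 - plateau_tol) * pmax_
  runs <- logical_runs(above)
  ## blocks attaining the global maximum (numeric tolerance on ties)
  score <- vapply(seq_len(nrow(runs)), function(i)
    max(power[runs[i, 1]:runs[i, 2]]), numeric(1))
  top <- which(score >= pmax_ * (1 - 1e-12))
  block <- runs[top[length(top)], ]   # higher-frequency block on ties
  ## middle bin of the block; upper-middle for even lengths, consistent
  ## with the higher-frequency bias of the tie rule
  len <- block[2] - block[1] + 1L
  freq[block[1] + (len - 1L) %/% 2L + as.integer(len %% 2L == 0L)]
}

#' Fundamental frequency of a leg's velocity trace
#'
#' Periodogram of the (demeaned) anchor-leg speed trace; the stepping
#' frequency is the spectral peak selected by the plateau rules of
#' [fundamental_from_spectrum()].
#'
#' @param vel A `velocity_series` from [leg_speed()], or a numeric vector.
#' @param leg Leg id when `vel` is a `velocity_series` (default the
#'   conventional anchor `"T1L"`).
#' @param plateau_tol Relative plateau tolerance.
#' @param fs Sampling rate, Hz; taken from `vel` when available.
#' @return Fundamental frequency, Hz; `NA` for a flat spectrum.
#' @export
fundamental_frequency <- function(vel, leg = "T1L", plateau_tol = 0.05,
                                  fs = NULL) {
  if (inherits(vel, "velocity_series")) {
    fs <- vel$fps
    x <- vel$speed[[leg]]
  } else {
    x <- as.numeric(vel)
    if (is.null(fs)) stop_wavegait("fs required for a bare numeric trace",
                                   class = "wavegait_param_error")
  }
  n <- length(x)
  if (n < 8L) {
    stop_wavegait("trace too short for spectral analysis (need >= 8 samples)",
                  class = "wavegait_length_error")
  }
  x <- x - mean(x)
  P <- Mod(stats::fft(x))^2
  nyq <- n %/% 2L + 1L
  freq <- (seq_len(nyq) - 1L) * fs / n
  fundamental_from_spectrum(freq[-1L], P[2:nyq], plateau_tol)
}

#' Multitaper coherence magnitude and phase between two traces
#'
#' Both traces are split into `R` non-overlapping segments, demeaned,
#' tapered with `K` DPSS tapers and Fourier transformed; cross- and
#' auto-spectra are averaged over all `R * K` tapered segments. Coherence
#' magnitude is `|Sxy| / sqrt(Sxx * Syy)` (amplitude-scale invariant, in
#' `[0, 1]`) and phase is `Arg(Sxy)` in degrees with
#' `Sxy = <Conj(X) * Y>`, so a delayed second signal has negative phase at
#' the delay frequency.
#'
#' @param x,y Equal-length numeric traces (or `velocity_series` plus leg
#'   names via [leg_coherence()]).
#' @param fs Sampling rate, Hz.
#' @param cfg A [run_config()] supplying `n_tapers` (K), `time_bandwidth`
#'   (NW) and the segmentation (`n_obs` R, else segments of `segment_s`).
#' @param f0 Frequency of interest, Hz; when given, scalar `magnitude` and
#'   `phase_deg` at the bin nearest `f0` are included.
#' @param tapers Optional explicit taper matrix (columns = tapers), e.g. a
#'   boxcar for a plain averaged periodogram; default DPSS.
#' @return List with the full `freq`, `coherence`, `phase_deg` spectra,
#'   `dof = 2*R*K`, `R`, `K`, and (when `f0` given) `magnitude`,
#'   `phase_at_f0`, `f_bin`.
#' @export
multitaper_coherence <- function(x, y, fs, cfg = run_config(), f0 = NULL,
                                 tapers = NULL) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) {
    stop_wavegait("traces must have equal length", class = "wavegait_param_error")
  }
  n <- length(x)
  R <- cfg$n_obs %||% max(1L, floor(n / round(cfg$segment_s * fs)))
  L <- floor(n / R)
  if (L < 8L) {
    stop_wavegait("segments too short (", L, " samples); use fewer ",
                  "observations R or longer traces",
                  class = "wavegait_length_error")
  }
  K <- cfg$n_tapers
  if (is.null(tapers)) tapers <- dpss_tapers(L, cfg$time_bandwidth, K)
  K <- ncol(tapers)

  nyq <- L %/% 2L + 1L
  Sxx <- Syy <- numeric(nyq)
  Sxy <- complex(real = numeric(nyq))
  for (r in seq_len(R)) {
    idx <- ((r - 1L) * L + 1L):(r * L)
    xs <- x[idx] - mean(x[idx])
    ys <- y[idx] - mean(y[idx])
    X <- stats::mvfft(tapers * xs)[seq_len(nyq), , drop = FALSE]
    Y <- stats::mvfft(tapers * ys)[seq_len(nyq), , drop = FALSE]
    Sxx <- Sxx + rowSums(Mod(X)^2)
    Syy <- Syy + rowSums(Mod(Y)^2)
    Sxy <- Sxy + rowSums(Conj(X) * Y)
  }
  denom <- sqrt(Sxx * Syy)
  coh <- ifelse(denom > 0, Mod(Sxy) / denom, NA_real_)
  coh <- pmin(coh, 1)
  phase <- Arg(Sxy) * 180 / pi
  freq <- (seq_len(nyq) - 1L) * fs / L
  out <- list(freq = freq, coherence = coh, phase_deg = phase,
              dof = 2L * R * K, R = R, K = K)
  if (!is.null(f0)) {
    i <- which.min(abs(freq - f0))
    out$f_bin <- freq[i]
    out$magnitude <- coh[i]
    out$phase_at_f0 <- wrap180(phase[i])
  }
  out
}

#' Analytic significance threshold for coherence magnitude
#'
#' The minimum coherence magnitude significant at level `alpha` given
#' `dof = 2*R*K` degrees of freedom:
#' `sqrt(1 - alpha^(1 / (dof/2 - 1)))`. Monotonically decreasing in `dof`.
#'
#' @param cfg A [run_config()] (uses `alpha`, `n_tapers`); alternatively
#'   pass `alpha` and `dof` directly.
#' @param dof Degrees of freedom `2*R*K` (> 2); required unless derivable
#'   from `cfg$n_obs`.
#' @param alpha Significance level, overriding `cfg$alpha`.
#' @return The threshold, in `[0, 1]`.
#' @export
coherence_threshold <- function(cfg = run_config(), dof = NULL, alpha = NULL) {
  alpha <- alpha %||% cfg$alpha
  if (is.null(dof)) {
    if (is.null(cfg$n_obs)) {
      stop_wavegait("dof must be supplied (or cfg$n_obs set)",
                    class = "wavegait_param_error")
    }
    dof <- 2 * cfg$n_obs * cfg$n_tapers
  }
  if (dof <= 2) {
    stop_wavegait("dof must exceed 2", class = "wavegait_param_error")
  }
  sqrt(1 - alpha^(1 / (dof / 2 - 1)))
}

#' Coherence of all legs against an anchor leg
#'
#' Determines the anchor leg's fundamental frequency from its velocity
#' spectrum, then computes multitaper coherence magnitude and phase of each
#' of the other five legs against the anchor at that frequency, flagging
#' significance against the analytic threshold.
#'
#' @param track A [leg_track_table()] (or a precomputed `velocity_series`).
#' @param cfg A [run_config()].
#' @param anchor Anchor leg id (default `"T1L"`; `"T3L"` is also standard
#'   for intersegmental analyses).
#' @return A tibble with one row per non-anchor leg: `leg`, `magnitude`,
#'   `phase_deg`, `significant`, plus the shared `f0`, `threshold`, `dof`.
#' @export
leg_coherence <- function(track, cfg = run_config(), anchor = "T1L") {
  vel <- if (inherits(track, "velocity_series")) track else
    leg_speed(track, cfg)
  f0 <- fundamental_frequency(vel, leg = anchor,
                              plateau_tol = cfg$plateau_tol)
  if (!is.finite(f0)) {
    stop_wavegait("anchor leg has a flat spectrum; fundamental undefined",
                  class = "wavegait_undefined_result")
  }
  others <- setdiff(LEG_IDS, anchor)
  rows <- lapply(others, function(leg) {
    mt <- multitaper_coherence(vel$speed[[anchor]], vel$speed[[leg]],
                               fs = vel$fps, cfg = cfg, f0 = f0)
    thr <- coherence_threshold(cfg, dof = mt$dof)
    tibble::tibble(animal = vel$animal_id, leg = leg, anchor = anchor,
                   magnitude = mt$magnitude, phase_deg = mt$phase_at_f0,
                   significant = mt$magnitude >= thr, f0 = f0,
                   threshold = thr, dof = mt$dof)
  })
  do.call(rbind, rows)
}

#' Percentage of legs significantly coherent with the anchor
#'
#' @param results Output of [leg_coherence()] (five non-anchor legs).
#' @return Percentage in `[0, 100]`.
#' @export
coherent_leg_fraction <- function(results) {
  stopifnot(is.data.frame(results), "significant" %in% names(results))
  100 * sum(results$significant) / nrow(results)
}
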