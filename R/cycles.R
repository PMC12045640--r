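# Walk-cycle extraction: T3 -> T1 sequences, pause filtering and the
# fraction of tracked time covered.

#' Extract walk cycles following the T3 -> T1 sequence
#'
#' Scans metathoracic (T3) swing onsets, either side. Bilaterally
#' near-synchronous T3 onsets (within a quarter period) form one cycle
#' start; a candidate cycle is accepted iff the next T2 onset and then the
#' next T1 onset occur, in that order, before the following T3 onset.
#' Overlapping candidates are resolved greedily left to right. The cycle
#' span runs from the first T3 onset to the next T3 onset (half-open).
#'
#' @param s A `swing_series` for all six legs.
#' @param period Cycle period in seconds used for the bilateral-synchrony
#'   window; `NULL` estimates it with [cycle_period()].
#' @return A tibble with one row per accepted cycle: `cycle`, `t_start`,
#'   `t_end`, `period_s`, and the first onset of each leg within the span
#'   (`NA` when a leg did not swing). Empty when no cycle qualifies.
#' @export
extract_t3_to_t1_cycles <- function(s, period = NULL) {
  stopifnot(inherits(s, "swing_series"))
  onsets_of <- function(seg) {
    sort(c(s$swings[[paste0(seg, "L")]]$onset_s,
           s$swings[[paste0(seg, "R")]]$onset_s))
  }
  t3 <- onsets_of("T3"); t2 <- onsets_of("T2"); t1 <- onsets_of("T1")
  empty <- tibble::tibble(cycle = integer(), t_start = numeric(),
                          t_end = numeric(), period_s = numeric(),
                          T3L = numeric(), T3R = numeric(), T2L = numeric(),
                          T2R = numeric(), T1L = numeric(), T1R = numeric())
  if (length(t3) < 2L || !length(t2) || !length(t1)) return(empty)
  period <- period %||% cycle_period(s)
  if (!is.finite(period) || period <= 0) return(empty)
  sync_win <- period / 4

  out <- NULL
  i <- 1L
  while (i <= length(t3)) {
    t0 <- t3[i]
    j <- i
    while (j < length(t3) && t3[j + 1L] <= t0 + sync_win) j <- j + 1L
    if (j >= length(t3)) break        # no following T3 onset: span undefined
    t_next <- t3[j + 1L]
    o2 <- t2[t2 > t0 & t2 < t_next]
    accepted <- FALSE
    if (length(o2)) {
      o1 <- t1[t1 > o2[1L] & t1 < t_next]
      if (length(o1)) {
        first_in <- function(leg) {
          on <- s$swings[[leg]]$onset_s
          on <- on[on >= t0 - 1e-12 & on < t_next]
          if (length(on)) on[1L] else NA_real_
        }
        out <- rbind(out, data.frame(
          t_start = t0, t_end = t_next, period_s = t_next - t0,
          T3L = first_in("T3L"), T3R = first_in("T3R"),
          T2L = first_in("T2L"), T2R = first_in("T2R"),
          T1L = first_in("T1L"), T1R = first_in("T1R")))
        accepted <- TRUE
      }
    }
    i <- j + 1L
    if (!accepted) next
  }
  if (is.null(out)) return(empty)
  tibble::as_tibble(cbind(cycle = seq_len(nrow(out)), out))
}

#' Filter pause periods out of a stance-duration distribution
#'
#' Stances longer than `median + 1*sd` of the animal's stance distribution
#' are discarded as pauses. (The stated bound "median +/- 1 s.d." is read
#' as the upper bound only: a lower bound would re-admit pauses rather
#' than remove them.) Applied per animal.
#'
#' @param stances Numeric vector of stance durations, seconds.
#' @return A list with `kept` and `discarded` numeric vectors and the
#'   `threshold` used (`Inf` when the distribution is degenerate).
#' @export
filter_pauses <- function(stances) {
  stances <- as.numeric(stances)
  if (!length(stances)) {
    return(list(kept = numeric(), discarded = numeric(), threshold = Inf))
  }
  s <- stats::sd(stances)
  thr <- if (!is.finite(s) || s == 0) Inf else stats::median(stances) + s
  list(kept = stances[stances <= thr], discarded = stances[stances > thr],
       threshold = thr)
}

#' Fraction of tracked time covered by extracted cycles
#'
#' @param cycles Output of [extract_t3_to_t1_cycles()].
#' @param total_time Total tracked time (including pauses), seconds (> 0).
#' @return Percentage in `[0, 100]`.
#' @export
extraction_fraction <- function(cycles, total_time) {
  stopifnot(is.finite(total_time), total_time > 0)
  if (!nrow(cycles)) return(0)
  100 * sum(cycles$t_end - cycles$t_start) / total_time
}
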