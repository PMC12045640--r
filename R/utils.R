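# Internal helpers shared across modules.

#' @keywords internal
#' @importFrom signal sgolayfilt
#' @importFrom tibble tibble
#' @importFrom jsonlite write_json
#' @importFrom stats median sd quantile fft mvfft rnorm runif rpois
#' @importFrom utils read.table write.table
"_PACKAGE"

## Canonical leg identifiers: three thoracic segments (T1 anterior ... T3
## posterior), left and right.
LEG_IDS <- c("T1L", "T1R", "T2L", "T2R", "T3L", "T3R")
SEGMENTS <- c("T1", "T2", "T3")

segment_of <- function(leg) substr(leg, 1L, 2L)
side_of <- function(leg) substr(leg, 3L, 3L)

`%||%` <- function(a, b) if (is.null(a)) b else a

## Wrap angles (degrees) into [-180, 180).
wrap180 <- function(x) ((x + 180) %% 360) - 180

## Wrap angles (degrees) into [0, 360).
wrap360 <- function(x) x %% 360

## Circular mean of angles in degrees; result wrapped to [-180, 180).
circ_mean_deg <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) return(NA_real_)
  r <- x * pi / 180
  wrap180(atan2(mean(sin(r)), mean(cos(r))) * 180 / pi)
}

## Smallest odd integer >= max(x, lo).
odd_at_least <- function(x, lo = 5L) {
  x <- max(as.integer(round(x)), lo)
  if (x %% 2L == 0L) x + 1L else x
}

## Maximal runs of TRUE in a logical vector; matrix with 1-based start/end
## (inclusive) per row.
logical_runs <- function(flag) {
  r <- rle(as.logical(flag))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  cbind(start = starts[keep], end = ends[keep])
}

stop_wavegait <- function(..., class) {
  stop(errorCondition(paste0(...), class = c(class, "wavegait_error")))
}
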