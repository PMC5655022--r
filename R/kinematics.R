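## Kinematic signal operators ----------------------------------------------
##
## Shared primitives over touch paths, attitude angle series and
## acceleration series.  All operators are deterministic and unit-free
## except where seconds are stated.

#' Five-number summary used throughout the feature inventory
#'
#' @param x Numeric vector (NAs removed).
#' @return Named vector `c(mean, sd, min, max, median)`; all `NA` when `x`
#'   is empty.  `sd` is `NA` for a single value (sample sd undefined).
#' @export
summary_stats <- function(x) {
  x <- x[is.finite(x)]
  if (!length(x))
    return(c(mean = NA_real_, sd = NA_real_, min = NA_real_,
             max = NA_real_, median = NA_real_))
  c(mean = mean(x), sd = if (length(x) > 1) stats::sd(x) else NA_real_,
    min = min(x), max = max(x), median = stats::median(x))
}

check_path <- function(x, y) {
  if (length(x) == 0L) stop("empty path")
  if (length(x) != length(y)) stop("x and y lengths differ")
}

#' Traversed length of a planar path
#'
#' Sum of Euclidean segment lengths in normalized screen units; 0 for a
#' single sample.
#'
#' @param x,y Coordinate vectors in path order.
#' @return Non-negative length.
#' @export
path_length <- function(x, y) {
  check_path(x, y)
  if (length(x) == 1L) return(0)
  sum(sqrt(diff(x)^2 + diff(y)^2))
}

#' Path efficiency (straightness index)
#'
#' Ratio of the straight-line distance between the first and last sample to
#' the traversed length; 1 for a perfectly direct drag.  Defined as 1 when
#' the traversed length is zero (a stationary touch is maximally direct).
#'
#' @inheritParams path_length
#' @return Value in `[0, 1]`.
#' @export
path_efficiency <- function(x, y) {
  check_path(x, y)
  len <- path_length(x, y)
  if (len == 0) return(1)
  n <- length(x)
  sqrt((x[n] - x[1])^2 + (y[n] - y[1])^2) / len
}

#' Per-segment speed statistics of a drag path
#'
#' Speeds are segment length over segment time; segments with zero time
#' difference are skipped.
#'
#' @param t Sample times in seconds (non-decreasing).
#' @inheritParams path_length
#' @return [summary_stats()] over per-segment speeds.
#' @export
segment_speed_stats <- function(t, x, y) {
  check_path(x, y)
  if (length(t) < 2L) stop("need >= 2 samples for speeds")
  dt <- diff(t)
  dl <- sqrt(diff(x)^2 + diff(y)^2)
  keep <- dt > 0
  summary_stats(dl[keep] / dt[keep])
}

## Collapse runs of equal consecutive values to single points.
collapse_plateaus <- function(v) {
  if (length(v) < 2L) return(v)
  v[c(TRUE, diff(v) != 0)]
}

#' Count interior local extrema of a series
#'
#' Plateaus (runs of equal values) are collapsed to single points first;
#' an interior point then counts if it is a strict local minimum or
#' maximum.  Used as a proxy for unsteady tilt control.
#'
#' @param values Ordered numeric vector (>= 1 value).
#' @return Integer count >= 0.
#' @export
oscillation_count <- function(values) {
  if (!length(values)) stop("empty series")
  v <- collapse_plateaus(values)
  if (length(v) < 3L) return(0L)
  d <- diff(v)
  sum(d[-length(d)] * d[-1] < 0)
}

## Direction sign map: the signed angle s*angle is positive when the device
## tilts in `direction`.  Pitch: negative pitch = forward; roll: positive
## roll = left (right edge lifted).
DIRECTION_SIGN <- c(forward = -1, backward = 1, left = 1, right = -1)

#' Detect maximal tilt episodes in one direction
#'
#' A tilt episode is a maximal contiguous run of samples whose
#' direction-signed angle exceeds `threshold`.  Boundaries are at sample
#' resolution (no sub-sample interpolation), so a single-sample run is an
#' episode of zero duration.
#'
#' @param t Sample times in seconds.
#' @param angle Roll (for directions left/right) or pitch (forward/backward)
#'   in radians.
#' @param direction One of `"forward"`, `"backward"`, `"left"`, `"right"`.
#' @param threshold Tilt threshold in radians (> 0).
#' @return Data frame with columns `t_start`, `t_end`, `peak` (maximum
#'   signed angle, radians) and `oscillations` (interior local extrema of
#'   the signed angle within the episode).
#' @export
detect_tilt_episodes <- function(t, angle, direction, threshold) {
  if (!length(t)) stop("empty angle series")
  direction <- match.arg(direction, names(DIRECTION_SIGN))
  s <- DIRECTION_SIGN[[direction]] * angle
  above <- s > threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  out <- data.frame(t_start = t[starts[keep]], t_end = t[ends[keep]],
                    peak = rep(NA_real_, length(keep)),
                    oscillations = rep(NA_integer_, length(keep)))
  for (i in seq_along(keep)) {
    seg <- s[starts[keep[i]]:ends[keep[i]]]
    out$peak[i] <- max(seg)
    out$oscillations[i] <- oscillation_count(seg)
  }
  out
}

#' Summarize tilt episodes over a game
#'
#' @param episodes Data frame from [detect_tilt_episodes()].
#' @param duration Total game time in seconds (> 0).
#' @return Named vector: `fraction` of time tilted, tilt `rate` (episodes
#'   per second), `peak_mean/peak_sd/peak_median` over per-episode peaks and
#'   `osc_mean/osc_sd/osc_median` over per-episode oscillation counts.
#'   All zeros when there are no episodes.
#' @export
tilt_features <- function(episodes, duration) {
  if (!is.numeric(duration) || duration <= 0) stop("duration must be > 0")
  n <- nrow(episodes)
  if (n == 0L)
    return(c(fraction = 0, rate = 0, peak_mean = 0, peak_sd = 0,
             peak_median = 0, osc_mean = 0, osc_sd = 0, osc_median = 0))
  ps <- summary_stats(episodes$peak)
  os <- summary_stats(as.numeric(episodes$oscillations))
  sd0 <- function(s) if (is.na(s[["sd"]])) 0 else s[["sd"]]
  c(fraction = min(1, sum(episodes$t_end - episodes$t_start) / duration),
    rate = n / duration,
    peak_mean = ps[["mean"]], peak_sd = sd0(ps), peak_median = ps[["median"]],
    osc_mean = os[["mean"]], osc_sd = sd0(os), osc_median = os[["median"]])
}

#' Rate of acceleration sign changes
#'
#' Zeros neither count as flips nor reset the last seen sign, which makes
#' the measure robust to a sensor at rest.
#'
#' @param values Acceleration samples (any unit; the rate is
#'   scale-invariant).
#' @param duration Seconds (> 0).
#' @return Sign flips per second.
#' @export
sign_change_rate <- function(values, duration) {
  if (!is.numeric(duration) || duration <= 0) stop("duration must be > 0")
  s <- sign(values)
  s <- s[s != 0]
  if (length(s) < 2L) return(0)
  sum(diff(s) != 0) / duration
}

#' Fraction of time a signal magnitude exceeds a threshold
#'
#' Time-weighted at sample resolution: each sample owns the interval
#' between the midpoints to its neighbours (clipped to the series span).
#'
#' @param t Sample times (>= 2 samples, non-decreasing).
#' @param values Signal samples.
#' @param threshold Exceedance threshold applied to `abs(values)`.
#' @return Fraction in `[0, 1]`.
#' @export
exceedance_fraction <- function(t, values, threshold) {
  n <- length(t)
  if (n < 2L) stop("need >= 2 samples")
  mids <- (t[-1] + t[-n]) / 2
  lo <- c(t[1], mids)
  hi <- c(mids, t[n])
  span <- t[n] - t[1]
  if (span <= 0) return(0)
  sum((hi - lo)[abs(values) > threshold]) / span
}

#' Match stimulus onsets to response taps
#'
#' Greedy first-tap-in-window matching: each stimulus takes the earliest
#' unconsumed tap in `(onset, onset + window]`; a consumed tap cannot answer
#' a later stimulus.  Unmatched stimuli are reported as missed.
#'
#' @param onsets Stimulus onset times, sorted.
#' @param taps Tap times, sorted.
#' @param window Response window in seconds (>= 0).
#' @return Data frame with columns `onset`, `rt` (NA when missed) and
#'   `missed`.
#' @export
reaction_times <- function(onsets, taps, window) {
  if (window < 0) stop("window must be non-negative")
  rt <- rep(NA_real_, length(onsets))
  used <- rep(FALSE, length(taps))
  for (i in seq_along(onsets)) {
    ok <- which(!used & taps > onsets[i] & taps <= onsets[i] + window)
    if (length(ok)) {
      j <- ok[1]
      used[j] <- TRUE
      rt[i] <- taps[j] - onsets[i]
    }
  }
  data.frame(onset = onsets, rt = rt, missed = is.na(rt))
}
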