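#' Inter-tap intervals from raw tap timestamps
#'
#' Converts an ordered vector of tap timestamps (milliseconds, arbitrary
#' origin) into the series of inter-tap intervals (ITIs). The first tap
#' anchors the response: all downstream comparisons are between cumulative
#' ITI sums and cumulative reference inter-onset-interval (IOI) sums, so the
#' absolute origin of the timestamps never matters.
#'
#' @param tap_times_ms Numeric vector of at least two strictly increasing
#'   timestamps in milliseconds.
#' @return Numeric vector of `length(tap_times_ms) - 1` positive intervals.
#' @examples
#' tap_intervals(c(0, 504, 788))  # 504 284
#' @export
tap_intervals <- function(tap_times_ms) {
  if (length(tap_times_ms) < 2) {
    stop("at least two taps are required to form an interval", call. = FALSE)
  }
  if (anyNA(tap_times_ms)) {
    stop("tap timestamps contain missing values", call. = FALSE)
  }
  iti <- diff(tap_times_ms)
  if (any(iti <= 0)) {
    stop("tap timestamps must be strictly increasing", call. = FALSE)
  }
  iti
}

#' Cumulative event timeline from an interval series
#'
#' Builds the cumulative timeline implied by a series of intervals, anchored
#' at the (implicit) first event: entry `k` is the sum of the first `k`
#' intervals. Applied to a normative IOI series this yields the reference
#' onset times; applied to a response's ITIs it yields tap times re-anchored
#' at the first tap.
#'
#' @param intervals Numeric vector of positive durations (ms or relative).
#' @return Strictly increasing numeric vector of cumulative times.
#' @examples
#' cumulative_times(c(520, 260, 260))  # 520 780 1040
#' @export
cumulative_times <- function(intervals) {
  if (length(intervals) == 0) {
    stop("interval series is empty", call. = FALSE)
  }
  if (anyNA(intervals) || any(intervals <= 0)) {
    stop("all intervals must be positive and non-missing", call. = FALSE)
  }
  cumsum(intervals)
}

#' Rescale a cumulative timeline to the relative (0, 1] range
#'
#' Divides a cumulative timeline by its final entry so the last event sits
#' exactly at 1. This is the transform that makes rhythm scoring invariant
#' to the global tempo of the reproduction: a reproduction that is a perfect
#' copy played at any speed maps onto the same relative timeline as the
#' reference.
#'
#' @param cumulative Strictly increasing numeric vector with positive last
#'   entry (as returned by [cumulative_times()]).
#' @return Numeric vector in (0, 1]; the last entry is exactly 1.
#' @examples
#' relative_times(cumulative_times(c(520, 260, 260, 520, 260, 260, 520, 520, 520)))
#' @export
relative_times <- function(cumulative) {
  if (length(cumulative) == 0) {
    stop("cumulative timeline is empty", call. = FALSE)
  }
  if (anyNA(cumulative) || cumulative[length(cumulative)] <= 0 ||
      is.unsorted(cumulative, strictly = TRUE)) {
    stop("cumulative timeline must be strictly increasing with positive span",
         call. = FALSE)
  }
  cumulative / cumulative[length(cumulative)]
}

# Relative interval series: each interval divided by the total span.
# First entry equals the first relative event time, so
# cumulative_times(relative_intervals(x)) == relative_times(cumulative_times(x)).
relative_intervals <- function(intervals) {
  intervals / sum(intervals)
}
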