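#' Tempo reproduction accuracy: mean percent deviation from the beat
#'
#' For an isochronous item with inter-beat interval `ibi_ms` and `n` taps,
#' the reference timeline is `k * ibi_ms` for `k = 1 .. n - 1`, anchored at
#' the first tap. The metric is the mean over k of
#' `|cumulative ITI_k - k * ibi_ms| / ibi_ms`, expressed in percent:
#' the absolute millisecond deviation of each tap from its beat, as a ratio
#' of the beat interval. Lower is better; an exactly metronomic reproduction
#' scores 0.
#'
#' @param tap_times_ms Strictly increasing tap timestamps (ms); must have
#'   exactly the item's required tap count.
#' @param item One-row tempo item.
#' @return List with `mean_pct` and `per_interval_pct`.
#' @examples
#' it <- tempo_item("T01", ibi_ms = 500)
#' tempo_deviation_pct(cumsum(c(0, rep(505, 7))), it)$mean_pct  # 4
#' @export
tempo_deviation_pct <- function(tap_times_ms, item) {
  stopifnot(nrow(item) == 1, item$type == "tempo")
  if (length(tap_times_ms) != item$n_taps) {
    stop("tempo accuracy requires exactly ", item$n_taps,
         " taps; scoring an excluded response violates the pipeline contract",
         call. = FALSE)
  }
  cum_iti <- cumulative_times(tap_intervals(tap_times_ms))
  beats <- seq_along(cum_iti) * item$ibi_ms
  per <- abs(cum_iti - beats) / item$ibi_ms * 100
  list(mean_pct = mean(per), per_interval_pct = per)
}

#' Rhythm reproduction accuracy in the absolute (millisecond) stream
#'
#' Compares the cumulative tap timeline (anchored at the first tap) with the
#' cumulative reference onset timeline: deviation `d_k = |tap_k - onset_k|`
#' in milliseconds, divided by the IOI at position `k`, averaged over all
#' `n` intervals and expressed in percent. Whole-sequence (cumulative)
#' alignment is deliberate: an early error propagates into later taps unless
#' the participant re-synchronises, which is exactly what the metric should
#' capture.
#'
#' @param tap_times_ms Strictly increasing tap timestamps (ms), structurally
#'   correct for the item (callers gate on the verdict).
#' @param item One-row rhythm item.
#' @return List with `mean_pct` and `per_interval_pct` (length `n`).
#' @examples
#' it <- rhythm_item("R01", c(520, 260, 260, 520, 260, 260, 520, 520, 520), "moderate")
#' taps <- cumsum(c(0, 504, 284, 283, 546, 285, 276, 518, 552, 546))
#' round(absolute_rhythm_deviation_pct(taps, it)$mean_pct)  # 19
#' @export
absolute_rhythm_deviation_pct <- function(tap_times_ms, item) {
  stopifnot(nrow(item) == 1, item$type == "rhythm")
  ioi <- item$ioi_ms[[1]]
  if (length(tap_times_ms) != length(ioi) + 1L) {
    stop("tap count does not match the item; scoring an excluded response ",
         "violates the pipeline contract", call. = FALSE)
  }
  cum_tap <- cumulative_times(tap_intervals(tap_times_ms))
  cum_onset <- cumulative_times(ioi)
  per <- abs(cum_tap - cum_onset) / ioi * 100
  list(mean_pct = mean(per), per_interval_pct = per)
}

#' Rhythm reproduction accuracy in the relative (tempo-invariant) stream
#'
#' Both timelines are rescaled so their last event sits at 1 (the last tap
#' is the reference point for relative time), then compared as in the
#' absolute stream: `|relative tap_k - relative onset_k| / relative IOI_k`,
#' averaged over `k = 1 .. n - 1`. The final interval is excluded because
#' the last event defines the scaling and its deviation is identically
#' zero. A reproduction that is an exact copy at any global tempo scores 0.
#'
#' @inheritParams absolute_rhythm_deviation_pct
#' @return List with `mean_pct` and `per_interval_pct` (length `n - 1`).
#' @examples
#' it <- rhythm_item("R01", c(520, 260, 260, 520, 260, 260, 520, 520, 520), "moderate")
#' taps <- cumsum(c(0, 504, 284, 283, 546, 285, 276, 518, 552, 546))
#' round(relative_rhythm_deviation_pct(taps, it)$mean_pct)  # 4
#' @export
relative_rhythm_deviation_pct <- function(tap_times_ms, item) {
  stopifnot(nrow(item) == 1, item$type == "rhythm")
  ioi <- item$ioi_ms[[1]]
  if (length(tap_times_ms) != length(ioi) + 1L) {
    stop("tap count does not match the item; scoring an excluded response ",
         "violates the pipeline contract", call. = FALSE)
  }
  n <- length(ioi)
  if (n < 2) {
    stop("relative accuracy needs at least two intervals: the final one ",
         "only sets the time scale", call. = FALSE)
  }
  rel_tap <- relative_times(cumulative_times(tap_intervals(tap_times_ms)))
  rel_onset <- relative_times(cumulative_times(ioi))
  rel_ioi <- relative_intervals(ioi)
  keep <- seq_len(n - 1)
  per <- abs(rel_tap[keep] - rel_onset[keep]) / rel_ioi[keep] * 100
  list(mean_pct = mean(per), per_interval_pct = per)
}

#' Synchrony orientation helper
#'
#' The scoring pipeline reports deviation (lower = better). Validity
#' analyses often want the opposite orientation — synchrony as inverted
#' asynchrony — so that larger values mean better timing and correlations
#' with ability measures carry their natural sign.
#'
#' @param deviation_pct Numeric vector of percent deviations.
#' @return The negated deviations.
#' @export
as_synchrony <- function(deviation_pct) {
  -deviation_pct
}
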