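# Shared fixtures: the published worked example (a 520/260 ms reference
# rhythm with three fictitious reproductions) and small builders.

ref_ioi <- c(520, 260, 260, 520, 260, 260, 520, 520, 520)
ref_item <- rhythm_item("REF", ref_ioi, "moderate")

iti_correct <- c(504, 284, 283, 546, 285, 276, 518, 552, 546)
# 8 ITIs, a 518 produced at an intended-260 position, then an extra 526:
iti_structural <- c(504, 284, 283, 546, 285, 518, 552, 546, 526)
# a 708 at an intended-520 position, otherwise like the correct row:
iti_outlier <- c(504, 284, 283, 708, 285, 276, 518, 552, 546)

taps_from_itis <- function(itis, origin = 0) origin + cumsum(c(0, itis))

# Long-format tap log from a named list of ITI vectors (one response each),
# all for the same item/session.
tap_log_from_itis <- function(iti_list, item_id, session = 1L) {
  purrr::imap_dfr(iti_list, function(itis, pid) {
    t <- taps_from_itis(itis)
    tibble::tibble(participant_id = pid, session = session,
                   item_id = item_id, tap_index = seq_along(t), time_ms = t)
  })
}

# Cohort of n jittered-but-correct reproductions of ref_item, deterministic
# under the given seed; jitter small enough never to cross a note-value
# midpoint.
correct_cohort_itis <- function(n, seed, jitter = 10) {
  set.seed(seed)
  stats::setNames(
    lapply(seq_len(n), function(i) ref_ioi + stats::runif(9, -jitter, jitter)),
    sprintf("P%02d", seq_len(n)))
}
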