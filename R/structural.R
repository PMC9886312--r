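#' Nearest-note-value classification of produced intervals
#'
#' Each produced interval is assigned to the nearest value in the item's
#' note-value alphabet. An interval whose assigned value differs from the
#' intended value at that position is a structural deviation: the tap
#' sequence realises a different note-value pattern than the reference
#' (e.g. a produced 518 ms at a position whose intended value is 260 ms is
#' nearer to the 520 ms alphabet entry, so the note value has been altered).
#' A produced interval exactly midway between two alphabet values is assigned
#' the intended value, so exactly ambiguous productions are not penalised
#' (`tie = "intended"`); `tie = "nearest_low"` resolves midpoints to the
#' smaller alphabet value instead.
#'
#' @param produced Numeric vector of produced intervals (ms or relative).
#' @param intended Numeric vector of intended normative values, same length.
#' @param alphabet Numeric vector of distinct normative note values; must
#'   contain every intended value.
#' @param tie Midpoint tie rule, `"intended"` (default) or `"nearest_low"`.
#' @return Tibble with columns `position`, `produced`, `intended`,
#'   `assigned`, `is_deviation`.
#' @examples
#' classify_intervals(c(284, 518), c(260, 260), c(260, 520))
#' @export
classify_intervals <- function(produced, intended, alphabet,
                               tie = c("intended", "nearest_low")) {
  tie <- match.arg(tie)
  stopifnot(length(produced) == length(intended), length(alphabet) > 0)
  alphabet <- sort(unique(as.numeric(alphabet)))
  if (!all(intended %in% alphabet)) {
    stop("every intended value must belong to the alphabet", call. = FALSE)
  }
  produced <- as.numeric(produced)
  intended <- as.numeric(intended)
  d <- abs(outer(produced, alphabet, "-"))
  # ties.method = "first" on the ascending alphabet resolves a residual tie
  # to the smaller note value
  jmin <- max.col(-d, ties.method = "first")
  assigned <- alphabet[jmin]
  dmin <- d[cbind(seq_along(produced), jmin)]
  if (tie == "intended") {
    # whenever the intended value attains the minimal distance (including
    # exact midpoints), keep it
    keep <- abs(produced - intended) == dmin
    assigned[keep] <- intended[keep]
  }
  tibble::new_tibble(list(
    position = seq_along(produced),
    produced = produced,
    intended = intended,
    assigned = assigned,
    is_deviation = assigned != intended
  ), nrow = length(produced))
}

#' Tap-count check against an item's expected count
#'
#' @param n_taps Number of taps in the response.
#' @param item One-row item tibble (see [rhythm_item()]).
#' @return Logical: does the response have exactly the expected tap count?
#' @export
check_tap_count <- function(n_taps, item) {
  stopifnot(nrow(item) == 1)
  n_taps == item$n_taps
}

#' Structural verdict for one rhythm reproduction
#'
#' Decides whether a reproduction is structurally correct in the requested
#' interval stream. A wrong tap count short-circuits (omitted or inserted
#' taps cannot be aligned, so per-interval classification is not attempted).
#' Otherwise every produced interval is classified against the note-value
#' alphabet: in the absolute stream, raw ITIs against the millisecond
#' alphabet; in the relative stream, span-normalised ITIs against the
#' span-normalised alphabet, which makes the verdict invariant to the global
#' tempo of the reproduction. Any deviation yields `structural_error`.
#'
#' @param tap_times_ms Strictly increasing tap timestamps (ms).
#' @param item One-row rhythm item.
#' @param stream `"absolute"` or `"relative"`.
#' @param tie Midpoint tie rule passed to [classify_intervals()].
#' @return List with `status` (`"correct"`, `"wrong_tap_count"` or
#'   `"structural_error"`), `stream`, `n_deviations` and `classification`
#'   (tibble; `NULL` when the tap count is wrong).
#' @examples
#' item <- rhythm_item("R01", c(520, 260, 260, 520, 260, 260, 520, 520, 520), "moderate")
#' taps <- cumsum(c(0, 504, 284, 283, 546, 285, 276, 518, 552, 546))
#' check_structure(taps, item)$status  # "correct"
#' @export
check_structure <- function(tap_times_ms, item,
                            stream = c("absolute", "relative"),
                            tie = "intended") {
  stream <- match.arg(stream)
  stopifnot(nrow(item) == 1, item$type == "rhythm")
  ioi <- item$ioi_ms[[1]]
  if (length(tap_times_ms) != length(ioi) + 1L) {
    return(list(status = "wrong_tap_count", stream = stream,
                n_deviations = NA_integer_, classification = NULL))
  }
  iti <- tap_intervals(tap_times_ms)
  if (stream == "relative") {
    produced <- relative_intervals(iti)
    intended <- relative_intervals(ioi)
    alphabet <- note_values(intended)
  } else {
    produced <- iti
    intended <- ioi
    alphabet <- note_values(ioi)
  }
  cls <- classify_intervals(produced, intended, alphabet, tie = tie)
  n_dev <- sum(cls$is_deviation)
  list(
    status = if (n_dev > 0) "structural_error" else "correct",
    stream = stream, n_deviations = n_dev,
    classification = cls
  )
}

#' Structural classification of a whole tap log
#'
#' Runs the structural check on every response in a long-format tap log.
#' Rhythm responses are checked independently in the absolute and relative
#' streams; tempo responses are checked for tap count only (their structure
#' is the isochronous pulse, reported in both streams for a uniform schema).
#' Responses with invalid timestamps (non-monotone, missing) are not dropped
#' silently: they appear with status `"invalid"` and are excluded downstream.
#'
#' @param taps Tap log tibble with columns `participant_id`, `session`,
#'   `item_id`, `time_ms` (ordered within response; a `tap_index` column is
#'   used for ordering when present).
#' @param items Item bank tibble.
#' @param tie Midpoint tie rule, see [classify_intervals()].
#' @return Tibble with one row per response x stream: `participant_id`,
#'   `session`, `item_id`, `type`, `stream`, `status`, `n_deviations`,
#'   `taps` (list of timestamps), `classification` (list-column).
#' @export
classify_structure <- function(taps, items, tie = "intended") {
  validate_item_bank(items)
  responses <- collect_responses(taps, items)
  n <- nrow(responses)
  item_idx <- match(responses$item_id, items$item_id)
  type <- items$type[item_idx]
  status <- matrix("", n, 2)       # columns: absolute, relative
  n_dev <- matrix(NA_integer_, n, 2)
  cls <- vector("list", 2 * n)

  for (i in seq_len(n)) {
    t <- responses$tap_times[[i]]
    if (!responses$valid[i]) {
      status[i, ] <- "invalid"
      next
    }
    item <- items[item_idx[i], ]
    if (type[i] == "tempo") {
      status[i, ] <- if (check_tap_count(length(t), item)) "correct"
                     else "wrong_tap_count"
      n_dev[i, ] <- 0L
      next
    }
    for (s in 1:2) {
      v <- check_structure(t, item, c("absolute", "relative")[s], tie = tie)
      status[i, s] <- v$status
      n_dev[i, s] <- v$n_deviations
      cls[2 * (i - 1) + s] <- list(v$classification)  # NULL-safe assignment
    }
  }

  idx <- rep(seq_len(n), each = 2)
  tibble::tibble(
    participant_id = responses$participant_id[idx],
    session = responses$session[idx],
    item_id = responses$item_id[idx],
    type = type[idx],
    stream = rep(c("absolute", "relative"), n),
    status = as.vector(t(status)),
    n_deviations = as.vector(t(n_dev)),
    taps = responses$tap_times[idx],
    classification = cls
  )
}

# Nest a long tap log into one row per response, validating timestamps.
# Unknown item_ids are an error (a mistyped bank is not a per-response issue).
collect_responses <- function(taps, items) {
  required <- c("participant_id", "session", "item_id", "time_ms")
  missing_cols <- setdiff(required, names(taps))
  if (length(missing_cols) > 0) {
    stop("tap log is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  unknown <- setdiff(unique(taps$item_id), items$item_id)
  if (length(unknown) > 0) {
    stop("tap log references unknown items: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if ("tap_index" %in% names(taps)) {
    taps <- dplyr::arrange(taps, .data$participant_id, .data$session,
                           .data$item_id, .data$tap_index)
  }
  taps |>
    dplyr::group_by(.data$participant_id, .data$session, .data$item_id) |>
    dplyr::summarise(tap_times = list(.data$time_ms), .groups = "drop") |>
    dplyr::mutate(
      valid = purrr::map_lgl(.data$tap_times, function(t) {
        length(t) >= 2 && !anyNA(t) && !is.unsorted(t, strictly = TRUE)
      }),
      reason = ifelse(.data$valid, NA_character_, "invalid_timestamps")
    )
}
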