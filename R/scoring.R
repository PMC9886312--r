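#' Per-item scores from classified, outlier-filtered responses
#'
#' Computes the temporal-accuracy metrics for every response whose stream
#' status is `correct`: tempo percent deviation for tempo items, absolute
#' and relative rhythm percent deviation for rhythm items. Responses
#' excluded upstream (wrong tap count, structural error, cohort outlier,
#' invalid timestamps) carry their status and missing metrics.
#'
#' @param classified Classification tibble, as returned by
#'   [classify_structure()] and updated by [flag_outliers()].
#' @param items Item bank tibble.
#' @return Tibble with one row per response: `participant_id`, `session`,
#'   `item_id`, `type`, `difficulty`, `status_abs`, `status_rel`,
#'   `tempo_dev_pct`, `abs_dev_pct`, `rel_dev_pct`, plus list-columns
#'   `abs_per_interval_pct`, `rel_per_interval_pct`.
#' @export
score_items <- function(classified, items) {
  validate_item_bank(items)
  wide <- classified |>
    dplyr::select("participant_id", "session", "item_id", "type",
                  "stream", "status", "taps") |>
    tidyr::pivot_wider(names_from = "stream",
                       values_from = c("status", "taps")) |>
    dplyr::rename(status_abs = "status_absolute",
                  status_rel = "status_relative",
                  taps = "taps_absolute") |>
    dplyr::select(-"taps_relative") |>
    dplyr::left_join(dplyr::select(items, "item_id", "difficulty"),
                     by = "item_id")

  scored <- purrr::pmap(wide, function(participant_id, session, item_id, type,
                                       status_abs, status_rel, taps,
                                       difficulty) {
    item <- items[items$item_id == item_id, ]
    out <- list(tempo_dev_pct = NA_real_, abs_dev_pct = NA_real_,
                rel_dev_pct = NA_real_, abs_per = NULL, rel_per = NULL)
    if (type == "tempo") {
      if (status_abs == "correct") {
        out$tempo_dev_pct <- tempo_deviation_pct(taps, item)$mean_pct
      }
    } else {
      if (status_abs == "correct") {
        r <- absolute_rhythm_deviation_pct(taps, item)
        out$abs_dev_pct <- r$mean_pct
        out$abs_per <- r$per_interval_pct
      }
      if (status_rel == "correct") {
        r <- relative_rhythm_deviation_pct(taps, item)
        out$rel_dev_pct <- r$mean_pct
        out$rel_per <- r$per_interval_pct
      }
    }
    out
  })

  wide |>
    dplyr::mutate(
      tempo_dev_pct = purrr::map_dbl(scored, "tempo_dev_pct"),
      abs_dev_pct = purrr::map_dbl(scored, "abs_dev_pct"),
      rel_dev_pct = purrr::map_dbl(scored, "rel_dev_pct"),
      abs_per_interval_pct = purrr::map(scored, "abs_per"),
      rel_per_interval_pct = purrr::map(scored, "rel_per")
    ) |>
    dplyr::select(-"taps") |>
    dplyr::relocate("difficulty", .after = "type")
}

#' Aggregate item scores to the participant level
#'
#' Means are taken over surviving items only: an item excluded for a
#' participant (wrong tap count, structural error, outlier) does not enter
#' that participant's denominator. `n_correct_rhythms` counts rhythm items
#' whose verdict is `correct` in the chosen stream (absolute by default;
#' the relative stream credits structurally faithful reproductions played
#' at a different tempo).
#'
#' @param item_scores Output of [score_items()].
#' @param correct_stream Stream defining "correctly reproduced":
#'   `"absolute"` (default) or `"relative"`.
#' @return Tibble with one row per participant x session: deviation means
#'   (`NA` when no item survives), `n_correct_rhythms`, counts of items
#'   administered and excluded per category.
#' @export
aggregate_participants <- function(item_scores,
                                   correct_stream = c("absolute", "relative")) {
  correct_stream <- match.arg(correct_stream)
  dup <- item_scores |>
    dplyr::count(.data$participant_id, .data$session, .data$item_id) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    stop("duplicate (participant, session, item) rows in item scores",
         call. = FALSE)
  }
  status_col <- if (correct_stream == "absolute") "status_abs" else "status_rel"
  item_scores |>
    dplyr::group_by(.data$participant_id, .data$session) |>
    dplyr::summarise(
      tempo_dev_pct = mean_or_na(.data$tempo_dev_pct[.data$type == "tempo"]),
      abs_rhythm_dev_pct = mean_or_na(.data$abs_dev_pct[.data$type == "rhythm"]),
      rel_rhythm_dev_pct = mean_or_na(.data$rel_dev_pct[.data$type == "rhythm"]),
      n_correct_rhythms = sum(.data$type == "rhythm" &
                                .data[[status_col]] == "correct"),
      n_rhythm_items = sum(.data$type == "rhythm"),
      n_tempo_items = sum(.data$type == "tempo"),
      n_excluded_rhythm_abs = sum(.data$type == "rhythm" &
                                    .data$status_abs != "correct"),
      n_excluded_rhythm_rel = sum(.data$type == "rhythm" &
                                    .data$status_rel != "correct"),
      n_excluded_tempo = sum(.data$type == "tempo" &
                               .data$status_abs != "correct"),
      .groups = "drop"
    )
}

mean_or_na <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) NA_real_ else mean(x)
}

#' Participant-level exclusion rules
#'
#' Excludes participants whose mean tempo deviation lies more than
#' `z_threshold` sample standard deviations from the cohort mean, and
#' participants who reproduced no rhythm correctly (their rhythm synchrony
#' is undefined). With fewer than three participants z-scoring is not
#' meaningful: a warning is issued and no z-exclusions are made.
#'
#' @param participants Output of [aggregate_participants()].
#' @param z_threshold Absolute z-score cutoff (default 3).
#' @param apply_to Metrics z-screened for outliers; the default screens the
#'   tempo mean only.
#' @return Tibble of excluded rows with a `reason` column
#'   (`"tempo_z_outlier"` or `"no_correct_rhythms"`).
#' @export
flag_participant_outliers <- function(participants, z_threshold = 3,
                                      apply_to = "tempo_dev_pct") {
  zed <- list()
  if (nrow(participants) < 3) {
    warning("fewer than 3 participants: z-score screening skipped",
            call. = FALSE)
  } else {
    for (metric in apply_to) {
      v <- participants[[metric]]
      z <- (v - mean(v, na.rm = TRUE)) / stats::sd(v, na.rm = TRUE)
      hit <- which(!is.na(z) & abs(z) > z_threshold)
      if (length(hit)) {
        zed[[metric]] <- dplyr::mutate(
          participants[hit, ],
          reason = paste0(sub("_dev_pct$", "", metric), "_z_outlier"))
      }
    }
  }
  none <- dplyr::filter(participants, .data$n_correct_rhythms == 0,
                        .data$n_rhythm_items > 0) |>
    dplyr::mutate(reason = "no_correct_rhythms")
  dplyr::bind_rows(c(zed, list(none))) |>
    dplyr::distinct(.data$participant_id, .data$session, .keep_all = TRUE)
}

#' Score perception responses with the confidence-weighted rule
#'
#' A same/different perception item earns 1 point for a correct answer
#' given with full confidence ("definitely"), 0.5 point for a correct
#' answer given with lesser confidence ("probably"), and 0 points for a
#' wrong or skipped ("I don't know") answer.
#'
#' @param responses Tibble with columns `truth` (`"same"`/`"different"`),
#'   `answer` (`"same"`/`"different"`/`"dont_know"`) and `confidence`
#'   (`"definitely"`/`"probably"`/`"none"`). `confidence == "none"` must
#'   coincide with `answer == "dont_know"`.
#' @return The input with a `points` column appended.
#' @examples
#' score_perception(tibble::tibble(
#'   truth = "different", answer = "different", confidence = "probably"
#' ))$points  # 0.5
#' @export
score_perception <- function(responses) {
  ok_truth <- responses$truth %in% c("same", "different")
  ok_answer <- responses$answer %in% c("same", "different", "dont_know")
  ok_conf <- responses$confidence %in% c("definitely", "probably", "none")
  if (!all(ok_truth & ok_answer & ok_conf)) {
    stop("malformed perception response: truth must be same/different, ",
         "answer same/different/dont_know, confidence definitely/probably/none",
         call. = FALSE)
  }
  mismatch <- (responses$confidence == "none") != (responses$answer == "dont_know")
  if (any(mismatch)) {
    stop("confidence 'none' must coincide with answer 'dont_know'",
         call. = FALSE)
  }
  dplyr::mutate(responses, points = dplyr::case_when(
    .data$answer == "dont_know" ~ 0,
    .data$answer != .data$truth ~ 0,
    .data$confidence == "definitely" ~ 1,
    .data$confidence == "probably" ~ 0.5
  ))
}
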