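#' Score a full tapping dataset
#'
#' The end-to-end pipeline: structural classification of every response in
#' both interval streams, cohort-level Tukey-fence outlier rejection,
#' per-item temporal-accuracy metrics, participant-level aggregation, and
#' the participant exclusion rules. Each stage only sees responses that
#' survived the previous one.
#'
#' @param taps Long tap-log tibble (`participant_id`, `session`, `item_id`,
#'   `tap_index`, `time_ms`).
#' @param items Item bank tibble (see [rhythm_item()], [read_item_bank()]).
#' @param k Outlier fence multiplier (default 3).
#' @param quartile_method `"linear"` or `"hinges"`, see [tukey_fences()].
#' @param min_cohort_n Minimum pooled sample size for fence estimation.
#' @param correct_stream Stream defining "correctly reproduced rhythms" in
#'   the participant aggregates (default `"absolute"`).
#' @param tie Midpoint tie rule for note-value classification.
#' @param outlier_filter Set `FALSE` to skip the cohort outlier stage
#'   (single-response scoring; the fence definition is inherently
#'   cohort-based).
#' @param z_threshold Participant-level z cutoff on the tempo mean.
#' @return Object of class `tap_scores`: list with tibbles `items`
#'   (per-response scores), `participants`, `fences`, `response_exclusions`
#'   (one row per excluded response x stream with a machine-readable
#'   reason), `participant_exclusions`, and the `config` used.
#' @examples
#' sim <- simulate_cohort(sim_config(seed = 1, n_participants = 8))
#' scores <- score_tapping(sim$taps, sim$items)
#' glance(scores)
#' @export
score_tapping <- function(taps, items, k = 3,
                          quartile_method = c("linear", "hinges"),
                          min_cohort_n = 4,
                          correct_stream = c("absolute", "relative"),
                          tie = "intended", outlier_filter = TRUE,
                          z_threshold = 3) {
  quartile_method <- match.arg(quartile_method)
  correct_stream <- match.arg(correct_stream)
  classified <- classify_structure(taps, items, tie = tie)
  if (outlier_filter) {
    filt <- flag_outliers(classified, items, k = k,
                          method = quartile_method, min_n = min_cohort_n)
    classified <- filt$classified
    fences <- filt$fences
  } else {
    fences <- NULL
  }
  item_scores <- score_items(classified, items)
  participants <- aggregate_participants(item_scores,
                                         correct_stream = correct_stream)
  part_excl <- flag_participant_outliers(participants,
                                         z_threshold = z_threshold)
  resp_excl <- classified |>
    dplyr::filter(.data$status != "correct") |>
    dplyr::transmute(.data$participant_id, .data$session, .data$item_id,
                     .data$stream, reason = .data$status)
  structure(
    list(items = item_scores, participants = participants, fences = fences,
         response_exclusions = resp_excl,
         participant_exclusions = part_excl,
         config = list(k = k, quartile_method = quartile_method,
                       min_cohort_n = min_cohort_n,
                       correct_stream = correct_stream, tie = tie,
                       outlier_filter = outlier_filter,
                       z_threshold = z_threshold)),
    class = "tap_scores")
}

#' Read and write tap logs
#'
#' The tap log is a long-format CSV with a mandatory header and columns
#' `participant_id`, `session`, `item_id`, `tap_index`, `time_ms`
#' (UTF-8, comma-separated, `.` decimal; timestamps in milliseconds with
#' arbitrary per-response origin).
#'
#' @param path CSV file path.
#' @param taps Tap-log tibble.
#' @return `read_tap_log()` returns the tap-log tibble; writers return
#'   `path` invisibly.
#' @export
read_tap_log <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    participant_id = readr::col_character(),
    session = readr::col_integer(),
    item_id = readr::col_character(),
    tap_index = readr::col_integer(),
    time_ms = readr::col_double()
  ))
}

#' @rdname read_tap_log
#' @export
write_tap_log <- function(taps, path) {
  write_atomic_csv(taps, path)
}

#' Write all pipeline outputs to a directory
#'
#' Emits `items.csv`, `participants.csv`, `fences.csv`,
#' `response_exclusions.csv`, `participant_exclusions.csv` and
#' `run_metadata.json` (config, package version, timestamp-free so runs are
#' byte-reproducible). Every file is written atomically (temp file in the
#' target directory, then rename), so a failed run never leaves partial
#' outputs behind.
#'
#' @param scores A `tap_scores` object from [score_tapping()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_scores <- function(scores, dir) {
  stopifnot(inherits(scores, "tap_scores"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  flat_items <- dplyr::select(scores$items, -dplyr::any_of(
    c("abs_per_interval_pct", "rel_per_interval_pct", "classification")))
  write_atomic_csv(flat_items, file.path(dir, "items.csv"))
  write_atomic_csv(scores$participants, file.path(dir, "participants.csv"))
  if (!is.null(scores$fences)) {
    write_atomic_csv(scores$fences, file.path(dir, "fences.csv"))
  }
  write_atomic_csv(scores$response_exclusions,
                   file.path(dir, "response_exclusions.csv"))
  write_atomic_csv(
    dplyr::select(scores$participant_exclusions,
                  dplyr::any_of(c("participant_id", "session", "reason"))),
    file.path(dir, "participant_exclusions.csv"))
  meta <- c(scores$config,
            list(package = "tapscore",
                 version = as.character(utils::packageVersion("tapscore"))))
  tmp <- tempfile(tmpdir = dir, fileext = ".json")
  jsonlite::write_json(meta, tmp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  file.rename(tmp, file.path(dir, "run_metadata.json"))
  invisible(dir)
}

write_atomic_csv <- function(df, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".csv")
  readr::write_csv(df, tmp)
  file.rename(tmp, path)
  invisible(path)
}
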