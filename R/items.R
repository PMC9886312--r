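#' Construct rhythm and tempo items
#'
#' An item bank is a tibble with one row per stimulus. Rhythm items carry a
#' normative IOI (inter-onset-interval) series as a list-column and a
#' difficulty label; tempo items carry a constant IBI (inter-beat interval)
#' and the required tap count. A rhythm item with `n` IOIs expects `n + 1`
#' taps; a tempo item expects `n_taps` taps (eight in the standard design).
#'
#' @param item_id Character scalar identifying the item.
#' @param ioi_ms Numeric vector of positive normative IOIs in milliseconds.
#' @param difficulty One of `"easy"`, `"moderate"`, `"complex"` (rhythm only).
#' @param ibi_ms Positive inter-beat interval in milliseconds (tempo only).
#' @param n_taps Required tap count for the tempo item (default 8).
#' @return A one-row item tibble; bind rows of these to form an item bank.
#' @examples
#' bank <- dplyr::bind_rows(
#'   rhythm_item("R01", c(520, 260, 260, 520, 260, 260, 520, 520, 520), "moderate"),
#'   tempo_item("T01", ibi_ms = 500)
#' )
#' @export
rhythm_item <- function(item_id, ioi_ms,
                        difficulty = c("easy", "moderate", "complex")) {
  difficulty <- match.arg(difficulty)
  stopifnot(is.character(item_id), length(item_id) == 1)
  if (length(ioi_ms) == 0 || anyNA(ioi_ms) || any(ioi_ms <= 0)) {
    stop("ioi_ms must be a non-empty vector of positive durations", call. = FALSE)
  }
  expected_taps <- length(ioi_ms) + 1L
  tibble::tibble(
    item_id = item_id, type = "rhythm", difficulty = difficulty,
    ioi_ms = list(as.numeric(ioi_ms)), ibi_ms = NA_real_,
    n_taps = expected_taps
  )
}

#' @rdname rhythm_item
#' @export
tempo_item <- function(item_id, ibi_ms, n_taps = 8L) {
  stopifnot(is.character(item_id), length(item_id) == 1)
  if (!is.numeric(ibi_ms) || length(ibi_ms) != 1 || is.na(ibi_ms) || ibi_ms <= 0) {
    stop("ibi_ms must be a single positive duration", call. = FALSE)
  }
  if (n_taps < 2) stop("a tempo item requires at least two taps", call. = FALSE)
  tibble::tibble(
    item_id = item_id, type = "tempo", difficulty = NA_character_,
    ioi_ms = list(NULL), ibi_ms = as.numeric(ibi_ms), n_taps = as.integer(n_taps)
  )
}

#' Distinct note values of a rhythm item
#'
#' The note-value alphabet is the set of distinct durations occurring in the
#' item's IOI series; interval classification assigns each produced interval
#' to its nearest alphabet value.
#'
#' @param ioi_ms Numeric vector of IOIs.
#' @return Sorted numeric vector of unique durations.
#' @export
note_values <- function(ioi_ms) {
  sort(unique(as.numeric(ioi_ms)))
}

validate_item_bank <- function(items) {
  required <- c("item_id", "type", "difficulty", "ioi_ms", "ibi_ms", "n_taps")
  missing_cols <- setdiff(required, names(items))
  if (length(missing_cols) > 0) {
    stop("item bank is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(items$item_id)) {
    stop("duplicate item_id in item bank", call. = FALSE)
  }
  if (!all(items$type %in% c("rhythm", "tempo"))) {
    stop("item type must be 'rhythm' or 'tempo'", call. = FALSE)
  }
  invisible(items)
}

#' Read and write an item bank as JSON
#'
#' One JSON record per item: `{item_id, type, difficulty, ioi_ms}` for rhythm
#' items, `{item_id, type, ibi_ms, n_taps}` for tempo items.
#'
#' @param path File path.
#' @param items Item bank tibble.
#' @return `read_item_bank()` returns the item bank tibble;
#'   `write_item_bank()` returns `path` invisibly.
#' @export
read_item_bank <- function(path) {
  recs <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  items <- purrr::map_dfr(recs, function(r) {
    if (identical(r$type, "rhythm")) {
      rhythm_item(r$item_id, unlist(r$ioi_ms), r$difficulty)
    } else if (identical(r$type, "tempo")) {
      tempo_item(r$item_id, r$ibi_ms, r$n_taps %||% 8L)
    } else {
      stop("unknown item type in ", path, ": ", r$type, call. = FALSE)
    }
  })
  validate_item_bank(items)
}

#' @rdname read_item_bank
#' @export
write_item_bank <- function(items, path) {
  validate_item_bank(items)
  recs <- purrr::pmap(items, function(item_id, type, difficulty, ioi_ms,
                                      ibi_ms, n_taps) {
    if (type == "rhythm") {
      list(item_id = item_id, type = type, difficulty = difficulty,
           ioi_ms = as.numeric(ioi_ms))
    } else {
      list(item_id = item_id, type = type, ibi_ms = ibi_ms,
           n_taps = as.integer(n_taps))
    }
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
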