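#' Tukey fences on an interval distribution
#'
#' Computes first and third quartiles and the outlier fences
#' `Q1 - k * IQR` and `Q3 + k * IQR`. With the default `k = 3` these are the
#' "far out" fences used to reject grossly deviant inter-tap intervals at
#' the cohort level. Values strictly outside the fences are outliers; values
#' exactly on a fence are retained ("at least k x IQR beyond the quartile").
#'
#' @param x Numeric vector of interval values.
#' @param k Fence multiplier (default 3).
#' @param method Quartile estimator: `"linear"` (interpolated order
#'   statistics, `stats::quantile` type 7, the default) or `"hinges"`
#'   (Tukey's hinges via `stats::fivenum`).
#' @param min_n Minimum sample size for fence estimation (default 4).
#' @return One-row tibble: `q1`, `q3`, `iqr`, `lower`, `upper`, `n`.
#' @examples
#' tukey_fences(c(1, 2, 3, 4, 100))  # upper fence 10: 100 is an outlier
#' @export
tukey_fences <- function(x, k = 3, method = c("linear", "hinges"), min_n = 4) {
  method <- match.arg(method)
  x <- x[!is.na(x)]
  if (length(x) < min_n) {
    stop("insufficient cohort: need at least ", min_n,
         " values for fence estimation, got ", length(x), call. = FALSE)
  }
  if (k < 0) stop("fence multiplier k must be non-negative", call. = FALSE)
  if (method == "linear") {
    q <- stats::quantile(x, c(0.25, 0.75), names = FALSE, type = 7)
  } else {
    f <- stats::fivenum(x)
    q <- f[c(2, 4)]
  }
  iqr <- q[2] - q[1]
  tibble::tibble(q1 = q[1], q3 = q[2], iqr = iqr,
                 lower = q[1] - k * iqr, upper = q[2] + k * iqr,
                 n = length(x))
}

outside_fences <- function(x, fences) {
  x < fences$lower | x > fences$upper
}

#' Cohort-level outlier rejection of tapping responses
#'
#' Flags whole responses whose interval series contains at least one
#' grossly deviant inter-tap interval, using Tukey fences at `k` x IQR on
#' cohort-pooled distributions. A single outlying interval invalidates the
#' whole item for that participant; there is no partial salvage.
#'
#' For a tempo item every ITI of every correct-count response to that item
#' is pooled into one distribution. For a rhythm item the procedure runs
#' only over responses already classified structurally correct in the given
#' stream, and separately per intended note value: all intervals intended
#' as, say, 520 ms (across positions and participants) form one
#' distribution, all 260 ms intervals another, each with its own fences.
#'
#' @param classified Output of [classify_structure()], or for
#'   `flag_tempo_outliers()` / `flag_rhythm_outliers()` the rows of a single
#'   item (one stream for rhythm).
#' @param items Item bank tibble.
#' @param k Fence multiplier (default 3).
#' @param method Quartile estimator, see [tukey_fences()].
#' @param min_n Minimum pooled sample size; below it the outlier stage is
#'   skipped for that group with a warning (cohort too small to estimate
#'   fences).
#' @return `flag_outliers()` returns a list with `classified` (statuses
#'   updated to `"outlier"` where flagged) and `fences` (one row per
#'   item/stream/note-value group: `item_id`, `stream`, `group_value`,
#'   `q1`, `q3`, `lower`, `upper`, `n`, `n_flagged`).
#' @export
flag_outliers <- function(classified, items, k = 3,
                          method = c("linear", "hinges"), min_n = 4) {
  method <- match.arg(method)
  validate_item_bank(items)
  fence_rows <- list()
  flagged_idx <- logical(nrow(classified))

  for (iid in unique(classified$item_id)) {
    item <- items[items$item_id == iid, ]
    if (item$type == "tempo") {
      idx <- which(classified$item_id == iid &
                   classified$stream == "absolute" &
                   classified$status == "correct")
      if (length(idx) == 0) next
      res <- flag_interval_group(classified$taps[idx], k, method, min_n)
      if (is.null(res)) next
      flagged <- idx[res$flagged]
      fence_rows[[length(fence_rows) + 1]] <- dplyr::mutate(
        res$fences, item_id = iid, stream = "absolute",
        group_value = NA_real_, n_flagged = length(flagged),
        .before = 1)
      flagged_idx[flagged] <- TRUE
      # mirror status onto the relative rows of the same responses
      rel <- match_rows(classified, classified[flagged, ], "relative")
      flagged_idx[rel] <- TRUE
    } else {
      for (s in c("absolute", "relative")) {
        idx <- which(classified$item_id == iid & classified$stream == s &
                     classified$status == "correct")
        if (length(idx) == 0) next
        ioi <- item$ioi_ms[[1]]
        intended <- if (s == "relative") relative_intervals(ioi) else ioi
        itis <- lapply(classified$taps[idx], function(t) {
          iti <- tap_intervals(t)
          if (s == "relative") relative_intervals(iti) else iti
        })
        for (g in note_values(intended)) {
          pos <- which(intended == g)
          pooled <- unlist(lapply(itis, `[`, pos))
          if (length(pooled) < min_n) {
            warning("cohort too small for outlier fences: item ", iid,
                    ", stream ", s, ", note value ", signif(g, 4),
                    " (n = ", length(pooled), "); stage skipped", call. = FALSE)
            next
          }
          fences <- tukey_fences(pooled, k = k, method = method, min_n = min_n)
          out <- vapply(itis, function(v) any(outside_fences(v[pos], fences)),
                        logical(1))
          fence_rows[[length(fence_rows) + 1]] <- dplyr::mutate(
            fences, item_id = iid, stream = s, group_value = g,
            n_flagged = sum(out), .before = 1)
          flagged_idx[idx[out]] <- TRUE
        }
      }
    }
  }

  classified$status[flagged_idx] <- "outlier"
  fences <- if (length(fence_rows)) dplyr::bind_rows(fence_rows)
            else tibble::tibble(item_id = character(), stream = character(),
                                group_value = numeric(), q1 = numeric(),
                                q3 = numeric(), iqr = numeric(),
                                lower = numeric(), upper = numeric(),
                                n = integer(), n_flagged = integer())
  list(classified = classified, fences = fences)
}

# Pool all ITIs of a set of responses, fence them, flag responses containing
# any interval outside the fences. Returns NULL when the pool is too small.
flag_interval_group <- function(tap_list, k, method, min_n) {
  itis <- lapply(tap_list, tap_intervals)
  pooled <- unlist(itis)
  if (length(pooled) < min_n) {
    warning("cohort too small for outlier fences (n = ", length(pooled),
            "); stage skipped", call. = FALSE)
    return(NULL)
  }
  fences <- tukey_fences(pooled, k = k, method = method, min_n = min_n)
  list(fences = fences,
       flagged = vapply(itis, function(v) any(outside_fences(v, fences)),
                        logical(1)))
}

# Row indices in `classified` matching the (participant, session, item) keys
# of `rows` in the given stream.
match_rows <- function(classified, rows, stream) {
  if (nrow(rows) == 0) return(integer(0))
  keys <- paste(classified$participant_id, classified$session,
                classified$item_id, classified$stream)
  want <- paste(rows$participant_id, rows$session, rows$item_id, stream)
  which(keys %in% want)
}

#' @rdname flag_outliers
#' @export
flag_tempo_outliers <- function(classified, items, k = 3,
                                method = "linear", min_n = 4) {
  flag_outliers(classified, items, k = k, method = method, min_n = min_n)
}

#' @rdname flag_outliers
#' @export
flag_rhythm_outliers <- flag_tempo_outliers
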