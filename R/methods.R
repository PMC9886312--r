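#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang %||% .data
NULL

#' @export
print.tap_scores <- function(x, ...) {
  g <- glance(x)
  cat("<tap_scores>\n")
  cat(sprintf("  %d participants, %d responses (%d rhythm, %d tempo items)\n",
              g$n_participants, g$n_responses, g$n_rhythm_items,
              g$n_tempo_items))
  cat(sprintf("  mean correct rhythms: %.1f / %d\n",
              g$mean_correct_rhythms, g$n_rhythm_items))
  cat(sprintf("  mean deviation: tempo %.1f%%, absolute rhythm %.1f%%, relative rhythm %.1f%%\n",
              g$mean_tempo_dev_pct, g$mean_abs_rhythm_dev_pct,
              g$mean_rel_rhythm_dev_pct))
  cat(sprintf("  excluded: %d responses, %d participants\n",
              nrow(x$response_exclusions) %||% 0L,
              nrow(x$participant_exclusions)))
  invisible(x)
}

#' Tidy and summarise scored tapping datasets
#'
#' `tidy()` returns the per-response item scores (one row per participant x
#' session x item); `glance()` a one-row cohort summary.
#'
#' @param x A `tap_scores` object.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy tap_scores
#' @export
tidy.tap_scores <- function(x, ...) {
  dplyr::select(x$items, -dplyr::any_of(
    c("abs_per_interval_pct", "rel_per_interval_pct")))
}

#' @rdname tidy.tap_scores
#' @method glance tap_scores
#' @export
glance.tap_scores <- function(x, ...) {
  p <- x$participants
  tibble::tibble(
    n_participants = dplyr::n_distinct(p$participant_id),
    n_responses = nrow(x$items),
    n_rhythm_items = max(p$n_rhythm_items, 0),
    n_tempo_items = max(p$n_tempo_items, 0),
    mean_correct_rhythms = mean(p$n_correct_rhythms),
    mean_tempo_dev_pct = mean_or_na(p$tempo_dev_pct),
    mean_abs_rhythm_dev_pct = mean_or_na(p$abs_rhythm_dev_pct),
    mean_rel_rhythm_dev_pct = mean_or_na(p$rel_rhythm_dev_pct),
    n_excluded_responses = nrow(x$response_exclusions),
    n_excluded_participants = nrow(x$participant_exclusions)
  )
}

#' @export
print.tap_omega <- function(x, ...) {
  cat(sprintf("McDonald's omega = %.3f (%d items%s%s)\n", x$omega, x$n_items,
              if (is.na(x$n_obs)) "" else sprintf(", n = %d", x$n_obs),
              if (x$n_imputed > 0) sprintf(", %d cells imputed", x$n_imputed)
              else ""))
  invisible(x)
}

#' Tidy methods for reliability objects
#'
#' @param x A `tap_omega` or `tap_retest` object.
#' @param ... Unused.
#' @return A tibble: per-item loadings/uniquenesses for `tidy.tap_omega()`,
#'   one-row summaries otherwise.
#' @method tidy tap_omega
#' @export
tidy.tap_omega <- function(x, ...) {
  tibble::tibble(item = seq_along(x$loadings),
                 loading = x$loadings, uniqueness = x$uniqueness)
}

#' @rdname tidy.tap_omega
#' @method glance tap_omega
#' @export
glance.tap_omega <- function(x, ...) {
  tibble::tibble(omega = x$omega, n_items = x$n_items, n_obs = x$n_obs,
                 n_imputed = x$n_imputed)
}

#' @export
print.tap_retest <- function(x, ...) {
  cat(sprintf("test-retest: %s = %.3f, Spearman rho = %.3f (p = %.3g, n = %d)\n",
              x$icc_type, x$icc, x$spearman_rho, x$spearman_p, x$n))
  invisible(x)
}

#' @rdname tidy.tap_omega
#' @method tidy tap_retest
#' @export
tidy.tap_retest <- function(x, ...) {
  tibble::tibble(statistic = c(x$icc_type, "spearman_rho"),
                 estimate = c(x$icc, x$spearman_rho))
}

#' @rdname tidy.tap_omega
#' @method glance tap_retest
#' @export
glance.tap_retest <- function(x, ...) {
  tibble::tibble(icc = x$icc, icc_type = x$icc_type,
                 spearman_rho = x$spearman_rho, spearman_p = x$spearman_p,
                 n = x$n)
}

#' Plot deviation distributions of a scored cohort
#'
#' Boxplots of per-response percent deviation by item, split by metric
#' (tempo, absolute rhythm, relative rhythm) and coloured by difficulty.
#'
#' @param object A `tap_scores` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tap_scores
#' @export
autoplot.tap_scores <- function(object, ...) {
  df <- object$items |>
    tidyr::pivot_longer(cols = c("tempo_dev_pct", "abs_dev_pct",
                                 "rel_dev_pct"),
                        names_to = "metric", values_to = "deviation_pct") |>
    dplyr::filter(!is.na(.data$deviation_pct)) |>
    dplyr::mutate(metric = dplyr::recode(.data$metric,
      tempo_dev_pct = "tempo", abs_dev_pct = "absolute rhythm",
      rel_dev_pct = "relative rhythm"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$item_id,
                                   y = .data$deviation_pct,
                                   fill = .data$difficulty)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::facet_wrap(~metric, scales = "free", ncol = 1) +
    ggplot2::labs(x = NULL, y = "deviation (%)",
                  title = "Per-item temporal deviation") +
    ggplot2::theme_minimal()
}

#' Plot one reproduction against its reference timeline
#'
#' Event-time plot of reference onsets and reproduced taps (anchored at the
#' first tap), in absolute milliseconds and on the relative 0-1 scale, with
#' segments marking the per-event deviation used by the accuracy metrics.
#'
#' @param tap_times_ms Tap timestamps of one response.
#' @param item One-row rhythm item.
#' @return A ggplot object.
#' @export
plot_tap_response <- function(tap_times_ms, item) {
  stopifnot(nrow(item) == 1, item$type == "rhythm")
  ioi <- item$ioi_ms[[1]]
  if (length(tap_times_ms) != length(ioi) + 1L) {
    stop("tap count does not match the item", call. = FALSE)
  }
  cum_tap <- cumulative_times(tap_intervals(tap_times_ms))
  cum_onset <- cumulative_times(ioi)
  df <- dplyr::bind_rows(
    tibble::tibble(scale = "absolute (ms)", position = seq_along(ioi),
                   reference = cum_onset, produced = cum_tap),
    tibble::tibble(scale = "relative (0-1)", position = seq_along(ioi),
                   reference = relative_times(cum_onset),
                   produced = relative_times(cum_tap))
  ) |>
    tidyr::pivot_longer(c("reference", "produced"),
                        names_to = "series", values_to = "time")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$series)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$series), size = 2) +
    ggplot2::geom_line(ggplot2::aes(group = .data$position),
                       colour = "grey60", linetype = "dotted") +
    ggplot2::facet_wrap(~scale, scales = "free_x", ncol = 1) +
    ggplot2::labs(x = "event time (anchored at first event)", y = NULL,
                  title = paste0("Reproduction vs reference: ", item$item_id)) +
    ggplot2::guides(colour = "none") +
    ggplot2::theme_minimal()
}
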