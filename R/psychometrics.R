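#' Item-mean imputation of a participant-by-item score matrix
#'
#' Replaces each missing cell with the mean of the observed values in its
#' item column, leaving observed cells untouched. Used before internal
#' consistency estimation when a portion of items is missing per
#' participant (e.g. rhythm items reproduced incorrectly carry no synchrony
#' value). Column means are invariant under the imputation.
#'
#' @param x Participant-by-item matrix or data frame of scores with `NA`
#'   for missing cells. Every column must have at least one observed value.
#' @return Object of the same shape with no missing cells, plus attribute
#'   `n_imputed` (number of cells filled).
#' @examples
#' impute_item_means(cbind(a = c(10, NA, 20), b = c(1, 2, 3)))
#' @export
impute_item_means <- function(x) {
  m <- as.matrix(x)
  if (is.logical(m)) storage.mode(m) <- "double"  # an all-NA column is logical
  if (!is.numeric(m)) stop("scores must be numeric", call. = FALSE)
  all_missing <- colSums(!is.na(m)) == 0
  if (any(all_missing)) {
    stop("column(s) fully missing: ",
         paste(colnames(m)[all_missing] %||% which(all_missing), collapse = ", "),
         call. = FALSE)
  }
  n_imputed <- sum(is.na(m))
  for (j in seq_len(ncol(m))) {
    miss <- is.na(m[, j])
    if (any(miss)) m[miss, j] <- mean(m[!miss, j])
  }
  out <- if (is.data.frame(x)) as.data.frame(m) else m
  attr(out, "n_imputed") <- n_imputed
  out
}

# Single-common-factor extraction by minimum residual (minres / ULS):
# minimise the sum of squared off-diagonal residuals of R - lambda lambda'.
# Returns standardized loadings aligned to a positive sum.
minres_single_factor <- function(R, tol = 1e-6, max_iter = 500) {
  p <- ncol(R)
  off <- upper.tri(R)
  # start from the first principal component scaled to unit communality cap
  e <- eigen(R, symmetric = TRUE)
  lambda0 <- e$vectors[, 1] * sqrt(max(e$values[1], 0))
  lambda0 <- pmax(pmin(lambda0, 0.995), -0.995)
  obj <- function(l) {
    res <- R - tcrossprod(l)
    sum(res[off]^2)
  }
  grad <- function(l) {
    res <- R - tcrossprod(l)
    diag(res) <- 0
    -4 * res %*% l
  }
  fit <- stats::optim(lambda0, obj, grad, method = "BFGS",
                      control = list(maxit = max_iter, reltol = tol))
  if (fit$convergence != 0) {
    stop("single-factor minres fit did not converge (code ", fit$convergence,
         ", objective ", signif(fit$value, 4), ")", call. = FALSE)
  }
  lambda <- as.numeric(fit$par)
  if (sum(lambda) < 0) lambda <- -lambda
  lambda
}

#' McDonald's omega (total) from a single-common-factor model
#'
#' Fits a one-factor model to the item correlation matrix by minimum
#' residual (unweighted least squares) and returns
#' `omega = (sum lambda)^2 / ((sum lambda)^2 + sum psi)` where `lambda` are
#' the standardized loadings and `psi = 1 - lambda^2` the uniquenesses.
#' Omega makes weaker assumptions than Cronbach's alpha (no essential
#' tau-equivalence) and is the internal-consistency coefficient reported by
#' the scoring pipeline. Dichotomous 0/1 item matrices are accepted and
#' analysed with product-moment correlations (a documented approximation).
#'
#' @param x Participant-by-item matrix or data frame (complete; run
#'   [impute_item_means()] first if cells are missing), or a correlation
#'   matrix when `is_correlation = TRUE`.
#' @param is_correlation Set `TRUE` when `x` is already a correlation matrix.
#' @param tol,max_iter Convergence tolerance and iteration cap for the
#'   minres fit.
#' @return Object of class `tap_omega`: list with `omega`, `loadings`,
#'   `uniqueness`, `n_items`, `n_obs`, `n_imputed`.
#' @examples
#' R <- matrix(0.49, 6, 6); diag(R) <- 1
#' mcdonald_omega(R, is_correlation = TRUE)$omega  # ~0.852
#' @export
mcdonald_omega <- function(x, is_correlation = FALSE, tol = 1e-6,
                           max_iter = 500) {
  if (is_correlation) {
    R <- as.matrix(x)
    n_obs <- NA_integer_
  } else {
    m <- as.matrix(x)
    if (anyNA(m)) {
      stop("score matrix has missing cells; impute first (impute_item_means)",
           call. = FALSE)
    }
    if (ncol(m) < 3) stop("omega requires at least 3 items", call. = FALSE)
    if (nrow(m) < ncol(m) + 1) {
      stop("omega requires more participants than items", call. = FALSE)
    }
    sds <- apply(m, 2, stats::sd)
    if (any(sds == 0)) {
      stop("constant item column(s): correlation undefined", call. = FALSE)
    }
    R <- stats::cor(m)
    n_obs <- nrow(m)
  }
  lambda <- minres_single_factor(R, tol = tol, max_iter = max_iter)
  psi <- 1 - lambda^2
  omega <- sum(lambda)^2 / (sum(lambda)^2 + sum(psi))
  structure(
    list(omega = omega, loadings = lambda, uniqueness = psi,
         n_items = ncol(R), n_obs = n_obs,
         n_imputed = attr(x, "n_imputed") %||% 0L),
    class = "tap_omega")
}

# Mean squares of the two-way participant x measurement layout used by the
# intraclass correlations. y: n x k matrix (participants x measurements).
icc_mean_squares <- function(y) {
  n <- nrow(y); k <- ncol(y)
  grand <- mean(y)
  row_m <- rowMeans(y); col_m <- colMeans(y)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_err <- sum((y - outer(row_m, rep(1, k)) -
                   outer(rep(1, n), col_m) + grand)^2)
  list(msr = ss_rows / (n - 1), msc = ss_cols / (k - 1),
       mse = ss_err / ((n - 1) * (k - 1)), n = n, k = k)
}

#' Test-retest agreement: intraclass and Spearman correlations
#'
#' Computes a single-measure intraclass correlation between paired sessions
#' — by default ICC(2,1), the two-way random-effects absolute-agreement
#' coefficient, which penalises systematic session shifts; ICC(3,1)
#' (consistency) is available — together with the Spearman rank
#' correlation, which is robust to single extreme observations in small
#' retest samples.
#'
#' @param test,retest Paired numeric score vectors (same participants, two
#'   sessions); at least 5 complete pairs.
#' @param icc_type `"ICC2"` (absolute agreement, default) or `"ICC3"`
#'   (consistency).
#' @return Object of class `tap_retest`: list with `icc`, `icc_type`,
#'   `spearman_rho`, `spearman_p`, `n`.
#' @examples
#' s <- c(10, 12, 15, 19, 23, 30)
#' test_retest(s, s)$icc  # 1
#' @export
test_retest <- function(test, retest, icc_type = c("ICC2", "ICC3")) {
  icc_type <- match.arg(icc_type)
  ok <- stats::complete.cases(test, retest)
  y <- cbind(test[ok], retest[ok])
  if (nrow(y) < 5) stop("need at least 5 complete pairs", call. = FALSE)
  if (stats::sd(y[, 1]) == 0 || stats::sd(y[, 2]) == 0) {
    stop("constant score vector: correlation undefined", call. = FALSE)
  }
  ms <- icc_mean_squares(y)
  icc <- if (icc_type == "ICC2") {
    (ms$msr - ms$mse) /
      (ms$msr + (ms$k - 1) * ms$mse + ms$k / ms$n * (ms$msc - ms$mse))
  } else {
    (ms$msr - ms$mse) / (ms$msr + (ms$k - 1) * ms$mse)
  }
  ct <- suppressWarnings(
    stats::cor.test(y[, 1], y[, 2], method = "spearman", exact = FALSE))
  structure(
    list(icc = icc, icc_type = icc_type,
         spearman_rho = unname(ct$estimate), spearman_p = ct$p.value,
         n = nrow(y)),
    class = "tap_retest")
}

#' Reliability report for a scored cohort
#'
#' Convenience wrapper: builds the participant-by-item matrix for a metric,
#' imputes missing cells with item means, and returns omega together with
#' test-retest statistics when a second session is supplied.
#'
#' @param item_scores Output of [score_items()] (session 1).
#' @param metric Which per-item value fills the matrix: `"abs_dev_pct"`,
#'   `"rel_dev_pct"`, `"tempo_dev_pct"`, or `"correct"` (dichotomous 0/1
#'   absolute-stream correctness of rhythm items).
#' @param retest_scores Optional [score_items()] output for the retest
#'   session of the same participants.
#' @return List with `omega` (`tap_omega`), `retest` (`tap_retest` or
#'   `NULL`), `metric`, `n_imputed`.
#' @export
reliability_report <- function(item_scores,
                               metric = c("abs_dev_pct", "rel_dev_pct",
                                          "tempo_dev_pct", "correct"),
                               retest_scores = NULL) {
  metric <- match.arg(metric)
  m <- item_score_matrix(item_scores, metric)
  mi <- impute_item_means(m)
  omega <- mcdonald_omega(mi)
  retest <- NULL
  if (!is.null(retest_scores)) {
    s1 <- participant_metric_means(item_scores, metric)
    s2 <- participant_metric_means(retest_scores, metric)
    merged <- dplyr::inner_join(s1, s2, by = "participant_id",
                                suffix = c("_t1", "_t2"))
    retest <- test_retest(merged$value_t1, merged$value_t2)
  }
  list(omega = omega, retest = retest, metric = metric,
       n_imputed = attr(mi, "n_imputed"))
}

item_score_matrix <- function(item_scores, metric) {
  df <- if (metric == "correct") {
    item_scores |>
      dplyr::filter(.data$type == "rhythm") |>
      dplyr::mutate(value = as.numeric(.data$status_abs == "correct"))
  } else {
    type_wanted <- if (metric == "tempo_dev_pct") "tempo" else "rhythm"
    item_scores |>
      dplyr::filter(.data$type == type_wanted) |>
      dplyr::mutate(value = .data[[metric]])
  }
  wide <- df |>
    dplyr::select("participant_id", "item_id", "value") |>
    tidyr::pivot_wider(names_from = "item_id", values_from = "value")
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$participant_id
  m
}

participant_metric_means <- function(item_scores, metric) {
  m <- item_score_matrix(item_scores, metric)
  tibble::tibble(participant_id = rownames(m),
                 value = rowMeans(m, na.rm = TRUE))
}
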