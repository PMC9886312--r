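test_that("perception scoring follows the confidence-weighted rule", {
  resp <- tibble::tibble(
    truth = c("different", "different", "same", "same", "different"),
    answer = c("different", "different", "different", "dont_know", "same"),
    confidence = c("definitely", "probably", "definitely", "none", "probably"))
  expect_equal(score_perception(resp)$points, c(1, 0.5, 0, 0, 0))
})

test_that("perception validation rejects malformed responses", {
  expect_error(score_perception(tibble::tibble(
    truth = "same", answer = "yes", confidence = "probably")), "malformed")
  expect_error(score_perception(tibble::tibble(
    truth = "same", answer = "same", confidence = "none")), "coincide")
})

test_that("perception subtest totals live on a half-point grid", {
  set.seed(51)
  resp <- tibble::tibble(
    truth = sample(c("same", "different"), 18, TRUE),
    answer = sample(c("same", "different", "dont_know"), 18, TRUE,
                    prob = c(0.45, 0.45, 0.1)))
  resp$confidence <- ifelse(resp$answer == "dont_know", "none",
                            sample(c("definitely", "probably"), 18, TRUE))
  total <- sum(score_perception(resp)$points)
  expect_gte(total, 0)
  expect_lte(total, 18)
  expect_equal(total * 2, round(total * 2))
})

make_item_scores <- function(abs_dev, status_abs,
                             tempo_dev = rep(10, 3), pid = "P1") {
  n_r <- length(abs_dev)
  dplyr::bind_rows(
    tibble::tibble(participant_id = pid, session = 1L,
                   item_id = sprintf("R%02d", seq_len(n_r)), type = "rhythm",
                   difficulty = "easy", status_abs = status_abs,
                   status_rel = status_abs, tempo_dev_pct = NA_real_,
                   abs_dev_pct = abs_dev, rel_dev_pct = abs_dev / 2),
    tibble::tibble(participant_id = pid, session = 1L,
                   item_id = sprintf("T%02d", seq_along(tempo_dev)),
                   type = "tempo", difficulty = NA_character_,
                   status_abs = "correct", status_rel = "correct",
                   tempo_dev_pct = tempo_dev, abs_dev_pct = NA_real_,
                   rel_dev_pct = NA_real_))
}

test_that("participant aggregation means run over surviving items only", {
  abs_dev <- c(10, 20, 30, 40, 50, 60, rep(NA_real_, 6))
  status <- c(rep("correct", 6), rep("structural_error", 3),
              rep("outlier", 2), "wrong_tap_count")
  p <- aggregate_participants(make_item_scores(abs_dev, status))
  expect_equal(p$n_correct_rhythms, 6)
  expect_equal(p$abs_rhythm_dev_pct, 35)
  expect_equal(p$n_excluded_rhythm_abs, 6)
  expect_equal(p$tempo_dev_pct, 10)
})

test_that("an all-correct zero-deviation participant aggregates cleanly", {
  p <- aggregate_participants(
    make_item_scores(rep(0, 12), rep("correct", 12), rep(0, 3)))
  expect_equal(p$n_correct_rhythms, 12)
  expect_equal(p$abs_rhythm_dev_pct, 0)
})

test_that("no surviving items yields missing means, zero correct", {
  p <- aggregate_participants(
    make_item_scores(rep(NA_real_, 4), rep("structural_error", 4)))
  expect_equal(p$n_correct_rhythms, 0)
  expect_true(is.na(p$abs_rhythm_dev_pct))
})

test_that("aggregation is permutation-invariant and rejects duplicates", {
  scores <- make_item_scores(c(5, 15, 25), rep("correct", 3))
  set.seed(52)
  shuffled <- scores[sample(nrow(scores)), ]
  expect_equal(aggregate_participants(scores),
               aggregate_participants(shuffled))
  expect_error(aggregate_participants(dplyr::bind_rows(scores, scores[1, ])),
               "duplicate")
})

test_that("participant exclusion flags tempo z-outliers and zero-correct cases", {
  set.seed(53)
  base <- tibble::tibble(
    participant_id = sprintf("P%02d", 1:20), session = 1L,
    tempo_dev_pct = rnorm(20, 20, 2),
    abs_rhythm_dev_pct = rnorm(20, 40, 5),
    rel_rhythm_dev_pct = rnorm(20, 15, 3),
    n_correct_rhythms = sample(4:10, 20, TRUE),
    n_rhythm_items = 12L, n_tempo_items = 12L,
    n_excluded_rhythm_abs = 2L, n_excluded_rhythm_rel = 2L,
    n_excluded_tempo = 0L)
  base$tempo_dev_pct[7] <- mean(base$tempo_dev_pct[-7]) +
    6 * sd(base$tempo_dev_pct[-7])
  base$n_correct_rhythms[12] <- 0L
  excl <- flag_participant_outliers(base)
  expect_setequal(excl$participant_id, c("P07", "P12"))
  expect_setequal(excl$reason, c("tempo_z_outlier", "no_correct_rhythms"))
  # a homogeneous cohort loses no one
  expect_equal(nrow(flag_participant_outliers(base[-c(7, 12), ])), 0)
})

test_that("tiny cohorts skip z-screening with a warning", {
  two <- tibble::tibble(participant_id = c("A", "B"), session = 1L,
                        tempo_dev_pct = c(5, 500),
                        n_correct_rhythms = c(3L, 3L), n_rhythm_items = 12L)
  expect_warning(excl <- flag_participant_outliers(two), "fewer than 3")
  expect_equal(nrow(excl), 0)
})
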