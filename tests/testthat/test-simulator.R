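test_that("configuration is validated", {
  expect_error(sim_config(p_omit = 1.2), "\\[0, 1\\]")
  expect_error(sim_config(p_omit = 0.6, p_insert = 0.3, p_substitute = 0.3),
               "must not exceed 1")
  expect_error(sim_config(jitter_sd_ms = -1), "non-negative")
})

test_that("the default bank has the published design shape", {
  bank <- default_item_bank()
  expect_equal(sum(bank$type == "rhythm"), 12)
  expect_equal(sum(bank$type == "tempo"), 12)
  expect_true(all(bank$n_taps[bank$type == "tempo"] == 8))
  expect_setequal(unique(bank$difficulty[bank$type == "rhythm"]),
                  c("easy", "moderate", "complex"))
  # every rhythm item offers at least two note values, so substitutions
  # are injectable and detectable
  expect_true(all(purrr::map_int(bank$ioi_ms[bank$type == "rhythm"],
                                 ~length(note_values(.x))) >= 2))
})

test_that("a noiseless error-free draw reproduces the item exactly", {
  cfg <- sim_config(jitter_sd_ms = 0, tempo_scale_sd = 0, p_omit = 0,
                    p_insert = 0, p_substitute = 0, p_outlier = 0)
  item <- cfg$item_bank[cfg$item_bank$item_id == "RM1", ]
  set.seed(71)
  r <- simulate_response(item, ability = 0, cfg)
  expect_equal(tap_intervals(r$tap_times_ms), item$ioi_ms[[1]])
  expect_identical(r$truth$error_type, "none")
})

test_that("forced error modes change the tap count as labelled", {
  base <- list(jitter_sd_ms = 0, tempo_scale_sd = 0, p_insert = 0,
               p_substitute = 0, p_outlier = 0)
  cfg_omit <- do.call(sim_config, c(base, list(p_omit = 1)))
  item <- cfg_omit$item_bank[cfg_omit$item_bank$item_id == "RM1", ]
  set.seed(72)
  r <- simulate_response(item, 0, cfg_omit)
  expect_identical(r$truth$error_type, "omit")
  expect_length(r$tap_times_ms, item$n_taps - 1L)
  cfg_ins <- sim_config(jitter_sd_ms = 0, tempo_scale_sd = 0, p_omit = 0,
                        p_substitute = 0, p_outlier = 0, p_insert = 1)
  r2 <- simulate_response(item, 0, cfg_ins)
  expect_length(r2$tap_times_ms, item$n_taps + 1L)
  expect_true(!is.unsorted(r2$tap_times_ms, strictly = TRUE))
})

test_that("a substitution is detectable at zero jitter; scaling splits streams", {
  cfg <- sim_config(jitter_sd_ms = 0, tempo_scale_sd = 0, p_omit = 0,
                    p_insert = 0, p_substitute = 1, p_outlier = 0)
  item <- cfg$item_bank[cfg$item_bank$item_id == "RM1", ]
  set.seed(73)
  r <- simulate_response(item, 0, cfg)
  expect_identical(check_structure(r$tap_times_ms, item, "absolute")$status,
                   "structural_error")
  # pure tempo scaling: absolute deviation positive, relative exactly zero
  cfg2 <- sim_config(jitter_sd_ms = 0, tempo_scale_sd = 0.3, p_omit = 0,
                     p_insert = 0, p_substitute = 0, p_outlier = 0)
  set.seed(74)
  r2 <- simulate_response(item, 0, cfg2)
  expect_gt(absolute_rhythm_deviation_pct(r2$tap_times_ms, item)$mean_pct, 0)
  expect_equal(relative_rhythm_deviation_pct(r2$tap_times_ms, item)$mean_pct,
               0, tolerance = 1e-9)
})

test_that("cohorts are byte-identical under the same seed", {
  cfg <- sim_config(seed = 99, n_participants = 5)
  s1 <- simulate_cohort(cfg)
  s2 <- simulate_cohort(cfg)
  expect_identical(s1$taps, s2$taps)
  expect_identical(s1$truth, s2$truth)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_tap_log(s1$taps, f1); write_tap_log(s2$taps, f2)
  expect_identical(readLines(f1), readLines(f2))
  s3 <- simulate_cohort(sim_config(seed = 100, n_participants = 5))
  expect_false(identical(s1$taps, s3$taps))
})

test_that("higher jitter yields strictly higher mean absolute deviation", {
  devs <- sapply(c(5, 15, 25), function(j) {
    cfg <- sim_config(seed = 777, n_participants = 40, jitter_sd_ms = j,
                      tempo_scale_sd = 0, p_omit = 0, p_insert = 0,
                      p_substitute = 0, p_outlier = 0, ability_sd = 0)
    sim <- simulate_cohort(cfg)
    scores <- score_tapping(sim$taps, sim$items, outlier_filter = FALSE)
    mean(scores$participants$abs_rhythm_dev_pct)
  })
  expect_true(all(diff(devs) > 0))
})

test_that("injected structural-error rate is recovered by the pipeline", {
  bank <- default_item_bank() |> dplyr::filter(type == "rhythm")
  cfg <- sim_config(seed = 778, n_participants = 60, item_bank = bank,
                    jitter_sd_ms = 5, tempo_scale_sd = 0.02,
                    p_omit = 0.1, p_insert = 0.1, p_substitute = 0.1,
                    p_outlier = 0, ability_sd = 0)
  sim <- simulate_cohort(cfg)
  injected <- mean(sim$truth$error_type != "none")
  scores <- score_tapping(sim$taps, sim$items)
  noncorrect <- mean(scores$items$status_abs != "correct")
  n <- nrow(sim$truth)
  ci <- 1.96 * sqrt(0.3 * 0.7 / n)
  expect_lt(abs(injected - 0.3), ci + 0.02)   # the draw itself
  expect_lt(abs(noncorrect - injected), 0.02) # detection matches injection
})
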