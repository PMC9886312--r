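#' Simulation configuration for synthetic tapping cohorts
#'
#' Bundles and validates the generative parameters of the synthetic-cohort
#' simulator. The generator emulates the response structure the scoring
#' pipeline assumes: additive Gaussian motor jitter on each interval, a
#' log-normal global tempo scale per response, mutually exclusive structural
#' errors (an omitted, inserted, or substituted note), a rare grossly
#' lengthened interval (outlier), and a latent participant ability trait
#' that modulates both jitter and error odds, inducing correlation across
#' subtests.
#'
#' Because the error modes are drawn mutually exclusively, the probability
#' that a rhythm response carries an injected structural error is exactly
#' `p_omit + p_insert + p_substitute`.
#'
#' @param seed Integer seed; fully determines the cohort.
#' @param n_participants Cohort size (default 40).
#' @param item_bank Item bank tibble (default [default_item_bank()]).
#' @param jitter_sd_ms Motor-noise SD in ms, additive per interval
#'   (default 15).
#' @param tempo_scale_sd SD of the log-normal global tempo scale
#'   (default 0.05).
#' @param p_omit,p_insert,p_substitute Structural-error probabilities per
#'   rhythm response; omission/insertion also apply to tempo responses,
#'   substitution needs at least two note values (default 0.05/0.05/0.10).
#' @param p_outlier Probability of one grossly lengthened interval,
#'   multiplier drawn from U(2.5, 4) (default 0.02).
#' @param ability_sd SD of the latent ability trait on the log scale; 0
#'   switches the trait off (default 0.3).
#' @param jitter_model `"additive"` (constant SD) or `"weber"` (SD
#'   proportional to interval length, scaled so a 500 ms interval gets
#'   `jitter_sd_ms`).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_participants = 40L,
                       item_bank = default_item_bank(),
                       jitter_sd_ms = 15, tempo_scale_sd = 0.05,
                       p_omit = 0.05, p_insert = 0.05, p_substitute = 0.10,
                       p_outlier = 0.02, ability_sd = 0.3,
                       jitter_model = c("additive", "weber")) {
  jitter_model <- match.arg(jitter_model)
  probs <- c(p_omit = p_omit, p_insert = p_insert,
             p_substitute = p_substitute, p_outlier = p_outlier)
  if (any(probs < 0 | probs > 1)) {
    stop("error probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (p_omit + p_insert + p_substitute > 1) {
    stop("p_omit + p_insert + p_substitute must not exceed 1", call. = FALSE)
  }
  if (jitter_sd_ms < 0 || tempo_scale_sd < 0 || ability_sd < 0) {
    stop("standard deviations must be non-negative", call. = FALSE)
  }
  validate_item_bank(item_bank)
  structure(
    list(seed = as.integer(seed), n_participants = as.integer(n_participants),
         item_bank = item_bank, jitter_sd_ms = jitter_sd_ms,
         tempo_scale_sd = tempo_scale_sd, p_omit = p_omit,
         p_insert = p_insert, p_substitute = p_substitute,
         p_outlier = p_outlier, ability_sd = ability_sd,
         jitter_model = jitter_model),
    class = "sim_config")
}

#' Default synthetic item bank
#'
#' Twelve rhythm items (four per difficulty level) over quaver/crotchet
#' style note-value alphabets, including the 520/260 ms reference pattern
#' used throughout the package examples, and twelve isochronous tempo items
#' with inter-beat intervals spanning roughly 80-140 bpm, eight taps each.
#'
#' @return Item bank tibble with 24 rows.
#' @export
default_item_bank <- function() {
  rhythms <- list(
    # easy: alterations on the downbeat, coarse two-value alphabets
    E1 = list(c(600, 600, 1200, 600, 600, 1200), "easy"),
    E2 = list(c(500, 500, 500, 1000, 500, 1000), "easy"),
    E3 = list(c(800, 400, 400, 800, 800, 400, 400, 800), "easy"),
    E4 = list(c(700, 700, 350, 350, 700, 700), "easy"),
    # moderate: upbeat alterations, denser 1:2 alphabets
    M1 = list(c(520, 260, 260, 520, 260, 260, 520, 520, 520), "moderate"),
    M2 = list(c(260, 260, 520, 260, 260, 520, 520, 260, 260), "moderate"),
    M3 = list(c(450, 450, 900, 450, 900, 450, 450, 900), "moderate"),
    M4 = list(c(300, 600, 300, 300, 600, 600, 300, 600), "moderate"),
    # complex: sixteenth-level values, three-value alphabets
    C1 = list(c(250, 125, 125, 500, 250, 250, 125, 125, 500), "complex"),
    C2 = list(c(400, 200, 200, 100, 100, 400, 200, 400, 400), "complex"),
    C3 = list(c(150, 150, 300, 600, 150, 150, 300, 600), "complex"),
    C4 = list(c(500, 125, 125, 250, 500, 250, 125, 125, 500), "complex")
  )
  rhythm_rows <- purrr::imap_dfr(rhythms, function(spec, nm) {
    rhythm_item(paste0("R", nm), spec[[1]], spec[[2]])
  })
  ibis <- round(60000 / seq(80, 140, length.out = 12))
  tempo_rows <- purrr::map2_dfr(sprintf("T%02d", 1:12), ibis,
                                function(id, ibi) tempo_item(id, ibi, 8L))
  dplyr::bind_rows(rhythm_rows, tempo_rows)
}

# Ability-modulated error probability: shift on the log-odds scale.
shift_prob <- function(p, shift) {
  if (p <= 0 || p >= 1) return(p)
  stats::plogis(stats::qlogis(p) + shift)
}

#' Simulate one tap response with ground-truth labels
#'
#' Draws intervals `scale * base + N(0, jitter)` (base = the item's IOI
#' series, or the IBI repeated for a tempo item), optionally injects one
#' structural error (omit / insert / substitute, mutually exclusive) and
#' optionally one grossly lengthened outlier interval, then emits tap
#' timestamps from a random origin. Negative intervals are rejected and
#' redrawn. Uses the current RNG state; seed management lives in
#' [simulate_cohort()].
#'
#' @param item One-row item tibble.
#' @param ability Latent ability on the standard-normal scale; positive
#'   values mean noisier, more error-prone tapping.
#' @param cfg A [sim_config()].
#' @return List with `tap_times_ms` and a one-row `truth` tibble
#'   (`error_type`, `outlier_injected`, `tempo_scale`).
#' @export
simulate_response <- function(item, ability, cfg) {
  stopifnot(nrow(item) == 1, inherits(cfg, "sim_config"))
  base <- if (item$type == "rhythm") item$ioi_ms[[1]]
          else rep(item$ibi_ms, item$n_taps - 1L)
  shift <- ability * cfg$ability_sd
  jitter_sd <- cfg$jitter_sd_ms * exp(shift)
  alphabet <- note_values(base)

  # mutually exclusive structural-error draw; substitution needs >= 2 values
  p_sub <- if (length(alphabet) >= 2) shift_prob(cfg$p_substitute, shift) else 0
  p_om <- shift_prob(cfg$p_omit, shift)
  p_in <- shift_prob(cfg$p_insert, shift)
  u <- stats::runif(1)
  error_type <- if (u < p_om) "omit"
                else if (u < p_om + p_in) "insert"
                else if (u < p_om + p_in + p_sub) "substitute"
                else "none"

  intended <- base
  if (error_type == "substitute") {
    pos <- sample.int(length(intended), 1)
    intended[pos] <- sample_one(setdiff(alphabet, intended[pos]))
  }

  scale <- exp(stats::rnorm(1, 0, cfg$tempo_scale_sd))
  itis <- draw_intervals(intended * scale, jitter_sd, cfg$jitter_model)

  outlier_injected <- stats::runif(1) < cfg$p_outlier
  if (outlier_injected) {
    pos <- sample.int(length(itis), 1)
    itis[pos] <- itis[pos] * stats::runif(1, 2.5, 4)
  }

  taps <- floor(stats::runif(1, 0, 5000)) + cumsum(c(0, itis))
  if (error_type == "omit" && length(taps) > 2) {
    taps <- taps[-sample_one(2:(length(taps) - 1))]
  } else if (error_type == "insert") {
    gap <- sample.int(length(itis), 1)
    taps <- sort(c(taps, taps[gap] + stats::runif(1, 0.2, 0.8) * itis[gap]))
  }
  list(
    tap_times_ms = taps,
    truth = tibble::tibble(error_type = error_type,
                           outlier_injected = outlier_injected,
                           tempo_scale = scale)
  )
}

# sample() treats a length-1 vector as 1:n; this does not
sample_one <- function(x) x[sample.int(length(x), 1)]

# Additive or Weber (proportional) jitter, with rejection of non-positive
# intervals; deterministic (no draw) when the jitter SD is zero.
draw_intervals <- function(mu, jitter_sd, model) {
  if (jitter_sd == 0) return(mu)
  sds <- if (model == "weber") jitter_sd * mu / 500 else rep(jitter_sd, length(mu))
  out <- mu + stats::rnorm(length(mu), 0, sds)
  bad <- which(out <= 0)
  guard <- 0
  while (length(bad) > 0 && guard < 100) {
    out[bad] <- mu[bad] + stats::rnorm(length(bad), 0, sds[bad])
    bad <- which(out <= 0)
    guard <- guard + 1
  }
  if (length(bad) > 0) out[bad] <- mu[bad]  # pathological sd: fall back to mean
  out
}

#' Simulate a full tapping cohort
#'
#' Generates one response per participant x item under the configuration,
#' with a per-participant RNG substream derived from the seed by a fixed
#' offset so regenerating participant `i` alone reproduces their data.
#'
#' @param cfg A [sim_config()].
#' @return List with `items` (the bank), `taps` (long tap-log tibble:
#'   `participant_id`, `session`, `item_id`, `tap_index`, `time_ms`) and
#'   `truth` (one row per response with injected-error labels and the
#'   participant's latent ability).
#' @examples
#' sim <- simulate_cohort(sim_config(seed = 7, n_participants = 4))
#' dplyr::count(sim$truth, error_type)
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed %% .Machine$integer.max)
  abilities <- stats::rnorm(cfg$n_participants)
  n_items <- nrow(cfg$item_bank)
  item_rows <- lapply(seq_len(n_items), function(j) cfg$item_bank[j, ])
  n_resp <- cfg$n_participants * n_items
  tap_vecs <- vector("list", n_resp)
  error_type <- character(n_resp)
  outlier_injected <- logical(n_resp)
  tempo_scale <- numeric(n_resp)

  r <- 0L
  for (i in seq_len(cfg$n_participants)) {
    set.seed((cfg$seed + i * 10007L) %% .Machine$integer.max)
    for (j in seq_len(n_items)) {
      r <- r + 1L
      sim <- simulate_response(item_rows[[j]], abilities[i], cfg)
      tap_vecs[[r]] <- sim$tap_times_ms
      error_type[r] <- sim$truth$error_type
      outlier_injected[r] <- sim$truth$outlier_injected
      tempo_scale[r] <- sim$truth$tempo_scale
    }
  }

  pid <- sprintf("P%03d", rep(seq_len(cfg$n_participants), each = n_items))
  iid <- rep(cfg$item_bank$item_id, cfg$n_participants)
  lens <- lengths(tap_vecs)
  taps <- tibble::tibble(
    participant_id = rep(pid, lens), session = 1L,
    item_id = rep(iid, lens),
    tap_index = sequence(lens),
    time_ms = unlist(tap_vecs))
  truth <- tibble::tibble(
    participant_id = pid, session = 1L, item_id = iid,
    ability = rep(abilities, each = n_items),
    error_type = error_type, outlier_injected = outlier_injected,
    tempo_scale = tempo_scale)
  list(items = cfg$item_bank, taps = taps, truth = truth)
}
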