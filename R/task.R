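#' Configure the two-option probabilistic reward task
#'
#' Builds a validated configuration for the 60-trial task: two stimuli, one
#' carrying the higher reward probability (default 0.75 vs 0.25), reward
#' magnitudes complementary to `magnitude_total` (default 100), and the
#' contingency re-randomized at every block boundary (default every 20
#' trials, giving three blocks).
#'
#' @param n_trials Total number of trials; must be a positive multiple of
#'   `block_length`.
#' @param block_length Trials per block; the identity of the high-probability
#'   option is re-drawn at each block start.
#' @param p_high Reward probability of the high-probability option, in
#'   (0.5, 1).
#' @param magnitude_low Smallest reward magnitude (points) shown on an option.
#' @param magnitude_total Sum of the two options' magnitudes on every trial;
#'   one option shows R, the other `magnitude_total - R`.
#' @param adjustment_enabled If `TRUE`, an option chosen on the two
#'   immediately preceding trials has its magnitude redrawn from the lower
#'   half of the range (see [apply_magnitude_adjustment()]).
#' @param rng_seed Optional integer seed used by [build_schedule()].
#'
#' @return A list of class `task_config`.
#' @examples
#' cfg <- task_config()
#' cfg$n_trials / cfg$block_length  # three blocks
#' @export
task_config <- function(n_trials = 60L, block_length = 20L, p_high = 0.75,
                        magnitude_low = 1L, magnitude_total = 100L,
                        adjustment_enabled = TRUE, rng_seed = NULL) {
  n_trials <- as.integer(n_trials)
  block_length <- as.integer(block_length)
  magnitude_low <- as.integer(magnitude_low)
  magnitude_total <- as.integer(magnitude_total)
  if (n_trials < 1L || block_length < 1L || n_trials %% block_length != 0L)
    stop("invalid task config: n_trials must be a positive multiple of block_length",
         call. = FALSE)
  if (!(p_high > 0.5 && p_high < 1))
    stop("invalid task config: p_high must lie in (0.5, 1)", call. = FALSE)
  if (magnitude_low < 1L)
    stop("invalid task config: magnitude_low must be >= 1", call. = FALSE)
  magnitude_high <- magnitude_total - magnitude_low
  if (magnitude_high <= magnitude_low)
    stop("invalid task config: magnitude_total too small for magnitude_low",
         call. = FALSE)
  structure(
    list(n_trials = n_trials, block_length = block_length, p_high = p_high,
         magnitude_low = magnitude_low, magnitude_high = magnitude_high,
         magnitude_total = magnitude_total,
         adjustment_enabled = isTRUE(adjustment_enabled), rng_seed = rng_seed),
    class = "task_config")
}

#' Build a pre-choice trial schedule
#'
#' Draws the full trial schedule before any choices are made: per block a
#' uniformly random high-probability option (constant within the block), per
#' trial complementary reward magnitudes (R uniform on the magnitude range
#' for one option, `magnitude_total - R` for the other), and a pre-drawn
#' rewarded option with `P(high option rewarded) = p_high`. Exactly one
#' option is rewarded on every trial; the feedback phase reveals it whether
#' or not a response is made.
#'
#' @param config A [task_config()].
#' @param seed Optional integer seed overriding `config$rng_seed`.
#'
#' @return A tibble with one row per trial: `trial`, `block`,
#'   `high_prob_option`, `mag_A`, `mag_B`, `rewarded`.
#' @examples
#' sched <- build_schedule(task_config(rng_seed = 1))
#' all(sched$mag_A + sched$mag_B == 100)
#' @export
build_schedule <- function(config = task_config(), seed = config$rng_seed) {
  stopifnot(inherits(config, "task_config"))
  with_seed(seed, {
    n <- config$n_trials
    n_blocks <- n %/% config$block_length
    block <- rep(seq_len(n_blocks), each = config$block_length)
    high <- sample(c("A", "B"), n_blocks, replace = TRUE)[block]
    mag_A <- sample(seq.int(config$magnitude_low, config$magnitude_high),
                    n, replace = TRUE)
    high_rewarded <- runif(n) < config$p_high
    rewarded <- ifelse(high_rewarded, high, ifelse(high == "A", "B", "A"))
    tibble::tibble(
      trial = seq_len(n), block = block, high_prob_option = high,
      mag_A = as.integer(mag_A),
      mag_B = config$magnitude_total - as.integer(mag_A),
      rewarded = rewarded)
  })
}

#' Redraw an over-chosen option's magnitude
#'
#' Implements the magnitude-balancing rule: once a stimulus has been chosen
#' on the two immediately preceding trials of the current block, its
#' magnitude on the current trial is redrawn uniformly from the lower half
#' of the range, `{magnitude_low, ..., floor(magnitude_total/2) - 1}`, and
#' the other option receives the complement. The run counter ignores trials
#' from earlier blocks and is broken by a no-response trial (`NA` in
#' `history`).
#'
#' @param record A one-row schedule tibble (a pre-choice trial).
#' @param history Character vector of choices made so far in the current
#'   block, in order (`"A"`, `"B"`, or `NA` for no response).
#' @param config The [task_config()] in force.
#'
#' @return The record, with magnitudes redrawn when the rule fires.
#' @export
apply_magnitude_adjustment <- function(record, history, config = task_config()) {
  if (!config$adjustment_enabled || length(history) < 2L) return(record)
  last2 <- tail(history, 2L)
  if (anyNA(last2) || last2[1] != last2[2]) return(record)
  opt <- last2[1]
  lo <- config$magnitude_low
  hi <- config$magnitude_total %/% 2L - 1L
  r <- sample(seq.int(lo, hi), 1L)
  if (opt == "A") {
    record$mag_A <- as.integer(r)
    record$mag_B <- config$magnitude_total - as.integer(r)
  } else {
    record$mag_B <- as.integer(r)
    record$mag_A <- config$magnitude_total - as.integer(r)
  }
  record
}

#' Resolve a trial given a choice
#'
#' Completes a pre-choice trial record: records the chosen option (or no
#' response), whether a response was made, and the points earned (the chosen
#' option's magnitude if it was the pre-drawn rewarded option, else zero).
#' No-response trials earn nothing and are excluded from model likelihoods
#' downstream.
#'
#' @param record A one-row schedule tibble with a pre-drawn `rewarded` option.
#' @param choice `"A"`, `"B"`, or `NA`/`"none"` for no response.
#'
#' @return The completed record with `chosen`, `response_made`, `points`.
#' @export
resolve_trial <- function(record, choice) {
  if (length(choice) != 1L) stop("choice must be a single value", call. = FALSE)
  if (is.na(choice) || identical(choice, "none")) {
    record$chosen <- NA_character_
    record$response_made <- FALSE
    record$points <- 0L
    return(record)
  }
  if (!choice %in% c("A", "B"))
    stop("choice must be 'A', 'B' or none", call. = FALSE)
  record$chosen <- choice
  record$response_made <- TRUE
  won <- record$chosen == record$rewarded
  record$points <- as.integer(won) *
    if (choice == "A") record$mag_A else record$mag_B
  record
}
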