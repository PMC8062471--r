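#' The eight reinforcement-learning models
#'
#' Returns the model catalogue: two static learning rules (`s1` constant
#' learning rate; `s2` separate rates for positive and negative prediction
#' errors), two dynamic rules (`d1` Pearce-Hall associability-gated rate;
#' `d2` separate rates for the first and second half of trials), and their
#' probability-weighting variants (`s1w`, `s2w`, `d1w`, `d2w`) which pass
#' the learned probability through the linear weighting transform
#' [weight_probability()] before computing expected values.
#'
#' @return A tibble with `model`, `free_params` (list-column of canonical
#'   parameter names), `n_params`, `dynamic`, `weighted`.
#' @examples
#' rl_models()
#' @export
rl_models <- function() {
  tibble::tibble(
    model = rl_model_names(),
    free_params = lapply(rl_model_names(), rl_par_names),
    n_params = vapply(.data$free_params, length, integer(1)),
    dynamic = .data$model %in% c("d1", "d2", "d1w", "d2w"),
    weighted = grepl("w$", .data$model))
}

#' @rdname rl_models
#' @export
rl_model_names <- function() c("s1", "s2", "d1", "d2", "s1w", "s2w", "d1w", "d2w")

#' Canonical free-parameter names of a model
#'
#' @param model Model name, one of [rl_model_names()].
#' @return Character vector of parameter names in the canonical order used
#'   throughout the package (choice-rule inverse temperature `beta` last).
#' @export
rl_par_names <- function(model) {
  base <- switch(match.arg(model, rl_model_names()),
    s1 = , s1w = "alpha",
    s2 = , s2w = c("alpha_pos", "alpha_neg"),
    d1 = , d1w = c("mu", "kappa"),
    d2 = , d2w = c("alpha1", "alpha2"))
  if (grepl("w$", model)) c(base, "gamma", "beta") else c(base, "beta")
}

rl_model_id <- function(model) match(match.arg(model, rl_model_names()),
                                     rl_model_names())

#' Construct a validated parameter set for a model
#'
#' @param model Model name, one of [rl_model_names()].
#' @param ... Named parameter values; exactly the model's free parameters
#'   (see [rl_par_names()]) must be supplied. Learning rates and the
#'   associability step `mu` must lie in (0, 1); `kappa`, `gamma` must be
#'   positive; `beta` must be non-negative.
#' @return A named list of class `agent_params`.
#' @examples
#' agent_params("s1w", alpha = 0.1, gamma = 1.2, beta = 0.15)
#' @export
agent_params <- function(model, ...) {
  model <- match.arg(model, rl_model_names())
  vals <- list(...)
  need <- rl_par_names(model)
  if (!setequal(names(vals), need))
    stop(sprintf("model %s requires exactly parameters: %s", model,
                 paste(need, collapse = ", ")), call. = FALSE)
  vals <- vals[need]
  rates <- intersect(need, c("alpha", "alpha_pos", "alpha_neg",
                             "alpha1", "alpha2", "mu"))
  for (nm in rates)
    if (vals[[nm]] <= 0 || vals[[nm]] >= 1)
      stop(sprintf("parameter %s must lie in (0, 1)", nm), call. = FALSE)
  for (nm in intersect(need, c("kappa", "gamma")))
    if (vals[[nm]] <= 0)
      stop(sprintf("parameter %s must be positive", nm), call. = FALSE)
  if (vals$beta < 0) stop("parameter beta must be non-negative", call. = FALSE)
  structure(c(list(model = model), vals), class = "agent_params")
}

params_to_vector <- function(params) {
  unlist(params[rl_par_names(params$model)])
}

#' Rescorla-Wagner update with a constant learning rate
#'
#' The predicted reward probability of the chosen stimulus moves toward the
#' observed reward indicator by a fixed fraction `alpha` of the prediction
#' error `r - p_pred`.
#'
#' @param p_pred Current predicted probability, in \[0, 1\].
#' @param r Observed reward indicator, 0 or 1.
#' @param alpha Learning rate in (0, 1).
#' @return List with `p_pred` (updated) and `delta` (prediction error).
#' @examples
#' update_static(0.5, 1, 0.1)  # p moves up by 0.05
#' @export
update_static <- function(p_pred, r, alpha) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)", call. = FALSE)
  delta <- r - p_pred
  list(p_pred = p_pred + alpha * delta, delta = delta)
}

#' Asymmetric update: separate rates for positive and negative errors
#'
#' @inheritParams update_static
#' @param alpha_pos Learning rate applied when the prediction error is
#'   positive, in (0, 1).
#' @param alpha_neg Learning rate applied when the prediction error is
#'   negative, in (0, 1).
#' @return List with `p_pred` and `delta`.
#' @export
update_asymmetric <- function(p_pred, r, alpha_pos, alpha_neg) {
  if (alpha_pos <= 0 || alpha_pos >= 1 || alpha_neg <= 0 || alpha_neg >= 1)
    stop("learning rates must lie in (0, 1)", call. = FALSE)
  delta <- r - p_pred
  a <- if (delta > 0) alpha_pos else alpha_neg
  list(p_pred = p_pred + a * delta, delta = delta)
}

#' Pearce-Hall update: associability-gated dynamic learning rate
#'
#' The associability `S` is a running average of absolute prediction errors,
#' `S <- (1 - mu) * S + mu * |delta|`; the effective learning rate is
#' `kappa * S`, clamped to \[0, 1\] so the predicted probability stays in
#' range. By default the associability is refreshed with the current
#' `|delta|` before the value update, so the rate applied on trial t already
#' reflects trial t's surprise; set `assoc_first = FALSE` to apply the
#' pre-update associability instead.
#'
#' @inheritParams update_static
#' @param S Current associability, non-negative.
#' @param mu Associability step size in (0, 1).
#' @param kappa Learning-rate scale, positive.
#' @param assoc_first Update associability before the value update?
#' @return List with `p_pred`, `S` (updated), `alpha_t` (effective rate
#'   applied), `delta`.
#' @export
update_pearce_hall <- function(p_pred, r, S, mu, kappa, assoc_first = TRUE) {
  if (S < 0) stop("associability S must be non-negative", call. = FALSE)
  if (mu <= 0 || mu >= 1) stop("mu must lie in (0, 1)", call. = FALSE)
  if (kappa <= 0) stop("kappa must be positive", call. = FALSE)
  delta <- r - p_pred
  if (assoc_first) {
    S_new <- (1 - mu) * S + mu * abs(delta)
    alpha_t <- min(kappa * S_new, 1)
  } else {
    alpha_t <- min(kappa * S, 1)
    S_new <- (1 - mu) * S + mu * abs(delta)
  }
  list(p_pred = p_pred + alpha_t * delta, S = S_new,
       alpha_t = alpha_t, delta = delta)
}

#' Split-half update: one rate per half of the session
#'
#' @inheritParams update_static
#' @param trial_index 1-based overall trial index.
#' @param n_trials Total trials in the session.
#' @param alpha1 Learning rate for trials `1..floor(n_trials/2)`.
#' @param alpha2 Learning rate for the remaining trials.
#' @return List with `p_pred` and `delta`.
#' @export
update_split_half <- function(p_pred, r, trial_index, n_trials, alpha1, alpha2) {
  if (trial_index < 1 || trial_index > n_trials)
    stop("trial_index out of range", call. = FALSE)
  a <- if (trial_index <= n_trials %/% 2) alpha1 else alpha2
  update_static(p_pred, r, a)
}

#' Linear probability weighting
#'
#' Distorts a learned probability linearly around 0.5 and clips to \[0, 1\]:
#' `F(p, gamma) = max(min(gamma * (p - 0.5) + 0.5, 1), 0)`. `gamma = 1` is
#' the identity (risk-neutral); `gamma > 1` compresses probabilities toward
#' the extremes (risk-aversive); `gamma < 1` flattens them toward 0.5
#' (risk-seeking).
#'
#' @param p_pred Probability (vectorized), in \[0, 1\].
#' @param gamma Weighting slope, positive.
#' @return Weighted probabilities in \[0, 1\].
#' @examples
#' weight_probability(c(0.25, 0.5, 0.9), gamma = 2)
#' @export
weight_probability <- function(p_pred, gamma) {
  if (gamma <= 0) stop("gamma must be positive", call. = FALSE)
  pmax(pmin(gamma * (p_pred - 0.5) + 0.5, 1), 0)
}

#' Sigmoidal choice rule
#'
#' Probability of choosing option A given expected values and inverse
#' temperature: `1 / (1 + exp(-beta * (q_A - q_B)))`, evaluated
#' overflow-safely.
#'
#' @param q_A,q_B Expected values of the two options (points).
#' @param beta Inverse temperature, non-negative; `beta = 0` yields random
#'   choice.
#' @return Probability of choosing A.
#' @examples
#' choice_probability(60, 40, 0.05)  # ~0.731
#' @export
choice_probability <- function(q_A, q_B, beta) {
  if (any(beta < 0)) stop("beta must be non-negative", call. = FALSE)
  plogis(beta * (q_A - q_B))
}

# Pack a completed trial tibble into the integer/double arrays the C++
# likelihood kernel consumes.
trials_arrays <- function(trials) {
  chosen <- trials$chosen
  list(
    chosen_A = ifelse(is.na(chosen), -1L, ifelse(chosen == "A", 1L, 0L)),
    reward_A = as.integer(trials$rewarded == "A"),
    mag_A = as.numeric(trials$mag_A),
    mag_B = as.numeric(trials$mag_B),
    block = as.integer(trials$block))
}

#' Run a model over a completed trial log
#'
#' Plays a model forward through an observed trial sequence, computing per
#' trial the (optionally weighted) predicted probabilities, expected values
#' `Q = magnitude x weighted probability`, the choice probability under the
#' sigmoidal rule, and the prediction-error update of the chosen stimulus.
#' The predicted probability is initialized to 0.5 and, by default,
#' re-initialized at every block boundary because the contingency is
#' re-randomized there (`reset_blocks = FALSE` keeps state across blocks).
#' No-response trials contribute no likelihood and trigger no update.
#'
#' @param trials A completed trial tibble (see [simulate_agent()] or
#'   [read_trials()]).
#' @param params An [agent_params()] object.
#' @param reset_blocks Re-initialize the learner at block boundaries?
#' @param assoc_first Pearce-Hall ordering flag, see [update_pearce_hall()].
#' @param S0 Initial associability for the dynamic models.
#'
#' @return A list of class `rl_run` with `trace` (tibble: `trial`, `block`,
#'   `p_pred`, `delta`, `S`, `alpha_t`, `q_A`, `q_B`, `p_choice_A`,
#'   `log_lik`) and `log_lik` (summed over responded trials).
#' @examples
#' cfg <- task_config(rng_seed = 1)
#' pars <- agent_params("s1", alpha = 0.2, beta = 0.1)
#' log <- simulate_agent(pars, cfg, seed = 1)
#' run_model(log, pars)$log_lik
#' @export
run_model <- function(trials, params, reset_blocks = TRUE,
                      assoc_first = TRUE, S0 = 1) {
  stopifnot(inherits(params, "agent_params"))
  if (nrow(trials) == 0L) stop("empty trial list", call. = FALSE)
  model <- params$model
  weighted <- grepl("w$", model)
  gamma <- if (weighted) params$gamma else 1
  beta <- params$beta
  n <- nrow(trials)

  p <- 0.5; S <- S0; cur_block <- trials$block[1]
  out <- tibble::tibble(
    trial = trials$trial, block = trials$block,
    p_pred = NA_real_, delta = NA_real_, S = NA_real_, alpha_t = NA_real_,
    q_A = NA_real_, q_B = NA_real_, p_choice_A = NA_real_, log_lik = 0)

  for (t in seq_len(n)) {
    if (reset_blocks && trials$block[t] != cur_block) {
      cur_block <- trials$block[t]; p <- 0.5; S <- S0
    }
    out$p_pred[t] <- p
    out$S[t] <- if (model %in% c("d1", "d1w")) S else NA_real_
    wA <- if (weighted) weight_probability(p, gamma) else p
    wB <- if (weighted) weight_probability(1 - p, gamma) else 1 - p
    qA <- trials$mag_A[t] * wA
    qB <- trials$mag_B[t] * wB
    pA <- choice_probability(qA, qB, beta)
    out$q_A[t] <- qA; out$q_B[t] <- qB; out$p_choice_A[t] <- pA

    ch <- trials$chosen[t]
    if (is.na(ch)) next
    x <- beta * (qA - qB)
    out$log_lik[t] <- if (ch == "A") plogis(x, log.p = TRUE) else
      plogis(-x, log.p = TRUE)

    pc <- if (ch == "A") p else 1 - p
    rc <- if (ch == "A") as.numeric(trials$rewarded[t] == "A") else
      as.numeric(trials$rewarded[t] == "B")
    up <- switch(model,
      s1 = , s1w = update_static(pc, rc, params$alpha),
      s2 = , s2w = update_asymmetric(pc, rc, params$alpha_pos, params$alpha_neg),
      d1 = , d1w = update_pearce_hall(pc, rc, S, params$mu, params$kappa,
                                      assoc_first = assoc_first),
      d2 = , d2w = update_split_half(pc, rc, t, n, params$alpha1, params$alpha2))
    out$delta[t] <- up$delta
    if (model %in% c("d1", "d1w")) { S <- up$S; out$alpha_t[t] <- up$alpha_t }
    p <- if (ch == "A") up$p_pred else 1 - up$p_pred
  }
  structure(list(trace = out, log_lik = sum(out$log_lik), params = params),
            class = "rl_run")
}

#' Fast log-likelihood of a model on a trial log
#'
#' Compiled equivalent of `run_model(...)$log_lik`, used by the fitting
#' routines; takes a raw parameter vector in the canonical order of
#' [rl_par_names()].
#'
#' @inheritParams run_model
#' @param model Model name.
#' @param par Numeric parameter vector in canonical order.
#' @return Summed log-likelihood over responded trials.
#' @export
rl_log_lik <- function(trials, model, par, reset_blocks = TRUE,
                       assoc_first = TRUE, S0 = 1) {
  a <- trials_arrays(trials)
  rl_loglik_cpp(as.numeric(par), rl_model_id(model), a$chosen_A, a$reward_A,
                a$mag_A, a$mag_B, a$block, reset_blocks, assoc_first, S0)
}

#' Simulate an agent performing the task
#'
#' Builds a task schedule, then plays the model as a generative policy:
#' each trial's choice is sampled from the sigmoidal choice probability,
#' magnitudes are adjusted for repeat choices when enabled, and the outcome
#' is resolved from the pre-drawn rewarded option.
#'
#' @param params An [agent_params()] object.
#' @param config A [task_config()].
#' @param seed Integer seed; fixed seed gives a bit-identical trial log.
#' @param subject_id Optional id recorded on every row.
#' @inheritParams run_model
#' @return A completed trial tibble: `subject_id` (if given), `trial`,
#'   `block`, `high_prob_option`, `mag_A`, `mag_B`, `chosen`, `rewarded`,
#'   `response_made`, `points`.
#' @export
simulate_agent <- function(params, config = task_config(), seed = NULL,
                           subject_id = NULL, reset_blocks = TRUE,
                           assoc_first = TRUE, S0 = 1) {
  stopifnot(inherits(params, "agent_params"))
  with_seed(seed, {
    sched <- build_schedule(config, seed = NULL)
    model <- params$model
    weighted <- grepl("w$", model)
    gamma <- if (weighted) params$gamma else 1
    n <- nrow(sched)
    block <- sched$block
    mag_A <- sched$mag_A; mag_B <- sched$mag_B; rewarded <- sched$rewarded
    chosen <- character(n); points <- integer(n)
    p <- 0.5; S <- S0; cur_block <- block[1]
    history <- character(0)
    for (t in seq_len(n)) {
      if (block[t] != cur_block) {
        cur_block <- block[t]
        history <- character(0)  # repeat-choice counter resets with the block
        if (reset_blocks) { p <- 0.5; S <- S0 }
      }
      rec <- list(mag_A = mag_A[t], mag_B = mag_B[t], rewarded = rewarded[t])
      rec <- apply_magnitude_adjustment(rec, history, config)
      wA <- if (weighted) weight_probability(p, gamma) else p
      wB <- if (weighted) weight_probability(1 - p, gamma) else 1 - p
      pA <- choice_probability(rec$mag_A * wA, rec$mag_B * wB, params$beta)
      ch <- if (runif(1) < pA) "A" else "B"
      rec <- resolve_trial(rec, ch)
      mag_A[t] <- rec$mag_A; mag_B[t] <- rec$mag_B
      chosen[t] <- ch; points[t] <- rec$points
      history <- c(history, ch)
      pc <- if (ch == "A") p else 1 - p
      rc <- as.numeric(rec$rewarded == ch)
      up <- switch(model,
        s1 = , s1w = update_static(pc, rc, params$alpha),
        s2 = , s2w = update_asymmetric(pc, rc, params$alpha_pos, params$alpha_neg),
        d1 = , d1w = update_pearce_hall(pc, rc, S, params$mu, params$kappa,
                                        assoc_first = assoc_first),
        d2 = , d2w = update_split_half(pc, rc, t, n, params$alpha1, params$alpha2))
      if (model %in% c("d1", "d1w")) S <- up$S
      p <- if (ch == "A") up$p_pred else 1 - up$p_pred
    }
    out <- tibble::tibble(
      trial = sched$trial, block = block,
      high_prob_option = sched$high_prob_option,
      mag_A = mag_A, mag_B = mag_B, chosen = chosen, rewarded = rewarded,
      response_made = TRUE, points = points)
    if (!is.null(subject_id))
      out <- dplyr::mutate(out, subject_id = subject_id, .before = 1)
    out
  })
}
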