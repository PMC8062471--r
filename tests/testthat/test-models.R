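test_that("static update follows the delta rule", {
  expect_equal(update_static(0.5, 1, 0.1), list(p_pred = 0.55, delta = 0.5))
  expect_equal(update_static(0.5, 0, 0.1), list(p_pred = 0.45, delta = -0.5))
  up <- update_static(0.3, 0.3, 0.2)  # zero prediction error
  expect_equal(up$p_pred, 0.3)
  expect_equal(up$delta, 0)
  expect_error(update_static(0.5, 1, 1.2), "alpha")
})

test_that("asymmetric update selects the rate by error sign and nests s1", {
  expect_equal(update_asymmetric(0.5, 1, 0.2, 0.05)$p_pred, 0.60)
  expect_equal(update_asymmetric(0.5, 0, 0.2, 0.05)$p_pred, 0.475)
  for (p in c(0.2, 0.5, 0.8)) for (r in 0:1)
    expect_equal(update_asymmetric(p, r, 0.3, 0.3),
                 update_static(p, r, 0.3))
})

test_that("Pearce-Hall update matches hand evaluation and converges", {
  up <- update_pearce_hall(0.5, 1, S = 1, mu = 0.5, kappa = 0.4)
  expect_equal(up$delta, 0.5)
  expect_equal(up$S, 0.75)          # (1-0.5)*1 + 0.5*|0.5|
  expect_equal(up$alpha_t, 0.3)     # 0.4 * 0.75
  expect_equal(up$p_pred, 0.65)     # 0.5 + 0.3*0.5
  # with a constant |delta| stream, S converges to that constant
  S <- 2
  for (i in 1:200) S <- update_pearce_hall(0.5, 1, S, mu = 0.3, kappa = 0.1)$S
  expect_equal(S, 0.5, tolerance = 1e-8)
  # effective rate is clamped so p_pred stays in [0, 1]
  up2 <- update_pearce_hall(0.1, 1, S = 5, mu = 0.2, kappa = 0.9)
  expect_lte(up2$alpha_t, 1)
  expect_lte(up2$p_pred, 1)
  expect_error(update_pearce_hall(0.5, 1, S = -1, mu = 0.5, kappa = 0.4), "S")
})

test_that("split-half update switches rate at mid-session", {
  expect_equal(update_split_half(0.5, 1, 30, 60, 0.1, 0.3)$p_pred, 0.55)
  expect_equal(update_split_half(0.5, 1, 31, 60, 0.1, 0.3)$p_pred, 0.65)
  expect_equal(update_split_half(0.5, 1, 40, 60, 0.1, 0.3)$p_pred, 0.65)
  expect_identical(update_split_half(0.4, 0, 10, 60, 0.2, 0.2),
                   update_static(0.4, 0, 0.2))
  expect_error(update_split_half(0.5, 1, 61, 60, 0.1, 0.3), "trial_index")
})

test_that("probability weighting is the clipped linear distortion", {
  p <- seq(0, 1, by = 0.05)
  expect_equal(weight_probability(p, 1), p)           # identity at gamma = 1
  for (g in c(0.3, 1, 2, 5)) {
    expect_equal(weight_probability(0.5, g), 0.5)     # fixed point at 0.5
    w <- weight_probability(p, g)
    expect_true(all(w >= 0 & w <= 1))
  }
  expect_equal(weight_probability(0.25, 2), 0)
  expect_equal(weight_probability(0.9, 2), 1)
  expect_error(weight_probability(0.5, 0), "gamma")
})

test_that("choice rule is sigmoidal, symmetric and overflow-safe", {
  expect_equal(choice_probability(40, 40, 0.3), 0.5)
  expect_equal(choice_probability(10, 90, 0), 0.5)
  expect_equal(choice_probability(60, 40, 0.05), 1 / (1 + exp(-1)))
  expect_equal(choice_probability(10, 80, 0.2),
               1 - choice_probability(80, 10, 0.2))
  big <- choice_probability(99, 1, 1e6)
  expect_true(is.finite(big) && big > 0 && big <= 1)
  expect_error(choice_probability(1, 2, -0.1), "beta")
})

test_that("run_model matches a naive trial-by-trial reimplementation", {
  set.seed(101)
  for (i in 1:20) {
    model <- sample(rl_model_names(), 1)
    par <- random_params(model)
    trials <- random_trials(seed = 200 + i, p_none = 0.05)
    params <- do.call(agent_params, c(list(model = model), as.list(par)))
    r <- run_model(trials, params)
    expect_equal(r$log_lik, naive_loglik(trials, model, par),
                 tolerance = 1e-10)
    expect_equal(rl_log_lik(trials, model, par), r$log_lik,
                 tolerance = 1e-10)
  }
})

test_that("model nesting holds on identical data", {
  trials <- random_trials(seed = 3)
  a <- 0.22; b <- 0.12; g <- 1
  ll <- function(model, ...) {
    pars <- do.call(agent_params, c(list(model = model), list(...)))
    run_model(trials, pars)$log_lik
  }
  base <- ll("s1", alpha = a, beta = b)
  expect_equal(ll("s2", alpha_pos = a, alpha_neg = a, beta = b), base,
               tolerance = 1e-10)
  expect_equal(ll("d2", alpha1 = a, alpha2 = a, beta = b), base,
               tolerance = 1e-10)
  expect_equal(ll("s1w", alpha = a, gamma = 1, beta = b), base,
               tolerance = 1e-10)
  expect_equal(ll("s2w", alpha_pos = a, alpha_neg = a, gamma = 1, beta = b),
               base, tolerance = 1e-10)
  expect_equal(ll("d2w", alpha1 = a, alpha2 = a, gamma = 1, beta = b), base,
               tolerance = 1e-10)
  expect_equal(ll("d1w", mu = 0.4, kappa = 0.5, gamma = 1, beta = b),
               ll("d1", mu = 0.4, kappa = 0.5, beta = b), tolerance = 1e-10)
})

test_that("latent probabilities stay complementary and bounded", {
  set.seed(77)
  for (i in 1:10) {
    model <- sample(rl_model_names(), 1)
    par <- random_params(model)
    params <- do.call(agent_params, c(list(model = model), as.list(par)))
    tr <- run_model(random_trials(seed = 400 + i), params)$trace
    expect_true(all(tr$p_pred >= 0 & tr$p_pred <= 1))
    expect_true(all(tr$p_choice_A >= 0 & tr$p_choice_A <= 1))
    # p_pred(B) = 1 - p_pred(A) by representation; Q uses both sides
    expect_true(all(is.finite(tr$q_A) & is.finite(tr$q_B)))
  }
})

test_that("random-policy likelihood is n*log(1/2) and states init at 0.5", {
  trials <- random_trials(seed = 9)
  pars <- agent_params("s1", alpha = 0.1, beta = 0)
  r <- run_model(trials, pars)
  expect_equal(r$log_lik, 60 * log(0.5), tolerance = 1e-12)
  expect_equal(r$trace$p_pred[1], 0.5)
  # re-initialization at each block boundary (contingency re-randomized)
  expect_equal(r$trace$p_pred[trials$trial %in% c(21, 41)], c(0.5, 0.5))
  # and carry-over when block resets are disabled
  pars2 <- agent_params("s1", alpha = 0.9, beta = 0.1)
  tr2 <- run_model(trials, pars2, reset_blocks = FALSE)$trace
  expect_false(isTRUE(all.equal(tr2$p_pred[21], 0.5)))
})

test_that("no-response trials are excluded from likelihood and updates", {
  trials <- random_trials(seed = 12)
  trials$chosen[c(5, 25)] <- NA
  trials$response_made[c(5, 25)] <- FALSE
  pars <- agent_params("s1", alpha = 0.3, beta = 0.1)
  ll_with <- run_model(trials, pars)$log_lik
  # dropping the rows entirely must give the same s1 likelihood
  ll_drop <- run_model(trials[-c(5, 25), ], pars)$log_lik
  expect_equal(ll_with, ll_drop, tolerance = 1e-12)
})

test_that("simulated agents are deterministic and sensitive to beta", {
  pars <- agent_params("s1w", alpha = 0.3, gamma = 1, beta = 1)
  cfg <- task_config()
  expect_identical(simulate_agent(pars, cfg, seed = 5),
                   simulate_agent(pars, cfg, seed = 5))
  # a sharp (beta = 1) learner beats chance on expected value
  props <- vapply(1:40, function(i)
    score_correct_choices(simulate_agent(pars, cfg, seed = i))$prop_correct,
    numeric(1))
  expect_gt(mean(props), 0.5)
  # a beta = 0 agent is at chance
  pars0 <- agent_params("s1", alpha = 0.3, beta = 0)
  props0 <- vapply(1:40, function(i)
    score_correct_choices(simulate_agent(pars0, cfg, seed = i))$prop_correct,
    numeric(1))
  se <- sd(props0) / sqrt(length(props0))
  expect_lt(abs(mean(props0) - 0.5), 3 * se + 0.02)
})

test_that("agent_params enforces each model's free-parameter set", {
  expect_error(agent_params("s1", alpha = 0.1), "beta")
  expect_error(agent_params("s1", alpha = 0.1, beta = 0.1, gamma = 1),
               "exactly")
  expect_error(agent_params("s1", alpha = 1.2, beta = 0.1), "alpha")
  expect_error(agent_params("s1w", alpha = 0.2, gamma = -1, beta = 0.1),
               "gamma")
  expect_error(agent_params("s1", alpha = 0.2, beta = -0.1), "beta")
  m <- rl_models()
  expect_equal(m$n_params, c(2L, 3L, 3L, 3L, 3L, 4L, 4L, 4L))
  expect_equal(sum(m$weighted), 4L)
})
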