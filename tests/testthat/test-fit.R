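test_that("default priors are proper densities on their supports", {
  pr <- default_priors()
  for (nm in names(pr)) {
    p <- pr[[nm]]
    dens <- function(x) exp(prior_log_density(p, x))
    upper <- if (p$family == "beta") 1 else Inf
    expect_equal(integrate(dens, 0, upper, rel.tol = 1e-9)$value, 1,
                 tolerance = 1e-6, label = paste("prior", nm))
  }
  # outside-support densities are -Inf on the log scale
  expect_identical(prior_log_density(pr$alpha, -0.1), -Inf)
  expect_identical(prior_log_density(pr$alpha, 1.5), -Inf)
  expect_identical(prior_log_density(pr$beta, -1), -Inf)
  # documented shapes: Gamma(2.8, scale 0.05) has mean 0.14
  expect_equal(pr$beta$a * pr$beta$b, 0.14)
  # the sensitivity set swaps only the learning-rate prior
  alt <- default_priors("beta22")
  expect_equal(alt$alpha, list(family = "beta", a = 2, b = 2))
  expect_equal(alt$gamma, default_priors()$gamma)
})

test_that("log posterior decomposes into likelihood plus log priors", {
  trials <- random_trials(seed = 21)
  pr <- default_priors()
  par <- c(alpha = 0.1, beta = 0.12)
  lp <- log_posterior(trials, "s1", par, pr)
  expect_equal(lp,
               rl_log_lik(trials, "s1", par) +
                 prior_log_density(pr$alpha, 0.1) +
                 prior_log_density(pr$beta, 0.12),
               tolerance = 1e-12)
  expect_identical(log_posterior(trials, "s1", c(alpha = -0.2, beta = 0.1)),
                   -Inf)
  # flat (uniform) priors reduce the posterior to the likelihood
  flat <- default_priors()
  flat$alpha <- flat$beta <- list(family = "beta", a = 1, b = 1)
  expect_equal(log_posterior(trials, "s1", par, flat),
               rl_log_lik(trials, "s1", par), tolerance = 1e-12)
})

test_that("fit_map is deterministic and monotone in restarts", {
  trials <- simulate_agent(agent_params("s1", alpha = 0.15, beta = 0.15),
                           task_config(), seed = 31)
  f1 <- fit_map(trials, "s1", n_restarts = 5, seed = 99)
  f2 <- fit_map(trials, "s1", n_restarts = 5, seed = 99)
  expect_identical(f1$theta_map, f2$theta_map)
  expect_identical(f1$log_evidence, f2$log_evidence)
  single <- fit_map(trials, "s1", n_restarts = 1, seed = 99)
  many <- fit_map(trials, "s1", n_restarts = 25, seed = 99)
  expect_gte(many$log_post, single$log_post)
  expect_error(fit_map(trials, "s1", n_restarts = 0), "n_restarts")
  g <- glance(f1)
  expect_equal(g$n_params, 2L)
  expect_equal(tidy(f1)$term, c("alpha", "beta"))
})

test_that("fit_map attains the dense grid-search optimum (s1)", {
  pr <- default_priors()
  for (s in 1:2) {
    trials <- simulate_agent(
      agent_params("s1", alpha = 0.12, beta = 0.1), task_config(), seed = 50 + s)
    grid <- as.matrix(expand.grid(alpha = seq(0.002, 0.998, length.out = 200),
                                  beta = seq(0.002, 1, length.out = 200)))
    a <- banditfit:::trials_arrays(trials)
    ll <- banditfit:::rl_loglik_batch(grid, 1L, a$chosen_A, a$reward_A,
                                      a$mag_A, a$mag_B, a$block, TRUE, TRUE, 1)
    lp <- ll + dbeta(grid[, 1], pr$alpha$a, pr$alpha$b, log = TRUE) +
      dgamma(grid[, 2], shape = pr$beta$a, scale = pr$beta$b, log = TRUE)
    fit <- fit_map(trials, "s1", n_restarts = 30, seed = 7)
    expect_gte(fit$log_post, max(lp) - 0.05)
  }
})

test_that("Laplace evidence is exact for a Gaussian and near-exact for
           Beta-Bernoulli", {
  # unnormalized standard normal: evidence sqrt(2*pi)
  lap <- laplace_evidence(function(x) -x^2 / 2, 0)
  expect_true(lap$hessian_ok)
  expect_equal(lap$log_evidence, 0.5 * log(2 * pi), tolerance = 1e-6)
  # Bernoulli likelihood with Beta(2, 2) prior, n = 60: exact marginal is
  # B(2 + k, 2 + n - k) / B(2, 2)
  set.seed(8)
  y <- rbinom(60, 1, 0.7)
  k <- sum(y); n <- length(y)
  logpost <- function(th) {
    if (th <= 0 || th >= 1) return(-Inf)
    k * log(th) + (n - k) * log(1 - th) + dbeta(th, 2, 2, log = TRUE)
  }
  map <- (k + 1) / (n + 2)  # mode of Beta(2 + k, 2 + n - k)
  lap2 <- laplace_evidence(logpost, map)
  exact <- lbeta(2 + k, 2 + n - k) - lbeta(2, 2)
  expect_equal(lap2$log_evidence, exact, tolerance = 0.1)
})

test_that("a flat mode yields hessian_ok = FALSE and missing evidence", {
  lap <- laplace_evidence(function(x) 0 * x[1], c(0.5))
  expect_false(lap$hessian_ok)
  expect_true(is.na(lap$log_evidence))
})

test_that("compare_models averages evidence, breaks ties to simplicity, and
           guards against missing cells", {
  fits <- tibble::tibble(
    subject_id = rep(c("a", "b"), each = 2),
    model = rep(c("s1", "s1w"), 2),
    log_evidence = c(-30, -30, -32, -32))
  cmp <- compare_models(fits)
  expect_equal(cmp$model[cmp$winner], "s1")  # tie on means -> fewer params
  one <- compare_models(tibble::tibble(subject_id = "a",
                                       model = c("s1", "s2"),
                                       log_evidence = c(-10, -9)))
  expect_equal(one$model[one$winner], "s2")
  fits$log_evidence[1] <- NA
  expect_error(compare_models(fits), "missing")
})

test_that("the fitted s1 learning rate recovers a known generative value", {
  errs <- vapply(1:12, function(i) {
    trials <- simulate_agent(agent_params("s1", alpha = 0.1, beta = 0.1),
                             task_config(), seed = 600 + i)
    fit <- fit_map(trials, "s1", n_restarts = 20, seed = i)
    abs(fit$theta_map[["alpha"]] - 0.1)
  }, numeric(1))
  expect_lt(median(errs), 0.1)
})
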