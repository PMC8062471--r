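make_perf_trials <- function(chooser, seed = 1) {
  # deterministic chooser applied to a fixed schedule
  s <- build_schedule(task_config(rng_seed = seed))
  s$chosen <- chooser(s)
  s$response_made <- !is.na(s$chosen)
  s
}

test_that("correctness is the true-probability x magnitude comparison", {
  tr <- tibble::tibble(
    trial = 1:3, block = 1L, high_prob_option = "A",
    mag_A = c(40L, 25L, 10L), mag_B = c(60L, 75L, 90L),
    chosen = c("A", "A", "A"), rewarded = "A", response_made = TRUE)
  # EV_A = .75*40 = 30 > EV_B = .25*60 = 15: correct
  # EV 18.75 vs 18.75: tied, excluded; EV 7.5 vs 22.5: incorrect
  sc <- score_correct_choices(tr)
  expect_equal(sc$n_scored, 2L)
  expect_equal(sc$prop_correct, 0.5)
  # an agent always choosing the higher-EV option scores 1
  best <- make_perf_trials(function(s) {
    pA <- ifelse(s$high_prob_option == "A", 0.75, 0.25)
    ifelse(pA * s$mag_A > (1 - pA) * s$mag_B, "A", "B")
  })
  expect_equal(score_correct_choices(best)$prop_correct, 1)
  # undefined proportion is flagged
  tied <- tr[2, ]
  expect_warning(score_correct_choices(tied), "undefined")
})

test_that("scoring agrees exactly with the brute-force EV oracle", {
  for (i in 1:200) {
    tr <- random_trials(seed = 5000 + i, p_none = 0.05)
    expect_identical(score_correct_choices(tr)$prop_correct,
                     naive_prop_correct(tr))
  }
})

test_that("block proportions reconstruct the overall proportion", {
  for (i in 1:20) {
    tr <- random_trials(seed = 7000 + i, p_none = 0.1)
    sc <- score_correct_choices(tr)
    b <- sc$blocks[[1]]
    expect_equal(sum(b$prop_correct * b$n_scored) / sum(b$n_scored),
                 sc$prop_correct, tolerance = 1e-12)
  }
})

test_that("two-way ANOVA F statistics match hand-computed sums of squares", {
  set.seed(4)
  d <- tidyr::expand_grid(sex = c("male", "female"),
                          stress_group = c("low", "high"), rep = 1:3)
  d$prop_correct <- round(runif(nrow(d), 0.4, 0.9), 3)
  res <- group_contrasts(d)$anova
  hand <- hand_anova_2x2(d$prop_correct, d$sex, d$stress_group)
  expect_equal(res$statistic[res$term == "sex"], hand$F1, tolerance = 1e-8)
  expect_equal(res$statistic[res$term == "stress_group"], hand$F2,
               tolerance = 1e-8)
  expect_equal(res$statistic[res$term == "sex:stress_group"], hand$F12,
               tolerance = 1e-8)
  expect_error(group_contrasts(dplyr::mutate(d, sex = "male")), "sex")
})

test_that("blockwise repeated-measures variant reports within-subject terms", {
  co <- generate_cohort(cohort_spec(n_per_group = 4, seed = 9))
  d <- dplyr::left_join(cohort_performance(co),
                        dplyr::select(co, -"trials"), by = "subject_id")
  res <- group_contrasts(d)
  expect_false(is.null(res$blockwise))
  expect_true("block" %in% res$blockwise$term)
  expect_true(any(grepl("block", res$blockwise$stratum)))
  expect_equal(nrow(res$cell_means), 4)
})

test_that("sex coefficient flips sign exactly under reversed coding", {
  set.seed(11)
  d <- tibble::tibble(
    sex = rep(c("male", "female"), each = 10),
    stress_group = "high",
    prop_correct = runif(20, 0.4, 0.9))
  b <- sex_difference_glm(d, covariates = character(0))
  d_flip <- dplyr::mutate(d, sex = ifelse(sex == "male", "female", "male"))
  b_flip <- sex_difference_glm(d_flip, covariates = character(0))
  expect_equal(b$estimate, -b_flip$estimate, tolerance = 1e-12)
  expect_equal(b$std.error, b_flip$std.error, tolerance = 1e-12)
})

test_that("a gamma-driven sex gap is absorbed by the gamma covariate only", {
  # built to have known structure: performance depends on gamma alone and
  # gamma differs by sex; alpha is independent noise
  set.seed(21)
  n <- 40
  d <- tibble::tibble(
    sex = rep(c("male", "female"), each = n / 2),
    stress_group = "high",
    gamma = rnorm(n, ifelse(sex == "male", 1.1, 1.6), 0.15),
    alpha = rnorm(n, 0.15, 0.04),
    prop_correct = 1.1 - 0.35 * gamma + rnorm(n, 0, 0.02))
  res <- sex_difference_glm(d)
  b0 <- res$estimate[res$covariate == "none" & res$scope == "overall"]
  expect_gt(b0, 0)  # males (coded 1) perform better here
  att_g <- res$attenuation[res$covariate == "gamma" & res$scope == "overall"]
  att_a <- res$attenuation[res$covariate == "alpha" & res$scope == "overall"]
  expect_gte(att_g, 0.5)
  expect_lt(att_a, 0.5)
})

test_that("null cohorts leave the sex coefficient near zero", {
  covered <- vapply(1:30, function(i) {
    set.seed(300 + i)
    d <- tibble::tibble(sex = rep(c("male", "female"), each = 10),
                        stress_group = "high",
                        prop_correct = rnorm(20, 0.7, 0.1))
    r <- sex_difference_glm(d, covariates = character(0))
    abs(r$estimate[r$scope == "overall"]) <
      2 * r$std.error[r$scope == "overall"]
  }, logical(1))
  expect_gte(mean(covered), 0.9)
})

test_that("parameter-performance regression finds structure and flags
           degenerate predictors", {
  set.seed(31)
  d <- tibble::tibble(
    sex = rep(c("male", "female"), each = 20),
    gamma = runif(40, 0.8, 2),
    alpha = 0.15,
    prop_correct = 0.95 - 0.25 * gamma + rnorm(40, 0, 0.03))
  res <- parameter_performance_regression(d)
  g <- dplyr::filter(res, parameter == "gamma")
  expect_true(all(g$slope < 0))
  expect_true(all(g$p.value < 0.01))
  expect_true(all(g$r.squared > 0.5))
  a <- dplyr::filter(res, parameter == "alpha")
  expect_true(all(a$note == "constant predictor"))
  expect_true(all(a$r.squared == 0))
  # permuted labels kill the association
  set.seed(32)
  d_perm <- dplyr::mutate(d, prop_correct = sample(prop_correct))
  res_p <- parameter_performance_regression(d_perm)
  expect_true(all(dplyr::filter(res_p, parameter == "gamma")$r.squared < 0.2))
})

test_that("model validation recovers positive coefficients from model-true
           data and nulls from random choosers", {
  co <- generate_cohort(cohort_spec(n_per_group = 4, seed = 41))
  fits <- fit_cohort(co, models = "s1w", n_restarts = 10, seed = 42)
  v <- validate_model_regression(co, fits, model = "s1w")
  expect_true(all(c("mag_diff", "wp_diff") %in% v$group_tests$term))
  expect_true(all(v$group_tests$mean > 0))
  expect_true(all(v$group_tests$p.value < 0.05))
  # beta = 0 subjects: coefficients centered on zero
  co0 <- co
  co0$trials <- lapply(seq_len(nrow(co0)), function(i)
    simulate_agent(agent_params("s1", alpha = 0.2, beta = 0),
                   task_config(), seed = 500 + i,
                   subject_id = co0$subject_id[i]))
  fits0 <- fit_cohort(co0, models = "s1w", n_restarts = 10, seed = 43)
  v0 <- validate_model_regression(co0, fits0, model = "s1w")
  expect_true(all(v0$group_tests$p.value > 0.01))
})
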