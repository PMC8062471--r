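#' Score correct choices against true expected value
#'
#' A choice is "correct" when the chosen option's true expected value --
#' its true reward probability (`p_high` for the block's high-probability
#' option, `1 - p_high` for the other) times its displayed magnitude --
#' exceeds the other option's. Trials where the two expected values tie
#' exactly (possible with complementary magnitudes, e.g. 25 vs 75 at
#' 0.75/0.25) are excluded from the denominator, as are no-response trials.
#'
#' @param trials A completed trial tibble for one subject.
#' @param p_high True reward probability of the high-probability option.
#' @return A one-row tibble: `prop_correct`, `n_scored` (responded,
#'   untied), `n_responded`, and a `blocks` list-column with the per-block
#'   breakdown (`block`, `prop_correct`, `n_scored`, `n_responded`).
#' @examples
#' log <- simulate_agent(agent_params("s1w", alpha = 0.1, gamma = 1, beta = 1),
#'                       task_config(), seed = 1)
#' score_correct_choices(log)
#' @export
score_correct_choices <- function(trials, p_high = 0.75) {
  t <- score_trials(trials, p_high)
  if (all(is.na(t$correct)))
    warning("proportion correct undefined: every trial tied or unresponded",
            call. = FALSE)
  blocks <- t |>
    dplyr::group_by(block = .data$block) |>
    dplyr::summarise(prop_correct = mean(.data$correct, na.rm = TRUE),
                     n_scored = sum(!is.na(.data$correct)),
                     n_responded = sum(.data$response_made),
                     .groups = "drop")
  tibble::tibble(
    prop_correct = mean(t$correct, na.rm = TRUE),
    n_scored = sum(!is.na(t$correct)),
    n_responded = sum(t$response_made),
    blocks = list(blocks))
}

# Per-trial correctness flags: TRUE/FALSE for scored trials, NA for ties
# and no-response trials.
score_trials <- function(trials, p_high = 0.75) {
  ev_A <- ifelse(trials$high_prob_option == "A", p_high, 1 - p_high) *
    trials$mag_A
  ev_B <- ifelse(trials$high_prob_option == "B", p_high, 1 - p_high) *
    trials$mag_B
  correct <- dplyr::case_when(
    !trials$response_made | is.na(trials$chosen) ~ NA,
    ev_A == ev_B ~ NA,
    trials$chosen == "A" ~ ev_A > ev_B,
    TRUE ~ ev_B > ev_A)
  dplyr::mutate(trials, ev_A = ev_A, ev_B = ev_B, correct = correct)
}

#' Per-subject task performance for a cohort
#'
#' Applies [score_correct_choices()] to each subject of a cohort tibble and
#' returns a flat performance table, with per-block proportions spread into
#' `prop_block_<b>` columns.
#'
#' @param cohort Cohort tibble with `subject_id` and `trials` columns.
#' @inheritParams score_correct_choices
#' @return A tibble: `subject_id`, `prop_correct`, `n_scored`,
#'   `n_responded`, `prop_block_1`, ...
#' @export
cohort_performance <- function(cohort, p_high = 0.75) {
  purrr::map2(cohort$subject_id, cohort$trials, function(sid, tr) {
    s <- score_correct_choices(tr, p_high)
    b <- s$blocks[[1]]
    wide <- setNames(as.list(b$prop_correct),
                     paste0("prop_block_", b$block))
    tibble::tibble(subject_id = sid, prop_correct = s$prop_correct,
                   n_scored = s$n_scored, n_responded = s$n_responded, !!!wide)
  }) |> dplyr::bind_rows()
}

#' Sex-by-stress factorial contrasts on task performance
#'
#' Two-way factorial ANOVA (type-II sums of squares) of the proportion of
#' correct choices on sex, stress group and their interaction, plus
#' uncorrected pairwise sex contrasts within each stress level, and a
#' repeated-measures variant with block as a within-subject factor.
#'
#' @param data Tibble with one row per subject: `prop_correct`, `sex`,
#'   `stress_group`, and `prop_block_*` columns for the block-wise variant
#'   (join [cohort_performance()] with the cohort).
#' @return A list of class `group_contrasts`: `anova` (term, df, F,
#'   p.value), `posthoc` (stress level, difference male - female, t, df,
#'   p.value), `blockwise` (within-subject ANOVA table), `cell_means`.
#' @export
group_contrasts <- function(data) {
  for (v in c("sex", "stress_group"))
    if (length(unique(data[[v]])) < 2)
      stop(sprintf("factor %s has fewer than two levels", v), call. = FALSE)
  cells <- table(data$sex, data$stress_group)
  if (any(cells < 2))
    warning("a sex x stress cell has fewer than two subjects", call. = FALSE)

  d <- dplyr::mutate(data, sex = factor(.data$sex),
                     stress_group = factor(.data$stress_group))
  fit <- lm(prop_correct ~ sex * stress_group, data = d)
  a2 <- car::Anova(fit, type = 2)
  anova_tbl <- tibble::tibble(
    term = rownames(a2), df = a2$Df, statistic = a2$`F value`,
    p.value = a2$`Pr(>F)`) |>
    dplyr::filter(.data$term != "Residuals")

  posthoc <- purrr::map(levels(d$stress_group), function(sl) {
    sub <- dplyr::filter(d, .data$stress_group == sl)
    if (min(table(sub$sex)) < 2) return(NULL)
    tt <- t.test(prop_correct ~ sex, data = sub, var.equal = TRUE)
    tibble::tibble(stress_group = sl,
                   contrast = "male - female",
                   estimate = unname(diff(tt$estimate)),
                   statistic = -unname(tt$statistic),  # t.test is female - male
                   df = unname(tt$parameter), p.value = tt$p.value)
  }) |> dplyr::bind_rows()

  blockwise <- NULL
  block_cols <- grep("^prop_block_", names(d), value = TRUE)
  if (length(block_cols) >= 2) {
    long <- d |>
      dplyr::mutate(.subject = dplyr::row_number()) |>
      tidyr::pivot_longer(dplyr::all_of(block_cols), names_to = "block",
                          names_prefix = "prop_block_",
                          values_to = "prop_block") |>
      dplyr::mutate(block = factor(.data$block),
                    .subject = factor(.data$.subject))
    aov_fit <- aov(prop_block ~ sex * stress_group * block +
                     Error(.subject / block), data = long)
    s <- summary(aov_fit)
    blockwise <- purrr::imap(s, function(tab, stratum) {
      tt <- tab[[1]]
      tibble::tibble(stratum = stratum,
                     term = trimws(rownames(tt)),
                     df = tt$Df, statistic = tt$`F value`,
                     p.value = tt$`Pr(>F)`)
    }) |> dplyr::bind_rows() |>
      dplyr::filter(.data$term != "Residuals")
  }

  cell_means <- d |>
    dplyr::group_by(.data$sex, .data$stress_group) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$prop_correct),
                     sd = sd(.data$prop_correct), .groups = "drop")

  structure(list(anova = anova_tbl, posthoc = posthoc, blockwise = blockwise,
                 cell_means = cell_means),
            class = "group_contrasts")
}

#' @export
print.group_contrasts <- function(x, ...) {
  cat("Two-way ANOVA (type II) on proportion correct\n")
  print(x$anova)
  cat("\nPairwise sex contrasts within stress level\n")
  print(x$posthoc)
  invisible(x)
}

#' Covariate-adjusted sex difference in performance
#'
#' Quantifies the sex difference in proportion correct among the high-stress
#' subjects with a linear model, coding male = 1 and female = 0, then
#' re-estimates it controlling each requested fitted parameter as a
#' covariate. The attenuation statistic `1 - b_adjusted / b_unadjusted`
#' measures how much of the sex coefficient the covariate absorbs. Run
#' overall and per block.
#'
#' @param data One row per subject with `prop_correct`, `prop_block_*`,
#'   `sex`, `stress_group`, and the fitted-parameter columns named by
#'   `covariates` (e.g. join with a winning-model fit table).
#' @param covariates Character vector of covariate column names to adjust
#'   for, each in its own model (default `c("alpha", "gamma")`).
#' @param stress_level Subset analyzed (default `"high"`; use `NULL` for
#'   all subjects).
#' @return A tibble: `scope` (`"overall"` or block id), `covariate`
#'   (`"none"` or the adjusted column), `estimate` (unstandardized sex
#'   coefficient), `std.error`, `p.value`, `attenuation` (vs the same
#'   scope's unadjusted coefficient; NA for the unadjusted rows).
#' @export
sex_difference_glm <- function(data, covariates = c("alpha", "gamma"),
                               stress_level = "high") {
  d <- if (is.null(stress_level)) data else
    dplyr::filter(data, .data$stress_group == stress_level)
  if (nrow(d) == 0) stop("no subjects in the requested stress level",
                         call. = FALSE)
  d$male <- as.integer(d$sex == "male")
  scopes <- c(overall = "prop_correct",
              setNames(grep("^prop_block_", names(d), value = TRUE),
                       sub("prop_", "", grep("^prop_block_", names(d),
                                             value = TRUE))))
  rows <- purrr::imap(scopes, function(ycol, scope) {
    fit0 <- lm(stats::reformulate("male", ycol), data = d)
    b0 <- coef(summary(fit0))["male", ]
    base <- tibble::tibble(scope = scope, covariate = "none",
                           estimate = b0[["Estimate"]],
                           std.error = b0[["Std. Error"]],
                           p.value = b0[["Pr(>|t|)"]], attenuation = NA_real_)
    adj <- purrr::map(covariates, function(cv) {
      fit1 <- lm(stats::reformulate(c("male", cv), ycol), data = d)
      kappa_x <- kappa(stats::model.matrix(fit1))
      if (kappa_x > 1e8)
        warning(sprintf("covariate %s nearly collinear (condition number %.2g)",
                        cv, kappa_x), call. = FALSE)
      b1 <- coef(summary(fit1))["male", ]
      tibble::tibble(scope = scope, covariate = cv,
                     estimate = b1[["Estimate"]],
                     std.error = b1[["Std. Error"]],
                     p.value = b1[["Pr(>|t|)"]],
                     attenuation = 1 - b1[["Estimate"]] / b0[["Estimate"]])
    }) |> dplyr::bind_rows()
    dplyr::bind_rows(base, adj)
  })
  dplyr::bind_rows(rows)
}

#' Regress task performance on fitted parameters, per sex
#'
#' Simple linear regressions of the proportion of correct choices on each
#' fitted parameter (by default the learning rate and the probability
#' weighting slope of the winning model), within each sex.
#'
#' @param data One row per subject with `prop_correct`, `sex`, and the
#'   parameter columns.
#' @param params Parameter column names to regress on.
#' @param by_sex Stratify by sex? If `FALSE`, one stratum `"all"`.
#' @return A tibble: `sex`, `parameter`, `n`, `slope`, `r.squared`,
#'   `p.value` (slope and p NA, with a note, when the predictor is
#'   constant).
#' @export
parameter_performance_regression <- function(data,
                                             params = c("alpha", "gamma"),
                                             by_sex = TRUE) {
  strata <- if (by_sex) split(data, data$sex) else list(all = data)
  purrr::imap(strata, function(d, sx) {
    purrr::map(params, function(pv) {
      if (nrow(d) < 3 || sum(complete.cases(d[, c("prop_correct", pv)])) < 3)
        return(NULL)
      if (sd(d[[pv]], na.rm = TRUE) == 0)
        return(tibble::tibble(sex = sx, parameter = pv, n = nrow(d),
                              slope = NA_real_, r.squared = 0,
                              p.value = NA_real_, note = "constant predictor"))
      fit <- lm(stats::reformulate(pv, "prop_correct"), data = d)
      sm <- summary(fit)
      tibble::tibble(sex = sx, parameter = pv, n = nrow(d),
                     slope = coef(fit)[[pv]], r.squared = sm$r.squared,
                     p.value = coef(sm)[pv, "Pr(>|t|)"], note = NA_character_)
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
}

#' Validate the winning model against choice behavior
#'
#' Two-stage (summary-statistics) check that choices track both components
#' of the modeled expected value: for each subject, a logistic regression
#' of the choose-A indicator on the standardized magnitude difference
#' `mag_A - mag_B` and the model-estimated weighted-probability difference
#' `F(p_A) - F(p_B)`; then one-sample t-tests of the per-subject
#' coefficients against zero at the group level. Subjects whose regression
#' separates (unbounded coefficients) are flagged and excluded from the
#' group tests.
#'
#' @param cohort Cohort tibble with `subject_id` and `trials`.
#' @param fits Fit table (from [fit_cohort()]) for the model named by
#'   `model`; per-subject parameters are taken from it.
#' @param model Model whose latent trace supplies the probability term.
#' @return A list of class `model_validation`: `subject_coefs` (tibble:
#'   `subject_id`, `term`, `estimate`, `separated`) and `group_tests`
#'   (tibble: `term`, `n`, `mean`, `statistic`, `df`, `p.value`).
#' @export
validate_model_regression <- function(cohort, fits, model = "s1w") {
  f <- dplyr::filter(fits, .data$model == !!model)
  coefs <- purrr::map(seq_len(nrow(cohort)), function(i) {
    sid <- cohort$subject_id[i]
    fr <- dplyr::filter(f, .data$subject_id == sid)
    if (nrow(fr) != 1) return(NULL)
    pars <- do.call(agent_params, c(list(model = model),
      as.list(fr[rl_par_names(model)])))
    tr <- cohort$trials[[i]]
    trace <- run_model(tr, pars)$trace
    gamma <- if (grepl("w$", model)) fr$gamma else 1
    wp_A <- weight_probability(trace$p_pred, gamma)
    wp_B <- weight_probability(1 - trace$p_pred, gamma)
    d <- tibble::tibble(
      y = as.integer(tr$chosen == "A"),
      mag_diff = as.numeric(scale(tr$mag_A - tr$mag_B)),
      wp_diff = as.numeric(scale(wp_A - wp_B)))
    d <- d[tr$response_made, ]
    sep <- FALSE
    g <- withCallingHandlers(
      glm(y ~ mag_diff + wp_diff, data = d, family = binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
          sep <<- TRUE
        invokeRestart("muffleWarning")
      })
    if (any(abs(coef(g)[-1]) > 15, na.rm = TRUE)) sep <- TRUE
    tibble::tibble(subject_id = sid,
                   term = c("mag_diff", "wp_diff"),
                   estimate = unname(coef(g)[c("mag_diff", "wp_diff")]),
                   separated = sep)
  }) |> dplyr::bind_rows()

  usable <- dplyr::filter(coefs, !.data$separated, is.finite(.data$estimate))
  group <- usable |>
    dplyr::group_by(.data$term) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$estimate),
                     statistic = t.test(.data$estimate)$statistic,
                     df = unname(t.test(.data$estimate)$parameter),
                     p.value = t.test(.data$estimate)$p.value,
                     .groups = "drop")
  structure(list(subject_coefs = coefs, group_tests = group),
            class = "model_validation")
}
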