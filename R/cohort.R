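#' Specify a synthetic sex-by-stress cohort
#'
#' Defines the generative structure of a simulated study population: four
#' groups (male/female crossed with low/high perceived stress), per-group
#' distributions of the generative model parameters, and per-group
#' Perceived Stress Scale (PSS, 0-40) score distributions. The defaults
#' emulate the qualitative group pattern the analysis stage is built to
#' detect: under high stress, females carry a higher mean probability
#' weighting `gamma` than males (1.6 vs 1.1; both low-stress groups 1.2),
#' and under low stress females carry a higher mean learning rate `alpha`
#' than males (0.20 vs 0.10; both high-stress groups 0.15). PSS scores are
#' drawn from discretized normals truncated to respect the group's side of
#' the stress threshold (low 14.89 +/- 3.06, high 23.17 +/- 3.79).
#'
#' @param n_per_group Subjects per sex x stress cell (>= 2).
#' @param model Generative model name (default `"s1w"`).
#' @param gamma_mean,gamma_sd Named numeric vectors (or scalar sd) of the
#'   per-group gamma distribution; groups are `"male_low"`, `"male_high"`,
#'   `"female_low"`, `"female_high"`.
#' @param alpha_mean,alpha_sd Per-group learning-rate distribution.
#' @param beta_mean,beta_sd Inverse-temperature distribution (shared across
#'   groups).
#' @param pss_mean,pss_sd Named vectors over `"low"`, `"high"` stress.
#' @param pss_threshold PSS score at or above which a subject counts as
#'   high stress.
#' @param seed Integer seed for [generate_cohort()].
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = 16,
                        model = "s1w",
                        gamma_mean = c(male_low = 1.2, male_high = 1.1,
                                       female_low = 1.2, female_high = 1.6),
                        gamma_sd = 0.3,
                        alpha_mean = c(male_low = 0.10, male_high = 0.15,
                                       female_low = 0.20, female_high = 0.15),
                        alpha_sd = 0.05,
                        beta_mean = 0.14, beta_sd = 0.05,
                        pss_mean = c(low = 14.89, high = 23.17),
                        pss_sd = c(low = 3.06, high = 3.79),
                        pss_threshold = 19,
                        seed = NULL) {
  if (n_per_group < 2) stop("n_per_group must be >= 2", call. = FALSE)
  model <- match.arg(model, rl_model_names())
  groups <- c("male_low", "male_high", "female_low", "female_high")
  expand <- function(x) if (length(x) == 1) setNames(rep(x, 4), groups) else x[groups]
  structure(list(
    n_per_group = as.integer(n_per_group), model = model,
    gamma_mean = expand(gamma_mean), gamma_sd = expand(gamma_sd),
    alpha_mean = expand(alpha_mean), alpha_sd = expand(alpha_sd),
    beta_mean = beta_mean, beta_sd = beta_sd,
    pss_mean = pss_mean, pss_sd = pss_sd,
    pss_threshold = pss_threshold, seed = seed),
    class = "cohort_spec")
}

# Truncated-normal draw by rejection; `lo`/`hi` inclusive bounds.
rtruncnorm1 <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      x <- rnorm(1, mean, sd)
      if (x >= lo && x <= hi) break
    }
    out[i] <- x
  }
  out
}

#' Generate a synthetic cohort
#'
#' Samples each subject's generative parameters and PSS score from the
#' group distributions of a [cohort_spec()], then simulates the subject's
#' full trial log with [simulate_agent()] under `config`. Deterministic
#' given the spec's (or the argument's) seed.
#'
#' @param spec A [cohort_spec()].
#' @param config A [task_config()] for the simulated sessions.
#' @param seed Integer seed overriding `spec$seed`.
#' @return A tibble with one row per subject: `subject_id`, `sex`, `pss`,
#'   `stress_group`, `true_alpha`, `true_gamma`, `true_beta` (plus any
#'   other generative parameters as `true_*`), and a `trials` list-column
#'   of completed trial logs.
#' @examples
#' cohort <- generate_cohort(cohort_spec(n_per_group = 2, seed = 1))
#' nrow(cohort)  # 8 subjects
#' @export
generate_cohort <- function(spec = cohort_spec(), config = task_config(),
                            seed = spec$seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(seed, {
    groups <- tidyr::expand_grid(sex = c("male", "female"),
                                 stress_group = c("low", "high"))
    subj <- tidyr::uncount(groups, spec$n_per_group)
    n <- nrow(subj)
    subj$subject_id <- sprintf("S%03d", seq_len(n))
    key <- paste(subj$sex, subj$stress_group, sep = "_")
    thr <- spec$pss_threshold

    pss_lo <- ifelse(subj$stress_group == "high", thr, 0)
    pss_hi <- ifelse(subj$stress_group == "high", 40, thr - 1)
    subj$pss <- as.integer(round(vapply(seq_len(n), function(i)
      rtruncnorm1(1, spec$pss_mean[[subj$stress_group[i]]],
                  spec$pss_sd[[subj$stress_group[i]]],
                  pss_lo[i] - 0.49, pss_hi[i] + 0.49), numeric(1))))
    subj$pss <- pmin(pmax(subj$pss, pss_lo), pss_hi)

    eps <- 1e-3  # keep sampled rates strictly inside (0, 1)
    subj$true_alpha <- unname(vapply(key, function(k)
      rtruncnorm1(1, spec$alpha_mean[[k]], spec$alpha_sd[[k]], eps, 1 - eps),
      numeric(1)))
    subj$true_gamma <- unname(vapply(key, function(k)
      rtruncnorm1(1, spec$gamma_mean[[k]], spec$gamma_sd[[k]], eps, Inf),
      numeric(1)))
    subj$true_beta <- rtruncnorm1(n, spec$beta_mean, spec$beta_sd, eps, Inf)

    sim_seeds <- sample.int(.Machine$integer.max - 1L, n)
    subj$trials <- purrr::map(seq_len(n), function(i) {
      pars <- switch(spec$model,
        s1 = agent_params("s1", alpha = subj$true_alpha[i],
                          beta = subj$true_beta[i]),
        s1w = agent_params("s1w", alpha = subj$true_alpha[i],
                           gamma = subj$true_gamma[i],
                           beta = subj$true_beta[i]),
        stop("generate_cohort: generative model must be s1 or s1w",
             call. = FALSE))
      simulate_agent(pars, config, seed = sim_seeds[i],
                     subject_id = subj$subject_id[i])
    })
    dplyr::select(subj, "subject_id", "sex", "pss", "stress_group",
                  dplyr::starts_with("true_"), "trials")
  })
}

#' Split subjects into stress groups by PSS threshold
#'
#' Assigns (or re-derives) `stress_group` from the PSS score: subjects
#' scoring at or above `threshold` are classed as high stress. The per-group
#' PSS mean and SD are attached as the `"pss_summary"` attribute and can be
#' retrieved with [pss_summary()].
#'
#' @param subjects Tibble with a `pss` column.
#' @param threshold PSS cutoff (default 19), within the 0-40 scale.
#' @return `subjects` with a (re)computed `stress_group` column.
#' @examples
#' s <- tibble::tibble(pss = c(14, 19, 23))
#' split_by_stress(s)$stress_group
#' @export
split_by_stress <- function(subjects, threshold = 19) {
  if (threshold < 0 || threshold > 40)
    stop("threshold must lie within the 0-40 PSS scale", call. = FALSE)
  subjects$stress_group <- ifelse(subjects$pss >= threshold, "high", "low")
  if (any(tabulate(factor(subjects$stress_group,
                          levels = c("low", "high"))) == 0))
    warning("a stress group is empty; downstream contrasts will be skipped",
            call. = FALSE)
  summ <- subjects |>
    dplyr::group_by(.data$stress_group) |>
    dplyr::summarise(n = dplyr::n(), pss_mean = mean(.data$pss),
                     pss_sd = sd(.data$pss), .groups = "drop")
  attr(subjects, "pss_summary") <- summ
  subjects
}

#' @rdname split_by_stress
#' @export
pss_summary <- function(subjects) {
  s <- attr(subjects, "pss_summary")
  if (is.null(s)) s <- attr(split_by_stress(subjects), "pss_summary")
  s
}
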