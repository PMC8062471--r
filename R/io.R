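TRIALS_COLS <- c("subject_id", "trial", "block", "high_prob_option",
                 "mag_A", "mag_B", "chosen", "rewarded", "response_made")
SUBJECT_COLS <- c("subject_id", "sex", "pss", "stress_group")
FIT_COLS <- c("subject_id", "model", "log_lik", "log_post", "log_evidence",
              "hessian_ok", "n_restarts")

check_columns <- function(df, required, what, path) {
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(sprintf("%s file %s is missing required column(s): %s", what, path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  extra <- setdiff(names(df), required)
  if (length(extra))
    warning(sprintf("%s file %s has unknown column(s): %s", what, path,
                    paste(extra, collapse = ", ")), call. = FALSE)
  invisible(df)
}

#' Read and write trial logs, subject tables, and fit tables
#'
#' CSV round-trip helpers with strict header validation. Trial logs use
#' 1-based trial indices and write no-response trials with `chosen = "none"`
#' (read back as `NA`). `write_trials()` accepts either a flat trial tibble
#' or a cohort tibble with a `trials` list-column, which it unnests.
#'
#' @param path File path.
#' @param trials,subjects,fits The tibble to write.
#' @return The read functions return a tibble (empty, with a warning, for
#'   an empty file); the write functions return `path` invisibly.
#' @name banditfit-io
NULL

#' @rdname banditfit-io
#' @export
write_trials <- function(trials, path) {
  if ("trials" %in% names(trials))
    trials <- dplyr::bind_rows(purrr::map2(
      trials$subject_id, trials$trials, function(sid, tr) {
        if (!"subject_id" %in% names(tr)) tr$subject_id <- sid
        tr
      }))
  out <- trials
  if (!"subject_id" %in% names(out)) out$subject_id <- "S001"
  out <- dplyr::mutate(out,
    chosen = ifelse(is.na(.data$chosen), "none", .data$chosen))
  readr::write_csv(out[, TRIALS_COLS], path)
  invisible(path)
}

#' @rdname banditfit-io
#' @export
read_trials <- function(path) {
  if (!file.exists(path))
    stop("trials file not found: ", path, call. = FALSE)
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          subject_id = "c", trial = "i", block = "i",
                          high_prob_option = "c", mag_A = "i", mag_B = "i",
                          chosen = "c", rewarded = "c", response_made = "l"))
  if (nrow(df) == 0) {
    warning("trials file is empty: ", path, call. = FALSE)
    return(tibble::as_tibble(df))
  }
  check_columns(df, TRIALS_COLS, "trials", path)
  bad <- which(!df$chosen %in% c("A", "B", "none"))
  if (length(bad))
    stop(sprintf("malformed chosen value at data row %d of %s", bad[1], path),
         call. = FALSE)
  dplyr::mutate(tibble::as_tibble(df),
                chosen = ifelse(.data$chosen == "none", NA_character_,
                                .data$chosen))
}

#' @rdname banditfit-io
#' @export
write_subjects <- function(subjects, path) {
  cols <- c(SUBJECT_COLS, grep("^true_", names(subjects), value = TRUE))
  readr::write_csv(subjects[, intersect(cols, names(subjects))], path)
  invisible(path)
}

#' @rdname banditfit-io
#' @export
read_subjects <- function(path) {
  if (!file.exists(path))
    stop("subjects file not found: ", path, call. = FALSE)
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (nrow(df) == 0) {
    warning("subjects file is empty: ", path, call. = FALSE)
    return(tibble::as_tibble(df))
  }
  missing <- setdiff(SUBJECT_COLS, names(df))
  if (length(missing))
    stop(sprintf("subjects file %s is missing required column(s): %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  tibble::as_tibble(df)
}

#' @rdname banditfit-io
#' @export
write_fits <- function(fits, path) {
  readr::write_csv(fits, path)
  invisible(path)
}

#' @rdname banditfit-io
#' @export
read_fits <- function(path) {
  if (!file.exists(path))
    stop("fits file not found: ", path, call. = FALSE)
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (nrow(df) == 0) {
    warning("fits file is empty: ", path, call. = FALSE)
    return(tibble::as_tibble(df))
  }
  missing <- setdiff(FIT_COLS, names(df))
  if (length(missing))
    stop(sprintf("fits file %s is missing required column(s): %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  tibble::as_tibble(df)
}

#' Run the full pipeline from a configuration
#'
#' Executes the requested stages in order -- `simulate` (generate a
#' synthetic cohort), `fit` (MAP fits for the requested models), `compare`
#' (model comparison by mean Laplace evidence), `analyze` (performance
#' scoring, factorial contrasts, covariate-adjusted sex-difference models,
#' parameter-performance regressions) -- writing each stage's CSV outputs
#' plus a JSON manifest (seeds, stage runtimes, output files) to
#' `output_dir`. Identical configuration and seed give byte-identical
#' outputs.
#'
#' @param config A named list (or path to a JSON file) with any of:
#'   `stages` (subset of simulate/fit/compare/analyze, or `"all"`),
#'   `seed`, `n_per_group`, `n_restarts`, `models`, `model` (generative),
#'   `output_dir`.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  known <- c("stages", "seed", "n_per_group", "n_restarts", "models",
             "model", "output_dir")
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  stages <- config[["stages"]] %||% "all"
  if (identical(stages, "all")) stages <- c("simulate", "fit", "compare",
                                            "analyze")
  bad <- setdiff(stages, c("simulate", "fit", "compare", "analyze"))
  if (length(bad))
    stop("unknown stage(s): ", paste(bad, collapse = ", "), call. = FALSE)
  seed <- config[["seed"]] %||% 1L
  out_dir <- config[["output_dir"]] %||% "banditfit_output"
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  models <- config[["models"]] %||% rl_model_names()
  n_restarts <- config[["n_restarts"]] %||% 100

  manifest <- list(seed = seed, stages = stages, outputs = list(),
                   runtimes = list())
  timed <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    v <- expr
    manifest$runtimes[[name]] <<- round(proc.time()[["elapsed"]] - t0, 2)
    v
  }

  cohort <- NULL; fits <- NULL
  if ("simulate" %in% stages) {
    cohort <- timed("simulate", generate_cohort(
      cohort_spec(n_per_group = config[["n_per_group"]] %||% 16,
                  model = config[["model"]] %||% "s1w", seed = seed)))
    write_trials(cohort, file.path(out_dir, "trials.csv"))
    write_subjects(cohort, file.path(out_dir, "subjects.csv"))
    manifest$outputs$trials <- "trials.csv"
    manifest$outputs$subjects <- "subjects.csv"
  }
  if (any(c("fit", "compare", "analyze") %in% stages) && is.null(cohort)) {
    tr <- read_trials(file.path(out_dir, "trials.csv"))
    sub <- read_subjects(file.path(out_dir, "subjects.csv"))
    cohort <- tr |>
      tidyr::nest(trials = -"subject_id") |>
      dplyr::left_join(sub, by = "subject_id")
  }
  if ("fit" %in% stages) {
    fits <- timed("fit", fit_cohort(cohort, models = models,
                                    n_restarts = n_restarts,
                                    seed = seed + 1L))
    write_fits(fits, file.path(out_dir, "fits.csv"))
    manifest$outputs$fits <- "fits.csv"
  }
  if (is.null(fits) && any(c("compare", "analyze") %in% stages))
    fits <- read_fits(file.path(out_dir, "fits.csv"))
  if ("compare" %in% stages) {
    cmp <- timed("compare", compare_models(fits))
    readr::write_csv(cmp, file.path(out_dir, "model_comparison.csv"))
    manifest$outputs$model_comparison <- "model_comparison.csv"
  }
  if ("analyze" %in% stages) {
    timed("analyze", {
      perf <- cohort_performance(cohort)
      win <- compare_models(fits)$model[1]
      win_fits <- dplyr::filter(fits, .data$model == win)
      d <- perf |>
        dplyr::left_join(dplyr::select(cohort, -"trials"), by = "subject_id") |>
        dplyr::left_join(
          dplyr::select(win_fits, "subject_id",
                        dplyr::any_of(c("alpha", "gamma", "beta"))),
          by = "subject_id")
      readr::write_csv(perf, file.path(out_dir, "performance.csv"))
      gc_res <- group_contrasts(d)
      readr::write_csv(gc_res$anova, file.path(out_dir, "anova.csv"))
      readr::write_csv(gc_res$posthoc, file.path(out_dir, "posthoc.csv"))
      covs <- intersect(c("alpha", "gamma"), names(d))
      readr::write_csv(sex_difference_glm(d, covariates = covs),
                       file.path(out_dir, "sex_difference_glm.csv"))
      readr::write_csv(parameter_performance_regression(d, params = covs),
                       file.path(out_dir, "parameter_performance.csv"))
      manifest$outputs$analysis <- c("performance.csv", "anova.csv",
                                     "posthoc.csv", "sex_difference_glm.csv",
                                     "parameter_performance.csv")
    })
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
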