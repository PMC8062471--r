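#' Prior specifications for MAP fitting
#'
#' The default prior set constrains all learning rates (`alpha`,
#' `alpha_pos`, `alpha_neg`, `alpha1`, `alpha2`) with a Beta(4.6, 50)
#' distribution, the probability-weighting slope `gamma` with a
#' Gamma(shape 1.9, scale 1.0), the inverse temperature `beta` with a
#' Gamma(shape 2.8, scale 0.05) -- prior mean 0.14, appropriate for expected
#' values on a 0-100 point scale -- and the Pearce-Hall `kappa` and `mu`
#' with a flat Beta(1, 1) on (0, 1). `set = "beta22"` swaps the
#' learning-rate prior for the less constrained Beta(2, 2), for sensitivity
#' runs.
#'
#' @param set `"default"` or `"beta22"`.
#' @return A named list of class `prior_spec`; each element has `family`
#'   (`"beta"` or `"gamma"`), `a`, `b` (shape1/shape2 for beta,
#'   shape/scale for gamma).
#' @examples
#' pr <- default_priors()
#' prior_log_density(pr$beta, 0.14)
#' @export
default_priors <- function(set = c("default", "beta22")) {
  set <- match.arg(set)
  rate_prior <- if (set == "default") list(family = "beta", a = 4.6, b = 50)
                else list(family = "beta", a = 2, b = 2)
  flat <- list(family = "beta", a = 1, b = 1)
  structure(list(
    alpha = rate_prior, alpha_pos = rate_prior, alpha_neg = rate_prior,
    alpha1 = rate_prior, alpha2 = rate_prior,
    mu = flat, kappa = flat,
    gamma = list(family = "gamma", a = 1.9, b = 1.0),
    beta = list(family = "gamma", a = 2.8, b = 0.05)),
    class = "prior_spec")
}

#' @rdname default_priors
#' @param prior A single prior element of a `prior_spec`.
#' @param x Value(s) at which to evaluate the log density.
#' @export
prior_log_density <- function(prior, x) {
  switch(prior$family,
    beta = dbeta(x, prior$a, prior$b, log = TRUE),
    gamma = dgamma(x, shape = prior$a, scale = prior$b, log = TRUE),
    stop("unknown prior family", call. = FALSE))
}

#' @rdname default_priors
#' @param n Number of draws.
#' @export
prior_sample <- function(prior, n = 1) {
  switch(prior$family,
    beta = rbeta(n, prior$a, prior$b),
    gamma = rgamma(n, shape = prior$a, scale = prior$b))
}

# Sum of log prior densities for a model's parameter vector (canonical order).
prior_log_density_vec <- function(par, model, priors) {
  nm <- rl_par_names(model)
  missing <- setdiff(nm, names(priors))
  if (length(missing))
    stop("prior missing for parameter(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  sum(vapply(seq_along(nm),
             function(i) prior_log_density(priors[[nm[i]]], par[i]),
             numeric(1)))
}

#' Log posterior density of a model on a trial log
#'
#' Sum of the model log-likelihood over responded trials and the log prior
#' densities of the free parameters; `-Inf` outside any prior's support.
#'
#' @inheritParams rl_log_lik
#' @param priors A [default_priors()]-style `prior_spec`.
#' @return Scalar log posterior (unnormalized).
#' @export
log_posterior <- function(trials, model, par, priors = default_priors(),
                          reset_blocks = TRUE, assoc_first = TRUE, S0 = 1) {
  lp <- prior_log_density_vec(par, model, priors)
  if (!is.finite(lp)) return(-Inf)
  lp + rl_log_lik(trials, model, par, reset_blocks = reset_blocks,
                  assoc_first = assoc_first, S0 = S0)
}

#' Laplace-approximation log evidence of a log-density maximum
#'
#' Approximates the log marginal likelihood from a mode `theta` of the log
#' posterior `fn`: `fn(theta) + (k/2) log(2*pi) - 0.5 log det(H)` where `H`
#' is the Hessian of `-fn` at `theta`, computed by central finite
#' differences with a relative step (`rel_step`, with one retry at ten
#' times the step if `H` is not positive definite). Larger models pay an
#' automatic complexity penalty through the determinant term.
#'
#' @param fn Function of a numeric vector returning the log density.
#' @param theta Numeric vector, a (local) maximum of `fn` interior to the
#'   support.
#' @param rel_step Relative finite-difference step per coordinate.
#' @return List with `log_evidence` (NA when the Hessian is not positive
#'   definite after retry), `hessian_ok`, `hessian`.
#' @examples
#' # standard normal: evidence of the unnormalized density exp(-x^2/2) is
#' # sqrt(2*pi), so log evidence ~ 0.5 * log(2*pi)
#' laplace_evidence(function(x) -x^2 / 2, 0)$log_evidence
#' @export
laplace_evidence <- function(fn, theta, rel_step = 1e-3) {
  k <- length(theta)
  try_chol <- function(H) {
    if (!all(is.finite(H))) return(NULL)
    ch <- tryCatch(chol(H), error = function(e) NULL)
    if (!is.null(ch) && all(is.finite(diag(ch))) && all(diag(ch) > 0)) ch
    else NULL
  }
  H <- NULL
  for (step in c(rel_step, rel_step * 10)) {
    H <- fd_hessian(function(x) -fn(x), theta, step)
    ch <- try_chol(H)
    if (is.null(ch)) {
      # boundary-mode fallback: one-sided cross terms are only O(h)
      # accurate and can make H indefinite; decouple those coordinates,
      # keeping their interior diagonal curvature
      side <- attr(H, "side")
      if (!is.null(side) && any(side != 0L) && all(is.finite(diag(H))) &&
          all(diag(H) > 0)) {
        H2 <- H
        for (i in which(side != 0L)) {
          H2[i, -i] <- 0
          H2[-i, i] <- 0
        }
        ch <- try_chol(H2)
        if (!is.null(ch)) H <- H2
      }
    }
    if (!is.null(ch)) {
      logdet <- 2 * sum(log(diag(ch)))
      return(list(
        log_evidence = fn(theta) + 0.5 * k * log(2 * pi) - 0.5 * logdet,
        hessian_ok = TRUE, hessian = H))
    }
  }
  list(log_evidence = NA_real_, hessian_ok = FALSE, hessian = H)
}

# Finite-difference Hessian of a negative log density at its minimum.
# Step sizes are calibrated per coordinate so that the function rises by
# roughly `target` at theta +/- h: second differences at that scale measure
# the curvature of the posterior bulk, which is what the Laplace
# approximation needs, and are insensitive to the kinks that piecewise
# model components (probability-weighting clips, sign-switched learning
# rates) put into the likelihood at infinitesimal scales. Central
# differences by default; when a mode sits close enough to a support
# boundary that the step would leave it (fn non-finite), that coordinate
# falls back to one-sided differences into the finite region.
fd_hessian <- function(fn, theta, rel_step, target = 0.5) {
  k <- length(theta)
  f0 <- fn(theta)
  h <- vapply(seq_len(k), function(i) {
    hi <- pmax(abs(theta[i]), 1e-4) * 0.05
    for (rep in 1:40) {
      e <- replace(numeric(k), i, hi)
      rises <- c(fn(theta + e), fn(theta - e)) - f0
      rises <- rises[is.finite(rises)]
      if (!length(rises)) { hi <- hi / 2; next }
      rise <- max(rises)
      if (rise > 4 * target) hi <- hi / 2
      else if (rise < target / 4) hi <- hi * 2
      else break
    }
    hi
  }, numeric(1))
  h <- h * rel_step / 1e-3  # retries widen the calibrated steps
  step <- function(i, s) replace(numeric(k), i, s * h[i])
  fp <- vapply(seq_len(k), function(i) fn(theta + step(i, 1)), numeric(1))
  fm <- vapply(seq_len(k), function(i) fn(theta + step(i, -1)), numeric(1))
  side <- ifelse(is.finite(fp) & is.finite(fm), 0L,
                 ifelse(is.finite(fp), 1L, ifelse(is.finite(fm), -1L, NA)))
  if (anyNA(side)) return(matrix(NaN, k, k))
  H <- matrix(NA_real_, k, k)
  for (i in seq_len(k)) {
    H[i, i] <- if (side[i] == 0L) {
      (fp[i] - 2 * f0 + fm[i]) / h[i]^2
    } else {
      f1 <- if (side[i] == 1L) fp[i] else fm[i]
      (fn(theta + step(i, 2 * side[i])) - 2 * f1 + f0) / h[i]^2
    }
    if (i > 1) for (j in seq_len(i - 1)) {
      if (side[i] == 0L && side[j] == 0L) {
        H[i, j] <- H[j, i] <-
          (fn(theta + step(i, 1) + step(j, 1)) -
           fn(theta + step(i, 1) + step(j, -1)) -
           fn(theta + step(i, -1) + step(j, 1)) +
           fn(theta + step(i, -1) + step(j, -1))) / (4 * h[i] * h[j])
      } else {
        si <- if (side[i] == 0L) 1L else side[i]
        sj <- if (side[j] == 0L) 1L else side[j]
        fi <- if (si == 1L) fp[i] else fm[i]
        fj <- if (sj == 1L) fp[j] else fm[j]
        H[i, j] <- H[j, i] <-
          (fn(theta + step(i, si) + step(j, sj)) - fi - fj + f0) /
          (si * sj * h[i] * h[j])
      }
    }
  }
  attr(H, "side") <- side
  H
}

#' Fit one model to one subject's trials by MAP estimation
#'
#' Maximizes the log posterior with Nelder-Mead simplex search restarted
#' from `n_restarts` random initial points drawn from the priors, operating
#' on the raw (constrained) parameters with `-Inf` log posterior outside
#' any prior support. The Laplace approximation at the best optimum gives
#' the log model evidence used for model comparison.
#'
#' @inheritParams log_posterior
#' @param n_restarts Number of random restarts (>= 1).
#' @param seed Integer seed; fixed seed gives a bit-identical fit.
#' @return An object of class `map_fit`: `model`, `theta_map` (named),
#'   `params` ([agent_params()] at the MAP), `log_lik`, `log_post`,
#'   `log_evidence`, `hessian_ok`, `n_restarts`, `n_converged`.
#' @examples
#' log <- simulate_agent(agent_params("s1", alpha = 0.1, beta = 0.1),
#'                       task_config(), seed = 1)
#' fit <- fit_map(log, "s1", n_restarts = 10, seed = 1)
#' glance(fit)
#' @export
fit_map <- function(trials, model, priors = default_priors(),
                    n_restarts = 100, seed = NULL, reset_blocks = TRUE,
                    assoc_first = TRUE, S0 = 1) {
  model <- match.arg(model, rl_model_names())
  if (n_restarts < 1) stop("n_restarts must be >= 1", call. = FALSE)
  nm <- rl_par_names(model)
  a <- trials_arrays(trials)
  mid <- rl_model_id(model)
  missing_pr <- setdiff(nm, names(priors))
  if (length(missing_pr))
    stop("prior missing for parameter(s): ", paste(missing_pr, collapse = ", "),
         call. = FALSE)
  # precompute prior family/shape vectors so the optimizer objective is cheap
  fam <- vapply(priors[nm], `[[`, character(1), "family")
  pa <- vapply(priors[nm], `[[`, numeric(1), "a")
  pb <- vapply(priors[nm], `[[`, numeric(1), "b")
  isb <- fam == "beta"
  negpost <- function(par) {
    lp <- sum(dbeta(par[isb], pa[isb], pb[isb], log = TRUE)) +
      sum(dgamma(par[!isb], shape = pa[!isb], scale = pb[!isb], log = TRUE))
    if (!is.finite(lp)) return(Inf)
    -(lp + rl_loglik_cpp(par, mid, a$chosen_A, a$reward_A, a$mag_A, a$mag_B,
                         a$block, reset_blocks, assoc_first, S0))
  }
  with_seed(seed, {
    # drawn row by row so the first k starts agree across n_restarts choices
    starts <- t(vapply(seq_len(n_restarts), function(i)
      vapply(nm, function(p) prior_sample(priors[[p]], 1), numeric(1)),
      numeric(length(nm))))
    colnames(starts) <- nm
    best <- NULL; n_conv <- 0L; n_ok <- 0L
    for (i in seq_len(n_restarts)) {
      o <- tryCatch(
        optim(starts[i, ], negpost, method = "Nelder-Mead",
              control = list(maxit = 2000)),
        error = function(e) NULL)
      if (is.null(o) || !is.finite(o$value)) next
      n_ok <- n_ok + 1L
      if (o$convergence == 0) n_conv <- n_conv + 1L
      if (is.null(best) || o$value < best$value) best <- o
    }
    if (is.null(best))
      stop(sprintf("fit_map: all %d restarts failed for model %s",
                   n_restarts, model), call. = FALSE)
    theta <- setNames(best$par, nm)
    lp_fn <- function(par) {
      v <- negpost(par)
      if (!is.finite(v)) -Inf else -v
    }
    lap <- laplace_evidence(lp_fn, theta)
    ll <- rl_loglik_cpp(theta, mid, a$chosen_A, a$reward_A, a$mag_A, a$mag_B,
                        a$block, reset_blocks, assoc_first, S0)
    structure(list(
      model = model, theta_map = theta,
      params = do.call(agent_params, c(list(model = model), as.list(theta))),
      log_lik = ll, log_post = -best$value,
      log_evidence = lap$log_evidence, hessian_ok = lap$hessian_ok,
      n_restarts = n_restarts, n_converged = n_conv),
      class = "map_fit")
  })
}

#' @export
print.map_fit <- function(x, ...) {
  cat(sprintf("MAP fit, model %s\n", x$model))
  print(round(x$theta_map, 4))
  cat(sprintf("log lik %.3f | log post %.3f | log evidence %s | %d/%d converged\n",
              x$log_lik, x$log_post,
              ifelse(x$hessian_ok, sprintf("%.3f", x$log_evidence), "NA"),
              x$n_converged, x$n_restarts))
  invisible(x)
}

#' Tidy and summarize MAP fits
#'
#' `tidy()` returns one row per free parameter with its MAP estimate;
#' `glance()` returns a one-row model-level summary.
#'
#' @param x A `map_fit` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.map_fit <- function(x, ...) {
  tibble::tibble(model = x$model, term = names(x$theta_map),
                 estimate = unname(x$theta_map))
}

#' @rdname tidy.map_fit
#' @export
glance.map_fit <- function(x, ...) {
  tibble::tibble(model = x$model, n_params = length(x$theta_map),
                 log_lik = x$log_lik, log_post = x$log_post,
                 log_evidence = x$log_evidence, hessian_ok = x$hessian_ok,
                 n_restarts = x$n_restarts, n_converged = x$n_converged)
}

#' Fit models to every subject of a cohort
#'
#' Maps [fit_map()] over the subjects of a cohort tibble (one row per
#' subject with a `trials` list-column, as produced by
#' [generate_cohort()]), for one or several models, and returns a tidy fit
#' table.
#'
#' @param cohort Cohort tibble with `subject_id` and `trials` columns.
#' @param models Character vector of model names (default: all eight).
#' @inheritParams fit_map
#' @return A tibble with one row per subject x model: `subject_id`,
#'   `model`, one column per parameter (NA when not free in that model),
#'   `log_lik`, `log_post`, `log_evidence`, `hessian_ok`, `n_restarts`,
#'   `n_converged`.
#' @export
fit_cohort <- function(cohort, models = rl_model_names(),
                       priors = default_priors(), n_restarts = 100,
                       seed = NULL, reset_blocks = TRUE) {
  grid <- tidyr::expand_grid(subject_id = cohort$subject_id, model = models)
  seeds <- derive_seeds(seed, nrow(grid))
  rows <- purrr::pmap(list(grid$subject_id, grid$model, seeds),
    function(sid, mod, s) {
      trials <- cohort$trials[[match(sid, cohort$subject_id)]]
      f <- fit_map(trials, mod, priors = priors, n_restarts = n_restarts,
                   seed = s, reset_blocks = reset_blocks)
      est <- as.list(f$theta_map)
      tibble::tibble(subject_id = sid, model = mod, !!!est,
                     log_lik = f$log_lik, log_post = f$log_post,
                     log_evidence = f$log_evidence, hessian_ok = f$hessian_ok,
                     n_restarts = f$n_restarts, n_converged = f$n_converged)
    })
  dplyr::bind_rows(rows)
}

#' Compare fitted models by mean Laplace evidence
#'
#' Averages the log model evidence across subjects per model; the winning
#' model is the one with the greatest mean evidence, ties broken toward
#' fewer free parameters.
#'
#' @param fits A fit table from [fit_cohort()] (or row-bound [fit_map()]
#'   glances with a `subject_id` column).
#' @param max_missing Maximum tolerated fraction of subject x model cells
#'   with missing evidence before comparison errors out.
#' @return A tibble: `model`, `n_params`, `n_subjects`, `mean_evidence`,
#'   `winner`.
#' @export
compare_models <- function(fits, max_missing = 0.1) {
  frac_na <- mean(is.na(fits$log_evidence))
  if (frac_na > max_missing)
    stop(sprintf("model comparison unreliable: %.0f%% of evidences missing",
                 100 * frac_na), call. = FALSE)
  npar <- setNames(rl_models()$n_params, rl_models()$model)
  out <- fits |>
    dplyr::group_by(.data$model) |>
    dplyr::summarise(
      n_subjects = dplyr::n(),
      mean_evidence = mean(.data$log_evidence, na.rm = TRUE),
      .groups = "drop") |>
    dplyr::mutate(n_params = unname(npar[.data$model]), .after = "model") |>
    dplyr::arrange(dplyr::desc(.data$mean_evidence), .data$n_params)
  out$winner <- seq_len(nrow(out)) == 1L
  out
}
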