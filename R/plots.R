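#' Group means of task performance with per-subject points
#'
#' Bar-plus-jitter plot of the proportion of correct choices per sex x
#' stress cell.
#'
#' @param data One row per subject with `prop_correct`, `sex`,
#'   `stress_group`.
#' @return A ggplot object.
#' @export
plot_group_performance <- function(data) {
  d <- dplyr::mutate(data,
    cell = interaction(.data$stress_group, .data$sex, sep = " / "))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$cell, y = .data$prop_correct,
                                  fill = .data$sex)) +
    ggplot2::stat_summary(fun = mean, geom = "col", width = 0.6,
                          alpha = 0.6) +
    ggplot2::stat_summary(fun.data = ggplot2::mean_se, geom = "errorbar",
                          width = 0.15) +
    ggplot2::geom_jitter(width = 0.08, size = 1.2, alpha = 0.7) +
    ggplot2::labs(x = "stress group / sex", y = "proportion correct") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Probability-weighting curves per group
#'
#' Plots the linear weighting transform `F(p, gamma)` over p in \[0, 1\]
#' for the mean fitted (or generative) `gamma` of each group.
#'
#' @param gammas Named numeric vector of weighting slopes (one curve each).
#' @return A ggplot object.
#' @examples
#' plot_weighting_curves(c(risk_neutral = 1, risk_averse = 1.6))
#' @export
plot_weighting_curves <- function(gammas) {
  p <- seq(0, 1, by = 0.01)
  d <- purrr::imap(gammas, function(g, nm)
    tibble::tibble(group = nm, p = p,
                   weighted = weight_probability(p, g))) |>
    dplyr::bind_rows()
  ggplot2::ggplot(d, ggplot2::aes(x = .data$p, y = .data$weighted,
                                  colour = .data$group)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::labs(x = "predicted probability",
                  y = "weighted probability") +
    ggplot2::theme_minimal()
}

#' Performance vs fitted parameter, per sex
#'
#' Scatterplot with per-sex least-squares lines of proportion correct
#' against a fitted parameter.
#'
#' @param data One row per subject with `prop_correct`, `sex`, and the
#'   column named by `param`.
#' @param param Parameter column to plot on the x axis.
#' @return A ggplot object.
#' @export
plot_parameter_performance <- function(data, param = "gamma") {
  ggplot2::ggplot(data, ggplot2::aes(x = .data[[param]],
                                     y = .data$prop_correct,
                                     colour = .data$sex)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
    ggplot2::labs(x = param, y = "proportion correct") +
    ggplot2::theme_minimal()
}

#' Plot the latent trace of a model run
#'
#' @param object An `rl_run` from [run_model()].
#' @param ... Unused.
#' @return A ggplot object showing the predicted probability, choice
#'   probability and prediction error over trials.
#' @export
autoplot.rl_run <- function(object, ...) {
  d <- object$trace |>
    tidyr::pivot_longer(c("p_pred", "p_choice_A", "delta"),
                        names_to = "quantity", values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$trial, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = which(diff(object$trace$block) != 0) + 0.5,
                        linetype = 3, colour = "grey60") +
    ggplot2::facet_wrap(~quantity, ncol = 1, scales = "free_y") +
    ggplot2::theme_minimal()
}

#' Plot a model-comparison table
#'
#' @param object The tibble returned by [compare_models()].
#' @param ... Unused.
#' @return A ggplot bar chart of mean log evidence per model.
#' @export
plot_model_comparison <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = stats::reorder(.data$model, .data$mean_evidence),
    y = .data$mean_evidence, fill = .data$winner)) +
    ggplot2::geom_col(width = 0.7) +
    ggplot2::coord_flip() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#2c7fb8",
                                          `FALSE` = "grey70"),
                               guide = "none") +
    ggplot2::labs(x = NULL, y = "mean log evidence") +
    ggplot2::theme_minimal()
}
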