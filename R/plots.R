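#' Predicted-vs-experimental log P plot
#'
#' Scatter of predicted against experimental log P with the identity line
#' and the descriptive regression line, the standard correlation plot for
#' partition-coefficient predictions.
#'
#' @inheritParams error_metrics
#' @param label Unquoted molecule-label column used for point labels
#'   (default `molecule_id`).
#' @return A ggplot object.
#' @examples
#' t2 <- load_builtin_fixture("table2_logp")
#' plot_logp_predictions(t2, `octanol_wet/2-par`, logP_exp)
#' @export
plot_logp_predictions <- function(data, predicted, experimental,
                                  label = molecule_id) {
  df <- tibble(
    experimental = dplyr::pull(data, {{ experimental }}),
    predicted = dplyr::pull(data, {{ predicted }}),
    label = dplyr::pull(data, {{ label }})
  )
  reg <- descriptive_regression(df, predicted, experimental)
  ggplot2::ggplot(df, ggplot2::aes(x = experimental, y = predicted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_abline(slope = reg$slope, intercept = reg$intercept,
                         colour = "steelblue") +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_text(ggplot2::aes(label = label), vjust = -0.8, size = 3) +
    ggplot2::labs(x = "experimental log P", y = "predicted log P",
                  subtitle = sprintf("m' = %.2f, b' = %.2f, R^2 = %.2f",
                                     reg$slope, reg$intercept, reg$r_squared)) +
    ggplot2::theme_minimal()
}

#' Tautomer stability ladder plot
#'
#' Relative tautomer Gibbs energies per molecule and solvent as a ladder
#' (one column per solvent/model), visualising stability gaps and possible
#' cross-solvent rank shifts.
#'
#' @param report A tibble from [tautomer_report()] (or any table with
#'   `molecule_id`, `phase`, `tautomer_id`, `delta_G`).
#' @return A ggplot object.
#' @export
plot_tautomer_ladder <- function(report) {
  check_columns(report, c("molecule_id", "phase", "tautomer_id", "delta_G"),
                "tautomer report")
  ggplot2::ggplot(report,
                  ggplot2::aes(x = .data$phase, y = .data$delta_G,
                               group = .data$tautomer_id)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::facet_wrap(~molecule_id, scales = "free_y") +
    ggplot2::labs(x = NULL, y = expression(Delta * G[tautomer] ~ "(kcal/mol)")) +
    ggplot2::theme_minimal()
}

#' @rdname fit_correction_params
#' @param object A `pmv_fit` object.
#' @method autoplot pmv_fit
#' @export
autoplot.pmv_fit <- function(object, ...) {
  df <- object$residuals
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$molecule_id,
                                                      .data$residual),
                                   y = .data$residual)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::labs(x = NULL,
                  y = "residual dGsolv (model - experiment, kcal/mol)",
                  subtitle = sprintf("%s %s fit, RMSE %.3f kcal/mol",
                                     object$solvent, object$model,
                                     sqrt(object$loss_value / object$n_molecules))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
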