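#' Prediction error metrics
#'
#' Paired error statistics of predictions against experiment: root-mean-square
#' error, mean absolute error and mean signed error
#' (`mean(predicted - experimental)`; underprediction gives negative values).
#' "MSE" in the blind-challenge reporting convention is the mean *signed*
#' error, never the mean squared error, so the column is named
#' `mean_signed_error` here.
#'
#' @param data A data frame with one row per molecule.
#' @param predicted,experimental Unquoted column names of predicted and
#'   experimental values (same units).
#' @return A one-row tibble: `rmse`, `mae`, `mean_signed_error`, `n`.
#' @examples
#' t2 <- load_builtin_fixture("table2_logp")
#' error_metrics(t2, `octanol_wet/2-par`, logP_exp)
#' @export
error_metrics <- function(data, predicted, experimental) {
  p <- dplyr::pull(data, {{ predicted }})
  e <- dplyr::pull(data, {{ experimental }})
  if (length(p) != length(e)) abort("predicted and experimental must pair up")
  if (length(p) < 1) abort("need at least one prediction/experiment pair")
  if (any(!is.finite(p)) || any(!is.finite(e))) abort("values must be finite")
  r <- p - e
  tibble(rmse = sqrt(mean(r^2)), mae = mean(abs(r)),
         mean_signed_error = mean(r), n = length(r))
}

#' Descriptive regression of predictions on experiment
#'
#' Ordinary least-squares line `predicted = m' * experimental + b'` with
#' `R^2` the squared Pearson correlation (identical to the OLS coefficient of
#' determination in simple regression). The regression direction —
#' predictions on the ordinate — matches the convention of the challenge
#' correlation plots.
#'
#' @inheritParams error_metrics
#' @return A one-row tibble: `slope`, `intercept`, `r_squared`, `n`.
#' @export
descriptive_regression <- function(data, predicted, experimental) {
  p <- dplyr::pull(data, {{ predicted }})
  e <- dplyr::pull(data, {{ experimental }})
  if (length(p) != length(e)) abort("predicted and experimental must pair up")
  if (length(p) < 3) abort("descriptive regression needs at least 3 pairs")
  if (stats::var(e) == 0) abort("experimental values are constant; regression is degenerate")
  fit <- lm(p ~ e)
  tibble(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         r_squared = cor(p, e)^2, n = length(p))
}

#' Full metrics report
#'
#' Convenience wrapper combining [error_metrics()] and
#' [descriptive_regression()] into the six-statistic bundle used in
#' challenge summary tables.
#'
#' @inheritParams error_metrics
#' @return A one-row tibble: `rmse`, `mae`, `mean_signed_error`, `slope`,
#'   `intercept`, `r_squared`, `n`.
#' @export
metrics_report <- function(data, predicted, experimental) {
  dplyr::bind_cols(
    dplyr::select(error_metrics(data, {{ predicted }}, {{ experimental }}), -"n"),
    descriptive_regression(data, {{ predicted }}, {{ experimental }})
  )
}

#' Leave-one-out impact of each molecule on the RMSE
#'
#' For each molecule, the RMSE of the remaining n-1 pairs, the drop relative
#' to the full-set RMSE, and the molecule's own signed error. Sorting is by
#' impact, so the first row is the molecule whose removal lowers the RMSE the
#' most — the dominant outlier.
#'
#' @inheritParams error_metrics
#' @param label Unquoted column identifying the molecule (default
#'   `molecule_id`).
#' @return A tibble sorted by decreasing `delta_rmse`: columns from `label`,
#'   `signed_error`, `rmse_without` and `delta_rmse = rmse_full - rmse_without`.
#' @export
leave_one_out_impact <- function(data, predicted, experimental,
                                 label = molecule_id) {
  p <- dplyr::pull(data, {{ predicted }})
  e <- dplyr::pull(data, {{ experimental }})
  lab <- dplyr::pull(data, {{ label }})
  if (length(p) < 2) abort("leave-one-out needs at least 2 pairs")
  r2 <- (p - e)^2
  full <- sqrt(mean(r2))
  without <- sqrt((sum(r2) - r2) / (length(r2) - 1))
  tibble(label = lab, signed_error = p - e,
         rmse_without = without, delta_rmse = full - without) %>%
    dplyr::rename(!!rlang::as_name(rlang::enquo(label)) := "label") %>%
    dplyr::arrange(dplyr::desc(.data$delta_rmse))
}

#' Per-class error decomposition across solvents
#'
#' Splits per-molecule solvation (or log P) errors by compound class and by
#' solvent — e.g. aliphatic versus aromatic alcohols in water versus octanol
#' — to expose class-specific systematic offsets. Within each class,
#' molecules are ordered by ascending octanol error when an octanol column is
#' present (the ordering used in the error-dissection plots).
#'
#' @param errors A data frame with columns `molecule_id`, `solvent`, `error`
#'   (long format; one row per molecule x solvent).
#' @param class_labels A data frame with columns `molecule_id`, `class`
#'   covering every molecule in `errors`.
#' @return A list of two tibbles: `by_class` (per class x solvent: `n`,
#'   `mean_error`, `median_error`) and `by_molecule` (per molecule: one
#'   error column per solvent plus `water_minus_octanol` when both phases
#'   are present, ordered within class).
#' @export
group_error_decomposition <- function(errors, class_labels) {
  check_columns(errors, c("molecule_id", "solvent", "error"), "errors table")
  check_columns(class_labels, c("molecule_id", "class"), "class labels")
  unknown <- setdiff(unique(errors$molecule_id), class_labels$molecule_id)
  if (length(unknown) > 0) {
    abort(sprintf("molecule(s) without class label: %s",
                  paste(unknown, collapse = ", ")))
  }
  joined <- dplyr::inner_join(as_tibble(errors), as_tibble(class_labels),
                              by = "molecule_id")
  by_class <- joined %>%
    dplyr::group_by(.data$class, .data$solvent) %>%
    dplyr::summarise(n = dplyr::n(), mean_error = mean(.data$error),
                     median_error = median(.data$error), .groups = "drop")
  wide <- joined %>%
    tidyr::pivot_wider(id_cols = c("molecule_id", "class"),
                       names_from = "solvent", values_from = "error")
  oct_col <- intersect(c("octanol_wet", "octanol_dry"), names(wide))
  if ("water" %in% names(wide) && length(oct_col) >= 1) {
    wide$water_minus_octanol <- wide$water - wide[[oct_col[1]]]
  }
  if (length(oct_col) >= 1) {
    wide <- dplyr::arrange(wide, .data$class, .data[[oct_col[1]]])
  } else {
    wide <- dplyr::arrange(wide, .data$class, .data$molecule_id)
  }
  list(by_class = by_class, by_molecule = wide)
}
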