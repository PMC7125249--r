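# --- internal: prepared training dataset -----------------------------------
#
# Precomputes everything parameter-independent for the regression loss:
# the vacuum reference energies (the correction applies only in solution),
# the experimental solvation free energies, and a padded index matrix that
# lets the grouped log-sum-exp over each molecule's states run as plain
# matrix arithmetic inside the optimizer.
prepare_training_data <- function(states, experiments, solvent = NULL,
                                  constants = thermo_constants(),
                                  mode = c("strict", "permissive")) {
  mode <- match.arg(mode)
  constants <- as_thermo_constants(constants)
  states <- validate_state_table(states)
  experiments <- validate_experiment_table(experiments)

  present <- setdiff(unique(states$phase), "vacuum")
  if (is.null(solvent)) {
    if (length(present) != 1) {
      abort(sprintf("state table contains %d solution phases (%s); specify `solvent`",
                    length(present), paste(present, collapse = ", ")))
    }
    solvent <- present
  }
  sol <- dplyr::filter(states, .data$phase == solvent)
  vac <- dplyr::filter(states, .data$phase == "vacuum")
  exps <- dplyr::filter(experiments,
                        .data$observable == "dGsolv", .data$solvent == !!solvent)
  if (nrow(sol) == 0) abort(sprintf("no solution states for phase %s", shQuote(solvent)))

  mols <- unique(sol$molecule_id)
  no_vac <- setdiff(mols, unique(vac$molecule_id))
  no_exp <- setdiff(mols, unique(exps$molecule_id))
  dropped <- union(no_vac, no_exp)
  if (length(dropped) > 0) {
    msg <- sprintf("molecule(s) lacking %s: %s",
                   paste(c("vacuum states"[length(no_vac) > 0],
                           "experimental dGsolv"[length(no_exp) > 0]), collapse = " and "),
                   paste(dropped, collapse = ", "))
    if (mode == "strict") abort(msg)
    warn(sprintf("dropping %d molecule(s) from training; %s", length(dropped), msg))
    mols <- setdiff(mols, dropped)
    if (length(mols) == 0) abort("no trainable molecules remain")
    sol <- dplyr::filter(sol, .data$molecule_id %in% mols)
  }
  mols <- sort(mols)
  sol <- dplyr::arrange(sol, match(.data$molecule_id, mols))

  g_vac <- vacuum_gibbs_energy(vac, constants)
  g_vac <- setNames(g_vac$G_vac, g_vac$molecule_id)[mols]
  dg_exp <- setNames(exps$value, exps$molecule_id)[mols]

  grp <- match(sol$molecule_id, mols)
  counts <- tabulate(grp, nbins = length(mols))
  K <- max(counts)
  idx <- matrix(NA_integer_, nrow = length(mols), ncol = K)
  pos <- sequence(counts) # rows are sorted by molecule
  idx[cbind(grp, pos)] <- seq_len(nrow(sol))

  list(solvent = solvent, molecules = mols, n = length(mols),
       E_sol = sol$E_sol, mu_ex = sol$mu_ex, V_m = sol$V_m, q = sol$q,
       idx = idx, K = K, g_vac = unname(g_vac), dg_exp = unname(dg_exp),
       rt = constants$RT)
}

# Model solvation free energies for every molecule in a prepared dataset at
# the given parameter values (stable grouped log-sum-exp).
prepared_dg_model <- function(prep, c_mu, c_V, c_q) {
  u <- prep$E_sol + c_mu * prep$mu_ex + c_V * prep$V_m + c_q * prep$q
  umat <- matrix(u[prep$idx], nrow = prep$n, ncol = prep$K)
  m <- umat[, 1] # first slot is always filled
  if (prep$K > 1) {
    for (k in 2:prep$K) m <- pmin(m, umat[, k], na.rm = TRUE)
  }
  s <- rowSums(exp(-(umat - m) / prep$rt), na.rm = TRUE)
  (m - prep$rt * log(s)) - prep$g_vac
}

#' Training loss of a correction model
#'
#' Sum of squared deviations between the model solvation free energies and
#' the experimental references,
#' `L = sum_molecules (dGsolv_model - dGsolv_exp)^2`,
#' where each model value runs the full partition-function aggregation with
#' the correction parameters inside the exponents. This is the objective
#' minimised by [fit_correction_params()]; it is nonlinear in the parameters
#' whenever any molecule has more than one state.
#'
#' @param states State table with solution rows of one solvent and vacuum
#'   rows for every molecule.
#' @param experiments Experiment table providing `dGsolv` values in that
#'   solvent for every molecule.
#' @param params A [correction_params()] object at which to evaluate the loss.
#' @param solvent Solution phase to train on; defaults to the single
#'   solution phase present.
#' @param constants A [thermo_constants()] object.
#' @return The loss in kcal^2 mol^-2 (a single number).
#' @export
training_loss <- function(states, experiments, params, solvent = NULL,
                          constants = thermo_constants()) {
  params <- as_correction_params(params)
  prep <- prepare_training_data(states, experiments, solvent, constants)
  r <- prepared_dg_model(prep, params$c_mu, params$c_V, params$c_q) - prep$dg_exp
  sum(r^2)
}

default_start_grid <- function(free) {
  grid <- list(c_mu = c(0.5, 1, 1.5), c_V = c(0, -0.01, -0.1), c_q = 0)
  expand.grid(grid[free], KEEP.OUT.ATTRS = FALSE)
}

# Minimise the loss over the free parameters for one prepared dataset.
# `weights` (molecule multiplicities) supports the molecule-level bootstrap.
fit_prepared <- function(prep, free, fixed, start_grid,
                         reltol = 1e-12, maxit = 5000, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, prep$n)
  n_eval <- 0L
  loss_at <- function(theta) {
    n_eval <<- n_eval + 1L
    p <- fixed
    p[free] <- theta
    r <- prepared_dg_model(prep, p[["c_mu"]], p[["c_V"]], p[["c_q"]]) - prep$dg_exp
    sum(weights * r^2)
  }
  best <- NULL
  for (i in seq_len(nrow(start_grid))) {
    start <- as.numeric(start_grid[i, free])
    if (length(free) == 1) {
      fit <- optim(start, loss_at, method = "Brent", lower = -5, upper = 5,
                   control = list(maxit = maxit))
    } else {
      fit <- optim(start, loss_at, method = "Nelder-Mead",
                   control = list(reltol = reltol, maxit = maxit))
    }
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (length(free) > 1) { # quasi-Newton polish from the best simplex solution
    polish <- optim(best$par, loss_at, method = "BFGS",
                    control = list(reltol = 1e-14, maxit = maxit))
    if (polish$value <= best$value) best <- polish
  }
  list(par = setNames(as.numeric(best$par), free), value = best$value,
       converged = best$convergence == 0, n_evaluations = n_eval)
}

#' Fit correction parameters to experimental solvation free energies
#'
#' Nonlinear least-squares training of the excess-chemical-potential
#' correction: minimises [training_loss()] over the free parameters of the
#' chosen model. `"2-par"` fits the scale `c_mu` and the PMV coefficient
#' `c_V`; `"1-par"` fixes `c_mu = 1` exactly (PMV-only correction) and fits
#' `c_V` alone. The charge coefficient `c_q` is fitted only on request and
#' is meaningful only when charged species are present.
#'
#' Optimisation is deterministic: a Nelder-Mead simplex started from a fixed
#' 3x3 grid (`c_mu` in 0.5/1/1.5, `c_V` in 0/-0.01/-0.1), with a
#' quasi-Newton polish from the best start; single-parameter fits use
#' bounded Brent minimisation.
#'
#' @inheritParams training_loss
#' @param model `"2-par"` or `"1-par"`.
#' @param fit_cq Also fit the net-charge coefficient `c_q` (default `FALSE`;
#'   requires molecules with nonzero `q` to be identifiable).
#' @param mode `"strict"` errors on molecules missing vacuum states or
#'   experimental values; `"permissive"` drops them with a warning.
#' @param start_grid Optional data frame of start points (columns a subset of
#'   `c_mu`, `c_V`, `c_q`).
#' @param reltol,maxit Convergence control for the simplex stage.
#' @return An object of class `pmv_fit` with [tidy()] / [glance()] methods:
#'   fitted [correction_params()], the loss at the optimum, per-molecule
#'   residuals, and optimizer diagnostics.
#' @examples
#' synth <- generate_dataset(synthetic_spec(n_molecules = 40, sigma = 0, seed = 7))
#' fit <- fit_correction_params(synth$states, synth$experiments,
#'                              solvent = "octanol_wet")
#' tidy(fit)
#' @export
fit_correction_params <- function(states, experiments, solvent = NULL,
                                  model = c("2-par", "1-par"),
                                  fit_cq = FALSE,
                                  mode = c("strict", "permissive"),
                                  constants = thermo_constants(),
                                  start_grid = NULL,
                                  reltol = 1e-12, maxit = 5000) {
  model <- match.arg(model)
  prep <- prepare_training_data(states, experiments, solvent, constants, mode)

  free <- c(if (model == "2-par") "c_mu", "c_V", if (fit_cq) "c_q")
  fixed <- c(c_mu = 1, c_V = 0, c_q = 0)
  if (prep$n < length(free)) {
    abort(sprintf("need at least %d molecules to fit %d parameter(s); have %d",
                  length(free), length(free), prep$n))
  }
  # degenerate dataset: loss cannot depend on the free parameters
  degenerate <- c(c_mu = all(prep$mu_ex == 0), c_V = all(prep$V_m == 0),
                  c_q = all(prep$q == 0))
  if (any(degenerate[free])) {
    abort(sprintf("loss is independent of parameter(s) %s on this dataset (all corresponding components are zero)",
                  paste(free[degenerate[free]], collapse = ", ")))
  }
  if (is.null(start_grid)) start_grid <- default_start_grid(free)
  check_columns(start_grid, free, "start grid")

  opt <- fit_prepared(prep, free, fixed, start_grid, reltol, maxit)
  est <- fixed
  est[names(opt$par)] <- opt$par
  params <- correction_params(
    c_mu = est[["c_mu"]], c_V = est[["c_V"]], c_q = est[["c_q"]],
    solvent_label = prep$solvent,
    free_mask = setNames(names(fixed) %in% free, names(fixed))
  )
  resid <- prepared_dg_model(prep, est[["c_mu"]], est[["c_V"]], est[["c_q"]]) - prep$dg_exp
  structure(
    list(params = params, model = model, fit_cq = fit_cq,
         loss_value = opt$value, n_molecules = prep$n,
         converged = opt$converged, n_evaluations = opt$n_evaluations,
         residuals = tibble(molecule_id = prep$molecules, residual = resid),
         solvent = prep$solvent),
    class = "pmv_fit"
  )
}

#' @export
print.pmv_fit <- function(x, ...) {
  cat(sprintf("<pmv_fit: %s, %s%s>\n", x$solvent, x$model,
              if (x$fit_cq) " + c_q" else ""))
  print(x$params)
  cat(sprintf("  loss = %.6g kcal^2/mol^2 over %d molecules (RMSE %.4f kcal/mol)\n",
              x$loss_value, x$n_molecules, sqrt(x$loss_value / x$n_molecules)))
  cat(sprintf("  converged: %s after %d loss evaluations\n",
              x$converged, x$n_evaluations))
  invisible(x)
}

#' @rdname fit_correction_params
#' @param x A `pmv_fit` object.
#' @param ... Unused.
#' @method tidy pmv_fit
#' @export
tidy.pmv_fit <- function(x, ...) {
  est <- c(c_mu = x$params$c_mu, c_V = x$params$c_V, c_q = x$params$c_q)
  tibble(term = names(est), estimate = unname(est),
         fitted = unname(x$params$free_mask[names(est)]))
}

#' @rdname fit_correction_params
#' @method glance pmv_fit
#' @export
glance.pmv_fit <- function(x, ...) {
  tibble(loss = x$loss_value,
         rmse = sqrt(x$loss_value / x$n_molecules),
         n_molecules = x$n_molecules,
         converged = x$converged,
         n_evaluations = x$n_evaluations)
}

#' Molecule-level bootstrap of the fitted parameters
#'
#' Resamples molecules with replacement, refits the correction model on each
#' resample, and summarises the spread of the fitted parameters as percentile
#' confidence intervals. Resamples containing fewer distinct molecules than
#' free parameters are skipped with a warning.
#'
#' @inheritParams fit_correction_params
#' @param n_resamples Number of bootstrap resamples (at least 1; fewer than
#'   100 triggers a warning since percentile intervals become unstable).
#' @param seed Integer seed; the resampling stream is fully reproducible and
#'   does not disturb the global RNG.
#' @param level Confidence level for the percentile interval (default 0.95).
#' @return A tibble with one row per free parameter: `estimate` (full-data
#'   fit), `se`, `conf_low`, `conf_high`, `n_resamples_used`.
#' @export
bootstrap_parameter_uncertainty <- function(states, experiments, solvent = NULL,
                                            model = c("2-par", "1-par"),
                                            fit_cq = FALSE,
                                            n_resamples = 200, seed = 1,
                                            level = 0.95,
                                            constants = thermo_constants()) {
  model <- match.arg(model)
  if (!is.numeric(n_resamples) || length(n_resamples) != 1 || n_resamples < 1) {
    abort("`n_resamples` must be a positive integer")
  }
  if (n_resamples < 100) {
    warn("fewer than 100 bootstrap resamples; percentile intervals will be noisy")
  }
  full <- fit_correction_params(states, experiments, solvent, model, fit_cq,
                                constants = constants)
  prep <- prepare_training_data(states, experiments, solvent, constants)
  free <- c(if (model == "2-par") "c_mu", "c_V", if (fit_cq) "c_q")
  fixed <- c(c_mu = 1, c_V = 0, c_q = 0)
  grid <- default_start_grid(free)

  draws <- withr::with_seed(seed, {
    replicate(n_resamples, sample.int(prep$n, prep$n, replace = TRUE),
              simplify = FALSE)
  })
  ests <- purrr::map(draws, function(ii) {
    if (length(unique(ii)) < length(free)) return(NULL)
    w <- tabulate(ii, nbins = prep$n)
    fit_prepared(prep, free, fixed, grid, weights = w)$par
  })
  skipped <- sum(purrr::map_lgl(ests, is.null))
  if (skipped > 0) {
    warn(sprintf("skipped %d resample(s) with fewer distinct molecules than parameters",
                 skipped))
  }
  mat <- do.call(rbind, purrr::compact(ests))
  a <- (1 - level) / 2
  full_est <- tidy(full)
  purrr::map_dfr(free, function(p) {
    tibble(term = p,
           estimate = full_est$estimate[full_est$term == p],
           se = stats::sd(mat[, p]),
           conf_low = unname(quantile(mat[, p], a)),
           conf_high = unname(quantile(mat[, p], 1 - a)),
           n_resamples_used = nrow(mat))
  })
}
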