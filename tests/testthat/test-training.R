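tc <- thermo_constants()

hand_dataset <- function() {
  # one molecule, one conformer, hand-set components
  states <- dplyr::bind_rows(
    sol_row("M1", "t1", "c1", phase = "octanol_wet",
            E_sol = -10, mu_ex = -5, V_m = 100),
    vac_row("M1", "t1", E_vac = 0))
  experiments <- tibble::tibble(molecule_id = "M1", observable = "dGsolv",
                                solvent = "octanol_wet", value = -12)
  list(states = states, experiments = experiments)
}

test_that("the loss reproduces hand arithmetic on a single-state molecule", {
  d <- hand_dataset()
  p <- correction_params(c_mu = 1, c_V = -0.01)
  # model dGsolv = -10 + (-5) + (-1) - 0 = -16; residual vs -12 is -4
  expect_equal(training_loss(d$states, d$experiments, p, "octanol_wet", tc), 16)
})

test_that("the loss vanishes at the generating parameters of noiseless data", {
  synth <- generate_dataset(synthetic_spec(n_molecules = 20, sigma = 0, seed = 9,
                                           solvents = "octanol_wet"))
  L <- training_loss(synth$states, synth$experiments,
                     param_preset("octanol_wet", "2-par"), "octanol_wet", tc)
  expect_lt(L, 1e-18)
})

test_that("the partition-function loss matches a naive brute-force oracle", {
  withr::with_seed(21, {
    rows <- list(); exps <- list()
    for (i in 1:4) {
      mol <- sprintf("T%d", i)
      for (j in 1:5) { # 5 solution states across 2 tautomers
        rows[[length(rows) + 1]] <- sol_row(
          mol, sprintf("%s_t%d", mol, 1 + (j > 3)), sprintf("c%d", j),
          phase = "octanol_wet", E_sol = runif(1, -30, 0),
          mu_ex = runif(1, -15, 0), V_m = runif(1, 50, 300))
      }
      for (j in 1:2) {
        rows[[length(rows) + 1]] <- vac_row(mol, sprintf("%s_t1", mol),
                                            sprintf("v%d", j),
                                            E_vac = runif(1, -20, 0))
      }
      exps[[length(exps) + 1]] <- tibble::tibble(
        molecule_id = mol, observable = "dGsolv", solvent = "octanol_wet",
        value = runif(1, -15, -5))
    }
    states <- dplyr::bind_rows(rows); experiments <- dplyr::bind_rows(exps)
  })
  p <- correction_params(c_mu = 1.2, c_V = -0.02)
  expect_equal(training_loss(states, experiments, p, "octanol_wet", tc),
               naive_training_loss(states, experiments, p, "octanol_wet", tc$RT),
               tolerance = 1e-10)
})

test_that("on single-state molecules the fit equals the closed-form OLS solution", {
  withr::with_seed(33, {
    n <- 30
    mu <- runif(n, -30, -2); V <- runif(n, 50, 350)
    E_sol <- runif(n, -800, -100); E_vac <- E_sol + runif(n, -2, 2)
    dg_exp <- E_sol + 1.27 * mu - 0.014 * V - E_vac + rnorm(n, 0, 0.4)
    ids <- sprintf("L%02d", seq_len(n))
    states <- dplyr::bind_rows(
      sol_row(ids, paste0(ids, "_t1"), "c1", phase = "octanol_wet",
              E_sol = E_sol, mu_ex = mu, V_m = V),
      vac_row(ids, paste0(ids, "_t1"), "v1", E_vac = E_vac))
    experiments <- tibble::tibble(molecule_id = ids, observable = "dGsolv",
                                  solvent = "octanol_wet", value = dg_exp)
  })
  fit <- fit_correction_params(states, experiments, "octanol_wet", constants = tc)
  # with one state per molecule the loss is exactly linear least squares
  ols <- lm(I(dg_exp - E_sol + E_vac) ~ 0 + mu + V)
  expect_equal(fit$params$c_mu, unname(coef(ols)["mu"]), tolerance = 1e-8)
  expect_equal(fit$params$c_V, unname(coef(ols)["V"]), tolerance = 1e-8)
  expect_true(fit$converged)
  # reported loss equals the loss recomputed at the fitted parameters
  expect_equal(fit$loss_value,
               training_loss(states, experiments, fit$params, "octanol_wet", tc),
               tolerance = 1e-9)
})

test_that("noiseless synthetic parameters are recovered to 1e-4", {
  truth <- correction_params(c_mu = 1.3, c_V = -0.01, solvent_label = "octanol_wet")
  synth <- generate_dataset(synthetic_spec(
    n_molecules = 200, sigma = 0, seed = 17, solvents = "octanol_wet",
    true_params = list(octanol_wet = truth)))
  fit <- fit_correction_params(synth$states, synth$experiments, "octanol_wet",
                               constants = tc)
  expect_equal(fit$params$c_mu, 1.3, tolerance = 1e-4)
  expect_equal(fit$params$c_V, -0.01, tolerance = 1e-4)
})

test_that("1-par models keep c_mu fixed at exactly 1", {
  synth <- generate_dataset(synthetic_spec(n_molecules = 40, sigma = 0.2, seed = 5,
                                           solvents = "octanol_wet"))
  fit <- fit_correction_params(synth$states, synth$experiments, "octanol_wet",
                               model = "1-par", constants = tc)
  expect_identical(fit$params$c_mu, 1)
  expect_false(fit$params$free_mask[["c_mu"]])
  expect_true(fit$params$free_mask[["c_V"]])
})

test_that("the fit is invariant to row permutation", {
  synth <- generate_dataset(synthetic_spec(n_molecules = 25, sigma = 0.3, seed = 8,
                                           solvents = "octanol_wet"))
  fit1 <- fit_correction_params(synth$states, synth$experiments, "octanol_wet",
                                constants = tc)
  perm <- withr::with_seed(1, synth$states[sample.int(nrow(synth$states)), ])
  fit2 <- fit_correction_params(perm, synth$experiments, "octanol_wet",
                                constants = tc)
  expect_equal(fit2$params$c_mu, fit1$params$c_mu, tolerance = 1e-10)
  expect_equal(fit2$params$c_V, fit1$params$c_V, tolerance = 1e-10)
})

test_that("degenerate and under-determined datasets are refused", {
  d <- hand_dataset()
  zeroed <- dplyr::mutate(d$states, mu_ex = ifelse(phase == "vacuum", NA, 0),
                          V_m = ifelse(phase == "vacuum", NA, 0))
  expect_error(
    fit_correction_params(zeroed, d$experiments, "octanol_wet", model = "1-par",
                          constants = tc),
    "independent of parameter")
  expect_error(
    fit_correction_params(d$states, d$experiments, "octanol_wet", constants = tc),
    "at least 2 molecules")
})

test_that("strict mode errors on missing coverage, permissive mode drops", {
  synth <- generate_dataset(synthetic_spec(n_molecules = 10, sigma = 0, seed = 2,
                                           solvents = "octanol_wet"))
  exp_partial <- synth$experiments[-1, ]
  expect_error(fit_correction_params(synth$states, exp_partial, "octanol_wet",
                                     constants = tc),
               "lacking.*experimental")
  expect_warning(
    fit <- fit_correction_params(synth$states, exp_partial, "octanol_wet",
                                 mode = "permissive", constants = tc),
    "dropping 1 molecule")
  expect_equal(fit$n_molecules, 9)
})

test_that("tidy and glance summarise a fit", {
  synth <- generate_dataset(synthetic_spec(n_molecules = 15, sigma = 0.1, seed = 4,
                                           solvents = "octanol_wet"))
  fit <- fit_correction_params(synth$states, synth$experiments, "octanol_wet",
                               constants = tc)
  td <- tidy(fit)
  expect_identical(td$term, c("c_mu", "c_V", "c_q"))
  expect_identical(td$fitted, c(TRUE, TRUE, FALSE))
  gl <- glance(fit)
  expect_equal(gl$rmse, sqrt(gl$loss / gl$n_molecules))
  expect_equal(gl$n_molecules, 15)
  expect_output(print(fit), "pmv_fit")
})

test_that("the bootstrap is reproducible and tightens on noiseless data", {
  synth <- generate_dataset(synthetic_spec(n_molecules = 20, sigma = 0, seed = 13,
                                           solvents = "octanol_wet"))
  b1 <- suppressWarnings(bootstrap_parameter_uncertainty(
    synth$states, synth$experiments, "octanol_wet",
    n_resamples = 30, seed = 99, constants = tc))
  b2 <- suppressWarnings(bootstrap_parameter_uncertainty(
    synth$states, synth$experiments, "octanol_wet",
    n_resamples = 30, seed = 99, constants = tc))
  expect_equal(b1, b2) # identical seed, identical intervals
  # noiseless data: interval width collapses
  expect_lt(max(b1$conf_high - b1$conf_low), 1e-6)
  expect_error(bootstrap_parameter_uncertainty(
    synth$states, synth$experiments, "octanol_wet", n_resamples = 0),
    "positive integer")
})
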