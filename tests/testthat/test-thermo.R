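tc <- thermo_constants()

test_that("the corrected chemical potential is the stated linear form", {
  wet2 <- param_preset("octanol_wet", "2-par")
  expect_equal(corrected_chemical_potential(-10, 150, 0, wet2), -14.8649)
  expect_equal(corrected_chemical_potential(0, 0, 0, wet2), 0)
  expect_equal(corrected_chemical_potential(-10, 100, 0, param_preset("water")),
               -20.251)
  # the charge term engages only through q
  w <- param_preset("water")
  expect_equal(corrected_chemical_potential(0, 0, 1, w), -15.728)
})

test_that("per-state Gibbs energies add E_sol to the corrected potential", {
  st <- sol_row("M1", "t1", "c1", E_sol = -500, mu_ex = -10, V_m = 150)
  out <- state_gibbs_energy(st, param_preset("octanol_wet", "2-par"))
  expect_equal(out$G, -514.8649)
  zero <- sol_row("M1", "t1", "c1", E_sol = 0, mu_ex = 0, V_m = 0)
  expect_equal(state_gibbs_energy(zero, correction_params())$G, 0)
  expect_error(state_gibbs_energy(vac_row(), correction_params()), "vacuum")
})

test_that("Boltzmann aggregation has the closed-form values and is stable", {
  expect_equal(boltzmann_aggregate(5, tc), 5)
  expect_equal(boltzmann_aggregate(c(0, 0), tc), -tc$RT * log(2))
  expect_equal(boltzmann_aggregate(c(0, 0), tc), -0.41068, tolerance = 1e-4)
  # a state 100 kcal/mol up contributes nothing, and nothing overflows
  expect_equal(boltzmann_aggregate(c(0, 100), tc), 0, tolerance = 1e-12)
  expect_equal(boltzmann_aggregate(c(-5e4, -5e4 + 1), tc),
               -5e4 - tc$RT * log(1 + exp(-1 / tc$RT)))
  expect_error(boltzmann_aggregate(numeric(0), tc), "empty")
  expect_error(boltzmann_aggregate(c(0, Inf), tc), "finite")
})

test_that("aggregation bound, monotonicity, offset covariance and T->0 limit hold", {
  withr::with_seed(7, {
    for (rep in 1:20) {
      # base energy on the absolute electronic scale, conformer spread small
      # enough that every state registers above machine epsilon
      g <- runif(1, -2000, -100) + runif(sample(2:6, 1), 0, 15)
      agg <- boltzmann_aggregate(g, tc)
      expect_lt(agg, min(g)) # strictly below for >1 state
      expect_lte(boltzmann_aggregate(c(g, min(g) + runif(1, 0, 15)), tc), agg)
      d <- runif(1, -50, 50)
      expect_equal(boltzmann_aggregate(g + d, tc), agg + d, tolerance = 1e-10)
      cold <- thermo_constants(1e-3)
      expect_equal(boltzmann_aggregate(g, cold), min(g), tolerance = 1e-6)
    }
  })
  expect_equal(boltzmann_aggregate(3.14, tc), 3.14) # equality iff one state
})

test_that("stable aggregation agrees with naive summation on small ensembles", {
  withr::with_seed(11, {
    for (rep in 1:50) {
      g <- runif(sample(1:6, 1), -50, 50)
      expect_equal(boltzmann_aggregate(g, tc), naive_aggregate(g, tc$RT),
                   tolerance = 1e-10)
    }
  })
})

test_that("molecule Gibbs energy composes conformer and tautomer partition functions", {
  one <- sol_row("M1", "t1", "c1", E_sol = -500, mu_ex = -10, V_m = 150)
  p <- param_preset("octanol_wet", "2-par")
  expect_equal(molecule_gibbs_energy(one, p, tc)$G, -514.8649)

  # two tautomers split by the SM02 water gap: dominant weight 1/(1+e^(-dG/RT))
  two <- dplyr::bind_rows(
    sol_row("M1", "t1", "c1", E_sol = 0, mu_ex = 0, V_m = 0),
    sol_row("M1", "t2", "c1", E_sol = 5.16, mu_ex = 0, V_m = 0))
  taut <- tautomer_gibbs_energy(two, correction_params(), tc)
  expect_equal(taut$weight[taut$tautomer_id == "t1"],
               1 / (1 + exp(-5.16 / tc$RT)), tolerance = 1e-12)
  expect_equal(taut$weight[taut$tautomer_id == "t1"], 0.99983, tolerance = 1e-5)
  expect_equal(sum(taut$weight), 1, tolerance = 1e-12)

  # multi-state molecule agrees with the naive two-level oracle
  st <- withr::with_seed(3, dplyr::bind_rows(lapply(1:2, function(t) {
    dplyr::bind_rows(lapply(1:3, function(c) {
      sol_row("M1", paste0("t", t), paste0("c", c),
              E_sol = runif(1, -30, 0), mu_ex = runif(1, -10, 0),
              V_m = runif(1, 50, 200))
    }))
  })))
  got <- molecule_gibbs_energy(st, p, tc)
  expect_equal(got$G, naive_molecule_G(st, p, tc$RT), tolerance = 1e-10)
  expect_lte(got$G, min(state_gibbs_energy(st, p)$G))

  # shifting every E_sol shifts G by exactly the same amount
  shifted <- dplyr::mutate(st, E_sol = E_sol + 7.5)
  expect_equal(molecule_gibbs_energy(shifted, p, tc)$G, got$G + 7.5,
               tolerance = 1e-10)
  expect_error(molecule_gibbs_energy(st[0, ], p, tc), "empty|no tautomers|non-empty")
})

test_that("the charge term shifts states uniformly without moving weights", {
  st <- dplyr::bind_rows(
    sol_row("M1", "t1", "c1", E_sol = -10, mu_ex = -5, V_m = 100, q = 1),
    sol_row("M1", "t1", "c2", E_sol = -9, mu_ex = -6, V_m = 110, q = 1),
    sol_row("M1", "t2", "c1", E_sol = -8, mu_ex = -4, V_m = 90, q = 1))
  p0 <- correction_params(c_mu = 1, c_V = -0.01, c_q = 0)
  p1 <- correction_params(c_mu = 1, c_V = -0.01, c_q = -15.728)
  t0 <- tautomer_gibbs_energy(st, p0, tc)
  t1 <- tautomer_gibbs_energy(st, p1, tc)
  expect_equal(t1$weight, t0$weight, tolerance = 1e-12)
  expect_equal(t1$G_t, t0$G_t - 15.728, tolerance = 1e-10)
})

test_that("vacuum aggregation pools all conformers of all tautomers", {
  expect_equal(vacuum_gibbs_energy(vac_row(E_vac = -480), tc)$G_vac, -480)
  two <- dplyr::bind_rows(vac_row(conformer_id = "v1", E_vac = -480),
                          vac_row(conformer_id = "v2", E_vac = -480,
                                  tautomer_id = "M1_t2"))
  expect_equal(vacuum_gibbs_energy(two, tc)$G_vac, -480 - tc$RT * log(2))
  expect_equal(vacuum_gibbs_energy(two, tc)$G_vac, -480.41068, tolerance = 1e-4)
  mixed <- dplyr::bind_rows(vac_row(), sol_row("M1", "M1_t1", "c9"))
  expect_error(vacuum_gibbs_energy(mixed, tc), "vacuum rows only")
})

test_that("solvation free energies subtract the gas-phase reference", {
  st <- dplyr::bind_rows(
    sol_row("M1", "t1", "c1", phase = "octanol_wet",
            E_sol = -500, mu_ex = -10, V_m = 150),
    vac_row("M1", "t1", E_vac = -480))
  dg <- solvation_free_energy(st, param_preset("octanol_wet", "2-par"),
                              constants = tc)
  expect_equal(dg$dG_solv, -514.8649 - (-480))
  # zero corrections, identical energies -> zero solvation energy
  st0 <- dplyr::bind_rows(
    sol_row("M2", "t1", "c1", E_sol = -100, mu_ex = -3, V_m = 50),
    vac_row("M2", "t1", E_vac = -100))
  expect_equal(solvation_free_energy(st0, correction_params(c_mu = 0),
                                     constants = tc)$dG_solv, 0)
  # missing vacuum reference is a coverage error
  expect_error(solvation_free_energy(sol_row(), correction_params()),
               "no vacuum rows")
})

test_that("log P converts transfer free energies and is antisymmetric", {
  expect_equal(log_partition_coefficient(1.36424, 0, tc), 1, tolerance = 1e-4)
  expect_equal(log_partition_coefficient(3, 3, tc), 0)
  expect_equal(log_partition_coefficient(1, 5, tc),
               -log_partition_coefficient(5, 1, tc))
  # linearity: d(logP)/d(G_wat) = 1/(RT ln10)
  expect_equal(log_partition_coefficient(2, 0, tc) - log_partition_coefficient(1, 0, tc),
               1 / tc$RT_ln10)
})

test_that("predict_logp composes the per-phase pipelines", {
  # moderate energies: the reference path is the naive (unshifted) oracle
  st <- random_state_table(n_molecules = 3, seed = 5, e_range = c(-30, 0))
  pw <- param_preset("water")
  po <- param_preset("octanol_wet", "2-par")
  pred <- predict_logp(st, pw, po, constants = tc)
  expect_equal(nrow(pred), 3)
  expect_identical(pred$molecule_id, sort(unique(st$molecule_id)))
  for (m in pred$molecule_id) {
    gw <- naive_molecule_G(st[st$molecule_id == m & st$phase == "water", ], pw, tc$RT)
    go <- naive_molecule_G(st[st$molecule_id == m & st$phase == "octanol_wet", ],
                           po, tc$RT)
    expect_equal(pred$logP_pred[pred$molecule_id == m], (gw - go) / tc$RT_ln10,
                 tolerance = 1e-10)
  }

  # hand-built single-state molecule: dG = 2.72848 -> log P = 2
  hand <- dplyr::bind_rows(
    sol_row("H1", "t1", "c1", phase = "water", E_sol = 2.72848, mu_ex = 0, V_m = 0),
    sol_row("H1", "t1", "c1", phase = "octanol_wet", E_sol = 0, mu_ex = 0, V_m = 0))
  expect_equal(predict_logp(hand, correction_params(), correction_params(),
                            constants = tc)$logP_pred, 2, tolerance = 2e-5)

  # coverage error names the one-phase molecule
  lop <- dplyr::bind_rows(st, sol_row("ONLYW", "t1", "c1", phase = "water"))
  expect_error(predict_logp(lop, pw, po, constants = tc), "ONLYW")

  # empty molecule set gives an empty table
  empty <- st[0, ]
  expect_equal(nrow(predict_logp(empty, pw, po, octanol_phase = "octanol_wet",
                                 constants = tc)), 0)
})
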