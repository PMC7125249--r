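#' Corrected excess chemical potential
#'
#' Applies the linear solvation correction
#' `mu_corr = c_mu * mu_ex + c_V * V_m + c_q * q`.
#' The partial-molar-volume term absorbs the known PMV-proportional error of
#' 3D RISM closures; the charge term is exercised only by the water model
#' (neutral-only octanol models carry `c_q = 0`).
#'
#' @param mu_ex Uncorrected excess chemical potential, kcal mol^-1 (vectorised).
#' @param V_m Partial molar volume, A^3 (vectorised).
#' @param q Net charge, e (vectorised).
#' @param params A [correction_params()] object.
#' @return Corrected excess chemical potential(s), kcal mol^-1.
#' @examples
#' corrected_chemical_potential(-10, 150, 0, param_preset("octanol_wet", "2-par"))
#' @export
corrected_chemical_potential <- function(mu_ex, V_m, q, params) {
  params <- as_correction_params(params)
  params$c_mu * mu_ex + params$c_V * V_m + params$c_q * q
}

#' Per-state Gibbs energy
#'
#' Adds a `G` column to a solution-phase state table:
#' `G = E_sol + corrected_chemical_potential(mu_ex, V_m, q)`. Rotational and
#' vibrational entropic contributions are deliberately ignored; the electronic
#' energy in solution plus the corrected excess chemical potential is the
#' working estimate of a state's Gibbs energy.
#'
#' @param states A solution-phase state table (see [validate_state_table()]).
#' @param params A [correction_params()] object.
#' @return The input tibble with an added numeric column `G` (kcal mol^-1).
#' @export
state_gibbs_energy <- function(states, params) {
  states <- validate_state_table(states)
  if (any(states$phase == "vacuum")) {
    abort("state_gibbs_energy() applies to solution phases only; found vacuum row(s). Use vacuum_gibbs_energy().")
  }
  params <- as_correction_params(params)
  dplyr::mutate(states,
                G = .data$E_sol +
                  corrected_chemical_potential(.data$mu_ex, .data$V_m, .data$q, params))
}

#' Boltzmann aggregation of state energies
#'
#' Collapses a set of per-state Gibbs energies into a single free energy via
#' the discrete partition function `G = -RT ln sum_i exp(-G_i / RT)`,
#' evaluated with a minimum shift so that energies of any magnitude are
#' handled without overflow. The result is always at or below the minimum of
#' the inputs (strictly below for more than one state at finite temperature).
#'
#' @param energies Numeric vector of state free energies, kcal mol^-1.
#' @param constants A [thermo_constants()] object.
#' @return A single free energy, kcal mol^-1.
#' @examples
#' boltzmann_aggregate(c(0, 0)) # -RT ln 2
#' @export
boltzmann_aggregate <- function(energies, constants = thermo_constants()) {
  constants <- as_thermo_constants(constants)
  if (length(energies) == 0) abort("cannot aggregate an empty set of energies")
  if (!is.numeric(energies) || any(!is.finite(energies))) {
    abort("`energies` must be a non-empty numeric vector of finite values")
  }
  lse_free_energy(energies, constants$RT)
}

#' Tautomer-resolved Gibbs energies of a molecule
#'
#' For each molecule and phase in a solution-phase state table, aggregates
#' conformers within each tautomer (microstate) into a tautomer free energy
#' `G_t`, and reports the Boltzmann population of each tautomer. The total
#' molecular Gibbs energy is a second partition function over the tautomers
#' (see [molecule_gibbs_energy()]).
#'
#' @inheritParams state_gibbs_energy
#' @param constants A [thermo_constants()] object.
#' @return A tibble with one row per (molecule_id, phase, tautomer_id):
#'   columns `n_conformers`, `G_t` (kcal mol^-1), `delta_G` (relative to the
#'   most stable tautomer of that molecule/phase) and `weight` (population).
#' @export
tautomer_gibbs_energy <- function(states, params, constants = thermo_constants()) {
  constants <- as_thermo_constants(constants)
  if (nrow(states) == 0) abort("cannot aggregate an empty ensemble")
  states <- state_gibbs_energy(states, params)
  states %>%
    dplyr::group_by(.data$molecule_id, .data$phase, .data$tautomer_id) %>%
    dplyr::summarise(n_conformers = dplyr::n(),
                     G_t = lse_free_energy(.data$G, constants$RT),
                     .groups = "drop_last") %>%
    dplyr::mutate(delta_G = .data$G_t - min(.data$G_t),
                  weight = boltzmann_weights(.data$G_t, constants$RT)) %>%
    dplyr::ungroup() %>%
    dplyr::arrange(.data$molecule_id, .data$phase, .data$tautomer_id)
}

#' Total molecular Gibbs energy in solution
#'
#' Composes the two-level partition function: conformers are aggregated
#' within each tautomer, and the tautomer free energies are aggregated into
#' the total molecular Gibbs energy
#' `G = -RT ln sum_t exp(-G_t / RT)`.
#'
#' @inheritParams tautomer_gibbs_energy
#' @return A tibble with one row per (molecule_id, phase): columns
#'   `n_tautomers`, `n_states` and `G` (kcal mol^-1).
#' @export
molecule_gibbs_energy <- function(states, params, constants = thermo_constants()) {
  constants <- as_thermo_constants(constants)
  taut <- tautomer_gibbs_energy(states, params, constants)
  taut %>%
    dplyr::group_by(.data$molecule_id, .data$phase) %>%
    dplyr::summarise(n_tautomers = dplyr::n(),
                     n_states = sum(.data$n_conformers),
                     G = lse_free_energy(.data$G_t, constants$RT),
                     .groups = "drop")
}

#' Gas-phase reference Gibbs energy
#'
#' Aggregates the vacuum conformers of each molecule into a gas-phase
#' reference energy `-RT ln sum exp(-E_vac / RT)`. All vacuum conformers of
#' all tautomers are pooled into a single sum: the gas-phase conformer set
#' produced upstream is not necessarily in one-to-one correspondence with the
#' solution conformers, so the reference is a single molecular partition
#' function rather than a per-tautomer one.
#'
#' @param states A state table of `phase == "vacuum"` rows only.
#' @param constants A [thermo_constants()] object.
#' @return A tibble with one row per molecule_id: columns `n_states` and
#'   `G_vac` (kcal mol^-1).
#' @export
vacuum_gibbs_energy <- function(states, constants = thermo_constants()) {
  constants <- as_thermo_constants(constants)
  states <- validate_state_table(states)
  if (nrow(states) == 0) abort("no vacuum rows found in the state table")
  if (any(states$phase != "vacuum")) {
    abort("vacuum_gibbs_energy() accepts vacuum rows only; filter the solution phases out first")
  }
  vac <- states
  vac %>%
    dplyr::group_by(.data$molecule_id) %>%
    dplyr::summarise(n_states = dplyr::n(),
                     G_vac = lse_free_energy(.data$E_vac, constants$RT),
                     .groups = "drop")
}

#' Solvation Gibbs energy
#'
#' Standard solvation free energy of each molecule in a given solvent:
#' the Boltzmann-aggregated solution Gibbs energy minus the pooled gas-phase
#' reference, `dGsolv = G_solution - G_vacuum`.
#'
#' @param states A state table containing both the solution rows of
#'   `solvent` and vacuum rows for every molecule.
#' @param params A [correction_params()] for the solvent.
#' @param solvent One of the solution phases; defaults to the single solution
#'   phase present in `states`.
#' @param constants A [thermo_constants()] object.
#' @return A tibble with one row per molecule_id: `G_solution`, `G_vac` and
#'   `dG_solv` (kcal mol^-1).
#' @export
solvation_free_energy <- function(states, params,
                                  solvent = NULL,
                                  constants = thermo_constants()) {
  constants <- as_thermo_constants(constants)
  states <- validate_state_table(states)
  present <- setdiff(unique(states$phase), "vacuum")
  if (is.null(solvent)) {
    if (length(present) != 1) {
      abort(sprintf("state table contains %d solution phases (%s); specify `solvent`",
                    length(present), paste(present, collapse = ", ")))
    }
    solvent <- present
  }
  sol <- dplyr::filter(states, .data$phase == solvent)
  if (nrow(sol) == 0) abort(sprintf("no rows with phase %s", shQuote(solvent)))
  vac <- dplyr::filter(states, .data$phase == "vacuum")
  if (nrow(vac) == 0) abort("no vacuum rows found in the state table")
  missing_vac <- setdiff(unique(sol$molecule_id), unique(vac$molecule_id))
  if (length(missing_vac) > 0) {
    abort(sprintf("molecule(s) missing vacuum states: %s",
                  paste(missing_vac, collapse = ", ")))
  }
  gs <- molecule_gibbs_energy(sol, params, constants)
  gv <- vacuum_gibbs_energy(vac, constants)
  gs %>%
    dplyr::inner_join(gv, by = "molecule_id", suffix = c("", "_vac")) %>%
    dplyr::transmute(.data$molecule_id,
                     G_solution = .data$G,
                     G_vac = .data$G_vac,
                     dG_solv = .data$G - .data$G_vac)
}

#' Octanol-water partition coefficient from Gibbs energies
#'
#' Converts a water/octanol Gibbs energy difference into the decadic
#' partition coefficient, `logP = (G_wat - G_oct) / (RT ln 10)`. By the
#' thermodynamic cycle the gas-phase contributions cancel in the transfer
#' free energy, so absolute solution-phase Gibbs energies are valid inputs;
#' no vacuum reference is needed for log P itself.
#'
#' @param G_wat,G_oct Gibbs energies in water and octanol, kcal mol^-1
#'   (vectorised).
#' @param constants A [thermo_constants()] object.
#' @return log P (dimensionless, log10 units); positive values favour the
#'   octanol phase.
#' @examples
#' log_partition_coefficient(0, 1.364247) # ~1
#' @export
log_partition_coefficient <- function(G_wat, G_oct, constants = thermo_constants()) {
  constants <- as_thermo_constants(constants)
  (G_wat - G_oct) / constants$RT_ln10
}

#' Predict per-molecule log P from state tables
#'
#' Runs the full pipeline for every molecule: per-state Gibbs energies with
#' the solvent-specific corrections, two-level partition-function aggregation
#' in each phase, and the direct conversion of the Gibbs energy difference
#' into log P.
#'
#' @param states A state table containing rows for `"water"` and for one
#'   octanol phase (and optionally vacuum rows, which are ignored here).
#' @param params_water,params_octanol [correction_params()] for the aqueous
#'   and the organic phase. Defaults are the published water model and the
#'   wet-octanol 2-parameter model.
#' @param octanol_phase `"octanol_wet"` or `"octanol_dry"`; defaults to the
#'   octanol phase present in `states`.
#' @param constants A [thermo_constants()] object.
#' @return A tibble sorted by `molecule_id` with columns `G_wat`, `G_oct`
#'   (kcal mol^-1) and `logP_pred`.
#' @export
predict_logp <- function(states,
                         params_water = param_preset("water"),
                         params_octanol = param_preset("octanol_wet", "2-par"),
                         octanol_phase = NULL,
                         constants = thermo_constants()) {
  constants <- as_thermo_constants(constants)
  states <- validate_state_table(states)
  if (is.null(octanol_phase)) {
    oct_present <- intersect(unique(states$phase), c("octanol_wet", "octanol_dry"))
    if (length(oct_present) != 1) {
      abort(sprintf("state table contains %d octanol phases; specify `octanol_phase`",
                    length(oct_present)))
    }
    octanol_phase <- oct_present
  }
  wat <- dplyr::filter(states, .data$phase == "water")
  oct <- dplyr::filter(states, .data$phase == octanol_phase)
  only_wat <- setdiff(unique(wat$molecule_id), unique(oct$molecule_id))
  only_oct <- setdiff(unique(oct$molecule_id), unique(wat$molecule_id))
  if (length(only_wat) + length(only_oct) > 0) {
    abort(sprintf(
      "molecule(s) present in one phase only: %s",
      paste(c(sprintf("%s (water only)", only_wat),
              sprintf("%s (%s only)", only_oct, octanol_phase)), collapse = ", ")))
  }
  if (nrow(wat) == 0) {
    return(tibble(molecule_id = character(), G_wat = numeric(),
                  G_oct = numeric(), logP_pred = numeric()))
  }
  g_wat <- molecule_gibbs_energy(wat, params_water, constants)
  g_oct <- molecule_gibbs_energy(oct, params_octanol, constants)
  dplyr::inner_join(
    dplyr::select(g_wat, "molecule_id", G_wat = "G"),
    dplyr::select(g_oct, "molecule_id", G_oct = "G"),
    by = "molecule_id"
  ) %>%
    dplyr::mutate(logP_pred = log_partition_coefficient(.data$G_wat, .data$G_oct,
                                                        constants)) %>%
    dplyr::arrange(.data$molecule_id)
}
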