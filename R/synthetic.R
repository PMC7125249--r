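#' Specification for a synthetic component dataset
#'
#' Defines the study conditions under which synthetic integral-equation-like
#' energy components are generated: ensemble sizes, component distributions,
#' ground-truth correction parameters per solvent, and the experimental noise
#' level. The distributions mimic the energy regime of real small-molecule
#' calculations — large negative absolute electronic energies, excess
#' chemical potentials of roughly -40 to +5 kcal mol^-1 scaling with the
#' partial molar volume, conformer spreads of order 1 kcal mol^-1 — so the
#' numerically delicate paths (partition functions over huge absolute
#' energies) are exercised by every generated dataset.
#'
#' @param n_molecules Number of molecules.
#' @param tautomer_range Integer range (min, max) of tautomers per molecule
#'   (default 1-3).
#' @param conformer_range Integer range (min, max) of conformers per
#'   tautomer and phase (default 1-5, the upstream conformer cap).
#' @param solvents Solution phases to generate (default water and wet
#'   octanol).
#' @param true_params Named list of [correction_params()] per solvent; the
#'   ground truth used to compute noiseless observables. Defaults to the
#'   published presets for the chosen solvents.
#' @param sigma Standard deviation of additive Gaussian noise on the
#'   experimental observables, kcal mol^-1 (log P noise is
#'   `sigma / (RT ln 10)`); 0 gives noiseless references.
#' @param seed Integer seed; identical specs generate identical datasets.
#' @return An object of class `synthetic_spec` (a list of the above).
#' @export
synthetic_spec <- function(n_molecules = 100,
                           tautomer_range = c(1L, 3L),
                           conformer_range = c(1L, 5L),
                           solvents = c("water", "octanol_wet"),
                           true_params = NULL,
                           sigma = 0.3,
                           seed = 1) {
  if (n_molecules < 1) abort("`n_molecules` must be at least 1")
  if (length(tautomer_range) != 2 || any(tautomer_range < 1) ||
      tautomer_range[1] > tautomer_range[2]) {
    abort("`tautomer_range` must be c(min, max) with 1 <= min <= max")
  }
  if (length(conformer_range) != 2 || any(conformer_range < 1) ||
      conformer_range[1] > conformer_range[2]) {
    abort("`conformer_range` must be c(min, max) with 1 <= min <= max")
  }
  if (!all(solvents %in% SOLUTION_PHASES)) {
    abort(sprintf("`solvents` must be among: %s",
                  paste(SOLUTION_PHASES, collapse = ", ")))
  }
  if (sigma < 0) abort("`sigma` must be non-negative")
  if (is.null(true_params)) {
    true_params <- lapply(setNames(solvents, solvents), function(s) {
      if (s == "water") param_preset("water") else param_preset(s, "2-par")
    })
  }
  if (!all(solvents %in% names(true_params))) {
    abort("`true_params` must provide parameters for every solvent")
  }
  structure(
    list(n_molecules = as.integer(n_molecules),
         tautomer_range = as.integer(tautomer_range),
         conformer_range = as.integer(conformer_range),
         solvents = solvents,
         true_params = lapply(true_params, as_correction_params),
         sigma = sigma, seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

#' Generate a synthetic component dataset with known ground truth
#'
#' Draws a full synthetic dataset under a [synthetic_spec()]: per-state
#' energy component tables for each solution phase plus vacuum, experimental
#' reference tables (solvation free energies per solvent and log P when both
#' partitioning phases are present) computed exactly from the ground-truth
#' parameters and then perturbed with the specified Gaussian noise, and the
#' noiseless observables themselves.
#'
#' Per molecule: the partial molar volume is uniform on 50-400 A^3; the
#' excess chemical potential is linear in the volume with negative slope
#' plus molecule-level Gaussian scatter; each state adds small conformer
#' perturbations; tautomers sit 2 kcal mol^-1 plus an exponential gap above
#' the most stable one; conformers spread exponentially with mean
#' 1 kcal mol^-1; absolute electronic energies are uniform on
#' -5000..-500 kcal mol^-1; vacuum conformers sit within +/-2 kcal mol^-1 of
#' the solution electronic baseline.
#'
#' @param spec A [synthetic_spec()].
#' @param constants A [thermo_constants()] object used for the noiseless
#'   observables.
#' @return An object of class `synthetic_dataset`: list with `states`
#'   (one validated state table covering all phases incl. vacuum),
#'   `experiments` (noisy reference table), `ground_truth` (list with
#'   `true_params`, `noiseless` observables tibble and the generating
#'   `spec`).
#' @examples
#' d <- generate_dataset(synthetic_spec(n_molecules = 5, sigma = 0, seed = 42))
#' head(d$states)
#' @export
generate_dataset <- function(spec, constants = thermo_constants()) {
  if (!inherits(spec, "synthetic_spec")) abort("`spec` must be a synthetic_spec()")
  constants <- as_thermo_constants(constants)
  withr::with_seed(spec$seed, generate_dataset_impl(spec, constants))
}

rint <- function(range) {
  if (range[1] == range[2]) return(range[1])
  sample(seq(range[1], range[2]), 1)
}

generate_dataset_impl <- function(spec, constants) {
  n <- spec$n_molecules
  ids <- sprintf("SYN%03d", seq_len(n))
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    mol <- ids[i]
    n_taut <- rint(spec$tautomer_range)
    taut_ids <- sprintf("%s_micro%03d", mol, seq_len(n_taut))
    E0 <- runif(1, -5000, -500)                  # absolute electronic baseline
    Vm0 <- runif(1, 50, 400)
    mu0 <- 5 - 0.1 * Vm0 + rnorm(1, 0, 3)        # PMV-scaling mu_ex, ~[-40, 5]
    taut_offsets <- c(0, 2 + rexp(n_taut - 1, rate = 1 / 5))[seq_len(n_taut)]

    mol_rows <- list()
    for (phase in spec$solvents) {
      phase_shift <- rnorm(1, 0, 1)              # solvent-specific electronics
      for (t in seq_len(n_taut)) {
        n_conf <- rint(spec$conformer_range)
        conf_offsets <- c(0, rexp(n_conf - 1, rate = 1))[seq_len(n_conf)]
        mol_rows[[length(mol_rows) + 1]] <- tibble(
          molecule_id = mol, tautomer_id = taut_ids[t],
          conformer_id = sprintf("c%02d", seq_len(n_conf)), phase = phase,
          E_sol = E0 + phase_shift + taut_offsets[t] + conf_offsets,
          E_vac = NA_real_,
          mu_ex = mu0 + rnorm(n_conf, 0, 0.5),
          V_m = pmax(20, Vm0 + rnorm(n_conf, 0, 2)),
          q = 0
        )
      }
    }
    n_vac <- rint(spec$conformer_range)
    vac_offsets <- c(0, rexp(n_vac - 1, rate = 1))[seq_len(n_vac)]
    mol_rows[[length(mol_rows) + 1]] <- tibble(
      molecule_id = mol, tautomer_id = taut_ids[1],
      conformer_id = sprintf("v%02d", seq_len(n_vac)), phase = "vacuum",
      E_sol = NA_real_,
      E_vac = E0 + runif(1, -2, 2) + vac_offsets,
      mu_ex = NA_real_, V_m = NA_real_, q = 0
    )
    rows[[i]] <- dplyr::bind_rows(mol_rows)
  }
  states <- validate_state_table(dplyr::bind_rows(rows))

  # noiseless observables under the ground-truth parameters
  noiseless <- purrr::map_dfr(spec$solvents, function(s) {
    sub <- dplyr::filter(states, .data$phase %in% c(s, "vacuum"))
    dg <- solvation_free_energy(sub, spec$true_params[[s]], solvent = s,
                                constants = constants)
    tibble(molecule_id = dg$molecule_id, observable = "dGsolv",
           solvent = s, value = dg$dG_solv)
  })
  both <- c("water", intersect(c("octanol_wet", "octanol_dry"), spec$solvents))
  if (length(both) == 2 && "water" %in% spec$solvents) {
    oct <- both[2]
    g_w <- molecule_gibbs_energy(dplyr::filter(states, .data$phase == "water"),
                                 spec$true_params[["water"]], constants)
    g_o <- molecule_gibbs_energy(dplyr::filter(states, .data$phase == oct),
                                 spec$true_params[[oct]], constants)
    logp <- tibble(
      molecule_id = g_w$molecule_id, observable = "logP", solvent = "",
      value = log_partition_coefficient(g_w$G, g_o$G, constants)
    )
    noiseless <- dplyr::bind_rows(noiseless, logp)
  }
  experiments <- noiseless
  if (spec$sigma > 0) {
    noise <- rnorm(nrow(experiments), 0, spec$sigma)
    is_logp <- experiments$observable == "logP"
    noise[is_logp] <- noise[is_logp] / constants$RT_ln10
    experiments$value <- experiments$value + noise
  }
  structure(
    list(states = states,
         experiments = validate_experiment_table(experiments),
         ground_truth = list(true_params = spec$true_params,
                             noiseless = noiseless, spec = spec)),
    class = "synthetic_dataset"
  )
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("<synthetic_dataset: %d molecules, %d state rows, solvents %s, sigma = %g, seed = %d>\n",
              x$ground_truth$spec$n_molecules, nrow(x$states),
              paste(x$ground_truth$spec$solvents, collapse = "+"),
              x$ground_truth$spec$sigma, x$ground_truth$spec$seed))
  invisible(x)
}

#' Synthetic dataset with a class-specific systematic offset
#'
#' Builds a dataset like [generate_dataset()] and then shifts the water-phase
#' electronic energies of a labelled subset of molecules by a constant,
#' emulating a class-specific model deficiency (e.g. hydroxyl-bearing
#' compounds): the experimental tables keep the unperturbed ground truth, so
#' predictions on the labelled molecules acquire a water-vs-octanol error
#' offset of exactly `offset` kcal mol^-1, i.e. a log P error of
#' `offset / (RT ln 10)`.
#'
#' @inheritParams generate_dataset
#' @param outlier_ids Molecule ids to perturb (indices into the generated
#'   `SYN...` ids are also accepted); must be non-empty.
#' @param offset Water-phase energy offset in kcal mol^-1 (finite).
#' @return A `synthetic_dataset`; `ground_truth$outliers` records the
#'   perturbed ids and the offset.
#' @export
generate_outlier_scenario <- function(spec, outlier_ids, offset,
                                      constants = thermo_constants()) {
  if (length(outlier_ids) == 0) abort("`outlier_ids` must be non-empty")
  if (!is.finite(offset)) abort("`offset` must be finite")
  data <- generate_dataset(spec, constants)
  if (is.numeric(outlier_ids)) {
    outlier_ids <- sprintf("SYN%03d", as.integer(outlier_ids))
  }
  unknown <- setdiff(outlier_ids, unique(data$states$molecule_id))
  if (length(unknown) > 0) {
    abort(sprintf("unknown outlier molecule(s): %s", paste(unknown, collapse = ", ")))
  }
  hit <- data$states$molecule_id %in% outlier_ids & data$states$phase == "water"
  data$states$E_sol[hit] <- data$states$E_sol[hit] + offset
  data$ground_truth$outliers <- list(ids = outlier_ids, offset = offset)
  data
}
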