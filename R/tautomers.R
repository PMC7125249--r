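#' Reassign conformers to corrected tautomer labels
#'
#' Individual conformations can undergo a protonation shift during the
#' upstream quantum-chemical optimisation, ending up labelled with the
#' starting microstate rather than the one they actually represent. This
#' operation applies an explicit user-supplied mapping
#' (`molecule_id, conformer_id, phase -> new_tautomer_id`) before the
#' partition functions are evaluated; it is idempotent and leaves unlisted
#' rows untouched. No structure perception is performed.
#'
#' @param states A state table.
#' @param map A data frame with columns `molecule_id`, `conformer_id`,
#'   `phase`, `new_tautomer_id`. Each target tautomer must already exist for
#'   the molecule.
#' @return The state table with corrected `tautomer_id` values.
#' @export
apply_reassignment <- function(states, map) {
  states <- validate_state_table(states)
  if (nrow(map) == 0) return(states)
  check_columns(map, c("molecule_id", "conformer_id", "phase", "new_tautomer_id"),
                "reassignment map")
  map <- as_tibble(map)
  known <- states %>%
    dplyr::distinct(.data$molecule_id, .data$tautomer_id)
  bad <- dplyr::anti_join(map, known,
                          by = c(molecule_id = "molecule_id",
                                 new_tautomer_id = "tautomer_id"))
  if (nrow(bad) > 0) {
    abort(sprintf("reassignment targets unknown tautomer(s): %s",
                  paste(unique(paste(bad$molecule_id, bad$new_tautomer_id, sep = "/")),
                        collapse = ", ")))
  }
  out <- states %>%
    dplyr::left_join(map, by = c("molecule_id", "conformer_id", "phase")) %>%
    dplyr::mutate(tautomer_id = dplyr::coalesce(.data$new_tautomer_id,
                                                .data$tautomer_id)) %>%
    dplyr::select(-"new_tautomer_id")
  validate_state_table(out)
}

#' Relative tautomer energies
#'
#' Shifts a set of tautomer Gibbs energies so the most stable tautomer sits
#' at exactly zero; ties all map to zero. Applying the operation twice is the
#' identity.
#'
#' @param G_per_tautomer Named numeric vector (or a data frame with columns
#'   `tautomer_id`, `G_t`) of tautomer free energies, kcal mol^-1.
#' @return Same shape as the input, shifted so `min == 0`.
#' @examples
#' relative_tautomer_energies(c(SM02_micro002 = -10, SM02_micro003 = -4.84))
#' @export
relative_tautomer_energies <- function(G_per_tautomer) {
  if (is.data.frame(G_per_tautomer)) {
    check_columns(G_per_tautomer, c("tautomer_id", "G_t"), "tautomer table")
    if (nrow(G_per_tautomer) == 0) abort("no tautomers given")
    out <- as_tibble(G_per_tautomer)
    out$G_t <- out$G_t - min(out$G_t)
    return(out)
  }
  if (length(G_per_tautomer) == 0) abort("no tautomers given")
  G_per_tautomer - min(G_per_tautomer)
}

#' Boltzmann populations of tautomers
#'
#' Softmax of `-G/RT` over the tautomers of one molecule; invariant to any
#' additive shift of the energies, so absolute and relative tautomer Gibbs
#' energies give identical populations.
#'
#' @inheritParams relative_tautomer_energies
#' @param constants A [thermo_constants()] object.
#' @return Named numeric vector (or tibble with `population` column) summing
#'   to 1.
#' @examples
#' tautomer_populations(c(a = 0, b = 5.16, c = 6.18))
#' @export
tautomer_populations <- function(G_per_tautomer, constants = thermo_constants()) {
  constants <- as_thermo_constants(constants)
  if (is.data.frame(G_per_tautomer)) {
    check_columns(G_per_tautomer, c("tautomer_id", "G_t"), "tautomer table")
    if (nrow(G_per_tautomer) == 0) abort("no tautomers given")
    out <- as_tibble(G_per_tautomer)
    out$population <- boltzmann_weights(out$G_t, constants$RT)
    return(out)
  }
  if (length(G_per_tautomer) == 0) abort("no tautomers given")
  setNames(boltzmann_weights(G_per_tautomer, constants$RT),
           names(G_per_tautomer))
}

#' Tautomer stability report for a state table
#'
#' End-to-end tautomer analysis per molecule for one solvent/model: tautomer
#' free energies from the conformer partition functions, energies relative to
#' the most stable microstate, Boltzmann populations, and the dominant
#' tautomer flag.
#'
#' @inheritParams tautomer_gibbs_energy
#' @param reassignment Optional reassignment map applied first
#'   (see [apply_reassignment()]).
#' @return A tibble with one row per (molecule_id, phase, tautomer_id):
#'   `G_t`, `delta_G`, `population`, `rank` (1 = most stable; ties share the
#'   minimum rank and are broken lexicographically in row order), `dominant`.
#' @export
tautomer_report <- function(states, params, constants = thermo_constants(),
                            reassignment = NULL) {
  if (!is.null(reassignment)) states <- apply_reassignment(states, reassignment)
  taut <- tautomer_gibbs_energy(states, params, constants)
  taut %>%
    dplyr::group_by(.data$molecule_id, .data$phase) %>%
    dplyr::mutate(population = .data$weight,
                  rank = rank(.data$G_t, ties.method = "min"),
                  dominant = seq_along(.data$G_t) == which.min(.data$G_t)) %>%
    dplyr::ungroup() %>%
    dplyr::select("molecule_id", "phase", "tautomer_id", "n_conformers",
                  "G_t", "delta_G", "population", "rank", "dominant")
}

#' Cross-solvent tautomer rank concordance
#'
#' Checks, per molecule, whether the stability ordering of the tautomers is
#' identical across a set of solvent/model columns — i.e. whether changing
#' the solvent environment shifts the dominant tautomer or reorders any pair
#' of microstates.
#'
#' @param rel_energies A data frame with columns `molecule_id`,
#'   `tautomer_id` and one numeric column per solvent/model (relative or
#'   absolute tautomer energies; ranking is shift-invariant).
#' @param columns Character vector of the solvent/model columns to compare;
#'   default: all numeric columns.
#' @return A list: `per_molecule` (tibble with `molecule_id`, `n_tautomers`,
#'   `concordant`, and the reference ordering), and `n_shifts` (count of
#'   molecules whose ordering differs between any two columns).
#' @examples
#' rank_shift_report(load_builtin_fixture("table4_relative_energies"))
#' @export
rank_shift_report <- function(rel_energies, columns = NULL) {
  check_columns(rel_energies, c("molecule_id", "tautomer_id"), "relative-energy table")
  rel_energies <- as_tibble(rel_energies)
  if (is.null(columns)) {
    columns <- names(rel_energies)[purrr::map_lgl(rel_energies, is.numeric)]
  }
  if (length(columns) < 2) abort("need at least two solvent/model columns to compare")
  if (any(is.na(rel_energies[columns]))) {
    abort("tautomer sets differ between columns (missing energies)")
  }
  per_mol <- rel_energies %>%
    dplyr::group_by(.data$molecule_id) %>%
    dplyr::group_modify(function(df, key) {
      orders <- purrr::map(columns, function(col) {
        df$tautomer_id[order(df[[col]], df$tautomer_id)]
      })
      tibble(n_tautomers = nrow(df),
             concordant = all(purrr::map_lgl(orders, identical, orders[[1]])),
             ordering = paste(orders[[1]], collapse = " < "))
    }) %>%
    dplyr::ungroup()
  list(per_molecule = per_mol,
       n_shifts = sum(!per_mol$concordant),
       columns = columns)
}
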