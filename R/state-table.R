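STATE_COLUMNS <- c("molecule_id", "tautomer_id", "conformer_id", "phase",
                   "E_sol", "E_vac", "mu_ex", "V_m", "q")

#' Validate a state table
#'
#' A state table holds one row per (molecule, tautomer, conformer, phase)
#' with the energy components produced upstream by the integral-equation /
#' quantum-chemistry pipeline: electronic energy in solution `E_sol`,
#' uncorrected excess chemical potential `mu_ex` and partial molar volume
#' `V_m` for solution phases, gas-phase electronic energy `E_vac` for
#' `vacuum` rows, and the molecular net charge `q`. Energies are in
#' kcal mol^-1, volumes in cubic angstrom, charges in elementary charges.
#'
#' Validation enforces the structural invariants:
#' * the state key (molecule, tautomer, conformer, phase) is unique;
#' * solution rows carry `E_sol`, `mu_ex`, `V_m` (and no `E_vac`);
#' * vacuum rows carry `E_vac` (and no `mu_ex`/`V_m`);
#' * `q` is constant within a molecule (the net charge cannot differ
#'   between tautomers or conformers of the same species).
#'
#' @param data A data frame with the state-table columns. `E_sol`, `E_vac`,
#'   `mu_ex`, `V_m` may contain `NA` for the phases where they do not apply;
#'   an empty cell on file read becomes `NA`. Zero is a legal value and never
#'   means "absent".
#' @return The validated table as a tibble, row order preserved.
#' @examples
#' validate_state_table(tibble::tibble(
#'   molecule_id = "SM02", tautomer_id = "SM02_micro002", conformer_id = "c0",
#'   phase = "water", E_sol = -500, E_vac = NA, mu_ex = -12, V_m = 180, q = 0
#' ))
#' @export
validate_state_table <- function(data) {
  check_columns(data, STATE_COLUMNS, "state table")
  data <- as_tibble(data)
  for (col in c("E_sol", "E_vac", "mu_ex", "V_m", "q")) {
    data[[col]] <- as.numeric(data[[col]])
  }
  bad_phase <- setdiff(unique(data$phase), PHASES)
  if (length(bad_phase) > 0) {
    abort(sprintf("unknown phase value(s): %s (expected %s)",
                  paste(bad_phase, collapse = ", "), paste(PHASES, collapse = ", ")))
  }
  key <- paste(data$molecule_id, data$tautomer_id, data$conformer_id, data$phase,
               sep = " / ")
  dup <- unique(key[duplicated(key)])
  if (length(dup) > 0) {
    abort(sprintf("duplicate state key(s): %s", paste(dup, collapse = "; ")))
  }
  sol <- data$phase != "vacuum"
  miss_sol <- sol & (is.na(data$E_sol) | is.na(data$mu_ex) | is.na(data$V_m))
  if (any(miss_sol)) {
    abort(sprintf("solution-phase row(s) missing E_sol/mu_ex/V_m: %s",
                  paste(unique(key[miss_sol]), collapse = "; ")))
  }
  miss_vac <- !sol & is.na(data$E_vac)
  if (any(miss_vac)) {
    abort(sprintf("vacuum row(s) missing E_vac: %s",
                  paste(unique(key[miss_vac]), collapse = "; ")))
  }
  extra_vac <- !sol & (!is.na(data$mu_ex) | !is.na(data$V_m))
  if (any(extra_vac)) {
    abort(sprintf("vacuum row(s) must not carry mu_ex or V_m: %s",
                  paste(unique(key[extra_vac]), collapse = "; ")))
  }
  if (any(is.na(data$q))) abort("column `q` must not contain missing values")
  nq <- tapply(data$q, data$molecule_id, function(x) length(unique(x)))
  if (any(nq > 1)) {
    abort(sprintf("net charge `q` is not constant within molecule(s): %s",
                  paste(names(nq)[nq > 1], collapse = ", ")))
  }
  data
}

#' Read and write state tables
#'
#' Reads a TSV or CSV state table (header `molecule_id, tautomer_id,
#' conformer_id, phase, E_sol, E_vac, mu_ex, V_m, q`), validates it with
#' [validate_state_table()], and returns a tibble. Empty cells denote absent
#' components; scientific notation is accepted. `write_state_table()` writes
#' the same layout back with full double precision, so a read/write round
#' trip is the identity.
#'
#' @param path File path.
#' @param dialect `"tsv"` (default) or `"csv"`; on read, guessed from the
#'   file extension when not given.
#' @param data A state table (validated on write).
#' @return A validated tibble of states (`read_state_table`), or `path`
#'   invisibly (`write_state_table`).
#' @export
read_state_table <- function(path, dialect = NULL) {
  df <- read_delim_table(path, dialect,
                         col_types = readr::cols(
                           molecule_id = "c", tautomer_id = "c",
                           conformer_id = "c", phase = "c",
                           E_sol = "d", E_vac = "d", mu_ex = "d", V_m = "d", q = "d"
                         ),
                         required = STATE_COLUMNS, what = "state table")
  validate_state_table(df)
}

#' @rdname read_state_table
#' @export
write_state_table <- function(data, path, dialect = NULL) {
  data <- validate_state_table(data)
  write_delim_table(data, path, dialect)
}

#' Read and write experiment tables
#'
#' Experimental reference values, one row per (molecule, observable,
#' solvent): solvation Gibbs energies (`observable = "dGsolv"`, kcal mol^-1,
#' `solvent` one of the solution phases) or partition coefficients
#' (`observable = "logP"`, log10 units, `solvent` empty).
#'
#' @inheritParams read_state_table
#' @param data An experiment table with columns
#'   `molecule_id, observable, solvent, value`.
#' @return A validated tibble (`read_experiment_table`), or `path` invisibly.
#' @export
read_experiment_table <- function(path, dialect = NULL) {
  df <- read_delim_table(path, dialect,
                         col_types = readr::cols(
                           molecule_id = "c", observable = "c",
                           solvent = "c", value = "d"
                         ),
                         required = c("molecule_id", "observable", "solvent", "value"),
                         what = "experiment table")
  validate_experiment_table(df)
}

#' @rdname read_experiment_table
#' @export
write_experiment_table <- function(data, path, dialect = NULL) {
  data <- validate_experiment_table(data)
  write_delim_table(data, path, dialect)
}

#' @rdname read_experiment_table
#' @export
validate_experiment_table <- function(data) {
  check_columns(data, c("molecule_id", "observable", "solvent", "value"),
                "experiment table")
  data <- as_tibble(data)
  data$value <- as.numeric(data$value)
  bad <- setdiff(unique(data$observable), c("dGsolv", "logP"))
  if (length(bad) > 0) {
    abort(sprintf("unknown observable(s): %s (expected dGsolv or logP)",
                  paste(bad, collapse = ", ")))
  }
  data$solvent[is.na(data$solvent)] <- ""
  bad_solv <- with(data, unique(solvent[observable == "dGsolv" &
                                          !solvent %in% SOLUTION_PHASES]))
  if (length(bad_solv) > 0) {
    abort(sprintf("dGsolv rows need a solution-phase solvent, got: %s",
                  paste(shQuote(bad_solv), collapse = ", ")))
  }
  key <- paste(data$molecule_id, data$observable, data$solvent, sep = " / ")
  dup <- unique(key[duplicated(key)])
  if (length(dup) > 0) {
    abort(sprintf("duplicate experiment record(s): %s", paste(dup, collapse = "; ")))
  }
  data
}

guess_dialect <- function(path, dialect) {
  if (!is.null(dialect)) return(match.arg(dialect, c("tsv", "csv")))
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "tsv"
}

read_delim_table <- function(path, dialect, col_types, required, what) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  dialect <- guess_dialect(path, dialect)
  reader <- if (dialect == "csv") readr::read_csv else readr::read_tsv
  df <- reader(path, col_types = col_types, na = c("", "NA"),
               progress = FALSE, show_col_types = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s %s is missing column(s): %s", what, path,
                  paste(missing, collapse = ", ")))
  }
  df
}

write_delim_table <- function(data, path, dialect) {
  dialect <- guess_dialect(path, dialect)
  if (dialect == "csv") readr::write_csv(data, path) else readr::write_tsv(data, path)
  invisible(path)
}
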