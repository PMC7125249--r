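#' Correction parameters for the excess chemical potential
#'
#' A solvent-specific correction model maps the raw integral-equation excess
#' chemical potential to a corrected one via
#' `mu_corr = c_mu * mu_ex + c_V * V_m + c_q * q`,
#' where `V_m` is the partial molar volume (the known error-scaling variable
#' of 3D RISM theory) and `q` the molecular net charge. `free_mask` records
#' which parameters are adjustable during training; fixed parameters keep
#' their values exactly.
#'
#' @param c_mu Dimensionless scale on the excess chemical potential.
#' @param c_V Partial-molar-volume coefficient, kcal mol^-1 A^-3.
#' @param c_q Net-charge coefficient, kcal mol^-1 e^-1.
#' @param solvent_label Free-text label, typically one of the phase names.
#' @param free_mask Named logical vector over `c("c_mu", "c_V", "c_q")`;
#'   `TRUE` marks a parameter as fitted rather than fixed.
#'
#' @return An object of class `correction_params`.
#' @examples
#' correction_params(c_mu = 1.28924, c_V = -0.01315, solvent_label = "octanol_wet")
#' @seealso [param_preset()] for the published models.
#' @export
correction_params <- function(c_mu = 1, c_V = 0, c_q = 0,
                              solvent_label = "unspecified",
                              free_mask = c(c_mu = FALSE, c_V = FALSE, c_q = FALSE)) {
  for (v in list(c_mu = c_mu, c_V = c_V, c_q = c_q)) {
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v)) {
      abort("`c_mu`, `c_V` and `c_q` must each be a single finite number.")
    }
  }
  mask <- c(c_mu = FALSE, c_V = FALSE, c_q = FALSE)
  if (!is.null(free_mask)) {
    if (is.null(names(free_mask)) || !all(names(free_mask) %in% names(mask))) {
      abort("`free_mask` must be a named logical vector over c_mu, c_V, c_q.")
    }
    mask[names(free_mask)] <- as.logical(free_mask)
  }
  structure(
    list(c_mu = as.numeric(c_mu), c_V = as.numeric(c_V), c_q = as.numeric(c_q),
         solvent_label = as.character(solvent_label), free_mask = mask),
    class = "correction_params"
  )
}

#' @export
print.correction_params <- function(x, ...) {
  flag <- function(p) if (x$free_mask[[p]]) " (fitted)" else ""
  cat(sprintf("<correction_params: %s>\n", x$solvent_label))
  cat(sprintf("  c_mu = %.6g%s\n  c_V  = %.6g kcal/mol/A^3%s\n  c_q  = %.6g kcal/mol/e%s\n",
              x$c_mu, flag("c_mu"), x$c_V, flag("c_V"), x$c_q, flag("c_q")))
  invisible(x)
}

as_correction_params <- function(x) {
  if (inherits(x, "correction_params")) return(x)
  abort("expected a `correction_params` object (see `correction_params()` or `param_preset()`).")
}

# Published trained models, keyed by (solvent, model). The water model uses a
# fixed unit scale on mu_ex plus PMV and charge terms; the octanol models come
# in a PMV-only (1-par) and a scaled (2-par) variant for dry and wet octanol.
.param_presets <- function() {
  list(
    water = correction_params(
      c_mu = 1, c_V = -0.10251, c_q = -15.728, solvent_label = "water",
      free_mask = c(c_mu = FALSE, c_V = TRUE, c_q = TRUE)
    ),
    `octanol_dry/1-par` = correction_params(
      c_mu = 1, c_V = -0.00799, c_q = 0, solvent_label = "octanol_dry",
      free_mask = c(c_mu = FALSE, c_V = TRUE, c_q = FALSE)
    ),
    `octanol_dry/2-par` = correction_params(
      c_mu = 1.33446, c_V = -0.00609, c_q = 0, solvent_label = "octanol_dry",
      free_mask = c(c_mu = TRUE, c_V = TRUE, c_q = FALSE)
    ),
    `octanol_wet/1-par` = correction_params(
      c_mu = 1, c_V = -0.01552, c_q = 0, solvent_label = "octanol_wet",
      free_mask = c(c_mu = FALSE, c_V = TRUE, c_q = FALSE)
    ),
    `octanol_wet/2-par` = correction_params(
      c_mu = 1.28924, c_V = -0.01315, c_q = 0, solvent_label = "octanol_wet",
      free_mask = c(c_mu = TRUE, c_V = TRUE, c_q = FALSE)
    )
  )
}

#' Published correction-model presets
#'
#' Returns the trained correction parameters of the published solvation
#' models: the water model (fixed `c_mu = 1`, fitted PMV and charge terms)
#' and the four n-octanol models (dry/wet crossed with 1-parameter PMV-only
#' and 2-parameter scaled corrections).
#'
#' @param solvent One of `"water"`, `"octanol_dry"`, `"octanol_wet"`.
#' @param model For octanol, `"1-par"` or `"2-par"`; ignored for water.
#' @return A [correction_params()] object.
#' @examples
#' param_preset("octanol_wet", "2-par")
#' @export
param_preset <- function(solvent = c("water", "octanol_dry", "octanol_wet"),
                         model = c("2-par", "1-par")) {
  solvent <- match.arg(solvent)
  model <- match.arg(model)
  key <- if (solvent == "water") "water" else paste(solvent, model, sep = "/")
  .param_presets()[[key]]
}

#' Read and write correction parameters as JSON
#'
#' `write_params()` serialises a [correction_params()] object (plus an
#' optional temperature) to a JSON file; `read_params()` restores it. The
#' round trip is lossless to full double precision (values are written with
#' all significant digits).
#'
#' @param params A [correction_params()] object.
#' @param path File path.
#' @param temperature Optional temperature in kelvin stored alongside the
#'   parameters (default 298.15).
#' @return `read_params()` returns a `correction_params` object with the
#'   stored temperature attached as attribute `"temperature"`;
#'   `write_params()` returns `path` invisibly.
#' @examples
#' p <- param_preset("octanol_wet", "2-par")
#' f <- tempfile(fileext = ".json")
#' write_params(p, f)
#' read_params(f)
#' @export
write_params <- function(params, path, temperature = 298.15) {
  params <- as_correction_params(params)
  obj <- list(
    solvent_label = params$solvent_label,
    c_mu = params$c_mu, c_V = params$c_V, c_q = params$c_q,
    free_mask = as.list(params$free_mask),
    T = temperature
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  if (!file.exists(path)) abort(sprintf("parameter file not found: %s", path))
  obj <- tryCatch(jsonlite::read_json(path),
                  error = function(e) abort(sprintf("malformed parameter file %s: %s",
                                                    path, conditionMessage(e))))
  needed <- c("c_mu", "c_V", "c_q", "solvent_label")
  missing <- setdiff(needed, names(obj))
  if (length(missing) > 0) {
    abort(sprintf("parameter file %s is missing field(s): %s",
                  path, paste(missing, collapse = ", ")))
  }
  mask <- c(c_mu = FALSE, c_V = FALSE, c_q = FALSE)
  if (!is.null(obj$free_mask)) mask[names(obj$free_mask)] <- unlist(obj$free_mask)
  out <- correction_params(
    c_mu = obj$c_mu, c_V = obj$c_V, c_q = obj$c_q,
    solvent_label = obj$solvent_label, free_mask = mask
  )
  attr(out, "temperature") <- if (is.null(obj$T)) 298.15 else obj$T
  out
}
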