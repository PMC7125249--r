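#' Thermodynamic constants
#'
#' Bundles the molar gas constant and the working temperature together with
#' the derived products `RT` and `RT * ln(10)` that appear in every partition
#' function and in the conversion between transfer free energies and log P.
#' All package functions that exponentiate energies accept one of these
#' objects so tests and users can vary the temperature.
#'
#' @param temperature Temperature in kelvin. Defaults to 298.15 K, the
#'   temperature at which both the training data and the blind-challenge
#'   measurements were taken.
#' @param R Molar gas constant in kcal mol^-1 K^-1 (CODATA value by default).
#'
#' @return An object of class `thermo_constants`: a list with elements `R`,
#'   `T`, `RT` and `RT_ln10`.
#' @examples
#' tc <- thermo_constants()
#' tc$RT # ~0.5925 kcal/mol at 298.15 K
#' @export
thermo_constants <- function(temperature = 298.15, R = 1.98720425864083e-3) {
  if (!is.numeric(temperature) || length(temperature) != 1 || !is.finite(temperature) ||
      temperature <= 0) {
    abort("`temperature` must be a single positive number (kelvin).")
  }
  if (!is.numeric(R) || length(R) != 1 || !is.finite(R) || R <= 0) {
    abort("`R` must be a single positive number (kcal/mol/K).")
  }
  structure(
    list(R = R, T = temperature, RT = R * temperature,
         RT_ln10 = R * temperature * log(10)),
    class = "thermo_constants"
  )
}

#' @export
print.thermo_constants <- function(x, ...) {
  cat(sprintf("<thermo_constants> T = %.4g K, RT = %.6f kcal/mol, RT ln10 = %.6f kcal/mol\n",
              x$T, x$RT, x$RT_ln10))
  invisible(x)
}

as_thermo_constants <- function(x) {
  if (inherits(x, "thermo_constants")) return(x)
  if (is.null(x)) return(thermo_constants())
  abort("`constants` must be created with `thermo_constants()`.")
}
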