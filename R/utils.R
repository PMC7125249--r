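# Numerically stable -RT ln sum(exp(-g/RT)) for a bare numeric vector.
# Shifts by the minimum energy before exponentiation so that absolute
# electronic energies (10^2..10^5 kcal/mol) never overflow.
lse_free_energy <- function(g, rt) {
  m <- min(g)
  m - rt * log(sum(exp(-(g - m) / rt)))
}

# Boltzmann weights of a set of free energies (softmax of -g/RT),
# invariant to additive shifts of g.
boltzmann_weights <- function(g, rt) {
  e <- exp(-(g - min(g)) / rt)
  e / sum(e)
}

#' Round half away from zero
#'
#' Decimal rounding with ties going away from zero, the convention used by
#' the printed tables this package reproduces. Base R's `round()` rounds
#' half to even, which disagrees on exact .5 ties.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @examples
#' round_half_up(0.125, 2) # 0.13, where round() gives 0.12
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# shared column checker for tabular inputs
check_columns <- function(data, cols, what) {
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(data)
}
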