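# Physical constants and small shared numerics.

# molar gas constant, J mol^-1 K^-1
.R_J <- 8.314462618

# atomic mass unit, kg
.AMU_KG <- 1.66053906660e-27

#' Thermal energy RT in kJ/mol
#'
#' @param temperature temperature in K.
#' @return RT in kJ/mol (2.478 kJ/mol at 298 K).
#' @export
#' @examples
#' rt_kj(298.15)
rt_kj <- function(temperature) {
  stopifnot(is.numeric(temperature), temperature > 0)
  .R_J * temperature / 1000
}

# trapezoid integral with half-bin rectangle extensions at both ends, so a
# function tabulated on bin centers integrates exactly over the full bin span
.trapz_bins <- function(x, y) {
  if (length(x) == 1L) return(y)
  w <- diff(x)
  pracma::trapz(x, y) + 0.5 * w[1] * y[1] + 0.5 * w[length(w)] * y[length(y)]
}

# scalar check helpers used by the constructors
.chk_num1 <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  if (nonneg && x < 0)
    stop(sprintf("'%s' must be >= 0", name), call. = FALSE)
  invisible(x)
}
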