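#' Physical constants and unit conventions
#'
#' The package works in a single fixed unit system: lengths in angstrom,
#' time in nanoseconds, mass in atomic mass units, energy in kcal/mol,
#' charge in elementary charges, and electrostatic potential in volts.
#'
#' @param temperature simulation temperature in kelvin (default 310, body
#'   temperature, the thermostat setting of the study systems).
#' @return A list of class `sim_constants` with components
#'   `R` (gas constant, kcal mol-1 K-1), `temperature` (K), `kT`
#'   (kcal mol-1), and `coulomb_to_volt` (multiply a potential expressed in
#'   e/angstrom by this factor to obtain volts).
#' @examples
#' const <- sim_constants()
#' const$kT           # ~0.616 kcal/mol at 310 K
#' @export
sim_constants <- function(temperature = 310) {
  if (!is.numeric(temperature) || length(temperature) != 1L || temperature <= 0)
    stop("temperature must be a single positive number (kelvin)")
  R <- 1.987204259e-3  # kcal mol-1 K-1
  structure(list(
    R = R,
    temperature = temperature,
    kT = R * temperature,
    coulomb_to_volt = 14.3996   # e/Angstrom -> V
  ), class = "sim_constants")
}

#' @export
print.sim_constants <- function(x, ...) {
  cat("Unit system: Angstrom, ns, amu, kcal/mol, e, V\n")
  cat(sprintf("  T      = %g K\n", x$temperature))
  cat(sprintf("  R      = %.9g kcal/mol/K\n", x$R))
  cat(sprintf("  k_B T  = %.6g kcal/mol\n", x$kT))
  invisible(x)
}
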