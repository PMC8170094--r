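# Physical constants (6 significant figures where known to that precision)
KB_KCAL_MOL_K <- 0.0019872   # Boltzmann constant, kcal/mol/K
KB_EV_K <- 8.6173e-5         # Boltzmann constant, eV/K
KCAL_MOL_PER_EV <- 23.0609   # energy conversion, kcal/mol per eV
HBAR_EV_S <- 6.5821e-16      # reduced Planck constant, eV s

#' Thermodynamic parameter bundle
#'
#' Collects the temperature-dependent constants used throughout the
#' free-energy and rate calculations: the Boltzmann constant in kcal/mol/K
#' and eV/K, the thermal energy `kBT` in both unit systems, and the
#' kcal/mol-per-eV conversion factor.
#'
#' @param temperature_K Absolute temperature in Kelvin. Default 300 K.
#'
#' @return An object of class `"thermo"`: a list with elements
#'   `temperature_K`, `kB` (kcal/mol/K), `kBT` (kcal/mol), `kB_eV` (eV/K),
#'   `kBT_eV` (eV) and `kcal_per_eV`.
#'
#' @examples
#' th <- thermo(300)
#' th$kBT  # 0.59616 kcal/mol
#' @export
thermo <- function(temperature_K = 300) {
  if (!is.numeric(temperature_K) || length(temperature_K) != 1L ||
      !is.finite(temperature_K) || temperature_K <= 0) {
    stop("`temperature_K` must be a single positive number.", call. = FALSE)
  }
  structure(
    list(
      temperature_K = temperature_K,
      kB = KB_KCAL_MOL_K,
      kBT = KB_KCAL_MOL_K * temperature_K,
      kB_eV = KB_EV_K,
      kBT_eV = KB_EV_K * temperature_K,
      kcal_per_eV = KCAL_MOL_PER_EV
    ),
    class = "thermo"
  )
}

#' @export
print.thermo <- function(x, ...) {
  cat(sprintf("<thermo> T = %g K, kBT = %.5g kcal/mol (%.5g eV)\n",
              x$temperature_K, x$kBT, x$kBT_eV))
  invisible(x)
}

#' Convert energies between kcal/mol and eV
#'
#' @param x Numeric vector of energies.
#' @return Numeric vector in the target unit (1 eV = 23.0609 kcal/mol).
#' @examples
#' kcal_to_ev(23.0609)  # 1
#' @export
kcal_to_ev <- function(x) x / KCAL_MOL_PER_EV

#' @rdname kcal_to_ev
#' @export
ev_to_kcal <- function(x) x * KCAL_MOL_PER_EV

as_thermo <- function(x) {
  if (inherits(x, "thermo")) return(x)
  if (is.numeric(x) && length(x) == 1L) return(thermo(x))
  stop("expected a `thermo` object or a temperature in Kelvin", call. = FALSE)
}
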