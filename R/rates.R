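convert_energies <- function(delta_g0, lambda_reorg,
                             energy_units = c("kcal/mol", "eV")) {
  energy_units <- match.arg(energy_units)
  if (energy_units == "kcal/mol") {
    delta_g0 <- kcal_to_ev(delta_g0)
    lambda_reorg <- kcal_to_ev(lambda_reorg)
  }
  if (!is.finite(lambda_reorg) || lambda_reorg <= 0) {
    stop("reorganization energy must be positive", call. = FALSE)
  }
  list(delta_g0_ev = delta_g0, lambda_ev = lambda_reorg)
}

#' Marcus nonadiabatic electron-transfer rate
#'
#' Evaluates the high-temperature nonadiabatic Marcus rate
#' `k = (2 pi / hbar) |T_AB|^2 (4 pi Lambda kBT)^(-1/2)
#'    exp(-(Lambda + dG0)^2 / (4 Lambda kBT))`
#' with energies handled internally in eV. The electronic coupling must be
#' supplied -- it is not derivable from the free-energy chain -- so this
#' route is an optional alternative to the empirical distance ruler.
#'
#' @param delta_g0 Driving force (product minus reactant minimum).
#' @param lambda_reorg Reorganization energy (> 0).
#' @param coupling_eV Electronic coupling `|T_AB|`, eV.
#' @param temperature_K Temperature, K. Default 300.
#' @param energy_units Units of `delta_g0` and `lambda_reorg`:
#'   `"kcal/mol"` (default, converted internally) or `"eV"`.
#'
#' @return Rate in 1/s.
#' @examples
#' marcus_rate(-0.5, 1, coupling_eV = 1e-3, energy_units = "eV")
#' @export
marcus_rate <- function(delta_g0, lambda_reorg, coupling_eV,
                        temperature_K = 300,
                        energy_units = c("kcal/mol", "eV")) {
  if (missing(coupling_eV) || is.null(coupling_eV)) {
    stop("`coupling_eV` is required for the Marcus rate; use ",
         "`moser_dutton_rate()` when no coupling is available", call. = FALSE)
  }
  en <- convert_energies(delta_g0, lambda_reorg, energy_units)
  kBT <- KB_EV_K * temperature_K
  pref <- 2 * pi / HBAR_EV_S * coupling_eV^2 /
    sqrt(4 * pi * en$lambda_ev * kBT)
  pref * exp(-(en$lambda_ev + en$delta_g0_ev)^2 / (4 * en$lambda_ev * kBT))
}

#' Empirical distance-ruler electron-transfer rate
#'
#' The empirical tunneling relationship for biological electron transfer:
#' `log10 k = 15 - 0.6 R - 3.1 (dG + Lambda)^2 / Lambda`, with `R` the
#' donor-acceptor edge-to-edge distance in Angstrom, energies in eV and the
#' rate in 1/s. Vectorized over `r_A`.
#'
#' @inheritParams marcus_rate
#' @param r_A Edge-to-edge distance(s), Angstrom.
#'
#' @return Rate(s) in 1/s.
#' @examples
#' moser_dutton_rate(-21.6, 84.5, r_A = 4.87)  # ~6e5
#' @export
moser_dutton_rate <- function(delta_g0, lambda_reorg, r_A,
                              energy_units = c("kcal/mol", "eV")) {
  en <- convert_energies(delta_g0, lambda_reorg, energy_units)
  10^(15 - 0.6 * r_A -
        3.1 * (en$delta_g0_ev + en$lambda_ev)^2 / en$lambda_ev)
}

#' Donor-acceptor distance implied by a target rate
#'
#' Inverts the empirical distance ruler for `R`:
#' `R = (15 - 3.1 (dG + Lambda)^2 / Lambda - log10 k) / 0.6`. A negative
#' result (rate faster than the contact limit allows) is returned as-is
#' with a warning.
#'
#' @inheritParams marcus_rate
#' @param k_target Target rate, 1/s (> 0).
#'
#' @return Distance in Angstrom.
#' @examples
#' implied_distance(-21.6, 84.5, k_target = 6.1e5)  # ~4.87
#' @export
implied_distance <- function(delta_g0, lambda_reorg, k_target,
                             energy_units = c("kcal/mol", "eV")) {
  stopifnot(k_target > 0)
  en <- convert_energies(delta_g0, lambda_reorg, energy_units)
  r <- (15 - 3.1 * (en$delta_g0_ev + en$lambda_ev)^2 / en$lambda_ev -
          log10(k_target)) / 0.6
  if (any(r < 0)) {
    warning("implied distance is negative: the target rate exceeds the ",
            "contact-limit rate for these energies", call. = FALSE)
  }
  r
}

#' Snapshot-averaged electron-transfer rate
#'
#' Applies the empirical distance ruler to each snapshot of a
#' donor-acceptor distance series and averages the resulting rates
#' arithmetically. Because the rate is convex (exponential) in distance,
#' the average is dominated by the close-approach snapshots and exceeds the
#' rate at the mean distance.
#'
#' @inheritParams marcus_rate
#' @param r_series Numeric vector of per-snapshot distances, Angstrom
#'   (non-empty), or a data frame with column `r_A`.
#'
#' @return A list with `k_et_per_s` (per-snapshot rates) and
#'   `mean_k_et_per_s`.
#' @export
average_rate_over_snapshots <- function(r_series, delta_g0, lambda_reorg,
                                        energy_units = c("kcal/mol", "eV")) {
  if (is.data.frame(r_series)) r_series <- r_series$r_A
  if (length(r_series) == 0L) stop("empty distance series", call. = FALSE)
  k <- moser_dutton_rate(delta_g0, lambda_reorg, r_series, energy_units)
  list(k_et_per_s = k, mean_k_et_per_s = mean(k))
}

#' Superoxide production rate from binding-weighted electron transfer
#'
#' Combines the electron-transfer rate with oxygen binding/unbinding
#' kinetics at the reaction site:
#' `k = k_bind * k_et / (k_et + k_unbind)`. The result is the superoxide
#' production rate while the enzyme is in the semiquinone state; if the
#' occupancy fraction `x_sq` of that state is supplied, the per-complex
#' rate `x_sq * k` is also returned.
#'
#' @param k_bind,k_unbind Oxygen binding and unbinding rates at the site,
#'   1/s (>= 0).
#' @param k_et Electron-transfer rate, 1/s (>= 0); `k_et + k_unbind` must
#'   be positive.
#' @param x_sq Optional semiquinone-state occupancy fraction.
#'
#' @return A list with `production_rate_per_s` and, when `x_sq` is given,
#'   `per_complex_rate_per_s`.
#' @examples
#' production_rate(2e5, 1e8, 6.1e5)$production_rate_per_s  # ~1.2e3
#' @export
production_rate <- function(k_bind, k_unbind, k_et, x_sq = NULL) {
  stopifnot(k_bind >= 0, k_unbind >= 0, k_et >= 0)
  if (k_et + k_unbind <= 0) {
    stop("k_et + k_unbind must be positive", call. = FALSE)
  }
  k <- k_bind * k_et / (k_et + k_unbind)
  out <- list(production_rate_per_s = k)
  if (!is.null(x_sq)) out$per_complex_rate_per_s <- x_sq * k
  out
}
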