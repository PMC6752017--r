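# Headspace / dissolved / bicarbonate partitioning of H2 and CO2 in sealed
# crimp-top microcosm vessels: ideal gas law for the headspace, Henry's law
# for the dissolved fraction, Henderson-Hasselbalch for bicarbonate.

.R_GAS <- 8.314462618  # J mol-1 K-1
.ATM_KPA <- 101.325

#' Microcosm vessel geometry
#'
#' Defaults describe a 27-ml crimp-seal tube holding a 10-ml slurry,
#' pressurized with 60 kPa N2 overpressure (absolute pressure 161.325 kPa)
#' and held near room temperature. Whether a reported pressurization is
#' gauge or absolute, and the exact incubation temperature, are
#' experiment-specific; both are plain arguments rather than hidden
#' assumptions.
#'
#' @param total_ml Total vessel volume (ml).
#' @param liquid_ml Slurry (liquid) volume (ml).
#' @param temperature_K Temperature (K).
#' @param pressure_kPa Absolute headspace pressure (kPa).
#' @return An object of class `"vessel_geometry"` with the derived
#'   `headspace_ml`.
#' @export
vessel_geometry <- function(total_ml = 27, liquid_ml = 10,
                            temperature_K = 298.15,
                            pressure_kPa = .ATM_KPA + 60) {
  if (total_ml <= 0 || liquid_ml < 0 || temperature_K <= 0 ||
      pressure_kPa <= 0)
    stop("vessel geometry parameters must be positive")
  head <- total_ml - liquid_ml
  if (head <= 0) stop("headspace volume (total - liquid) must be positive")
  structure(list(total_ml = total_ml, liquid_ml = liquid_ml,
                 headspace_ml = head, temperature_K = temperature_K,
                 pressure_kPa = pressure_kPa), class = "vessel_geometry")
}

#' Gas solubility and carbonate constants
#'
#' Henry solubility constants (mol L-1 atm-1) and the first carbonate
#' dissociation constant. The defaults are standard 25 degC values:
#' K_H(CO2) = 0.0339 and K_H(H2) = 7.8e-4 mol/L/atm, pKa1 = 6.35. All are
#' overridable for other temperatures or ionic strengths.
#'
#' @param henry Named vector of Henry constants per gas id.
#' @param pKa1 First carbonate dissociation constant (pH units).
#' @return An object of class `"gas_constants"`.
#' @export
gas_constants <- function(henry = c(co2 = 0.0339, h2 = 7.8e-4),
                          pKa1 = 6.35) {
  if (any(henry <= 0) || pKa1 <= 0)
    stop("gas constants must be positive")
  structure(list(henry = henry, pKa1 = pKa1), class = "gas_constants")
}

#' Headspace amount from a mixing ratio
#'
#' Ideal-gas amount of a gas in the vessel headspace:
#' n = x P V_head / (R T), in micromoles.
#'
#' @param mixing_ratio Headspace mixing ratio (mole fraction, in \[0, 1\]).
#' @param geom A [vessel_geometry()].
#' @return Amount in umol.
#' @export
headspace_amount <- function(mixing_ratio, geom = vessel_geometry()) {
  stopifnot(inherits(geom, "vessel_geometry"))
  if (any(mixing_ratio < 0 | mixing_ratio > 1))
    stop("mixing_ratio must lie in [0, 1]")
  p_pa <- geom$pressure_kPa * 1000
  v_m3 <- geom$headspace_ml * 1e-6
  mixing_ratio * p_pa * v_m3 / (.R_GAS * geom$temperature_K) * 1e6
}

#' Dissolved amount from a mixing ratio
#'
#' Henry's-law amount of gas dissolved in the slurry:
#' n = K_H x P_atm V_liq, in micromoles.
#'
#' @inheritParams headspace_amount
#' @param gas Gas id (`"co2"` or `"h2"`, matching `names(k$henry)`).
#' @param k A [gas_constants()].
#' @return Amount in umol.
#' @export
dissolved_amount <- function(mixing_ratio, gas, geom = vessel_geometry(),
                             k = gas_constants()) {
  stopifnot(inherits(geom, "vessel_geometry"), inherits(k, "gas_constants"))
  if (any(mixing_ratio < 0 | mixing_ratio > 1))
    stop("mixing_ratio must lie in [0, 1]")
  gas <- tolower(gas)
  if (!gas %in% names(k$henry))
    stop("no Henry constant for gas '", gas, "'")
  p_atm <- geom$pressure_kPa / .ATM_KPA
  # K_H [mol/L/atm] * partial pressure [atm] * volume [L] -> mol -> umol
  k$henry[[gas]] * mixing_ratio * p_atm * (geom$liquid_ml / 1000) * 1e6
}

#' Bicarbonate amount in equilibrium with dissolved CO2
#'
#' Henderson-Hasselbalch: HCO3- = dissolved CO2 * 10^(pH - pKa1). At
#' pH = pKa1 the bicarbonate pool equals the dissolved CO2 pool. Carbonate
#' (CO3^2-) is neglected; at pH <= 7.5 its contribution is below 1 percent.
#'
#' @param dissolved_co2 Dissolved CO2 amount (umol).
#' @param pH Slurry pH.
#' @param k A [gas_constants()].
#' @return Bicarbonate amount in umol.
#' @export
bicarbonate_amount <- function(dissolved_co2, pH, k = gas_constants()) {
  stopifnot(inherits(k, "gas_constants"))
  if (any(dissolved_co2 < 0)) stop("dissolved_co2 must be >= 0")
  dissolved_co2 * 10^(pH - k$pKa1)
}

#' Total vessel amount of H2 or CO2
#'
#' Sums the headspace and dissolved pools, and for CO2 additionally the
#' bicarbonate pool derived from pH. H2 is pH-independent.
#'
#' @inheritParams dissolved_amount
#' @param pH Slurry pH; required for CO2, ignored for H2.
#' @param fresh_weight_g Optional gut-content fresh weight (g); when given,
#'   a per-gram-fresh-weight value is reported as well.
#' @return A one-row data frame with columns `gas`, `headspace_umol`,
#'   `dissolved_umol`, `bicarbonate_umol`, `total_umol` and (if
#'   `fresh_weight_g` is given) `umol_per_gFW`.
#' @examples
#' total_gas(0.05, "co2", pH = 7.0,
#'           geom = vessel_geometry(pressure_kPa = 101.325))
#' @export
total_gas <- function(mixing_ratio, gas, pH = NULL,
                      geom = vessel_geometry(), k = gas_constants(),
                      fresh_weight_g = NULL) {
  gas <- tolower(gas)
  head <- headspace_amount(mixing_ratio, geom)
  diss <- dissolved_amount(mixing_ratio, gas, geom, k)
  bic <- 0
  if (gas == "co2") {
    if (is.null(pH)) stop("pH is required for CO2 (bicarbonate pool)")
    bic <- bicarbonate_amount(diss, pH, k)
  }
  out <- data.frame(gas = gas, headspace_umol = head, dissolved_umol = diss,
                    bicarbonate_umol = bic, total_umol = head + diss + bic,
                    stringsAsFactors = FALSE)
  if (!is.null(fresh_weight_g)) {
    if (fresh_weight_g <= 0) stop("fresh_weight_g must be positive")
    out$umol_per_gFW <- out$total_umol / fresh_weight_g
  }
  out
}
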