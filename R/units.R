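# Physical conversions between oxygen saturation, concentration and partial
# pressure in (sea)water, and depth to hydrostatic pressure.
#
# Formulations pinned here:
#   * vapour pressure of pure water: Buck (1981) over liquid water;
#   * seawater vapour-pressure depression: Green & Carritt (1967),
#     p_sw = p_w * (1 - 5.37e-4 * S);
#   * oxygen solubility: Garcia & Gordon (1992), Benson & Krause coefficient
#     fit (ml l^-1), converted to mmol m^-3 with 44.6596 umol per ml O2;
#   * depth -> pressure: Saunders (1981) with latitude-dependent gravity;
#   * hydrostatic effect on equilibrium pO2: Henry's-law pressure correction
#     exp(Vm * P / (R * T)) with Vm = 32 cm^3 mol^-1 for dissolved O2.

#' @keywords internal
MOLE_FRACTION_O2 <- 0.20946

#' @keywords internal
STANDARD_ATM_KPA <- 101.325

#' Saturation vapour pressure of water
#'
#' Buck (1981) empirical fit over liquid water, with the Green & Carritt
#' seawater depression applied when `salinity > 0`.
#'
#' @param temp water temperature, degrees C (valid roughly -2 to 40).
#' @param salinity practical salinity (psu); 0 for fresh water.
#' @return vapour pressure in kPa.
#' @export
vapour_pressure <- function(temp, salinity = 0) {
  stopifnot(all(temp > -273.15))
  pw <- 0.61121 * exp((18.678 - temp / 234.5) * (temp / (257.14 + temp)))
  pw * (1 - 5.37e-4 * salinity)
}

#' Convert oxygen saturation (% air saturation) to partial pressure
#'
#' pO2 = (sat/100) x chi_O2 x (P_baro - p_vapour(T)), with chi_O2 = 0.20946
#' the mole fraction of O2 in dry air. The inverse is
#' [po2_to_saturation()]; the two round-trip exactly.
#'
#' @param sat percent air saturation (>= 0; values slightly above 100 allowed
#'   for supersaturation).
#' @param temp water temperature, degrees C; must lie in (-2, 40).
#' @param salinity practical salinity (psu). Defaults to 0 (the vapour
#'   pressure of pure water), appropriate when the respirometry system's
#'   calibration did not track salinity.
#' @param baro_kpa barometric pressure, kPa (default one standard atmosphere).
#' @return oxygen partial pressure, kPa.
#' @export
saturation_to_po2 <- function(sat, temp, salinity = 0, baro_kpa = STANDARD_ATM_KPA) {
  stopifnot(all(sat >= 0))
  if (any(temp < -2 | temp > 40)) {
    stop("temperature out of the supported -2..40 degC range")
  }
  (sat / 100) * MOLE_FRACTION_O2 * (baro_kpa - vapour_pressure(temp, salinity))
}

#' @rdname saturation_to_po2
#' @param po2 oxygen partial pressure, kPa.
#' @export
po2_to_saturation <- function(po2, temp, salinity = 0, baro_kpa = STANDARD_ATM_KPA) {
  stopifnot(all(po2 >= 0))
  if (any(temp < -2 | temp > 40)) {
    stop("temperature out of the supported -2..40 degC range")
  }
  100 * po2 / (MOLE_FRACTION_O2 * (baro_kpa - vapour_pressure(temp, salinity)))
}

#' Oxygen saturation concentration in seawater
#'
#' Garcia & Gordon (1992) solubility fit (Benson & Krause data), i.e. the
#' equilibrium O2 concentration of water in contact with water-saturated air
#' at one atmosphere total pressure.
#'
#' @param temp temperature, degrees C (-5 to 45 supported by the fit).
#' @param salinity practical salinity (psu, 0-42).
#' @return saturation concentration, mmol m^-3.
#' @export
o2_saturation_concentration <- function(temp, salinity = 35) {
  if (any(temp < -5 | temp > 45)) stop("temperature outside solubility fit range")
  if (any(salinity < 0 | salinity > 42)) stop("salinity outside solubility fit range")
  ts <- log((298.15 - temp) / (273.15 + temp))
  a <- c(2.00907, 3.22014, 4.05010, 4.94457, -0.256847, 3.88767)
  b <- c(-0.00624523, -0.00737614, -0.0103410, -0.00817083)
  c0 <- -4.88682e-07
  lnc <- a[1] + a[2] * ts + a[3] * ts^2 + a[4] * ts^3 + a[5] * ts^4 + a[6] * ts^5 +
    salinity * (b[1] + b[2] * ts + b[3] * ts^2 + b[4] * ts^3) +
    c0 * salinity^2
  exp(lnc) * 44.6596      # ml/l -> mmol/m^3
}

#' Convert dissolved oxygen concentration to partial pressure
#'
#' Linear in concentration: pO2 = conc / alpha(T, S) x f(P), where alpha is
#' the solubility coefficient (saturation concentration divided by the
#' atmospheric O2 partial pressure at the surface) and f(P) =
#' exp(Vm P / (R T)) is the hydrostatic Henry's-law correction at pressure P
#' (dbar), using a partial molar volume Vm = 32 cm^3 mol^-1 for dissolved O2.
#'
#' @param conc dissolved O2, mmol m^-3 (>= 0).
#' @param temp temperature, degrees C.
#' @param salinity practical salinity, psu.
#' @param pressure_dbar hydrostatic pressure at depth, dbar (0 at surface).
#' @return oxygen partial pressure, kPa.
#' @export
o2_conc_to_po2 <- function(conc, temp, salinity = 35, pressure_dbar = 0) {
  stopifnot(all(conc >= 0), all(pressure_dbar >= 0))
  csat <- o2_saturation_concentration(temp, salinity)
  po2_air <- MOLE_FRACTION_O2 * (STANDARD_ATM_KPA - vapour_pressure(temp, salinity))
  alpha <- csat / po2_air                       # mmol m^-3 kPa^-1
  vm <- 32e-6                                   # m^3 mol^-1
  r <- 8.31446                                  # J mol^-1 K^-1
  pa <- pressure_dbar * 1e4                     # dbar -> Pa
  (conc / alpha) * exp(vm * pa / (r * (temp + 273.15)))
}

#' Hydrostatic pressure at depth
#'
#' Saunders (1981) depth-to-pressure formulation with latitude-dependent
#' gravity: p = h * 1.0052405 * (1 + 0.00528 sin^2(lat)) + 2.36e-6 h^2.
#'
#' @param depth depth below sea surface, m (>= 0).
#' @param lat latitude, degrees.
#' @return pressure, dbar.
#' @export
pressure_at_depth <- function(depth, lat = 0) {
  if (any(depth < 0)) stop("negative depth")
  s2 <- sin(lat * pi / 180)^2
  depth * 1.0052405 * (1 + 0.00528 * s2) + 2.36e-6 * depth^2
}
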