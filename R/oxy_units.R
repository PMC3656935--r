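#' @keywords internal
o2_units <- c("kPa", "percent_sat", "mg_per_L", "mL_per_L")

# oxygen density at STP, mg per mL, for the mL/L <-> mg/L conversion
O2_MG_PER_ML <- 1.42905

check_TS <- function(temperature, salinity) {
  if (any(!is.finite(temperature)) || any(temperature < -2) ||
      any(temperature > 40))
    stop("temperature must lie in [-2, 40] C")
  if (any(!is.finite(salinity)) || any(salinity < 0) || any(salinity > 42))
    stop("salinity must lie in [0, 42]")
  invisible(NULL)
}

#' Oxygen solubility at 100 % air saturation
#'
#' Dissolved oxygen concentration (mg/L) of water in equilibrium with the
#' atmosphere at 1 atm total pressure, from the Benson-Krause equation (the
#' formulation behind the USGS DOTABLES tables). Decreases with both
#' temperature and salinity.
#'
#' @param temperature water temperature, degrees C, in \[-2, 40\].
#' @param salinity practical salinity, in \[0, 42\].
#' @return saturation concentration in mg O2 per litre (vectorized).
#' @examples
#' o2_saturation_concentration(18, 0)
#' o2_saturation_concentration(18, 35)
#' @export
o2_saturation_concentration <- function(temperature, salinity) {
  check_TS(temperature, salinity)
  Tk <- temperature + 273.15
  lnC <- -139.34411 + 1.575701e5 / Tk - 6.642308e7 / Tk^2 +
    1.243800e10 / Tk^3 - 8.621949e11 / Tk^4 -
    salinity * (1.7674e-2 - 1.0754e1 / Tk + 2.1407e3 / Tk^2)
  exp(lnC)
}

#' Convert dissolved oxygen between units
#'
#' Converts among oxygen partial pressure (`"kPa"`), percent air saturation
#' (`"percent_sat"`), concentration (`"mg_per_L"`), and volumetric
#' concentration (`"mL_per_L"`). kPa and percent saturation are related by
#' the fixed air-saturation oxygen partial pressure (`constants$p_o2_sat`,
#' default 20.95 kPa) and need no hydrography; conversions involving mg/L or
#' mL/L additionally require temperature and salinity through the
#' Benson-Krause solubility and refuse to run without them.
#'
#' All conversions are exactly invertible and positive-homogeneous.
#'
#' @param value oxygen value(s) to convert, >= 0.
#' @param from,to units, one of `"kPa"`, `"percent_sat"`, `"mg_per_L"`,
#'   `"mL_per_L"`.
#' @param temperature,salinity hydrography; required only when `from` or `to`
#'   is a concentration unit.
#' @param constants an `acartia_constants` object (for `p_o2_sat`).
#' @return converted value(s), same length as `value`.
#' @examples
#' o2_convert(2, "mg_per_L", "kPa", temperature = 18, salinity = 35)
#' o2_convert(50, "percent_sat", "kPa")
#' @export
o2_convert <- function(value, from, to, temperature = NULL, salinity = NULL,
                       constants = model_constants()) {
  from <- match.arg(from, o2_units)
  to <- match.arg(to, o2_units)
  if (any(!is.finite(value)) || any(value < 0))
    stop("oxygen value must be finite and >= 0")
  if (from == to) return(value)

  needs_sol <- c(from, to) %in% c("mg_per_L", "mL_per_L")
  if (any(needs_sol)) {
    if (is.null(temperature) || is.null(salinity))
      stop("temperature and salinity are required to convert ", from,
           " to ", to)
    sat <- o2_saturation_concentration(temperature, salinity)
  }

  # to the canonical unit, kPa
  kpa <- switch(from,
    kPa = value,
    percent_sat = value / 100 * constants$p_o2_sat,
    mg_per_L = value / sat * constants$p_o2_sat,
    mL_per_L = value * O2_MG_PER_ML / sat * constants$p_o2_sat
  )
  switch(to,
    kPa = kpa,
    percent_sat = kpa / constants$p_o2_sat * 100,
    mg_per_L = kpa / constants$p_o2_sat * sat,
    mL_per_L = kpa / constants$p_o2_sat * sat / O2_MG_PER_ML
  )
}

#' Batch-convert a table of oxygen readings
#'
#' @param readings data.frame with columns `value`, `unit`, and (for
#'   solubility-dependent conversions) `temperature`, `salinity`.
#' @param to target unit.
#' @param constants an `acartia_constants` object.
#' @return the input data.frame with added columns `value_converted` and
#'   `unit_converted`.
#' @export
o2_convert_table <- function(readings, to, constants = model_constants()) {
  stopifnot(is.data.frame(readings),
            all(c("value", "unit") %in% names(readings)))
  out <- readings
  out$value_converted <- vapply(seq_len(nrow(readings)), function(i) {
    o2_convert(readings$value[i], as.character(readings$unit[i]), to,
               temperature = readings$temperature[i],
               salinity = readings$salinity[i],
               constants = constants)
  }, numeric(1))
  out$unit_converted <- to
  out
}
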