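#' Model constants for the Acartia tonsa hypoxia model
#'
#' Builds the full set of physiological and regression constants used
#' throughout the package. Defaults are the published parameterization for
#' *Acartia tonsa*: the oxygen-limitation line \eqn{ARR = a \cdot PO_2 + b},
#' the target and minimum survivable respiration rates (TRR, MRR) at the
#' 18 degree C reference, the bioenergetic conversion factors that map egg
#' production, somatic growth, and ingestion into oxygen-utilization units,
#' and the salinity-dependent Q10 table.
#'
#' Any field can be overridden, e.g. to substitute a locally measured
#' oxygen-limitation line for the packaged coefficients.
#'
#' @param ... named overrides of individual fields (see Details).
#'
#' @details Fields (with defaults):
#' \describe{
#'   \item{slope_a}{slope of the maximum-respiration line,
#'     ug O2 mg dw^-1 d^-1 kPa^-1 (34.9)}
#'   \item{intercept_b}{intercept of the line, ug O2 mg dw^-1 d^-1 (-20.5);
#'     stored signed so the line is always ARR = a*PO2 + b}
#'   \item{TRR}{target respiration rate at 18 C, ug O2 mg dw^-1 d^-1 (261.5)}
#'   \item{MRR}{minimum survivable respiration rate at 18 C (91.0)}
#'   \item{T_ref}{reference temperature, C (18)}
#'   \item{pcrit_se, pleth_se}{standard errors on the thresholds, kPa (1.7);
#'     carried as constants, never recomputed}
#'   \item{egg_dry_wt}{egg dry weight, ug (0.104)}
#'   \item{egg_resp_cost}{respiratory cost of egg production,
#'     ug O2 per mg egg dw (264)}
#'   \item{vol_to_dw}{body volume to dry weight, ug dw mm^-3 (167.6)}
#'   \item{dw_to_C}{dry weight to carbon, ug C per ug dw (0.4)}
#'   \item{NGE}{net growth efficiency (0.75)}
#'   \item{RQ_mass}{respiratory quotient in mass units, ug C per ug O2 (0.338)}
#'   \item{ingestion_resp_slope, ingestion_resp_intercept}{ingestion to
#'     respiration relation R = 0.07 I + 33.39 (ug C mg dw^-1 d^-1)}
#'   \item{female_dw_intercept, female_dw_slope}{adult female dry weight line
#'     dw = 8.67 - 0.25 T (ug)}
#'   \item{q10_table}{data.frame with columns salinity, q10; default
#'     (15, 1.5), (25, 2.03), (35, 2.22)}
#'   \item{regression_cutoff}{PO2 cutoff for the oxygen-limited fit, kPa (8)}
#'   \item{p_o2_sat}{oxygen partial pressure at air saturation, kPa (20.95)}
#'   \item{fit_r2}{coefficient of determination of the packaged line
#'     (0.735, informational only)}
#' }
#'
#' @return An object of class `acartia_constants` (a validated named list).
#' @examples
#' cc <- model_constants()
#' cc$TRR
#' model_constants(slope_a = 30)$slope_a
#' @seealso [load_constants()] to read constants from a YAML file.
#' @export
model_constants <- function(...) {
  cc <- default_constants_list()
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(cc))
    if (length(bad))
      stop("unknown constant(s): ", paste(bad, collapse = ", "))
    if ("q10_table" %in% names(over))
      over$q10_table <- as_q10_table(over$q10_table)
    cc[names(over)] <- over
  }
  validate_constants(cc)
}

default_constants_list <- function() {
  list(
    slope_a = 34.9,
    intercept_b = -20.5,
    TRR = 261.5,
    MRR = 91.0,
    T_ref = 18,
    pcrit_se = 1.7,
    pleth_se = 1.7,
    egg_dry_wt = 0.104,
    egg_resp_cost = 264,
    vol_to_dw = 167.6,
    dw_to_C = 0.4,
    NGE = 0.75,
    RQ_mass = 0.338,
    ingestion_resp_slope = 0.07,
    ingestion_resp_intercept = 33.39,
    female_dw_intercept = 8.67,
    female_dw_slope = 0.25,
    q10_table = data.frame(salinity = c(15, 25, 35),
                           q10 = c(1.5, 2.03, 2.22)),
    regression_cutoff = 8,
    p_o2_sat = 20.95,
    fit_r2 = 0.735
  )
}

as_q10_table <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("salinity", "q10") %in% names(x)))
    return(data.frame(salinity = as.numeric(x$salinity),
                      q10 = as.numeric(x$q10)))
  }
  # list of (salinity, q10) pairs, as parsed from YAML
  if (is.list(x)) {
    sal <- vapply(x, function(p) as.numeric(p[["salinity"]]), numeric(1))
    q <- vapply(x, function(p) as.numeric(p[["q10"]]), numeric(1))
    return(data.frame(salinity = sal, q10 = q))
  }
  stop("q10_table must be a data.frame or list of (salinity, q10) pairs")
}

validate_constants <- function(cc) {
  num_fields <- setdiff(names(default_constants_list()), "q10_table")
  for (f in num_fields) {
    v <- cc[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("constant '", f, "' must be a single finite number")
    cc[[f]] <- as.numeric(v)
  }
  if (cc$slope_a <= 0) stop("slope_a must be > 0")
  if (!(cc$TRR > cc$MRR && cc$MRR > 0)) stop("need TRR > MRR > 0")
  if (cc$NGE <= 0 || cc$NGE >= 1) stop("NGE must lie in (0, 1)")
  if (cc$regression_cutoff <= 0) stop("regression_cutoff must be > 0")
  if (cc$p_o2_sat <= 0) stop("p_o2_sat must be > 0")
  qt <- cc$q10_table
  if (nrow(qt) < 1 || any(!is.finite(qt$salinity)) || any(!is.finite(qt$q10)))
    stop("q10_table must have finite salinity and q10 values")
  if (any(diff(qt$salinity) <= 0))
    stop("q10_table must be strictly increasing in salinity")
  if (any(qt$q10 <= 0)) stop("all Q10 values must be > 0")
  structure(cc, class = "acartia_constants")
}

#' @export
print.acartia_constants <- function(x, ...) {
  cat("Acartia tonsa hypoxia model constants\n")
  cat(sprintf("  line: ARR = %.3g * PO2 %+.3g (cutoff %.3g kPa, R2 %.3g)\n",
              x$slope_a, x$intercept_b, x$regression_cutoff, x$fit_r2))
  cat(sprintf("  TRR = %.4g, MRR = %.4g ug O2 mg dw-1 d-1 at %g C\n",
              x$TRR, x$MRR, x$T_ref))
  cat(sprintf("  Q10: %s\n",
              paste(sprintf("S%g=%g", x$q10_table$salinity, x$q10_table$q10),
                    collapse = ", ")))
  invisible(x)
}

#' Read model constants from a YAML configuration file
#'
#' The file mirrors the field names of [model_constants()]; fields omitted
#' from the file keep their packaged defaults. The packaged default file
#' (`system.file("extdata", "default_constants.yml", package = "acartia")`)
#' reproduces every published constant.
#'
#' @param path path to a YAML file.
#' @return An `acartia_constants` object.
#' @export
load_constants <- function(path) {
  if (!file.exists(path)) stop("constants file not found: ", path)
  raw <- yaml::read_yaml(path)
  do.call(model_constants, raw)
}

#' Write model constants to a YAML configuration file
#'
#' @param constants an `acartia_constants` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_constants <- function(constants, path) {
  cc <- unclass(constants)
  cc$q10_table <- lapply(seq_len(nrow(constants$q10_table)), function(i)
    list(salinity = constants$q10_table$salinity[i],
         q10 = constants$q10_table$q10[i]))
  yaml::write_yaml(cc, path)
  invisible(path)
}

#' Salinity-dependent Q10 temperature coefficient
#'
#' Piecewise-linear interpolation of the tabulated Q10 values against
#' salinity. Outside the tabulated salinity range the nearest endpoint is
#' used (clamping; no extrapolation), matching how the published table is
#' applied.
#'
#' @param S practical salinity (vectorized); must be finite and >= 0.
#' @param constants an `acartia_constants` object.
#' @return Q10 (dimensionless), same length as `S`.
#' @examples
#' q10_for_salinity(25)  # 2.03
#' q10_for_salinity(30)  # midway between 2.03 and 2.22
#' @export
q10_for_salinity <- function(S, constants = model_constants()) {
  if (!is.numeric(S) || any(!is.finite(S)))
    stop("salinity must be finite")
  if (any(S < 0)) stop("salinity must be >= 0")
  qt <- constants$q10_table
  if (nrow(qt) == 1L) return(rep(qt$q10, length(S)))
  stats::approx(qt$salinity, qt$q10, xout = S, rule = 2)$y
}

#' Adult female dry weight as a function of temperature
#'
#' Evaluates the published linear relation dw = 8.67 - 0.25 T (micrograms per
#' female). The relation is only meaningful while it yields a positive
#' weight.
#'
#' @param T temperature in degrees C (vectorized).
#' @param constants an `acartia_constants` object.
#' @return dry weight in micrograms per female.
#' @examples
#' female_dry_wt(18.5)  # 4.045
#' @export
female_dry_wt <- function(T, constants = model_constants()) {
  if (!is.numeric(T) || any(!is.finite(T))) stop("temperature must be finite")
  dw <- constants$female_dw_intercept - constants$female_dw_slope * T
  if (any(dw <= 0)) {
    tmax <- constants$female_dw_intercept / constants$female_dw_slope
    stop(sprintf(
      "temperature yields non-positive female dry weight; valid for T < %g C",
      tmax))
  }
  dw
}

#' Q10 temperature scaling of a rate
#'
#' Scales a physiological rate from one temperature to another using the
#' standard Q10 relation `rate * Q10^((T_to - T_from)/10)`.
#'
#' @param rate a non-negative rate (any units; vectorized).
#' @param T_from,T_to temperatures in degrees C.
#' @param Q10 temperature coefficient, > 0.
#' @return the rate at `T_to`, in the same units.
#' @examples
#' q10_scale(261.5, 18, 5, 2.03)
#' @export
q10_scale <- function(rate, T_from, T_to, Q10) {
  if (any(!is.finite(Q10)) || any(Q10 <= 0)) stop("Q10 must be > 0")
  if (any(!is.finite(rate)) || any(rate < 0)) stop("rate must be >= 0")
  rate * Q10^((T_to - T_from) / 10)
}
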