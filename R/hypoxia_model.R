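#' Theoretical maximum respiration rate at a given oxygen partial pressure
#'
#' Evaluates the oxygen-limitation line `ARR = a * PO2 + b`, floored at zero
#' (the floor only matters below the line's root, ~0.59 kPa with the
#' published coefficients). This is the respiration rate an oxygen-limited
#' animal can sustain, valid below the critical oxygen partial pressure.
#'
#' @param po2 oxygen partial pressure, kPa, >= 0 (vectorized).
#' @param constants an `acartia_constants` object.
#' @return respiration rate, ug O2 mg dw^-1 d^-1 at 18 C.
#' @examples
#' arr_at(1.6)  # ~35
#' @export
arr_at <- function(po2, constants = model_constants()) {
  if (any(!is.finite(po2)) || any(po2 < 0)) stop("po2 must be >= 0")
  pmax(0, constants$slope_a * po2 + constants$intercept_b)
}

#' Critical oxygen partial pressure
#'
#' The PO2 below which the animal cannot sustain its target respiration
#' rate: the target rate is Q10-scaled from 18 C to the ambient temperature
#' (Q10 chosen by salinity) and inverted through the oxygen-limitation line.
#' Sub-lethal effects of hypoxia (reduced egg production and growth) are
#' expected below this threshold.
#'
#' @param T temperature, degrees C (vectorized).
#' @param S practical salinity.
#' @param constants an `acartia_constants` object.
#' @return critical PO2 in kPa.
#' @examples
#' pcrit(18, 25)  # ~8.1 kPa
#' pcrit(5, 25)   # ~3.6 kPa
#' @export
pcrit <- function(T, S, constants = model_constants()) {
  trr_t <- q10_scale(constants$TRR, constants$T_ref, T,
                     q10_for_salinity(S, constants))
  invert_to_po2(trr_t, constants)
}

#' Lethal oxygen partial pressure
#'
#' The PO2 below which the animal cannot sustain its minimum survivable
#' respiration rate; hypoxia-induced mortality is expected below it. Always
#' less than [pcrit()] at the same conditions since MRR < TRR.
#'
#' @inheritParams pcrit
#' @return lethal PO2 in kPa.
#' @examples
#' pleth(18, 25)    # ~3.2 kPa
#' pleth(20, 30)    # ~3.6 kPa
#' @export
pleth <- function(T, S, constants = model_constants()) {
  mrr_t <- q10_scale(constants$MRR, constants$T_ref, T,
                     q10_for_salinity(S, constants))
  invert_to_po2(mrr_t, constants)
}

#' Critical and lethal thresholds for given conditions
#'
#' @inheritParams pcrit
#' @return data.frame with columns `temperature`, `salinity`, `q10`,
#'   `pcrit`, `pcrit_se`, `pleth`, `pleth_se` (kPa).
#' @examples
#' hypoxia_thresholds(c(5, 18, 25), 25)
#' @export
hypoxia_thresholds <- function(T, S, constants = model_constants()) {
  n <- max(length(T), length(S))
  T <- rep_len(T, n); S <- rep_len(S, n)
  data.frame(temperature = T, salinity = S,
             q10 = q10_for_salinity(S, constants),
             pcrit = pcrit(T, S, constants),
             pcrit_se = constants$pcrit_se,
             pleth = pleth(T, S, constants),
             pleth_se = constants$pleth_se)
}

#' 24-h probability of hypoxia-induced mortality (copepodites)
#'
#' Linear interpolation in respiration-rate space between zero mortality at
#' the lethal threshold and full mortality at half the lethal threshold:
#' with `P_L = pleth(T, S)`,
#' \deqn{m = \frac{ARR(P_L) - ARR(PO_2)}{ARR(P_L) - ARR(P_L/2)}}
#' clamped to \[0, 1\]; `m = 0` at and above `P_L`, and values >= 1 (below
#' `P_L/2`) mean 100 % mortality. Because the maximum-respiration line is
#' linear, this is also linear in PO2 over (P_L/2, P_L). Estimates apply to
#' copepodites; nauplii tolerate lower oxygen and are outside the model.
#'
#' @param po2 oxygen partial pressure, kPa, >= 0 (vectorized).
#' @inheritParams pcrit
#' @param raw if `TRUE`, also return the unclamped interpolant.
#' @return probability of death within 24 h (d^-1), in \[0, 1\]; if
#'   `raw = TRUE`, a data.frame with columns `m` and `m_raw`.
#' @examples
#' mortality_24h(3.2, 18, 25)  # ~0 at the lethal threshold
#' mortality_24h(1.6, 18, 25)  # ~1 at half the threshold
#' @export
mortality_24h <- function(po2, T, S, constants = model_constants(),
                          raw = FALSE) {
  if (any(!is.finite(po2)) || any(po2 < 0)) stop("po2 must be >= 0")
  p_l <- pleth(T, S, constants)
  # ARR at the thresholds: by construction arr_at(p_l) is the Q10-scaled MRR
  arr_pl <- arr_at(p_l, constants)
  arr_half <- arr_at(p_l / 2, constants)
  m_raw <- (arr_pl - arr_at(po2, constants)) / (arr_pl - arr_half)
  m <- ifelse(po2 >= p_l, 0, pmin(1, pmax(0, m_raw)))
  if (raw) data.frame(m = m, m_raw = m_raw) else m
}

#' Predicted egg production from an analogous respiration rate
#'
#' Back-converts an oxygen-limited respiration rate into a weight-specific
#' egg production rate by dividing by the respiratory cost of egg production
#' (the published coefficient 0.00379 = 1/264). Valid only below the
#' critical oxygen partial pressure.
#'
#' @param arr analogous respiration rate, ug O2 mg dw^-1 d^-1 (vectorized).
#' @param constants an `acartia_constants` object.
#' @return egg production rate, ug dw (eggs) per ug dw (female) d^-1.
#' @examples
#' egg_production(arr_at(5))
#' @export
egg_production <- function(arr, constants = model_constants()) {
  if (any(!is.finite(arr)) || any(arr < 0)) stop("arr must be >= 0")
  arr / constants$egg_resp_cost
}

#' Predicted somatic growth from an analogous respiration rate
#'
#' Back-converts an oxygen-limited respiration rate into carbon-specific
#' somatic growth via NGE/(1-NGE) * RQ_mass (the published coefficient
#' 1.014 = 3 * 0.338). Valid only below the critical oxygen partial
#' pressure.
#'
#' @inheritParams egg_production
#' @return somatic growth rate, ug C mg dw^-1 d^-1.
#' @examples
#' somatic_growth(arr_at(5))
#' @export
somatic_growth <- function(arr, constants = model_constants()) {
  if (any(!is.finite(arr)) || any(arr < 0)) stop("arr must be >= 0")
  arr * (constants$NGE / (1 - constants$NGE)) * constants$RQ_mass
}

#' Classify environmental samples and predict hypoxia effects
#'
#' For each sample (temperature, salinity, oxygen partial pressure) computes
#' the temperature/salinity-specific thresholds and classifies the expected
#' effect on *A. tonsa*:
#' \describe{
#'   \item{none}{`po2 >= pcrit`; respiration is not oxygen-limited, so no
#'     rate predictions are made (fields are `NA`).}
#'   \item{sublethal}{`pleth <= po2 < pcrit`; oxygen-limited egg production
#'     and somatic growth are predicted, mortality is 0.}
#'   \item{lethal}{`po2 < pleth`; all rates plus a positive 24-h mortality
#'     probability.}
#' }
#' Boundary conventions: `po2 == pcrit` is classified `none`;
#' `po2 == pleth` is `sublethal` (mortality is exactly 0 there).
#'
#' @param samples data.frame with columns `temperature`, `salinity`, `po2`
#'   (kPa; convert other oxygen units first with [o2_convert()]), and
#'   optionally `label`.
#' @param constants an `acartia_constants` object.
#' @return data.frame, one row per sample in input order: `label`,
#'   `temperature`, `salinity`, `po2_kpa`, `pcrit_kpa`, `pleth_kpa`, `arr`,
#'   `egg_production`, `somatic_growth`, `mortality_24h`, `effect`
#'   (factor none/sublethal/lethal).
#' @examples
#' predict_hypoxia_effects(
#'   data.frame(temperature = 18, salinity = 10, po2 = c(15, 5, 2)))
#' @export
predict_hypoxia_effects <- function(samples, constants = model_constants()) {
  stopifnot(is.data.frame(samples))
  req <- c("temperature", "salinity", "po2")
  missing_cols <- setdiff(req, names(samples))
  if (length(missing_cols))
    stop("sample table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  n <- nrow(samples)
  lab <- if ("label" %in% names(samples)) as.character(samples$label)
         else rep(NA_character_, n)
  if (!n)
    return(data.frame(label = character(), temperature = numeric(),
                      salinity = numeric(), po2_kpa = numeric(),
                      pcrit_kpa = numeric(), pleth_kpa = numeric(),
                      arr = numeric(), egg_production = numeric(),
                      somatic_growth = numeric(), mortality_24h = numeric(),
                      effect = factor(character(),
                                      levels = c("none", "sublethal",
                                                 "lethal"))))
  if (any(!is.finite(samples$po2)) || any(samples$po2 < 0))
    stop("po2 must be finite and >= 0 (offending row(s): ",
         paste(which(!is.finite(samples$po2) | samples$po2 < 0),
               collapse = ", "), ")")
  Tt <- samples$temperature; S <- samples$salinity; po2 <- samples$po2
  pc <- pcrit(Tt, S, constants)
  pl <- pleth(Tt, S, constants)
  effect <- ifelse(po2 >= pc, "none",
                   ifelse(po2 >= pl, "sublethal", "lethal"))
  limited <- effect != "none"
  arr <- ifelse(limited, arr_at(po2, constants), NA_real_)
  epr <- ifelse(limited, arr / constants$egg_resp_cost, NA_real_)
  grw <- ifelse(limited,
                arr * (constants$NGE / (1 - constants$NGE)) *
                  constants$RQ_mass,
                NA_real_)
  mort <- ifelse(limited, mortality_24h(po2, Tt, S, constants), NA_real_)
  data.frame(label = lab, temperature = Tt, salinity = S, po2_kpa = po2,
             pcrit_kpa = pc, pleth_kpa = pl, arr = arr,
             egg_production = epr, somatic_growth = grw,
             mortality_24h = mort,
             effect = factor(effect,
                             levels = c("none", "sublethal", "lethal")))
}
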