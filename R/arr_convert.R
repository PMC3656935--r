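#' Convert egg production rate to analogous respiration rate
#'
#' Re-expresses an egg production rate (eggs female^-1 d^-1) as the rate of
#' oxygen utilization it implies (ug O2 mg dry wt^-1 d^-1): eggs are turned
#' into egg dry weight, costed at the respiratory cost of egg production, and
#' normalized by the adult female dry weight at the experiment temperature.
#'
#' @param epr egg production rate, eggs female^-1 d^-1, >= 0 (vectorized).
#' @param T experiment temperature, degrees C.
#' @param constants an `acartia_constants` object.
#' @return analogous respiration rate, ug O2 mg dw^-1 d^-1.
#' @examples
#' epr_to_arr(50, 18)
#' @export
epr_to_arr <- function(epr, T, constants = model_constants()) {
  if (any(!is.finite(epr)) || any(epr < 0))
    stop("egg production rate must be >= 0")
  dw_mg <- female_dry_wt(T, constants) / 1000
  epr * constants$egg_dry_wt * (constants$egg_resp_cost / 1000) / dw_mg
}

#' Convert somatic growth rate to analogous respiration rate
#'
#' Volume-based growth (mm^3 copepod^-1 d^-1) is converted to carbon-specific
#' growth (ug C mg dw^-1 d^-1) via the volume-to-dry-weight and
#' dry-weight-to-carbon factors and the mean dry weight of the growing
#' animals, then divided by the growth-to-respiration factor
#' NGE/(1-NGE) * RQ_mass (1.014 with defaults).
#'
#' The mean dry weight is an explicit per-observation input: the published
#' stage-averaged weights (0.283-0.416 ug, nauplius to CIII, by temperature
#' and oxygen treatment) are not unambiguously paired with treatments, so no
#' default is assumed.
#'
#' @param G somatic growth rate, mm^3 copepod^-1 d^-1, >= 0 (vectorized).
#' @param mean_dry_wt mean dry weight of the animals, ug copepod^-1, > 0.
#' @param constants an `acartia_constants` object.
#' @return analogous respiration rate, ug O2 mg dw^-1 d^-1.
#' @examples
#' growth_to_arr(1e-4, mean_dry_wt = 0.354)
#' @export
growth_to_arr <- function(G, mean_dry_wt, constants = model_constants()) {
  if (any(!is.finite(G)) || any(G < 0)) stop("growth rate must be >= 0")
  if (any(!is.finite(mean_dry_wt)) || any(mean_dry_wt <= 0))
    stop("mean_dry_wt must be > 0")
  g_c <- G * constants$vol_to_dw * constants$dw_to_C / (mean_dry_wt / 1000)
  g_c / (constants$NGE / (1 - constants$NGE) * constants$RQ_mass)
}

#' Convert ingestion rate to analogous respiration rate
#'
#' Applies the ingestion-respiration relation R = 0.07 I + 33.39 (carbon
#' units) and the mass respiratory quotient to express a carbon-specific
#' ingestion rate as oxygen utilization. Note the affine form: zero ingestion
#' maps to the basal respiration term, not to zero.
#'
#' @param I ingestion rate, ug C mg dw^-1 d^-1, >= 0 (vectorized).
#' @param constants an `acartia_constants` object.
#' @return analogous respiration rate, ug O2 mg dw^-1 d^-1.
#' @examples
#' ingestion_to_arr(511)
#' @export
ingestion_to_arr <- function(I, constants = model_constants()) {
  if (any(!is.finite(I)) || any(I < 0)) stop("ingestion rate must be >= 0")
  (constants$ingestion_resp_slope * I + constants$ingestion_resp_intercept) /
    constants$RQ_mass
}

#' Standardize an analogous respiration rate to the reference temperature
#'
#' Q10-scales a rate measured at temperature `T` to the model's reference
#' temperature (18 C), using the salinity-matched Q10.
#'
#' @param arr analogous respiration rate, >= 0 (vectorized).
#' @param T measurement temperature, degrees C.
#' @param S practical salinity (selects the Q10).
#' @param constants an `acartia_constants` object.
#' @return the rate at the reference temperature, same units.
#' @examples
#' standardize_to_ref(104.166, T = 5, S = 25)  # ~261.5
#' @export
standardize_to_ref <- function(arr, T, S, constants = model_constants()) {
  q10_scale(arr, T, constants$T_ref, q10_for_salinity(S, constants))
}

#' Convert a table of vital-rate observations to 18 C analogous respiration
#' rates
#'
#' Runs the full conversion pipeline on an observation table: each row is
#' converted to an analogous respiration rate with the converter matching its
#' `rate_type` and then Q10-standardized to the reference temperature.
#'
#' @param observations data.frame with columns `study`, `rate_type` (one of
#'   `"egg_production"`, `"somatic_growth"`, `"ingestion"`), `value` (native
#'   units), `temperature`, `salinity`, `po2` (kPa), and `mean_dry_wt`
#'   (ug; required for somatic growth rows, ignored otherwise).
#' @param constants an `acartia_constants` object.
#' @return data.frame with columns `study`, `po2`, `arr18`, `source_type`,
#'   `n` (1 per raw measurement).
#' @seealso [arr_group_means()] for the study-by-PO2 averaging step.
#' @export
observations_to_arr <- function(observations, constants = model_constants()) {
  req <- c("study", "rate_type", "value", "temperature", "salinity", "po2")
  missing_cols <- setdiff(req, names(observations))
  if (length(missing_cols))
    stop("observation table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  if (!nrow(observations)) stop("empty observation table")
  if (any(!is.finite(observations$po2)) || any(observations$po2 < 0))
    stop("po2 must be >= 0")
  type <- as.character(observations$rate_type)
  bad <- setdiff(unique(type), c("egg_production", "somatic_growth",
                                 "ingestion"))
  if (length(bad)) stop("unknown rate_type: ", paste(bad, collapse = ", "))

  arr <- numeric(nrow(observations))
  for (i in seq_len(nrow(observations))) {
    arr[i] <- switch(type[i],
      egg_production = epr_to_arr(observations$value[i],
                                  observations$temperature[i], constants),
      somatic_growth = {
        if (is.null(observations$mean_dry_wt))
          stop("mean_dry_wt column required for somatic_growth rows")
        growth_to_arr(observations$value[i], observations$mean_dry_wt[i],
                      constants)
      },
      ingestion = ingestion_to_arr(observations$value[i], constants)
    )
  }
  arr18 <- standardize_to_ref(arr, observations$temperature,
                              observations$salinity, constants)
  data.frame(study = as.character(observations$study),
             po2 = observations$po2,
             arr18 = arr18,
             source_type = type,
             n = 1L,
             stringsAsFactors = FALSE)
}

#' Average analogous respiration rates by study and oxygen partial pressure
#'
#' Collapses individual ARR records to one mean per (study, PO2) group,
#' mirroring how literature values reported only as treatment means are kept
#' comparable with raw measurements. Means are n-weighted, so grouping
#' already-grouped records reproduces the same means. PO2 values are matched
#' after rounding to 2 decimals (kPa), the precision at which experimental
#' target pressures are reported.
#'
#' @param records data.frame as returned by [observations_to_arr()] (columns
#'   `study`, `po2`, `arr18`, `n`; `source_type` optional).
#' @return data.frame with one row per (study, po2) pair; `n` is the total
#'   number of contributing raw measurements and `arr18` their mean;
#'   `source_type` is the unique type or `"mixed"`.
#' @export
arr_group_means <- function(records) {
  if (!is.data.frame(records) || !nrow(records))
    stop("records must be a non-empty data.frame")
  stopifnot(all(c("study", "po2", "arr18") %in% names(records)))
  n <- if ("n" %in% names(records)) records$n else rep(1L, nrow(records))
  key_po2 <- round(records$po2, 2)
  key <- paste(records$study, format(key_po2, nsmall = 2), sep = "\r")
  idx <- split(seq_len(nrow(records)), key)
  out <- do.call(rbind, lapply(idx, function(i) {
    st <- if ("source_type" %in% names(records)) {
      u <- unique(as.character(records$source_type[i]))
      if (length(u) == 1L) u else "mixed"
    } else NA_character_
    data.frame(study = as.character(records$study[i[1]]),
               po2 = key_po2[i[1]],
               arr18 = sum(records$arr18[i] * n[i]) / sum(n[i]),
               source_type = st,
               n = as.integer(sum(n[i])),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$study, out$po2), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a vital-rate observation table from CSV
#'
#' @param path CSV file with columns `study`, `rate_type`, `value`,
#'   `temperature`, `salinity`, `po2`, `mean_dry_wt`.
#' @return data.frame of observations.
#' @export
read_observations <- function(path) {
  obs <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("study", "rate_type", "value", "temperature", "salinity", "po2")
  missing_cols <- setdiff(req, names(obs))
  if (length(missing_cols))
    stop("observation CSV lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  obs
}
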