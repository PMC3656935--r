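# Run code with a temporary RNG seed, restoring the caller's RNG state, so
# generators are pure functions of their seed.
with_local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  code
}

#' Specification for a synthetic vital-rate dataset
#'
#' Defines the seeded generator layout for [gen_vital_rates()]. The default
#' layout mirrors the structure of the compiled literature dataset behind the
#' maximum-respiration fit: 17 (study, PO2) groups totalling 153 individual
#' measurements spread over egg production (two studies), somatic growth
#' (one study, with stage-averaged mean dry weight), and ingestion (one
#' study), all at PO2 below the 8 kPa regression cutoff. Optionally a
#' fraction of extra groups is placed above the cutoff, where rates are high
#' and variable rather than oxygen-limited.
#'
#' @param seed integer seed; the generator is a pure function of the spec.
#' @param noise_sd ARR scatter, ug O2 mg dw^-1 d^-1. Applied at two levels
#'   with the same magnitude: a group-level (study x PO2) deviation from the
#'   line, and per-measurement scatter around the group value. The
#'   group-level term is what keeps group means realistically off the line
#'   (R2 well below 1) even for large groups.
#' @param true_slope,true_intercept parameters of the generating
#'   oxygen-limitation line.
#' @param above_cutoff_fraction fraction of groups to place above the
#'   regression cutoff.
#' @param groups optional custom layout: data.frame with columns `study`,
#'   `rate_type`, `temperature`, `salinity`, `mean_dry_wt`, `po2`, `n`.
#' @return list of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1, noise_sd = 25, true_slope = 34.9,
                         true_intercept = -20.5, above_cutoff_fraction = 0,
                         groups = NULL) {
  if (!is.finite(seed)) stop("seed must be a finite integer")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (above_cutoff_fraction < 0 || above_cutoff_fraction >= 1)
    stop("above_cutoff_fraction must lie in [0, 1)")
  if (is.null(groups)) groups <- default_fixture_groups()
  req <- c("study", "rate_type", "temperature", "salinity", "mean_dry_wt",
           "po2", "n")
  stopifnot(is.data.frame(groups), all(req %in% names(groups)))
  if (any(groups$n < 1)) stop("every group needs n >= 1 measurements")
  if (above_cutoff_fraction > 0) {
    f <- above_cutoff_fraction
    m <- max(1L, round(f / (1 - f) * nrow(groups)))
    extra <- data.frame(study = "high_o2",
                        rate_type = "ingestion",
                        temperature = 18.5, salinity = 10,
                        mean_dry_wt = NA_real_,
                        po2 = seq(12, 20, length.out = m),
                        n = 3L)
    groups <- rbind(groups, extra)
  }
  structure(list(seed = as.integer(seed), groups = groups,
                 noise_sd = noise_sd, true_slope = true_slope,
                 true_intercept = true_intercept,
                 above_cutoff_fraction = above_cutoff_fraction),
            class = "fixture_spec")
}

default_fixture_groups <- function() {
  rbind(
    data.frame(study = "egg_study_A", rate_type = "egg_production",
               temperature = 20, salinity = 15, mean_dry_wt = NA_real_,
               po2 = c(2.4, 3.2, 4.0, 5.0, 6.0), n = 10L),
    data.frame(study = "egg_study_B", rate_type = "egg_production",
               temperature = 18, salinity = 30, mean_dry_wt = NA_real_,
               po2 = c(2.2, 3.5, 4.8, 6.2), n = 9L),
    data.frame(study = "growth_study", rate_type = "somatic_growth",
               temperature = 25, salinity = 15, mean_dry_wt = 0.336,
               po2 = c(2.6, 3.8, 5.2, 6.6, 7.6), n = 11L),
    data.frame(study = "ingestion_study", rate_type = "ingestion",
               temperature = 18.5, salinity = 10, mean_dry_wt = NA_real_,
               po2 = c(5.2, 6.2, 7.2), n = 4L)
  )
}

# Inverse conversion chains (native units from an ARR at experiment
# temperature); exact inverses of the arr_convert forward maps.
arr_to_epr <- function(arr_T, T, constants) {
  arr_T * female_dry_wt(T, constants) /
    (constants$egg_dry_wt * constants$egg_resp_cost)
}
arr_to_growth <- function(arr_T, mean_dry_wt, constants) {
  arr_T * (constants$NGE / (1 - constants$NGE)) * constants$RQ_mass *
    (mean_dry_wt / 1000) / (constants$vol_to_dw * constants$dw_to_C)
}
arr_to_ingestion <- function(arr_T, constants) {
  pmax(0, (arr_T * constants$RQ_mass - constants$ingestion_resp_intercept) /
         constants$ingestion_resp_slope)
}

#' Generate a synthetic vital-rate observation table
#'
#' Draws 18 C analogous respiration rates around the generating line and
#' back-converts them through the exact inverses of the conversion chains
#' into native egg-production / somatic-growth / ingestion units, so the
#' forward pipeline ([observations_to_arr()] at the same constants) recovers
#' the drawn ARR values. Groups below the regression cutoff scatter
#' normally about the line (truncated at 0); groups above it draw uniformly
#' between 80 % of the target respiration rate and the line value,
#' emulating the high, variable rates seen under ample oxygen.
#'
#' @param spec a [fixture_spec()].
#' @param constants an `acartia_constants` object.
#' @return data.frame of observations (columns as [read_observations()]);
#'   attribute `arr18_true` holds the drawn per-row ARR values and attribute
#'   `spec` the generating spec.
#' @examples
#' obs <- gen_vital_rates(fixture_spec(seed = 42))
#' nrow(obs)  # 153
#' @export
gen_vital_rates <- function(spec = fixture_spec(),
                            constants = model_constants()) {
  stopifnot(inherits(spec, "fixture_spec"))
  g <- spec$groups
  cutoff <- constants$regression_cutoff
  with_local_seed(spec$seed, {
    rows <- lapply(seq_len(nrow(g)), function(i) {
      n <- g$n[i]
      line_val <- spec$true_slope * g$po2[i] + spec$true_intercept
      if (g$po2[i] < cutoff) {
        grp_dev <- if (spec$noise_sd > 0) stats::rnorm(1, 0, spec$noise_sd)
                   else 0
        arr18 <- pmax(0, line_val + grp_dev +
                        stats::rnorm(n, 0, spec$noise_sd))
      } else {
        lo <- 0.8 * constants$TRR
        if (line_val < lo)
          stop("infeasible above-cutoff group at po2 = ", g$po2[i],
               ": line value below 0.8 * TRR")
        arr18 <- stats::runif(n, lo, line_val)
      }
      q10 <- q10_for_salinity(g$salinity[i], constants)
      arr_T <- q10_scale(arr18, constants$T_ref, g$temperature[i], q10)
      value <- switch(as.character(g$rate_type[i]),
        egg_production = arr_to_epr(arr_T, g$temperature[i], constants),
        somatic_growth = arr_to_growth(arr_T, g$mean_dry_wt[i], constants),
        ingestion = arr_to_ingestion(arr_T, constants),
        stop("unknown rate_type in fixture groups: ", g$rate_type[i]))
      data.frame(study = g$study[i], rate_type = g$rate_type[i],
                 value = value, temperature = g$temperature[i],
                 salinity = g$salinity[i], po2 = g$po2[i],
                 mean_dry_wt = g$mean_dry_wt[i], arr18_true = arr18,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    arr18_true <- out$arr18_true
    out$arr18_true <- NULL
    rownames(out) <- NULL
    attr(out, "arr18_true") <- arr18_true
    attr(out, "spec") <- spec
    out
  })
}

#' Generate synthetic bottle-incubation tables
#'
#' Builds grazing experiments with known true ingestion rates: for each
#' treatment the grazing coefficient implied by the target dry-weight
#' specific carbon ingestion is found by inverting the Frost closed form,
#' final cell counts follow exact exponential dynamics, and multiplicative
#' lognormal counting noise (coefficient of variation `cv`, mean-preserving)
#' is applied to the final counts. With `cv = 0` the grazing pipeline
#' recovers the truths exactly.
#'
#' The default design mirrors the supplementary feeding experiments: three
#' experiments of 12 bottles (3 grazing + 3 controls per oxygen treatment),
#' 610 mL bottles, 12 adult females per grazing bottle, initial algal
#' concentration 1921 cells mL^-1 at 55 pg C cell^-1, incubated at 18.5 C.
#' Incubations default to 2 d.
#'
#' @param seed integer seed.
#' @param true_ingestion named vector of dry-weight-specific carbon
#'   ingestion truths, ug C mg dw^-1 d^-1, one per treatment (defaults:
#'   normoxic 511, hypoxic 146).
#' @param n_experiments number of experiments.
#' @param cv coefficient of variation of the counting noise, >= 0.
#' @param temperature incubation temperature, C (sets copepod dry weight).
#' @param volume_ml,duration_d,copepods,initial_cells,control_k,cell_carbon
#'   design constants.
#' @param constants an `acartia_constants` object.
#' @return data.frame of bottles (columns as [read_bottles()] plus
#'   `temperature`); attribute `truth` holds the generating parameters,
#'   including the true grazing coefficients.
#' @examples
#' b <- gen_bottles(seed = 1, cv = 0)
#' table(b$treatment, b$role)
#' @export
gen_bottles <- function(seed = 1,
                        true_ingestion = c(normoxic = 511, hypoxic = 146),
                        n_experiments = 3, cv = 0.1, temperature = 18.5,
                        volume_ml = 610, duration_d = 2, copepods = 12,
                        initial_cells = 1921, control_k = 0.2,
                        cell_carbon = 55, constants = model_constants()) {
  if (cv < 0) stop("cv must be >= 0")
  if (any(true_ingestion < 0)) stop("true_ingestion must be >= 0")
  if (is.null(names(true_ingestion)))
    stop("true_ingestion must be a named vector (one truth per treatment)")
  dw <- female_dry_wt(temperature, constants)
  # target ingestion in cells copepod^-1 d^-1
  i_cells <- true_ingestion * (dw * 1e-3) / (cell_carbon * 1e-6)
  g_true <- vapply(i_cells, function(ic) {
    if (ic == 0) return(0)
    f <- function(g) {
      x <- (control_k - g) * duration_d
      (volume_ml * g / copepods) * initial_cells * expm1_over_x(x) - ic
    }
    stats::uniroot(f, c(1e-12, 50), tol = 1e-12)$root
  }, numeric(1))

  sdlog <- sqrt(log(1 + cv^2))
  with_local_seed(seed, {
    rows <- list()
    for (e in seq_len(n_experiments)) {
      for (tr in names(true_ingestion)) {
        for (b in 1:3) {  # controls
          ct <- initial_cells * exp(control_k * duration_d)
          rows[[length(rows) + 1L]] <- data.frame(
            experiment = paste0("exp", e), treatment = tr, role = "control",
            volume_ml = volume_ml, duration_d = duration_d, copepods = 0L,
            initial_cells_per_ml = initial_cells, final_cells_per_ml = ct,
            temperature = temperature, stringsAsFactors = FALSE)
        }
        for (b in 1:3) {  # grazing bottles
          ct <- initial_cells *
            exp((control_k - g_true[[tr]]) * duration_d)
          rows[[length(rows) + 1L]] <- data.frame(
            experiment = paste0("exp", e), treatment = tr, role = "grazing",
            volume_ml = volume_ml, duration_d = duration_d,
            copepods = copepods,
            initial_cells_per_ml = initial_cells, final_cells_per_ml = ct,
            temperature = temperature, stringsAsFactors = FALSE)
        }
      }
    }
    out <- do.call(rbind, rows)
    if (cv > 0)
      out$final_cells_per_ml <- out$final_cells_per_ml *
        exp(stats::rnorm(nrow(out), -sdlog^2 / 2, sdlog))
    rownames(out) <- NULL
    attr(out, "truth") <- list(true_ingestion = true_ingestion,
                               g_true = g_true, control_k = control_k,
                               cv = cv, dry_wt = dw,
                               cell_carbon = cell_carbon)
    out
  })
}

#' Generate synthetic environmental samples
#'
#' Seeded Gaussian draws of temperature, salinity, and oxygen partial
#' pressure per stratum (e.g. contrasting monitoring stations), truncated to
#' physically valid ranges. With zero standard deviations the stratum is
#' degenerate and every sample classifies identically, which pins down
#' ground truth for classifier tests.
#'
#' @param seed integer seed.
#' @param n total number of samples, split evenly across strata (remainder
#'   to the first strata).
#' @param strata data.frame with columns `label`, `t_mean`, `t_sd`,
#'   `s_mean`, `s_sd`, `po2_mean`, `po2_sd`. Default: a severely hypoxic
#'   and a mildly hypoxic station.
#' @return data.frame with columns `label`, `temperature`, `salinity`,
#'   `po2`.
#' @examples
#' gen_env_samples(seed = 1, n = 4)
#' @export
gen_env_samples <- function(seed = 1, n = 100, strata = NULL) {
  if (n < 0) stop("n must be >= 0")
  if (is.null(strata))
    strata <- data.frame(
      label = c("north_station", "south_station"),
      t_mean = c(24, 24), t_sd = c(2, 2),
      s_mean = c(12, 18), s_sd = c(2, 2),
      po2_mean = c(2.5, 9), po2_sd = c(1.5, 3))
  req <- c("label", "t_mean", "t_sd", "s_mean", "s_sd", "po2_mean", "po2_sd")
  stopifnot(is.data.frame(strata), all(req %in% names(strata)))
  if (n == 0)
    return(data.frame(label = character(), temperature = numeric(),
                      salinity = numeric(), po2 = numeric()))
  ns <- rep(n %/% nrow(strata), nrow(strata))
  ns[1] <- ns[1] + n %% nrow(strata)
  clamp <- function(x, lo, hi) pmin(hi, pmax(lo, x))
  with_local_seed(seed, {
    out <- do.call(rbind, lapply(seq_len(nrow(strata)), function(i) {
      m <- ns[i]
      if (!m) return(NULL)
      data.frame(
        label = strata$label[i],
        temperature = clamp(stats::rnorm(m, strata$t_mean[i],
                                         strata$t_sd[i]), -2, 40),
        salinity = clamp(stats::rnorm(m, strata$s_mean[i],
                                      strata$s_sd[i]), 0, 42),
        po2 = pmax(0, stats::rnorm(m, strata$po2_mean[i],
                                   strata$po2_sd[i])),
        stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    out
  })
}
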