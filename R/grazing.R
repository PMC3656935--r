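#' Apparent algal growth rate in a bottle
#'
#' Exponential growth rate implied by initial and final cell concentrations:
#' `k = ln(ct/c0)/t`.
#'
#' @param c0,ct initial and final cell concentrations, cells mL^-1, > 0.
#' @param t incubation duration, d, > 0.
#' @return growth rate, d^-1 (vectorized).
#' @examples
#' algal_growth_rate(1000, 2000, 1)  # ln 2
#' @export
algal_growth_rate <- function(c0, ct, t) {
  if (any(!is.finite(c0)) || any(c0 <= 0) ||
      any(!is.finite(ct)) || any(ct <= 0))
    stop("cell concentrations must be > 0")
  if (any(!is.finite(t)) || any(t <= 0)) stop("duration must be > 0")
  log(ct / c0) / t
}

# (e^x - 1)/x with a stable series near the removable singularity at 0
expm1_over_x <- function(x) {
  ifelse(abs(x) < 1e-8, 1 + x / 2 + x^2 / 6, expm1(x) / x)
}

#' Frost grazing rates from a bottle incubation
#'
#' Closed-form grazing mathematics for bottle incubations: the grazing
#' coefficient is the shortfall of apparent algal growth in a copepod bottle
#' relative to the control growth rate, `g = k - ln(ct/c0)/t`; the
#' time-averaged cell concentration under exponential dynamics is
#' `Cbar = c0 (e^((k-g)t) - 1) / ((k-g) t)` (continuously `c0` when k = g);
#' clearance is `F = V g / N` and ingestion `I = F * Cbar`.
#'
#' A treatment bottle that outgrew the controls yields negative `g` (and
#' `I`); such values are returned as-is with `negative_grazing = TRUE` for
#' quality control, never clipped.
#'
#' @param control_k mean apparent growth rate in the control bottles, d^-1.
#' @param c0,ct initial and final cell concentrations in the grazing bottle,
#'   cells mL^-1, > 0.
#' @param t incubation duration, d, > 0.
#' @param volume bottle volume, mL, > 0.
#' @param n_copepods number of copepods in the bottle, >= 1.
#' @return list with `g` (grazing coefficient, d^-1), `clearance`
#'   (mL copepod^-1 d^-1), `mean_cells` (cells mL^-1), `ingestion`
#'   (cells copepod^-1 d^-1), `negative_grazing` (logical).
#' @examples
#' frost_rates(0.1, 1921, 1200, 1, 610, 12)
#' @export
frost_rates <- function(control_k, c0, ct, t, volume, n_copepods) {
  if (!is.finite(control_k)) stop("control_k must be finite")
  if (any(!is.finite(volume)) || any(volume <= 0))
    stop("volume must be > 0")
  if (any(!is.finite(n_copepods)) || any(n_copepods < 1))
    stop("n_copepods must be >= 1")
  k_app <- algal_growth_rate(c0, ct, t)
  g <- control_k - k_app
  x <- (control_k - g) * t  # = ln(ct/c0)
  mean_cells <- c0 * expm1_over_x(x)
  clearance <- volume * g / n_copepods
  ingestion <- clearance * mean_cells
  neg <- g < -1e-12  # tolerate floating-point zero
  if (any(neg))
    warning("grazing bottle outgrew controls (negative grazing); ",
            "values returned unclipped")
  list(g = g, clearance = clearance, mean_cells = mean_cells,
       ingestion = ingestion, negative_grazing = neg)
}

#' Convert cell ingestion to dry-weight-specific carbon ingestion
#'
#' @param I ingestion, cells copepod^-1 d^-1.
#' @param cell_carbon algal carbon content, pg C cell^-1 (default 55, for
#'   *Rhodomonas* sp.).
#' @param copepod_dry_wt copepod dry weight, ug.
#' @return ingestion rate, ug C mg dry wt^-1 d^-1.
#' @examples
#' carbon_specific_ingestion(37582, 55, 4.045)  # ~511
#' @export
carbon_specific_ingestion <- function(I, cell_carbon = 55, copepod_dry_wt) {
  if (any(!is.finite(cell_carbon)) || any(cell_carbon <= 0))
    stop("cell_carbon must be > 0")
  if (any(!is.finite(copepod_dry_wt)) || any(copepod_dry_wt <= 0))
    stop("copepod_dry_wt must be > 0")
  I * (cell_carbon * 1e-6) / (copepod_dry_wt * 1e-3)
}

#' Food carbon concentration from a cell count
#'
#' @param cells_per_ml algal concentration, cells mL^-1.
#' @param cell_carbon algal carbon content, pg C cell^-1.
#' @return food concentration, ug C L^-1.
#' @examples
#' food_carbon_concentration(1921, 55)  # ~106 ug C/L
#' @export
food_carbon_concentration <- function(cells_per_ml, cell_carbon = 55) {
  cells_per_ml * cell_carbon * 1e-6 * 1000
}

#' Compare ingestion (or other) values between two treatments
#'
#' Two-sided t-test between treatment groups: classical pooled-variance
#' two-sample (`"student"`), Welch (`"welch"`), or paired by experiment
#' (`"paired"`). The paired mode matches a design where treatment means are
#' compared within each of a small number of experiments (df = n_pairs - 1).
#'
#' @param values_a,values_b numeric vectors (>= 2 values each; equal lengths
#'   for `"paired"`).
#' @param mode test variant.
#' @return list with `t`, `df`, `p`.
#' @examples
#' compare_treatments(c(10, 12, 14), c(20, 22, 24), mode = "student")
#' @export
compare_treatments <- function(values_a, values_b,
                               mode = c("welch", "student", "paired")) {
  mode <- match.arg(mode)
  if (length(values_a) < 2 || length(values_b) < 2)
    stop("need at least 2 values per group")
  if (mode == "paired" && length(values_a) != length(values_b))
    stop("paired comparison requires equal-length groups")
  ht <- switch(mode,
    welch = stats::t.test(values_a, values_b, var.equal = FALSE),
    student = stats::t.test(values_a, values_b, var.equal = TRUE),
    paired = stats::t.test(values_a, values_b, paired = TRUE))
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Read a bottle-incubation table from CSV
#'
#' @param path CSV with columns `experiment`, `treatment` (normoxic/hypoxic),
#'   `role` (grazing/control), `volume_ml`, `duration_d`, `copepods`,
#'   `initial_cells_per_ml`, `final_cells_per_ml`, and optionally
#'   `temperature`.
#' @return data.frame of bottles.
#' @export
read_bottles <- function(path) {
  b <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("experiment", "treatment", "role", "volume_ml", "duration_d",
           "copepods", "initial_cells_per_ml", "final_cells_per_ml")
  missing_cols <- setdiff(req, names(b))
  if (length(missing_cols))
    stop("bottle CSV lacks column(s): ", paste(missing_cols, collapse = ", "))
  b
}

#' Ingestion rates for a table of bottle incubations
#'
#' Full grazing pipeline: for each experiment the control growth rate is the
#' mean apparent growth rate over all control bottles (both oxygen levels,
#' following the finding that control growth does not differ between them);
#' each grazing bottle then yields Frost clearance and ingestion, converted
#' to dry-weight-specific carbon ingestion.
#'
#' @param bottles data.frame as from [read_bottles()].
#' @param cell_carbon algal carbon content, pg C cell^-1.
#' @param copepod_dry_wt copepod dry weight, ug; if `NULL`, computed from the
#'   bottle's `temperature` column via [female_dry_wt()].
#' @param constants an `acartia_constants` object.
#' @return data.frame with one row per grazing bottle: `experiment`,
#'   `treatment`, `control_k`, `g`, `clearance_ml`, `mean_cells`,
#'   `ingestion_cells`, `ingestion_ugC` (ug C mg dw^-1 d^-1),
#'   `negative_grazing`.
#' @export
grazing_rates <- function(bottles, cell_carbon = 55, copepod_dry_wt = NULL,
                          constants = model_constants()) {
  stopifnot(is.data.frame(bottles))
  req <- c("experiment", "treatment", "role", "volume_ml", "duration_d",
           "copepods", "initial_cells_per_ml", "final_cells_per_ml")
  missing_cols <- setdiff(req, names(bottles))
  if (length(missing_cols))
    stop("bottle table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  role <- as.character(bottles$role)
  if (!all(role %in% c("grazing", "control")))
    stop("role must be 'grazing' or 'control'")
  graz <- bottles[role == "grazing", , drop = FALSE]
  if (!nrow(graz)) stop("no grazing bottles in table")
  if (any(graz$copepods < 1)) stop("grazing bottles must have copepods >= 1")

  k_all <- algal_growth_rate(bottles$initial_cells_per_ml,
                             bottles$final_cells_per_ml, bottles$duration_d)
  ctrl_k <- tapply(k_all[role == "control"],
                   bottles$experiment[role == "control"], mean)

  out <- do.call(rbind, lapply(seq_len(nrow(graz)), function(i) {
    exp_i <- as.character(graz$experiment[i])
    if (!exp_i %in% names(ctrl_k))
      stop("experiment '", exp_i, "' has no control bottles")
    fr <- withCallingHandlers(
      frost_rates(ctrl_k[[exp_i]], graz$initial_cells_per_ml[i],
                  graz$final_cells_per_ml[i], graz$duration_d[i],
                  graz$volume_ml[i], graz$copepods[i]),
      warning = function(w) invokeRestart("muffleWarning"))
    dw <- if (!is.null(copepod_dry_wt)) copepod_dry_wt
          else if (!is.null(graz$temperature))
            female_dry_wt(graz$temperature[i], constants)
          else stop("supply copepod_dry_wt or a temperature column")
    data.frame(experiment = exp_i,
               treatment = as.character(graz$treatment[i]),
               control_k = ctrl_k[[exp_i]],
               g = fr$g, clearance_ml = fr$clearance,
               mean_cells = fr$mean_cells, ingestion_cells = fr$ingestion,
               ingestion_ugC = carbon_specific_ingestion(fr$ingestion,
                                                         cell_carbon, dw),
               negative_grazing = fr$negative_grazing,
               stringsAsFactors = FALSE)
  }))
  if (any(out$negative_grazing))
    warning(sum(out$negative_grazing),
            " grazing bottle(s) outgrew controls (negative grazing)")
  rownames(out) <- NULL
  out
}
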