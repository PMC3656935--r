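#' Fit the theoretical maximum respiration line
#'
#' Ordinary least squares of 18 C analogous respiration rate on oxygen
#' partial pressure, restricted to group means strictly below the PO2 cutoff
#' (oxygen-limited region). The fit is unweighted, regressing the group means
#' themselves regardless of how many raw measurements each contains.
#'
#' The packaged constants keep the published coefficients (34.9, -20.5); a
#' refit replaces them only if the user opts in via [fit_to_constants()].
#'
#' @param means data.frame of ARR group means (columns `po2`, `arr18`), as
#'   from [arr_group_means()].
#' @param cutoff PO2 cutoff in kPa; only points with `po2 < cutoff` (strict)
#'   enter the fit. Default taken from `constants$regression_cutoff` (8 kPa).
#' @param constants an `acartia_constants` object.
#' @return An object of class `arr_fit`: list with `slope`, `intercept`,
#'   `r2`, `slope_t`, `slope_p` (two-sided single-coefficient t-test), `n`,
#'   `cutoff`.
#' @examples
#' d <- data.frame(po2 = c(2, 4, 6), arr18 = 34.9 * c(2, 4, 6) - 20.5)
#' fit_max_resp(d)
#' @export
fit_max_resp <- function(means, cutoff = NULL,
                         constants = model_constants()) {
  stopifnot(is.data.frame(means), all(c("po2", "arr18") %in% names(means)))
  if (is.null(cutoff)) cutoff <- constants$regression_cutoff
  d <- means[means$po2 < cutoff, , drop = FALSE]
  if (nrow(d) < 3)
    stop("insufficient data: need >= 3 group means below the cutoff, have ",
         nrow(d))
  if (length(unique(d$po2)) < 2 || stats::var(d$po2) == 0)
    stop("degenerate design: PO2 values below the cutoff are all identical")
  fit <- stats::lm(arr18 ~ po2, data = d)
  sm <- summary(fit)
  structure(list(
    slope = unname(stats::coef(fit)["po2"]),
    intercept = unname(stats::coef(fit)["(Intercept)"]),
    r2 = sm$r.squared,
    slope_t = sm$coefficients["po2", "t value"],
    slope_p = sm$coefficients["po2", "Pr(>|t|)"],
    n = nrow(d),
    cutoff = cutoff
  ), class = "arr_fit")
}

#' @export
print.arr_fit <- function(x, ...) {
  cat(sprintf(
    "Maximum respiration line (PO2 < %g kPa, n = %d):\n", x$cutoff, x$n))
  cat(sprintf("  ARR = %.4g * PO2 %+.4g\n", x$slope, x$intercept))
  cat(sprintf("  R2 = %.3f, slope t = %.3f, p = %.3g\n",
              x$r2, x$slope_t, x$slope_p))
  invisible(x)
}

#' Invert a respiration rate to an oxygen partial pressure
#'
#' Solves the maximum-respiration line for PO2: the oxygen partial pressure
#' at which the line equals a given respiration rate. Inverting the target
#' respiration rate gives the critical oxygen partial pressure; inverting the
#' minimum survivable rate gives the lethal one.
#'
#' @param resp_rate respiration rate, ug O2 mg dw^-1 d^-1 (vectorized).
#' @param fit an `arr_fit` object or an `acartia_constants` object (uses the
#'   packaged `slope_a`/`intercept_b`).
#' @return PO2 in kPa.
#' @examples
#' invert_to_po2(261.5)  # critical PO2 at 18 C, ~8.1 kPa
#' invert_to_po2(91.0)   # lethal PO2 at 18 C, ~3.2 kPa
#' @export
invert_to_po2 <- function(resp_rate, fit = model_constants()) {
  ab <- line_coefs(fit)
  if (ab[["slope"]] <= 0)
    stop("line slope must be > 0 to invert a respiration rate")
  (resp_rate - ab[["intercept"]]) / ab[["slope"]]
}

line_coefs <- function(fit) {
  if (inherits(fit, "arr_fit"))
    c(slope = fit$slope, intercept = fit$intercept)
  else if (inherits(fit, "acartia_constants"))
    c(slope = fit$slope_a, intercept = fit$intercept_b)
  else stop("expected an 'arr_fit' or 'acartia_constants' object")
}

#' Adopt refitted line coefficients into a constants object
#'
#' Returns a copy of `constants` whose line slope/intercept (and cutoff,
#' informational R2) come from a fit, for users substituting locally measured
#' data for the packaged parameterization.
#'
#' @param fit an `arr_fit` object.
#' @param constants the constants to update.
#' @return an `acartia_constants` object.
#' @export
fit_to_constants <- function(fit, constants = model_constants()) {
  stopifnot(inherits(fit, "arr_fit"))
  cc <- unclass(constants)
  cc$slope_a <- fit$slope
  cc$intercept_b <- fit$intercept
  cc$regression_cutoff <- fit$cutoff
  cc$fit_r2 <- fit$r2
  validate_constants(cc)
}
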