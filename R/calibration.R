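#' Fit a linear plate-assay standard curve
#'
#' Ordinary least squares of measured response on known concentration, the
#' model behind both the melamine-cyanurate turbidity assay (CYA vs OD600) and
#' the DPD chlorine assay (ppm vs A530). A fresh curve is fitted per plate in
#' practice because temperature and matrix shift the response; the R-squared
#' quality flag (default threshold 0.98) warns when a plate's standards drift.
#'
#' @param concentration known standard concentrations (>= 2 distinct values).
#' @param response measured responses (same length, finite).
#' @param assay free-text tag, e.g. `"melamine_cyanurate_OD600"` or
#'   `"dpd_A530"`.
#' @param r2_threshold warn (flag) below this R-squared.
#' @return object of class `calibration_curve`: slope, intercept, r_squared,
#'   range (of the standards), `low_r2` flag and the underlying `lm` fit.
#' @export
#' @examples
#' cc <- fit_standard(c(0, 1, 2), c(0.10, 0.30, 0.50))
#' coef(cc)
fit_standard <- function(concentration, response,
                         assay = "melamine_cyanurate_OD600",
                         r2_threshold = 0.98) {
  stopifnot(is.numeric(concentration), is.numeric(response),
            length(concentration) == length(response),
            all(is.finite(concentration)), all(is.finite(response)))
  if (length(unique(concentration)) < 2L)
    stop("degenerate_standards: need >= 2 distinct concentrations",
         call. = FALSE)
  fit <- stats::lm(response ~ concentration)
  # summary.lm warns on zero-residual fits; noiseless standards are legitimate
  r2 <- suppressWarnings(summary(fit)$r.squared)
  if (is.nan(r2)) r2 <- 1  # zero-variance response on a flat line
  structure(
    list(slope = unname(coef(fit)[2L]), intercept = unname(coef(fit)[1L]),
         r_squared = r2, assay = assay,
         range = range(concentration), low_r2 = r2 < r2_threshold,
         fit = fit),
    class = "calibration_curve"
  )
}

#' @export
coef.calibration_curve <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("Calibration curve [%s]: response = %.4g + %.4g x conc, R2 = %.4f%s\n",
              x$assay, x$intercept, x$slope, x$r_squared,
              if (x$low_r2) "  (low-R2 flag)" else ""))
  invisible(x)
}

#' @export
predict.calibration_curve <- function(object, concentration, ...) {
  object$intercept + object$slope * concentration
}

#' Invert a standard curve to estimate concentration
#'
#' `(response - intercept) / slope`. Values outside the fitted standard range
#' are flagged `extrapolated`; negative estimates are returned as-is with a
#' `negative` flag rather than clipped, because sub-blank readings carry
#' meaning in the chlorine assay (a solution more reduced than deionized
#' water). `clip = TRUE` clamps negatives to zero instead.
#'
#' @param curve a [fit_standard()] object.
#' @param response numeric vector of measured responses.
#' @param clip clamp negative estimates to zero (off by default).
#' @return numeric vector of concentrations with logical attributes
#'   `"extrapolated"` and `"negative"`.
#' @export
estimate_conc <- function(curve, response, clip = FALSE) {
  stopifnot(inherits(curve, "calibration_curve"), is.numeric(response))
  if (curve$slope == 0) stop("zero-slope curve cannot be inverted",
                             call. = FALSE)
  conc <- (response - curve$intercept) / curve$slope
  extrap <- conc < curve$range[1L] | conc > curve$range[2L]
  neg <- conc < 0
  if (clip) conc <- pmax(conc, 0)
  structure(conc, extrapolated = extrap, negative = neg)
}

#' Consumed substrate from initial and remaining concentrations
#'
#' @param initial initial CYA concentration (ppm, >= 0).
#' @param remaining measured remaining CYA (ppm; may exceed initial within
#'   noise, in which case the negative consumption is flagged, not clipped).
#' @return data.frame with `initial`, `remaining`, `consumed`,
#'   `negative_flag`.
#' @export
#' @examples
#' consumed_cya(200, 50)
consumed_cya <- function(initial, remaining) {
  stopifnot(is.numeric(initial), all(initial >= 0), is.numeric(remaining))
  consumed <- initial - remaining
  data.frame(initial = initial, remaining = remaining, consumed = consumed,
             negative_flag = consumed < 0)
}

#' Free / total / combined chlorine panel from DPD readings
#'
#' Free chlorine from the A530 reading after DPD reagents 1+2; total chlorine
#' from the same well after potassium iodide addition; combined chlorine is
#' total minus free, exactly. Negative values (sub-blank readings) are flagged
#' and preserved.
#'
#' @param a530_free absorbance before KI (free chlorine).
#' @param a530_total absorbance after KI (total chlorine).
#' @param curve DPD calibration curve from [fit_standard()].
#' @return data.frame with `free_ppm`, `total_ppm`, `combined_ppm`,
#'   `negative_flag`.
#' @export
dpd_panel <- function(a530_free, a530_total, curve) {
  free <- as.numeric(estimate_conc(curve, a530_free))
  total <- as.numeric(estimate_conc(curve, a530_total))
  data.frame(free_ppm = free, total_ppm = total,
             combined_ppm = total - free,
             negative_flag = free < 0 | total < 0)
}

#' Normalize activities to a reference condition
#'
#' Expresses each condition's activity as a percentage of the reference
#' condition (e.g. residual activity after heat treatment relative to the
#' 25 degC sample, or granule activity relative to the pre-aging sample). The
#' reference itself is 100% by construction.
#'
#' @param activity named numeric vector of activities.
#' @param reference name of the reference condition.
#' @return named numeric vector of percentages.
#' @export
#' @examples
#' normalize_activity(c(`25C` = 150, `75C` = 141), "25C")
normalize_activity <- function(activity, reference) {
  stopifnot(is.numeric(activity), !is.null(names(activity)),
            reference %in% names(activity))
  ref <- activity[[reference]]
  if (!is.finite(ref) || ref <= 0)
    stop("reference activity must be positive", call. = FALSE)
  100 * activity / ref
}
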