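#' Kinetic parameter container
#'
#' @param kcat turnover number, per second (> 0).
#' @param Km Michaelis constant, uM (> 0).
#' @param kcat_se,Km_se standard errors (optional).
#' @param enzyme_molar_mass subunit molar mass in g/mol used to convert an
#'   enzyme dose in mg/L to a molar concentration. The true value for these
#'   hydrolases is not published; the default 40,000 g/mol is an assumption
#'   and is flagged as such, so absolute progress-curve slopes from mg/L doses
#'   are simulation capabilities, not reproduced observations.
#' @return list of class `kinetic_params`.
#' @export
kinetic_params <- function(kcat, Km, kcat_se = NA_real_, Km_se = NA_real_,
                           enzyme_molar_mass = 40000) {
  stopifnot(kcat > 0, Km > 0, enzyme_molar_mass > 0)
  structure(list(kcat = kcat, Km = Km, kcat_se = kcat_se, Km_se = Km_se,
                 enzyme_molar_mass = enzyme_molar_mass,
                 molar_mass_assumed = enzyme_molar_mass == 40000),
            class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat(sprintf("kcat = %.4g /s%s, Km = %.4g uM%s\n", x$kcat,
              if (is.na(x$kcat_se)) "" else sprintf(" (se %.2g)", x$kcat_se),
              x$Km,
              if (is.na(x$Km_se)) "" else sprintf(" (se %.2g)", x$Km_se)))
  invisible(x)
}

#' @export
coef.kinetic_params <- function(object, ...) {
  c(kcat = object$kcat, Km = object$Km)
}

enzyme_mgL_to_uM <- function(mgL, molar_mass) mgL / molar_mass * 1000

cya_ppm_to_uM <- function(ppm) ppm / 129.07 * 1000
cya_uM_to_ppm <- function(uM) uM * 129.07 / 1000

#' Michaelis-Menten rate
#'
#' `v = kcat * E0 * S / (Km + S)` in uM/s.
#'
#' @param params a [kinetic_params()] object.
#' @param E0 enzyme molar concentration, uM (>= 0).
#' @param S substrate concentration, uM (>= 0, vectorized).
#' @return rate(s) in uM/s.
#' @export
#' @examples
#' p <- kinetic_params(kcat = 10.1, Km = 115)
#' mm_rate(p, E0 = 0.01, S = 115)   # half of Vmax
mm_rate <- function(params, E0, S) {
  stopifnot(inherits(params, "kinetic_params"), E0 >= 0, all(S >= 0))
  params$kcat * E0 * S / (params$Km + S)
}

#' Fit Michaelis-Menten parameters from initial-rate data
#'
#' Nonlinear least squares of `v = kcat * E0 * S / (Km + S)` with positivity
#' bounds (`nls`, port algorithm). Starting values come from the Hanes-Woolf
#' linearization (`S/v` regressed on `S`). Standard errors are taken from the
#' Jacobian at the optimum. Non-convergence or a solution pinned at the
#' positivity boundary raises an error.
#'
#' @param S substrate concentrations, uM (>= 4 values spanning the Km).
#' @param v initial rates, uM/s.
#' @param E0 enzyme molar concentration used in the assays, uM.
#' @param enzyme_molar_mass carried into the returned [kinetic_params()].
#' @return a [kinetic_params()] object with the fitted `nls` object attached
#'   as attribute `"fit"`.
#' @export
fit_mm <- function(S, v, E0, enzyme_molar_mass = 40000) {
  stopifnot(is.numeric(S), is.numeric(v), length(S) == length(v), E0 > 0)
  if (length(S) < 4L)
    stop("degenerate_design: need at least 4 rate observations", call. = FALSE)
  if (any(S < 0) || any(v < 0))
    stop("substrate and rates must be non-negative", call. = FALSE)
  keep <- S > 0 & v > 0
  if (sum(keep) < 4L)
    stop("degenerate_design: need at least 4 positive observations",
         call. = FALSE)
  hw <- stats::lm(I(S[keep] / v[keep]) ~ S[keep])
  vmax0 <- 1 / coef(hw)[[2L]]
  km0 <- coef(hw)[[1L]] * vmax0
  if (!is.finite(vmax0) || vmax0 <= 0) vmax0 <- max(v)
  if (!is.finite(km0) || km0 <= 0) km0 <- stats::median(S)
  dat <- data.frame(S = S, v = v)
  fit <- tryCatch(
    stats::nls(v ~ kcat * E0 * S / (Km + S), data = dat,
               start = list(kcat = vmax0 / E0, Km = km0),
               algorithm = "port", lower = c(kcat = 1e-12, Km = 1e-12),
               control = stats::nls.control(maxiter = 200, warnOnly = FALSE)),
    error = function(e) stop("fit_failed: ", conditionMessage(e),
                             call. = FALSE)
  )
  est <- coef(fit)
  if (any(est <= 1e-10))
    stop("fit_failed: solution pinned at positivity boundary", call. = FALSE)
  se <- summary(fit)$coefficients[, "Std. Error"]
  out <- kinetic_params(est[["kcat"]], est[["Km"]],
                        kcat_se = se[["kcat"]], Km_se = se[["Km"]],
                        enzyme_molar_mass = enzyme_molar_mass)
  attr(out, "fit") <- fit
  out
}

#' Time to reach a substrate level under the integrated MM law
#'
#' Implicit solution of `dS/dt = -kcat E0 S/(Km+S)`:
#' `t = (Km ln(S0/S) + (S0 - S)) / (kcat E0)` (seconds, concentrations in uM).
#'
#' @param params a [kinetic_params()] object.
#' @param E0 enzyme molar concentration, uM (> 0).
#' @param S0_uM,S_uM initial and target substrate, uM (0 < S <= S0).
#' @return time in seconds.
#' @export
mm_implicit_time <- function(params, E0, S0_uM, S_uM) {
  stopifnot(inherits(params, "kinetic_params"), E0 > 0,
            S0_uM > 0, S_uM > 0, S_uM <= S0_uM)
  (params$Km * log(S0_uM / S_uM) + (S0_uM - S_uM)) / (params$kcat * E0)
}

#' Simulate a CYA depletion progress curve
#'
#' Integrates `dS/dt = -kcat E0 S/(Km + S)` (adaptive-step `deSolve::lsoda`,
#' absolute tolerance 1e-8 on S) over a time grid in hours, converting ppm to
#' uM with the CYA molar mass (129.07 g/mol). Hypochlorite inactivation events
#' switch the enzyme off instantaneously: from the first event time onward the
#' substrate is held constant. Biuret is produced 1:1 on a molar basis; its
#' ppm track uses the biuret molar mass (103.08 g/mol). At S >> Km the curve
#' is the zero-order (constant-rate) regime.
#'
#' @param params a [kinetic_params()] object.
#' @param E0 enzyme molar concentration, uM (>= 0). Use
#'   `enzyme_mgL / molar_mass * 1000` for a mass dose.
#' @param S0_ppm initial CYA, ppm (>= 0).
#' @param t_hours time grid in hours (non-negative, increasing).
#' @param inactivation_times_hr times (hr) at which hypochlorite kills the
#'   enzyme; only the earliest matters.
#' @return data.frame of class `time_course`: `time_hr`, `cya_ppm`,
#'   `biuret_ppm`, `enzyme_active`.
#' @export
simulate_progress <- function(params, E0, S0_ppm, t_hours,
                              inactivation_times_hr = numeric(0)) {
  stopifnot(inherits(params, "kinetic_params"), E0 >= 0, S0_ppm >= 0,
            is.numeric(t_hours), length(t_hours) >= 1L)
  if (any(t_hours < 0) || any(inactivation_times_hr < 0))
    stop("times must be non-negative", call. = FALSE)
  if (is.unsorted(t_hours, strictly = TRUE))
    stop("t_hours must be strictly increasing", call. = FALSE)
  t_star <- if (length(inactivation_times_hr)) min(inactivation_times_hr)
            else Inf
  S0_uM <- cya_ppm_to_uM(S0_ppm)
  S_uM <- rep(S0_uM, length(t_hours))
  if (E0 > 0 && S0_uM > 0) {
    eval_grid <- unique(sort(c(0, pmin(t_hours, t_star))))
    deriv <- function(t, y, parms) {
      list(-params$kcat * E0 * y[1L] / (params$Km + y[1L]) * 3600)
    }
    sol <- deSolve::lsoda(c(S = S0_uM), times = eval_grid, func = deriv,
                          parms = NULL, rtol = 1e-10, atol = 1e-8)
    lut <- stats::approx(sol[, "time"], sol[, "S"],
                         xout = pmin(t_hours, t_star), rule = 2)$y
    S_uM <- pmax(lut, 0)
  }
  out <- data.frame(
    time_hr = t_hours,
    cya_ppm = cya_uM_to_ppm(S_uM),
    biuret_ppm = (S0_uM - S_uM) * 103.08 / 1000,
    enzyme_active = t_hours < t_star & E0 > 0
  )
  class(out) <- c("time_course", "data.frame")
  attr(out, "params") <- params
  attr(out, "E0_uM") <- E0
  out
}

#' @export
plot.time_course <- function(x, ...) {
  graphics::plot(x$time_hr, x$cya_ppm, type = "l", xlab = "time (hr)",
                 ylab = "CYA (ppm)", ...)
  graphics::lines(x$time_hr, x$biuret_ppm, lty = 2)
  graphics::legend("right", legend = c("CYA", "biuret"), lty = c(1, 2),
                   bty = "n")
  invisible(x)
}

#' Three-stage pool remediation plan
#'
#' Composes the pipeline's calculators into the reduce -> hydrolyze -> oxidize
#' procedure: (1) reductant dose to neutralize residual free chlorine
#' ([reductant_dose()]); (2) enzyme dose and hydrolysis time to bring CYA to
#' target (integrated MM law, [mm_implicit_time()]); (3) hypochlorite shock
#' equivalents to oxidize the biuret produced (4.5 ClO- equivalents per
#' biuret, [electron_equivalents()]), which also inactivates the remaining
#' enzyme.
#'
#' @param volume_L pool volume in liters.
#' @param cya_ppm current CYA level.
#' @param free_cl_ppm residual free chlorine (ppm as ClO-).
#' @param params a [kinetic_params()] object.
#' @param enzyme_mgL enzyme dose in mg/L (converted with
#'   `params$enzyme_molar_mass`).
#' @param target_cya_ppm CYA level to reach by hydrolysis (> 0).
#' @param reductant reductant species name.
#' @param reductant_eq mol reductant per mol ClO-; default from
#'   [reductant_presets()].
#' @return list of class `remediation_plan`.
#' @export
plan_remediation <- function(volume_L, cya_ppm, free_cl_ppm, params,
                             enzyme_mgL, target_cya_ppm,
                             reductant = "sodium_sulfite",
                             reductant_eq = NULL) {
  stopifnot(volume_L > 0, cya_ppm >= 0, free_cl_ppm >= 0,
            inherits(params, "kinetic_params"), enzyme_mgL >= 0,
            target_cya_ppm > 0)
  if (is.null(reductant_eq)) {
    presets <- reductant_presets()
    hit <- presets$equivalents[presets$reductant == reductant]
    if (!length(hit))
      stop("no preset equivalents for '", reductant,
           "'; supply reductant_eq", call. = FALSE)
    reductant_eq <- hit
  }
  stage1 <- reductant_dose(free_cl_ppm, "hypochlorite", reductant,
                           reductant_eq)
  E0 <- enzyme_mgL_to_uM(enzyme_mgL, params$enzyme_molar_mass)
  if (cya_ppm <= target_cya_ppm) {
    hours <- 0
    removed_ppm <- 0
  } else {
    if (E0 <= 0)
      stop("unreachable_target: CYA above target with zero enzyme",
           call. = FALSE)
    hours <- mm_implicit_time(params, E0, cya_ppm_to_uM(cya_ppm),
                              cya_ppm_to_uM(target_cya_ppm)) / 3600
    removed_ppm <- cya_ppm - target_cya_ppm
  }
  biuret_mmol <- removed_ppm / 129.07 * volume_L       # 1:1 molar with CYA
  shock_eq <- electron_equivalents("biuret", 0)$equivalents
  shock_mmol <- shock_eq * biuret_mmol
  shock_ppm <- shock_mmol * 51.45 / volume_L           # as ClO-
  structure(
    list(volume_L = volume_L, cya_ppm = cya_ppm,
         target_cya_ppm = target_cya_ppm,
         stage1_reduce = stage1,
         stage2_hydrolyze = list(enzyme_mgL = enzyme_mgL, E0_uM = E0,
                                 hours_to_target = hours,
                                 cya_removed_ppm = removed_ppm,
                                 biuret_produced_ppm =
                                   removed_ppm / 129.07 * 103.08),
         stage3_oxidize = list(equivalents_per_biuret = shock_eq,
                               biuret_mmol = biuret_mmol,
                               hypochlorite_mmol = shock_mmol,
                               hypochlorite_ppm_as_ClO = shock_ppm)),
    class = "remediation_plan"
  )
}

#' @export
print.remediation_plan <- function(x, ...) {
  cat(sprintf("Remediation plan for %.4g L at %.4g ppm CYA (target %.4g ppm)\n",
              x$volume_L, x$cya_ppm, x$target_cya_ppm))
  cat(sprintf("  1. reduce:    %.3g ppm %s against %.3g ppm free chlorine\n",
              x$stage1_reduce$dose_ppm, x$stage1_reduce$reductant,
              x$stage1_reduce$oxidant_ppm))
  cat(sprintf("  2. hydrolyze: %.3g mg/L enzyme, %.3g hr to target (%.3g ppm biuret formed)\n",
              x$stage2_hydrolyze$enzyme_mgL, x$stage2_hydrolyze$hours_to_target,
              x$stage2_hydrolyze$biuret_produced_ppm))
  cat(sprintf("  3. oxidize:   %.3g ppm hypochlorite (as ClO-; %.1f eq per biuret), inactivates remaining enzyme\n",
              x$stage3_oxidize$hypochlorite_ppm_as_ClO,
              x$stage3_oxidize$equivalents_per_biuret))
  invisible(x)
}
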