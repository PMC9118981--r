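#' Isotope-labeling configuration
#'
#' Settings of the 1:1 nitrogen-label tracer design: the fraction of molecules
#' that are fully 15N-labeled, the isotopic purities of the light and heavy
#' materials, and which background-correction variant to apply to the m/z 29
#' channel.
#'
#' @param label_mix_fraction fraction of substrate molecules fully
#'   15N-labeled (0.5 for a 1:1 mix).
#' @param light_purity fraction of 14N per atom in the unlabeled material
#'   (0.9963, i.e. natural-abundance nitrogen).
#' @param heavy_purity fraction of 15N per atom in the labeled material.
#' @param background_correction `"symmetric_excess"` (default) estimates
#'   air-derived m/z 28 as `area28 - area30` (reaction-derived 28 should equal
#'   30 under a 1:1 mix); `"total_28"` treats all of m/z 28 as air.
#' @return list of class `isotope_config`.
#' @export
isotope_config <- function(label_mix_fraction = 0.5,
                           light_purity = 0.9963,
                           heavy_purity = 0.99,
                           background_correction = c("symmetric_excess",
                                                     "total_28")) {
  stopifnot(label_mix_fraction >= 0, label_mix_fraction <= 1,
            light_purity >= 0, light_purity <= 1,
            heavy_purity >= 0, heavy_purity <= 1)
  structure(
    list(label_mix_fraction = label_mix_fraction,
         light_purity = light_purity, heavy_purity = heavy_purity,
         background_correction = match.arg(background_correction)),
    class = "isotope_config"
  )
}

binom_pair <- function(p15) {
  c(`28` = (1 - p15)^2, `29` = 2 * p15 * (1 - p15), `30` = p15^2)
}

#' Expected N2 isotopomer distribution under a labeling mechanism
#'
#' Closed-form isotopomer model for dinitrogen formed from a mix of fully
#' 14N- and fully 15N-labeled substrate (fraction labeled `p`), assuming ideal
#' isotopic purity:
#' \itemize{
#'   \item intermolecular: both nitrogens drawn independently from the fully
#'     scrambled pool — binomial, 1:2:1 at m/z 28:29:30 for p = 0.5;
#'   \item urea, intramolecular: each N2 keeps both nitrogens of one molecule —
#'     only m/z 28 and 30 (1:0:1 at p = 0.5);
#'   \item biuret, intramolecular: each molecule's three nitrogens yield one
#'     within-molecule N2 plus half an N2 assembled from the pooled leftover
#'     nitrogens — 5:2:5 at p = 0.5;
#'   \item mixture: fraction `f` of molecules react intramolecularly, the rest
#'     intermolecularly (N2 yield per molecule is mechanism-independent, so
#'     `f` is also the intramolecular fraction of product N2 for urea).
#' }
#'
#' @param compound `"urea"` or `"biuret"`.
#' @param mechanism `"intermolecular"`, `"intramolecular"` or `"mixture"`.
#' @param f fraction of molecules reacting intramolecularly (mixture only).
#' @param p fraction of molecules fully labeled (default 0.5).
#' @return named probability vector over m/z 28, 29, 30 (class
#'   `isotopomer_distribution`).
#' @export
#' @examples
#' expected_distribution("urea", "intermolecular")     # 1:2:1
#' expected_distribution("biuret", "intramolecular")   # 5:2:5
expected_distribution <- function(compound = c("urea", "biuret"),
                                  mechanism = c("intermolecular",
                                                "intramolecular", "mixture"),
                                  f = NULL, p = 0.5) {
  compound <- match.arg(compound)
  mechanism <- match.arg(mechanism)
  stopifnot(p >= 0, p <= 1)
  inter <- binom_pair(p)
  intra_pair <- c(`28` = 1 - p, `29` = 0, `30` = p)
  intra <- switch(compound,
    urea = intra_pair,
    # per molecule: 1 within-molecule N2 + 1/2 N2 from the pooled leftover N
    biuret = (2 / 3) * intra_pair + (1 / 3) * inter
  )
  probs <- switch(mechanism,
    intermolecular = inter,
    intramolecular = intra,
    mixture = {
      if (is.null(f)) stop("mixture mechanism needs f", call. = FALSE)
      stopifnot(f >= 0, f <= 1)
      f * intra + (1 - f) * inter
    }
  )
  structure(probs, compound = compound, mechanism = mechanism,
            f = f, p = p, class = "isotopomer_distribution")
}

#' Expected m/z 29/30 ratio for a given intramolecular fraction
#'
#' Evaluates the mixture model of [expected_distribution()] at a 1:1 label mix
#' and returns the 29/30 ion ratio. Closed forms: `2(1-f)/(1+f)` for urea and
#' `(6-4f)/(3+2f)` for biuret; both equal 2 at f = 0 (pure intermolecular).
#'
#' @param compound `"urea"` or `"biuret"`.
#' @param f fraction intramolecular, in `[0, 1]` (vectorized).
#' @return numeric ratio(s).
#' @export
#' @examples
#' expected_ratio("urea", 0)     # 2
#' expected_ratio("biuret", 1)   # 0.4
expected_ratio <- function(compound = c("urea", "biuret"), f) {
  compound <- match.arg(compound)
  stopifnot(is.numeric(f))
  if (any(f < 0 | f > 1)) stop("f must lie in [0, 1]", call. = FALSE)
  vapply(f, function(fi) {
    d <- expected_distribution(compound, "mixture", f = fi, p = 0.5)
    unname(d[["29"]] / d[["30"]])
  }, numeric(1))
}

#' Percent intramolecular N2 formation from a measured 29/30 ratio
#'
#' Algebraic inverse of the 1:1-mix isotopomer mixture model:
#' `100 (2 - x) / (2 + x)` for urea and `150 (2 - x) / (2 + x)` for biuret.
#' (The commonly printed forms with numerator and denominator transposed,
#' `-100 (x + 2) / (x - 2)`, are the reciprocal scaled by 10^4 and do not map
#' measured ratios into `[0, 100]`; the derived inverses above reproduce the
#' published conversions.) Ratios slightly above 2 are plausible noise around
#' a purely intermolecular mechanism, so out-of-range results are clamped to
#' `[0, 100]` and flagged rather than erroring.
#'
#' @param compound `"urea"` or `"biuret"`.
#' @param x measured (background-corrected) m/z 29/30 area ratio, >= 0
#'   (vectorized).
#' @param clamp clamp results into `[0, 100]` (default) with a `"clamped"`
#'   attribute; `FALSE` returns the raw value.
#' @return numeric percentage(s); attribute `"clamped"` marks values that fell
#'   outside `[0, 100]` before clamping.
#' @export
#' @examples
#' fraction_intramolecular("urea", 0.93)    # ~36.5%
#' fraction_intramolecular("biuret", 1.44)  # ~24.4%
fraction_intramolecular <- function(compound = c("urea", "biuret"), x,
                                    clamp = TRUE) {
  compound <- match.arg(compound)
  stopifnot(is.numeric(x))
  if (any(x < 0)) stop("ratio x must be >= 0", call. = FALSE)
  scale <- switch(compound, urea = 100, biuret = 150)
  raw <- scale * (2 - x) / (2 + x)
  out_of_range <- raw < 0 | raw > 100
  val <- if (clamp) pmin(pmax(raw, 0), 100) else raw
  structure(val, clamped = out_of_range & clamp)
}

#' Correct the m/z 29 channel for atmospheric nitrogen
#'
#' Air leaking into a headspace vial contributes mostly m/z 28 (99.63% 14N2)
#' plus a small natural-abundance m/z 29 component, `2 (1-q)/q` per unit of
#' air-derived 28 (q = fraction 14N per atom). The default
#' `"symmetric_excess"` estimator takes air-derived 28 as
#' `max(area28 - area30, 0)`, because under a 1:1 label mix the reaction makes
#' 28 and 30 in equal amounts; `"total_28"` attributes all of m/z 28 to air.
#' Corrected areas are floored at zero. With q = 1 the correction is the
#' identity.
#'
#' @param areas named numeric vector with elements `"28"`, `"29"`, `"30"`
#'   (non-negative integrated ion areas).
#' @param config an [isotope_config()].
#' @return named numeric vector of corrected areas with attribute
#'   `"background29"` (the subtracted amount).
#' @export
correct_background <- function(areas, config = isotope_config()) {
  stopifnot(all(c("28", "29", "30") %in% names(areas)),
            all(is.finite(areas[c("28", "29", "30")])),
            all(areas[c("28", "29", "30")] >= 0))
  q <- config$light_purity
  air28 <- switch(config$background_correction,
    symmetric_excess = max(areas[["28"]] - areas[["30"]], 0),
    total_28 = areas[["28"]]
  )
  bg29 <- if (q > 0) air28 * 2 * (1 - q) / q else 0
  out <- areas
  out[["29"]] <- max(areas[["29"]] - bg29, 0)
  structure(out, background29 = bg29,
            method = config$background_correction)
}

#' m/z 45/46 ratio of trace nitrous oxide
#'
#' N2O assembled from two nitrogens of a fully scrambled 1:1 14N/15N pool is
#' binomial over m/z 44:45:46 = 1:2:1, predicting a 45/46 ratio of 2 — the
#' signature of intermolecular N-N bond formation in the trace N2O channel.
#'
#' @param areas named numeric vector with elements `"45"` and `"46"`.
#' @return the 45/46 area ratio.
#' @export
#' @examples
#' n2o_ratio(c(`44` = 1, `45` = 2, `46` = 1))   # 2
n2o_ratio <- function(areas) {
  stopifnot(all(c("45", "46") %in% names(areas)))
  if (areas[["46"]] <= 0)
    stop("undefined ratio: m/z 46 area is zero", call. = FALSE)
  unname(areas[["45"]] / areas[["46"]])
}

#' Integrate chromatogram peaks over named retention-time windows
#'
#' Trapezoidal area above a linear baseline drawn between the window edges.
#' Negative net areas (baseline above signal) are clipped to zero and flagged.
#'
#' @param time strictly increasing retention times (min).
#' @param intensity signal intensities (same length).
#' @param windows data.frame with columns `name`, `rt` (window center, min)
#'   and `half_width` (min).
#' @return data.frame with `name`, `rt`, `area`, `clipped`.
#' @export
integrate_peaks <- function(time, intensity, windows) {
  stopifnot(is.numeric(time), is.numeric(intensity),
            length(time) == length(intensity), length(time) >= 2L,
            all(diff(time) > 0),
            is.data.frame(windows),
            all(c("name", "rt", "half_width") %in% names(windows)))
  rows <- lapply(seq_len(nrow(windows)), function(k) {
    lo <- windows$rt[k] - windows$half_width[k]
    hi <- windows$rt[k] + windows$half_width[k]
    sel <- which(time >= lo & time <= hi)
    if (length(sel) < 2L)
      stop("empty_window: window '", windows$name[k],
           "' covers fewer than 2 points", call. = FALSE)
    t <- time[sel]; y <- intensity[sel]
    baseline <- y[1L] + (y[length(y)] - y[1L]) *
      (t - t[1L]) / (t[length(t)] - t[1L])
    net <- y - baseline
    area <- sum(diff(t) * (head(net, -1L) + tail(net, -1L)) / 2)
    data.frame(name = windows$name[k], rt = windows$rt[k],
               area = max(area, 0), clipped = area < 0,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Estimate the intramolecular N2 fraction from an ion table
#'
#' Full deconvolution pipeline: background-correct the m/z 29 channel
#' ([correct_background()]), form the corrected 29/30 ratio, and invert the
#' isotopomer mixture model ([fraction_intramolecular()]).
#'
#' @param areas named numeric vector with elements `"28"`, `"29"`, `"30"`.
#' @param compound `"urea"` or `"biuret"`.
#' @param config an [isotope_config()].
#' @param clamp clamp the percentage into `[0, 100]` (flagged).
#' @return object of class `mechanism_estimate`: `compound`, `x` (corrected
#'   ratio), `percent_intramolecular`, `clamped`, `background29`, `method`,
#'   `light_purity`, and a `formula` note recording that the derived inverse
#'   (not the transposed printed form) is used.
#' @export
estimate_mechanism <- function(areas, compound = c("urea", "biuret"),
                               config = isotope_config(), clamp = TRUE) {
  compound <- match.arg(compound)
  corrected <- correct_background(areas, config)
  if (corrected[["30"]] <= 0)
    stop("undefined ratio: corrected m/z 30 area is zero", call. = FALSE)
  x <- corrected[["29"]] / corrected[["30"]]
  pct <- fraction_intramolecular(compound, x, clamp = clamp)
  structure(
    list(compound = compound, x = unname(x),
         percent_intramolecular = as.numeric(pct),
         clamped = as.logical(attr(pct, "clamped")),
         background29 = attr(corrected, "background29"),
         method = attr(corrected, "method"),
         light_purity = config$light_purity,
         formula = paste0(switch(compound, urea = "100", biuret = "150"),
                          "*(2-x)/(2+x), derived inverse of the mixture",
                          " model (printed form has numerator/denominator",
                          " transposed)")),
    class = "mechanism_estimate"
  )
}

#' @export
print.mechanism_estimate <- function(x, ...) {
  cat(sprintf(
    "%s: corrected m/z 29/30 = %.3f -> %.1f%% intramolecular N2%s\n",
    x$compound, x$x, x$percent_intramolecular,
    if (isTRUE(x$clamped)) " (clamped)" else ""))
  cat(sprintf("  background correction: %s (q = %.4f, removed %.3g from m/z 29)\n",
              x$method, x$light_purity, x$background29))
  invisible(x)
}
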