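#' Species registry for pool-chemistry calculations
#'
#' Small built-in registry of the chemical species handled by the dosing,
#' speciation and electron-balance calculators: cyanuric acid (CYA) and its
#' \eqn{^{13}C_3/^{15}N_3} isotopologue, biuret, urea, hypochlorite (as the free
#' ion and as sodium hypochlorite) and the two pool reductants. Nitrogen in the
#' amide/amine positions of CYA, biuret and urea starts at oxidation state -3.
#'
#' @param extra optional data.frame with the same columns to append or override
#'   (matched by `name`); lets callers register species without editing the
#'   package.
#' @return data.frame with columns `name`, `formula`, `molar_mass` (g/mol),
#'   `n_nitrogen`, `n_oxidation_state`.
#' @export
#' @examples
#' species_registry()
species_registry <- function(extra = NULL) {
  reg <- data.frame(
    name = c("cyanuric_acid", "cyanuric_acid_13C15N", "biuret", "urea",
             "hypochlorite", "sodium_hypochlorite", "sodium_sulfite",
             "sodium_thiosulfate"),
    formula = c("C3H3N3O3", "13C3H3 15N3O3", "C2H5N3O2", "CH4N2O",
                "ClO-", "NaClO", "Na2SO3", "Na2S2O3"),
    molar_mass = c(129.07, 135.07, 103.08, 60.06,
                   51.45, 74.44, 126.04, 158.11),
    n_nitrogen = c(3L, 3L, 3L, 2L, 0L, 0L, 0L, 0L),
    n_oxidation_state = c(-3L, -3L, -3L, -3L, NA_integer_, NA_integer_,
                          NA_integer_, NA_integer_),
    stringsAsFactors = FALSE
  )
  if (!is.null(extra)) {
    stopifnot(is.data.frame(extra), all(names(reg) %in% names(extra)))
    reg <- reg[!reg$name %in% extra$name, , drop = FALSE]
    reg <- rbind(reg, extra[, names(reg)])
  }
  reg
}

get_species <- function(species, registry = species_registry()) {
  if (is.character(species)) {
    hit <- registry[registry$name == species, , drop = FALSE]
    if (nrow(hit) != 1L)
      stop("unknown species: '", species, "'", call. = FALSE)
    return(as.list(hit))
  }
  stopifnot(is.list(species), !is.null(species$molar_mass))
  species
}

#' Convert between ppm (mg/L) and millimolar concentration
#'
#' Dilute aqueous assumption: 1 ppm is taken as 1 mg/L at unit water density.
#'
#' @param ppm concentration in mg/L (non-negative).
#' @param mM concentration in mmol/L.
#' @param species registry name (see [species_registry()]) or a list with a
#'   `molar_mass` element.
#' @param registry species registry data.frame.
#' @return numeric concentration in the requested unit.
#' @export
#' @examples
#' ppm_to_mM(100, "cyanuric_acid")   # ~0.77 mM, the chlorine-lock threshold
ppm_to_mM <- function(ppm, species, registry = species_registry()) {
  stopifnot(is.numeric(ppm), all(ppm >= 0))
  sp <- get_species(species, registry)
  if (sp$molar_mass <= 0) stop("molar mass must be positive", call. = FALSE)
  ppm / sp$molar_mass
}

#' @rdname ppm_to_mM
#' @export
mM_to_ppm <- function(mM, species, registry = species_registry()) {
  stopifnot(is.numeric(mM), all(mM >= 0))
  sp <- get_species(species, registry)
  if (sp$molar_mass <= 0) stop("molar mass must be positive", call. = FALSE)
  mM * sp$molar_mass
}

#' Hypochlorous acid / hypochlorite speciation
#'
#' Two-species equilibrium HOCl <-> OCl- + H+. The temperature-dependent pKa
#' uses the standard empirical form pKa = 3000/T - 10.0686 + 0.0253 T with T in
#' kelvin; `pka_fun` can swap in another model. Molecular Cl2 (relevant only
#' below pH ~4) is outside the two-species model.
#'
#' @param pH pool pH, in (0, 14).
#' @param temperature_C water temperature in degrees Celsius, 0-45.
#' @param pka_fun function of temperature in kelvin returning the HOCl pKa.
#' @return list with `pH`, `temperature_C`, `pKa` and `fractions` (named
#'   numeric, HOCl and OCl, summing to 1).
#' @export
#' @examples
#' chlorine_speciation(7.33, 25)
chlorine_speciation <- function(pH, temperature_C = 25,
                                pka_fun = hocl_pka) {
  stopifnot(length(pH) == 1L, length(temperature_C) == 1L)
  if (!is.finite(pH) || pH <= 0 || pH >= 14)
    stop("pH must lie strictly between 0 and 14", call. = FALSE)
  if (!is.finite(temperature_C) || temperature_C < 0 || temperature_C > 45)
    stop("temperature must lie in [0, 45] degC", call. = FALSE)
  pka <- pka_fun(temperature_C + 273.15)
  f_hocl <- 1 / (1 + 10^(pH - pka))
  structure(
    list(pH = pH, temperature_C = temperature_C, pKa = pka,
         fractions = c(HOCl = f_hocl, OCl = 1 - f_hocl)),
    class = "speciation_profile"
  )
}

#' @rdname chlorine_speciation
#' @param T_kelvin absolute temperature.
#' @export
hocl_pka <- function(T_kelvin) 3000 / T_kelvin - 10.0686 + 0.0253 * T_kelvin

#' @export
print.speciation_profile <- function(x, ...) {
  cat(sprintf("Chlorine speciation at pH %.2f, %.1f degC (pKa %.3f)\n",
              x$pH, x$temperature_C, x$pKa))
  cat(sprintf("  HOCl: %.1f%%   OCl-: %.1f%%\n",
              100 * x$fractions[["HOCl"]], 100 * x$fractions[["OCl"]]))
  invisible(x)
}

#' Hypochlorite equivalents from the nitrogen electron balance
#'
#' Each ClO- accepts two electrons (Cl(+1) -> Cl(-1)). Oxidizing the n_N
#' nitrogens of a substrate from their initial oxidation state (-3 for the
#' amide nitrogens of urea and biuret) to `target_os` therefore needs
#' n_N * |target_os - initial| / 2 molar equivalents of hypochlorite. Driving
#' biuret's three nitrogens to N2 (oxidation state 0) costs 4.5 equivalents;
#' on to nitrate (+5) costs 12.
#'
#' @param species registry name or list with `n_nitrogen` and
#'   `n_oxidation_state`.
#' @param target_os target nitrogen oxidation state, 0 (N2) or +5 (nitrate).
#' @param registry species registry data.frame.
#' @return list of class `electron_balance` with `electrons_total` and
#'   `equivalents`.
#' @export
#' @examples
#' electron_equivalents("biuret", 0)$equivalents   # 4.5
#' electron_equivalents("urea", 0)$equivalents     # 3
electron_equivalents <- function(species, target_os = 0,
                                 registry = species_registry()) {
  sp <- get_species(species, registry)
  if (is.na(sp$n_nitrogen %||% NA) || sp$n_nitrogen == 0)
    stop("species '", sp$name %||% "?", "' has no nitrogen to oxidize",
         call. = FALSE)
  if (!target_os %in% c(0, 5))
    stop("target oxidation state must be 0 (N2) or +5 (nitrate)", call. = FALSE)
  initial <- sp$n_oxidation_state %||% -3L
  d_os <- abs(target_os - initial)
  electrons <- sp$n_nitrogen * d_os
  structure(
    list(species = sp$name %||% sp$formula, n_nitrogen = sp$n_nitrogen,
         delta_os = d_os, electrons_total = electrons,
         equivalents = electrons / 2),
    class = "electron_balance"
  )
}

#' @export
print.electron_balance <- function(x, ...) {
  cat(sprintf(
    "%s: %d N x %d e- = %d electrons -> %.1f ClO- equivalents (2 e- each)\n",
    x$species, x$n_nitrogen, x$delta_os, x$electrons_total, x$equivalents))
  invisible(x)
}

#' Reductant dose to neutralize residual hypochlorite
#'
#' Plain molar-mass arithmetic: the recommended reductant dose (ppm) is
#' `equivalents * oxidant_ppm / M(oxidant) * M(reductant)`. The oxidant basis
#' species must be stated explicitly because "ppm hypochlorite" is ambiguous
#' (as ClO- vs as NaOCl). The effective ratios observed in pool water
#' titrations (~1:1 for thiosulfate, ~2:1 for sulfite, mol reductant per mol
#' ClO-) ship as the documented presets in [reductant_presets()], not as
#' hard-coded stoichiometric truth.
#'
#' @param oxidant_ppm residual oxidant concentration in ppm (> 0 unless
#'   equivalents is 0).
#' @param oxidant_species basis species the ppm refers to (default free ClO-).
#' @param reductant_species registry name of the reducing agent.
#' @param equivalents moles of reductant per mole of oxidant (>= 0).
#' @param registry species registry data.frame.
#' @return list of class `dose_recommendation`.
#' @export
#' @examples
#' reductant_dose(5.72, "hypochlorite", "sodium_thiosulfate", 1)  # ~17.6 ppm
#' reductant_dose(5.72, "hypochlorite", "sodium_sulfite", 2)      # ~28.0 ppm
reductant_dose <- function(oxidant_ppm, oxidant_species = "hypochlorite",
                           reductant_species, equivalents,
                           registry = species_registry()) {
  stopifnot(is.numeric(oxidant_ppm), oxidant_ppm >= 0,
            is.numeric(equivalents), equivalents >= 0)
  ox <- get_species(oxidant_species, registry)
  red <- get_species(reductant_species, registry)
  if (ox$molar_mass <= 0 || red$molar_mass <= 0)
    stop("molar masses must be positive", call. = FALSE)
  dose <- equivalents * (oxidant_ppm / ox$molar_mass) * red$molar_mass
  structure(
    list(oxidant_ppm = oxidant_ppm, oxidant_basis = ox$name %||% ox$formula,
         reductant = red$name %||% red$formula, equivalents = equivalents,
         dose_ppm = dose),
    class = "dose_recommendation"
  )
}

#' @rdname reductant_dose
#' @export
reductant_presets <- function() {
  data.frame(
    reductant = c("sodium_thiosulfate", "sodium_sulfite"),
    equivalents = c(1, 2),
    note = c("effective ~1:1 mol/mol ClO- observed in pool-water titration",
             "effective ~2:1 mol/mol ClO- observed in pool-water titration"),
    stringsAsFactors = FALSE
  )
}

#' @export
print.dose_recommendation <- function(x, ...) {
  cat(sprintf(
    "%.3g ppm %s (x%.2g eq) to neutralize %.3g ppm oxidant (as %s)\n",
    x$dose_ppm, x$reductant, x$equivalents, x$oxidant_ppm, x$oxidant_basis))
  invisible(x)
}

#' Soluble nitrogen remaining during biuret oxidation
#'
#' Empirical mass-balance model of the bleach titration of biuret: all nitrogen
#' in solution at zero equivalents, a linear decline to the terminal soluble
#' fraction (nitrate; ~10%) at the completion dose (~6 equivalents), constant
#' beyond.
#'
#' @param equivalents molar equivalents of hypochlorite added (>= 0, vector ok).
#' @param completion_equivalents dose at which the decline bottoms out.
#' @param terminal_soluble_fraction fraction of the initial nitrogen remaining
#'   in solution at/after completion.
#' @return numeric vector of fractions in `[terminal_soluble_fraction, 1]`.
#' @export
#' @examples
#' nitrogen_remaining(c(0, 3, 6, 10))
nitrogen_remaining <- function(equivalents, completion_equivalents = 6,
                               terminal_soluble_fraction = 0.10) {
  stopifnot(is.numeric(equivalents))
  if (any(equivalents < 0)) stop("equivalents must be >= 0", call. = FALSE)
  stopifnot(completion_equivalents > 0,
            terminal_soluble_fraction >= 0, terminal_soluble_fraction <= 1)
  frac <- 1 - (1 - terminal_soluble_fraction) *
    pmin(equivalents / completion_equivalents, 1)
  frac
}
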