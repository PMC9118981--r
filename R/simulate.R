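# Seeded generators for every input the pipeline consumes. Each one is a pure
# function of its arguments and seed (the caller's RNG stream is untouched),
# and returns the planted truth alongside the artifact so tests never have to
# reverse-engineer it.

#' Synthetic reference CAH sequence
#'
#' A deterministic synthetic stand-in for the reference sequence that carries
#' the anchor numbering (arginines at positions 194 and 324) and one instance
#' of the diagnostic motif in the C-terminal quarter. It is generated in code
#' — it is not a database sequence — and exists so the alignment-based anchor
#' check and the protein generator work fully offline.
#'
#' @param length sequence length (default 380).
#' @param motif_start 1-based start of the planted motif instance; default
#'   puts it in the final quarter.
#' @return a single amino-acid string.
#' @export
synthetic_reference_cah <- function(length = 380, motif_start = 360) {
  pat <- cah_motif()
  L <- base::length(pat$positions)
  stopifnot(length >= 250, motif_start >= 1, motif_start + L - 1 <= length)
  with_seed(987123, {
    chars <- sample(AA20, length, replace = TRUE)
    inst <- vapply(pat$positions, function(s) sample(s, 1L), character(1))
    chars[motif_start:(motif_start + L - 1L)] <- inst
    chars[194] <- "R"
    chars[324] <- "R"
    paste(chars, collapse = "")
  })
}

#' Generate protein sequences with planted CAH truth
#'
#' Positives are point-mutated copies of the synthetic reference with the
#' motif window and the neighborhoods of both anchor arginines protected, so
#' they carry a C-terminal motif instance and both anchors by construction.
#' Barbiturase-like sequences are built the same way but with one anchor
#' arginine substituted (R -> K). Negatives are i.i.d. uniform residues (a
#' deliberately non-natural composition that makes the motif false-positive
#' rate analytically checkable: ~(1/20)^11 per window for the 14-position
#' motif with 3 wildcards).
#'
#' @param n_pos,n_neg,n_barb counts per class (>= 0).
#' @param length_range length range for negative sequences.
#' @param seed integer seed.
#' @param mutation_rate per-residue substitution probability for
#'   positive/barbiturase-like sequences (outside protected windows).
#' @param reference reference sequence to derive positives from.
#' @return list with `sequences` (named character vector) and `truth`
#'   (data.frame `seq_id`, `class`).
#' @export
gen_proteins <- function(n_pos, n_neg, n_barb = 0,
                         length_range = c(300, 400), seed = 1,
                         mutation_rate = 0.08,
                         reference = synthetic_reference_cah()) {
  stopifnot(n_pos >= 0, n_neg >= 0, n_barb >= 0,
            length(length_range) == 2L, length_range[1] <= length_range[2],
            mutation_rate >= 0, mutation_rate < 1)
  if (length_range[1] < length(cah_motif()$positions))
    stop("length range shorter than the motif", call. = FALSE)
  ref_chars <- strsplit(reference, "")[[1]]
  ref_len <- length(ref_chars)
  pat_len <- length(cah_motif()$positions)
  motif_start <- regexpr(motif_regex(cah_motif()), reference, perl = TRUE)[1]
  stopifnot(motif_start > 0)
  protected <- c(motif_start:(motif_start + pat_len - 1L),
                 pmax(194 - 8, 1):pmin(194 + 8, ref_len),
                 pmax(324 - 8, 1):pmin(324 + 8, ref_len))
  mutate_ref <- function(kill_anchor = NA) {
    chars <- ref_chars
    mut <- runif(ref_len) < mutation_rate
    mut[protected] <- FALSE
    idx <- which(mut)
    if (length(idx))
      chars[idx] <- vapply(chars[idx], function(a)
        sample(setdiff(AA20, a), 1L), character(1))
    if (!is.na(kill_anchor)) chars[kill_anchor] <- "K"
    paste(chars, collapse = "")
  }
  with_seed(seed, {
    seqs <- character(0)
    cls <- character(0)
    for (i in seq_len(n_pos)) {
      seqs <- c(seqs, mutate_ref())
      cls <- c(cls, "positive")
    }
    for (i in seq_len(n_barb)) {
      seqs <- c(seqs, mutate_ref(kill_anchor = sample(c(194, 324), 1L)))
      cls <- c(cls, "barbiturase_like")
    }
    for (i in seq_len(n_neg)) {
      L <- sample(length_range[1]:length_range[2], 1L)
      seqs <- c(seqs, paste(sample(AA20, L, replace = TRUE), collapse = ""))
      cls <- c(cls, "negative")
    }
    ids <- sprintf("%s_%03d", cls,
                   as.integer(stats::ave(seq_along(cls), cls,
                                         FUN = seq_along)))
    names(seqs) <- ids
    list(sequences = seqs,
         truth = data.frame(seq_id = ids, class = cls,
                            stringsAsFactors = FALSE))
  })
}

motif_regex <- function(pattern) {
  paste0(vapply(seq_along(pattern$positions), function(i) {
    if (pattern$wildcard[i]) "."
    else if (length(pattern$positions[[i]]) == 1L) pattern$positions[[i]]
    else paste0("[", paste(pattern$positions[[i]], collapse = ""), "]")
  }, character(1)), collapse = "")
}

#' Generate a GC/MS N2 ion table by explicit atom pairing
#'
#' Monte-Carlo sampler that assigns each substrate molecule a label state
#' (fraction `label_mix_fraction` fully 15N, honoring both isotopic purities
#' per atom), routes a fraction `f_intra` of molecules through the
#' intramolecular channel (N2 keeps within-molecule partners; for biuret the
#' third nitrogen joins the pool) and the rest through the intermolecular
#' channel (all nitrogens join the fully scrambled pool, then pair at
#' random). Air N2 with natural 15N abundance is added so that it makes up
#' `air_fraction` of the final molecule count. The sampler is deliberately
#' independent of the closed-form [expected_distribution()] so the two act as
#' mutual oracles.
#'
#' Trace N2O areas (m/z 44/45/46) are also emitted, sampled from binomial
#' assembly out of the scrambled pool at 1% of the N2 count.
#'
#' @param compound `"urea"` or `"biuret"`.
#' @param f_intra fraction of molecules reacting intramolecularly.
#' @param n_molecules number of substrate molecules (>= 1).
#' @param air_fraction fraction of the final N2 count that is atmospheric.
#' @param config an [isotope_config()].
#' @param seed integer seed.
#' @return list with `areas` (named counts at m/z 28, 29, 30, 44, 45, 46) and
#'   `truth` (f_intra, air_fraction, and the air-free ratio `x_air_free`).
#' @export
gen_ion_table <- function(compound = c("urea", "biuret"), f_intra,
                          n_molecules, air_fraction = 0,
                          config = isotope_config(), seed = 1) {
  compound <- match.arg(compound)
  stopifnot(f_intra >= 0, f_intra <= 1, n_molecules >= 1,
            air_fraction >= 0, air_fraction < 1)
  n_atoms <- switch(compound, urea = 2L, biuret = 3L)
  with_seed(seed, {
    n <- as.integer(n_molecules)
    labeled <- runif(n) < config$label_mix_fraction
    p15 <- ifelse(labeled, config$heavy_purity, 1 - config$light_purity)
    # per-molecule atom matrix of 15N indicators
    atoms <- matrix(runif(n * n_atoms) < rep(p15, n_atoms), nrow = n)
    intra <- runif(n) < f_intra
    masses <- integer(0)
    pool <- logical(0)
    if (any(intra)) {
      if (compound == "urea") {
        masses <- 28L + atoms[intra, 1L] + atoms[intra, 2L]
      } else {
        ai <- atoms[intra, , drop = FALSE]
        leftout <- sample.int(3L, nrow(ai), replace = TRUE)
        left_atom <- ai[cbind(seq_len(nrow(ai)), leftout)]
        masses <- 28L + rowSums(ai) - left_atom
        pool <- c(pool, left_atom)
      }
    }
    if (any(!intra)) pool <- c(pool, as.vector(atoms[!intra, , drop = FALSE]))
    if (length(pool) >= 2L) {
      pool <- pool[sample.int(length(pool))]
      if (length(pool) %% 2L) pool <- pool[-length(pool)]
      half <- length(pool) / 2L
      masses <- c(masses, 28L + pool[2 * seq_len(half) - 1L] +
                            pool[2 * seq_len(half)])
    }
    counts <- c(`28` = sum(masses == 28L), `29` = sum(masses == 29L),
                `30` = sum(masses == 30L))
    x_air_free <- if (counts[["30"]] > 0) counts[["29"]] / counts[["30"]]
                  else NA_real_
    n_rxn <- sum(counts)
    n_air <- round(air_fraction / (1 - air_fraction) * n_rxn)
    if (n_air > 0) {
      p15_air <- 1 - 0.9963
      air <- stats::rmultinom(1L, n_air, binom_pair(p15_air))[, 1L]
      counts <- counts + stats::setNames(air, c("28", "29", "30"))
    }
    n_n2o <- max(round(0.01 * n_rxn), 10L)
    n2o <- stats::rmultinom(1L, n_n2o,
                            binom_pair(mean(p15)))[, 1L]
    areas <- c(counts, stats::setNames(n2o, c("44", "45", "46")))
    list(areas = as.numeric(areas) |> stats::setNames(names(areas)),
         truth = list(compound = compound, f_intra = f_intra,
                      air_fraction = air_fraction,
                      x_air_free = unname(x_air_free)))
  })
}

#' Generate a noisy linear plate table
#'
#' Responses follow `intercept + slope * concentration + N(0, noise_sd)` for
#' both the standard series and the samples with planted true concentrations.
#'
#' @param slope,intercept true line.
#' @param standards known standard concentrations.
#' @param sample_conc true sample concentrations (the planted truth).
#' @param noise_sd Gaussian response noise.
#' @param seed integer seed.
#' @return list with `plate` (data.frame `well`, `role`, `concentration`,
#'   `response`) and `truth` (`sample_conc`).
#' @export
gen_plate <- function(slope, intercept, standards, sample_conc,
                      noise_sd = 0, seed = 1) {
  stopifnot(slope != 0, length(standards) >= 2L, noise_sd >= 0)
  with_seed(seed, {
    n_s <- length(standards); n_x <- length(sample_conc)
    conc <- c(standards, sample_conc)
    resp <- intercept + slope * conc + rnorm(n_s + n_x, 0, noise_sd)
    plate <- data.frame(
      well = sprintf("W%02d", seq_len(n_s + n_x)),
      role = rep(c("standard", "sample"), c(n_s, n_x)),
      concentration = c(standards, rep(NA_real_, n_x)),
      response = resp,
      stringsAsFactors = FALSE
    )
    list(plate = plate, truth = list(sample_conc = sample_conc))
  })
}

#' Generate noisy Michaelis-Menten initial-rate data
#'
#' `v = mm_rate(params, E0, S) * (1 + N(0, cv))`.
#'
#' @param params a [kinetic_params()] object.
#' @param E0 enzyme molar concentration, uM.
#' @param S substrate grid, uM.
#' @param cv multiplicative noise coefficient of variation (>= 0).
#' @param seed integer seed.
#' @return data.frame with `S_uM`, `v_uM_s`.
#' @export
gen_rate_data <- function(params, E0, S, cv = 0, seed = 1) {
  stopifnot(cv >= 0)
  with_seed(seed, {
    v <- mm_rate(params, E0, S) * (1 + rnorm(length(S), 0, cv))
    data.frame(S_uM = S, v_uM_s = pmax(v, 0))
  })
}

#' Generate a synthetic chromatogram of Gaussian peaks
#'
#' Sum of Gaussian peaks (each parameterized by retention time, standard
#' deviation in minutes and total area) over a flat baseline with optional
#' Gaussian noise. Default retention times follow the headspace separation of
#' N2 (1.84 min), CO2 (2.62 min) and N2O (2.88 min).
#'
#' @param peaks data.frame with columns `rt`, `sd`, `area`; default three
#'   peaks at the headspace retention times.
#' @param t_range time axis range (min).
#' @param dt sampling interval (min).
#' @param baseline constant baseline level.
#' @param noise_sd Gaussian noise sd.
#' @param seed integer seed.
#' @return list with `time`, `intensity`, and `truth` (the peak table).
#' @export
gen_chromatogram <- function(peaks = data.frame(rt = c(1.84, 2.62, 2.88),
                                                sd = c(0.02, 0.02, 0.02),
                                                area = c(1000, 400, 20)),
                             t_range = c(1, 4), dt = 0.002,
                             baseline = 0, noise_sd = 0, seed = 1) {
  stopifnot(is.data.frame(peaks) || is.null(peaks), noise_sd >= 0)
  with_seed(seed, {
    time <- seq(t_range[1], t_range[2], by = dt)
    intensity <- rep(baseline, length(time))
    if (!is.null(peaks) && nrow(peaks)) {
      stopifnot(all(c("rt", "sd", "area") %in% names(peaks)),
                all(peaks$rt >= t_range[1] & peaks$rt <= t_range[2]))
      for (k in seq_len(nrow(peaks)))
        intensity <- intensity + peaks$area[k] *
          stats::dnorm(time, peaks$rt[k], peaks$sd[k])
    }
    if (noise_sd > 0) intensity <- intensity + rnorm(length(time), 0, noise_sd)
    list(time = time, intensity = intensity, truth = peaks)
  })
}
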