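---
title: "Models and methods behind cyaclear"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cyaclear}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cyaclear)
```

cyaclear implements the computational pipeline of an enzymatic
cyanuric-acid (CYA) remediation workflow: mining cyanuric acid hydrolase
(CAH) candidates from protein sequence, the pool-chlorine chemistry around
enzyme deployment, plate-assay calibration, Michaelis–Menten kinetics, and —
at its analytical core — the stable-isotope GC/MS deconvolution that
distinguishes intra- from intermolecular N–N bond formation when hypochlorite
oxidizes biuret or urea. This vignette records the models, their assumptions,
the defaults, and the numerical choices, in the spirit of a methods section.

## The isotopomer mechanism model

An equimolar mix of fully ¹⁴N- and fully ¹⁵N-labeled substrate is oxidized by
excess hypochlorite and the headspace N₂ isotopomers are read at m/z 28
(¹⁴N¹⁴N), 29 (¹⁴N¹⁵N) and 30 (¹⁵N¹⁵N). Two limiting mechanisms make sharply
different predictions:

* **Intermolecular**: amide bonds are cleaved first (chloramine chemistry)
  and N₂ is assembled from a fully scrambled nitrogen pool. Binomial pairing
  from a 50/50 pool gives 28:29:30 = 1:2:1, i.e. a 29/30 ratio of 2.
* **Intramolecular**: both nitrogens of a product N₂ come from one substrate
  molecule. For urea (two nitrogens) this yields only 28 and 30 (1:0:1). A
  biuret molecule has three nitrogens: one N₂ forms within the molecule and
  the leftover nitrogen joins the scrambled pool, so per two molecules the
  expectation is two within-molecule N₂ (one 28, one 30) plus one pool N₂
  (1:2:1), totalling 5:2:5.

For a mixture in which a fraction $f$ of molecules react intramolecularly
(N₂ yield per molecule is the same on both routes), the 29/30 ratio is

$$x_\text{urea} = \frac{2(1-f)}{1+f}, \qquad
  x_\text{biuret} = \frac{6-4f}{3+2f},$$

both equal to 2 at $f = 0$. `expected_ratio()` evaluates these through the
distribution model; `fraction_intramolecular()` applies the algebraic
inverses

$$\%\,\text{intra}_\text{urea} = 100\,\frac{2-x}{2+x}, \qquad
  \%\,\text{intra}_\text{biuret} = 150\,\frac{2-x}{2+x}.$$

A transposed variant of these conversion formulas, $-100(x+2)/(x-2)$,
circulates in print; it is the reciprocal up to scale and maps every measured
ratio outside $[0, 100]$. We use the forms derived from the mixture model —
they reproduce the published conversions — and record the choice in the
estimator's metadata. The round trip
`fraction_intramolecular(expected_ratio(f)) == 100 f` is enforced to 1e−9 on
a 101-point grid in the test suite; it is the consistency check binding the
distribution model to the conversion formulas.

Measured ratios slightly above 2 are plausible noise around a purely
intermolecular mechanism, so out-of-range percentages are clamped into
$[0, 100]$ with an explicit flag rather than rejected.

### Background correction

Air ingress adds N₂ that is 99.63% ¹⁴N per atom: a large m/z 28 signal plus a
natural-abundance m/z 29 component of $2(1-q)/q$ per unit of air-derived 28
($q = 0.9963$). Which m/z 28 quantity to treat as "air" is genuinely open;
both supported modes are reported in the output metadata:

* `symmetric_excess` (default): air-derived 28 is `max(area28 − area30, 0)`,
  because under a 1:1 label mix the reaction contributes 28 and 30 in equal
  amounts. This is unbiased when label purities are ideal and degrades
  gracefully otherwise.
* `total_28`: all of m/z 28 is attributed to air — the literal reading of
  "based on m/z 28". It overcorrects in proportion to the reaction's own 28,
  which is visible only at low air levels.

Corrected areas are floored at zero, and with $q = 1$ the correction is the
identity. The m/z 30 channel needs no correction (air contributes
$(1-q)^2 \approx 10^{-5}$ of itself there).

### Isotopic purity

The conversion formulas assume ideal labeling (50/50 mix, pure materials), as
is conventional. The configured purities (light 0.9963, heavy 0.99) are
applied where they matter measurably: in the background correction and in the
atom-pairing Monte-Carlo generator. Propagating them through the closed forms
would change estimates by well under the measurement noise and would silently
redefine the published conversion; we deliberately do not.

### The atom-pairing generator as oracle

`gen_ion_table()` samples ion tables by explicit atom bookkeeping — each
molecule drawn labeled or not, each atom ¹⁵N with the purity-appropriate
probability, intramolecular routes keeping within-molecule partners, the rest
pooled, shuffled and paired — deliberately sharing no code with the
closed-form `expected_distribution()`. The suite verifies their agreement
within 3σ multinomial bands at 10⁶ molecules for $f \in \{0, 0.25, 0.5, 1\}$
on both compounds, and that `estimate_mechanism()` recovers planted fractions
to ±2 percentage points with up to 30% air contamination. Trace N₂O is
emitted at 1% of the N₂ count and assembled binomially from the pool; the
m/z 45/46 ratio of 2 it predicts is reported separately and never folded into
the N₂ estimate. The generator does not attempt realistic peak shapes,
detector response or CO₂ interference — passing tests demonstrate estimator
correctness under multinomial counting statistics, not robustness to
chromatographic artifacts.

## Sequence mining

The diagnostic motif `S-G-G-X-E-X-Q-G-P-X-G-G-G-P` (14 positions, wildcards
at 4, 6 and 10) marks the conserved C-terminal metal-binding region of CAHs.
`scan_motif()` matches it by vectorised per-position set intersection
(overlaps allowed, 1-based coordinates); the test oracle is an independent
perl-regex scan. "Near the C-terminus" is unquantified in the source
material; we require the hit to start in the final 25% of the sequence
(`c_term_threshold = 0.75`, configurable), which comfortably contains the
motif in all known family members.

What separates true CAHs from barbiturases — same fold, no CYA activity — is
a pair of active-site arginines at reference positions 194 and 324.
`check_anchors()` maps them onto a candidate by global alignment:
Needleman–Wunsch with affine gaps (BLOSUM62, gap open 11, extend 1, the
BLAST-protein defaults), implemented in C++ with deterministic tie-breaking
(diagonal, then up, then left) so results are bit-reproducible. The alignment
parameters for this mapping are not dictated by anything we reimplement; they
are our choice and are therefore plain function arguments. Test routes check
the score against an independent aligner (Biostrings) and re-score the
returned gapped strings by hand.

No real reference sequence ships with the package: `synthetic_reference_cah()`
deterministically builds a synthetic stand-in with arginines at 194/324 and a
C-terminal motif instance, and `gen_proteins()` derives planted positives
(mutated copies protecting the motif and anchor neighborhoods),
barbiturase-like decoys (one anchor R→K) and uniform-random negatives.
Uniform residue composition is deliberate: it makes the motif false-positive
rate analytically $(1/20)^{11}$ per window, which the suite checks with a
relaxed pattern. Classification on these constructions is exact by design;
performance on natural sequence (compositional bias, indel-rich homologs) is
not claimed.

The position frequency matrix (`pfm_from_alignment()`) counts residues per
column excluding gaps; information content is $\log_2 20$ minus the column
Shannon entropy — the logo letter-height convention.

## Pool chemistry

* **Units.** ppm ≡ mg/L at unit water density; `ppm_to_mM()` divides by the
  molar mass. No density or activity corrections.
* **Speciation.** Two-species HOCl/OCl⁻ equilibrium with
  $pK_a(T) = 3000/T - 10.0686 + 0.0253\,T$ (T in kelvin), the standard
  empirical form; the function is swappable. Molecular Cl₂ matters only below
  pH ≈ 4 and is out of scope.
* **Electron balance.** Hypochlorite accepts 2 e⁻; amide nitrogen starts at
  −3. Equivalents = $n_N \lvert \Delta OS\rvert / 2$: biuret→N₂ 4.5,
  urea→N₂ 3, biuret→nitrate 12.
* **Reductant dosing** is exact molar-mass arithmetic on an explicit oxidant
  basis species, because "ppm hypochlorite" is ambiguous (as ClO⁻ vs NaOCl —
  the two differ by 45%). The effective pool-water ratios (~1:1 thiosulfate,
  ~2:1 sulfite per ClO⁻) ship as documented presets in
  `reductant_presets()`; at 5.72 ppm ClO⁻ they give 17.6 and 28.0 ppm, about
  1% above the empirically observed endpoints (17.4 / 27.7 ppm) — no single
  clean stoichiometry reproduces those exactly, so the equivalents stay an
  explicit parameter rather than hard-coded truth.
* **Soluble nitrogen** during the bleach titration of biuret is modeled
  piecewise-linearly from 100% at 0 equivalents to a terminal 10% (nitrate)
  at 6 equivalents, constant beyond — a mass-balance summary of the observed
  titration, not a kinetic model.

## Assay calibration

Standard curves are ordinary least squares (one per plate; `lm` behind the
surface). The 0-concentration standard is included in the fit — the intercept
absorbs the blank. R² below 0.98 sets a warning flag only; drift is expected
and is exactly why curves are refitted per plate. Inversion preserves
negative estimates (sub-blank chlorine readings indicate a solution more
reduced than deionized water and are information, not error); `clip = TRUE`
exists but is off by default. Combined chlorine is total − free, exactly.
Normalization to a reference condition is scale-invariant by construction.

## Kinetics

`fit_mm()` fits $v = k_{cat} E_0 S/(K_m + S)$ by bounded nonlinear least
squares (`nls`, port algorithm, positivity bounds) started from the
Hanes–Woolf linearization; standard errors come from the Jacobian at the
optimum, and boundary-pinned or non-convergent fits raise errors rather than
returning silently. Only initial-rate data are fitted — progress curves are
simulation-only, matching how the published constants were determined.

`simulate_progress()` integrates the depletion ODE with `deSolve::lsoda`
(rtol 1e−10, atol 1e−8 on S in μM); the suite cross-checks every grid point
against the analytic implicit solution
$K_m \ln(S_0/S) + (S_0 - S) = k_{cat} E_0 t$ to 1e−6 relative.
Hypochlorite inactivation is modeled as an instantaneous step to zero
activity at the first event time — full inactivation is observed at even
0.14 ppm over hours, and no rate constant for the inactivation itself is
measurable from available data. At $S \gg K_m$ the simulated depletion is
zero-order (constant rate), the regime in which 200–6,000 ppm CYA is
observed to fall linearly.

Converting an enzyme dose in mg/L to molarity requires a subunit molar mass
that is not published for these enzymes; `kinetic_params()` carries it as a
required configuration value (default 40,000 g/mol, flagged as an
assumption). Absolute depletion slopes from mass doses are therefore
simulation capabilities, not reproduced observations — the suite checks
linearity, not slope.

`plan_remediation()` composes the stages: reductant dose, time-to-target from
the implicit MM law (equivalent to inverting the simulator, which is verified
against the same law), and shock equivalents = 4.5 × biuret produced (1:1
molar with CYA removed). Stage ordering is fixed: reducing first protects the
enzyme; shocking last oxidizes biuret and inactivates the enzyme in one step.

## Problem sizes and reproducibility

All generators take a seed, restore the caller's RNG state, and are
bit-reproducible (tested). The suite's chosen scales — 10⁶ molecules for the
Monte-Carlo/closed-form comparison, 50 seeds × 8 substrate levels for the
kinetics recovery study (median parameter error < 5% at 1% noise), 1,000
random sequences for the scanner/oracle equivalence — were picked so that the
statistical bands (3σ multinomial, ±2 percentage points, binomial error)
are meaningful while the whole suite runs in a few minutes on one core.

## Known limitations

* No chloramine reaction-network kinetics: the intermolecular route is
  represented only by its isotopomer signature, not by a mechanism model.
* No aqueous equilibrium beyond the two-species HOCl/OCl⁻ system (no
  carbonate buffering, chloramines, or Cl₂).
* No vendor raw-file parsing, mass calibration, or deconvolution of
  overlapping CO₂/N₂O peaks; chromatogram handling assumes baseline-resolved
  windows.
* The mining module is a pattern/anchor classifier, not a homology search: no
  HMMs, no database queries, and the planted-truth evaluation does not
  predict sensitivity on natural proteomes.
* Calibration is strictly linear (the assays are used in their linear range);
  no 4PL.
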