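---
title: "Carbon-positional 13C enrichment analysis: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Carbon-positional 13C enrichment analysis: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poslabel)
```

This vignette documents the models implemented by `poslabel`, the
assumptions behind them, the tunable parameters, and the design decisions
taken where the design was genuinely open. It states no empirical result
beyond what the package's tests and acceptance script compute themselves.

## 1. The measurement model

A trimethylsilylated metabolite ion observed by GC-(TOF)MS is a mixture
of isotopologues spread over integer mass-shift channels M+0, M+1, ….
Two carbon pools contribute: the *labelable* carbons inherited from the
metabolite (exposed to the ¹³C tracer) and everything else — carbons
introduced by TMS/MEOX derivatization plus H, N, O, P, Si — which stays
at natural isotope abundance (NIA). Silicon matters: each Si atom carries
4.7% M+1 and 3.1% M+2, so TMS-rich fragments have heavy natural tails
that would masquerade as labeling if uncorrected.

`theoretical_isotopologue_pattern()` is the forward model: each labelable
carbon is ¹³C with probability `p13_labelable * purity`, where
`p13_labelable` is the ¹³C content of the carbon source feeding those
positions and `purity` the tracer's isotopic purity; the remainder of the
formula contributes its NIA pattern by convolution. Three consequences
anchor the semantics: a source at natural ¹³C with a pure tracer is
indistinguishable from the natural pattern; a fragment without labelable
carbons is independent of the labeling probability; a fully labeled
3-carbon pool at 99% purity is Binomial(3, 0.99).

The carbon NIA defaults to 1.109% (ambient carbon) and is overridable
everywhere (`isotope_table(c13 = ...)`, `correction_config(p13_natural)`).
Isotope masses and abundances are the IUPAC/CODATA standard values
embedded in the package; ion m/z subtracts one electron mass
(0.000549 amu) per positive charge, which is what makes the G6P fragment
cation reproduce 706.2694 at four decimals.

## 2. NIA / tracer-purity correction

`build_correction_matrix()` implements the standard tracer-correction
formalism: column *j* is the theoretical observed pattern of a species
carrying exactly *j* tracer-derived labels — labeled positions are ¹³C
with probability equal to the tracer purity, unlabeled labelable
positions sit at natural ¹³C, and the residual formula contributes NIA
(all elements in `"full"` mode; only derivatization carbons in
`"carbon_only"` mode, provided because nominal-mass workflows sometimes
correct carbon only). The matrix is rectangular: measured vectors longer
than `n_labelable + 1` keep their Si-driven M+1/M+2 rows and the system
is solved in the least-squares sense.

`correct_isotopologues()` solves `M x = measured` for `x >= 0`.
Non-negative least squares is the default; the alternative (plain solve,
clip negatives) is faster but biases enrichment near the 0 and 1
boundaries, exactly where natural-abundance QC samples and saturated
pulses live. The solve is performed on the sum-normalized vector because
NNLS termination tolerances are absolute. Correctness is pinned by two
test oracles: exhaustive isotope-assignment enumeration for small
formulas and an independent polynomial-expansion route for every shipped
fragment (tolerance 1e-10), plus the exact forward-model round trip.

Fractional enrichment is `E13C = sum(i·x_i) / (n · sum(x))`, the
per-carbon average label fraction. The corrected isotopologue *sum* is
label-invariant, which is what licenses one concentration calibration
across a labeling time course (tested to 0.5%).

Validity limits: NIA correction is only trusted inside a
calibration-derived abundance window (`validity_range_check()`); below it
the additive noise floor inflates apparent enrichment (the tests
reproduce this inflation), above it detector saturation clips the most
abundant isotopologue first.

## 3. Positional algebra

The enrichment of a substructure equals the average enrichment over its
positions, so with the paired fragments (1,2,3-C₃ and 2,3-C₂ of 3PGA):

`e1 = 3·e123 − 2·e23`.

Because this is a difference of noisy quantities, `e1` can leave [0, 1].
Such values are *flagged, never clamped* — clamping would bias early time
points (where `e1` is near 0) upward and silently hide instrument bias.
Flagged samples are excluded from rate fits. The relative enrichment
`rel = e23/e1 × 100%` is reported as `NA` (an explicit undefined marker)
when `e1 < 0.01`, since the ratio is meaningless in pre-pulse samples;
values above 100% are flagged as a data-quality symptom (they cannot
occur under photosynthetic pulse labeling, where 1-C labels first, and
were the basis for preferring the high-resolution instrument).

Molar positional ¹³C uses carbon-count weighting:
`C13C_123 = 3·e123·C`, `C13C_23 = 2·e23·C`, `C13C_1 = 1·e1·C`. The
weighting is a design decision: it is the unique choice that makes
`C13C_123 = C13C_1 + C13C_23` hold exactly (an additivity the positional
comparison logic relies on), and it gives `C13C` the natural reading
"nmol of ¹³C atoms". A `per_position = TRUE` switch reports unweighted
per-position averages for users who prefer that convention.

`adjust_to_reference()` rescales a measured enrichment by a co-measured
reference (e.g. intracellular G6P set to 100% under fully labeled
glucose, 33.3% under 2-of-6-labeled glucoses), absorbing intracellular
label dilution and tracer-purity differences between feeding experiments.

## 4. Quantification

Concentration runs through: corrected isotopologue sum of the
quantification fragment → internal-standard ratio (¹³C₆-sorbitol; the
calibration series must carry the same internal standard, so the
normalization cancels) → ng on-column via an OLS calibration line → whole
sample via the extraction-to-injection volume ratio (`volume_factor`,
default 100 = 1 µL injected of a 100 µL extract) → nmol via the molar
mass (default 186.06 g/mol, the 3PGA free acid; a `purity_factor` covers
reference substances certified below 100%) → per OD₇₅₀·mL.

The linear range is auto-detected as the longest contiguous amount window
whose log-log slope stays within 1 ± 0.1 *and* whose every adjacent step
is near-proportional (within ±0.3); the second clause stops a saturation
plateau at the window edge from hiding behind an acceptable overall
slope. A user-supplied range always wins. Samples mapping outside the
range are marked enrichment-only rather than dropped.

## 5. Kinetic rate fitting

Labeling courses are fitted with the standard logistic
`I(t) = i_max / (1 + exp(−a(t − t_mid)))`, parameterized so the maximum
slope — the assimilation rate — has the closed form `A13C = i_max·a/4`
(verified against the numerical derivative to 1e-6). The saturating
exponential `i_max(1 − e^{−kt})` with initial slope `k·i_max` is provided
as the alternative estimator; on lagged sigmoid data its initial slope
disagrees with the logistic rate by design, which is the diagnostic for a
lag phase that the exponential cannot represent.

Numerical choices, each of which materially affected estimator quality
in simulation:

* **Relative (1/f²-weighted) least squares.** Abundance-derived values
  carry multiplicative noise; raw-scale SSE lets plateau noise dominate
  the sparsely sampled rise and inflates the steepness estimate. Weights
  are floored at 5% of the data maximum so the zero-valued pulse-start
  point cannot acquire infinite weight.
* **Seeded multi-start.** 1000 random starts (configurable) inside
  data-driven bounds, simplex refinement of the best five, then a
  weighted `nls` polish accepted only if it improves the objective.
  Noise-free curves are recovered to 1e-6.
* **Steepness cap.** The fitted maximum slope may not exceed three times
  the steepest secant in the data (`a ≤ 12·s_max/vmax`): with one or two
  points on the rise, unbounded steepness admits near-step fits with
  arbitrarily large rates.
* **Soft t₀ penalty.** Labeling starts at zero but the logistic never
  reaches zero; the objective penalizes model values at t = 0 above 5% of
  the plateau instead of forcing I(0) = 0.
* **Classification.** `sigmoidal` requires (i) at least two data points
  at ≥ 0.75·i_max — the plateau must be sampled, not merely touched by
  the final point, (ii) the fitted t = 0 value within twice the
  tolerance, and (iii) the model slope at the last time point at most
  half the midpoint slope (the curve has flattened inside the window).
  A monotone ramp therefore classifies `ambiguous`; an all-zero series is
  `no_signal`. Thresholds are exposed as arguments.

Replicate handling follows the replicate-culture design: fit each
replicate's time course separately, then aggregate (mean ± SE). In the
pipeline, a positional series never rising above 10% of the
complete-molecule signal in the same replicate is reported as `n.d.`
(not detected) rather than fitted — the CBB-deficient preset exercises
this path. Samples beyond 60 min are excluded from rate fits (the fitting
window) but kept in enrichment outputs. Group comparisons use the
heteroscedastic two-tailed Welch t-test with the conventional star levels.

## 6. Carbon-fate maps

`emp_map()` encodes glycolysis: one glucose → two 3PGA, with
(1-C ← g3, 2-C ← g2, 3-C ← g1) and (1-C ← g4, 2-C ← g5, 3-C ← g6); the
DHAP-derived half is carbon-mirrored. `opp_map()` encodes the oxidative
pentose-phosphate route: 1-C of G6P is lost as CO₂ and three G6P yield
five 3PGA, three of them (g4, g5, g6). The main-text-level description
fixes only the 1-C sources (g2 and g3) of the two rearranged products;
their 2-C/3-C sources are completed here from the canonical
transketolase/transaldolase atom transitions — tracking C15 of
3 pentose phosphates through S7P/E4P into two F6P and one triose gives
(1-C g2, 2-C g3, 3-C g2′) and (1-C g3, 2-C g3′, 3-C g2″), primes marking
atoms from different glucose molecules (irrelevant for enrichment
predictions, which only see positional marginals). This derivation is
consistent with all three positional-tracer outcomes the maps are tested
against; users can supply alternative maps via `carbon_fate_map()`.

Mixtures weight products by molar 3PGA yield (2 per glucose EMP, 5/3 per
glucose OPP, scaled by flux fractions) because enrichment is a property
of the 3PGA *pool*; raw flux weighting is available and differs by well
under 0.01 at an 11% OPP share. Predictions are steady-state only — no
dynamic G6P-pool dilution is modeled; feeding experiments normalize via
`adjust_to_reference()` instead. `rubisco_map()` encodes carboxylation:
CO₂ enters 1-C of one product; 1,2-C₂ of RuBP map inversely onto its
2,3-C₂; the second product carries 3,4,5-C₃ of RuBP in order.

## 7. The synthetic-data generator

`sim_config()` + `emit_isotopologue_table()` replace instrument files.
The kinetic truth is an anchored logistic (exactly zero at pulse start)
for 1-C, a lagged anchored logistic scaled by an *anaplerotic plateau*
< 1 for 2,3-C₂ (mobilized unlabeled storage carbohydrate keeps 2,3-C₂
saturation below 100%), and `e123 = (e1 + 2·e23)/3` by construction, so
the positional algebra is exact on the truth sidecar. Preset parameters
are phenomenological: midpoints 5.4/8.4 min and steepness 0.5 min⁻¹
(chosen so the wild-type plateau and rate are of the observed order),
concentrations 1.32/1.42/0.99 nmol·OD₇₅₀⁻¹·mL⁻¹ for the three genotype
presets, anaplerotic plateaus 0.90 (steady-state) and 0.97
(low-CO₂-preacclimated, less storage carbohydrate), and a CBB-deficient
preset with 2,3-C₂ labeling identically zero and a lower, later 1-C
course. The anaplerotic plateaus are illustrative, constrained only
qualitatively.

Fragment tables are emitted through the *same forward model the
correction inverts*: positional marginals → tracer-count distribution
assuming independence across positions (the joint positional isotopomer
distribution is unidentifiable from the two measured fragments;
independence is the maximum-entropy completion and exactly consistent
with the averaging identities — a documented limitation, not a claim
about real isotopomer correlations) → convolution with NIA and purity →
scaling through metabolite amount, biomass and per-fragment response →
noise. The noise model is sample-level multiplicative log-normal
(default sd 0.10, biology plus whole-peak technical variation),
per-channel multiplicative noise (default sd 0.02; isotopologue ratios
within one peak are far more precise than peak totals), an additive
exponential floor (default 0, set > 0 to reproduce low-abundance
enrichment inflation), and a saturation ceiling. Every generator requires
a seed and is byte-deterministic given it.

What passing tests on these data do show: the correction, algebra,
quantification and fitting stages invert the stated forward model at
realistic noise, and the qualitative genotype/condition contrasts
propagate end to end. What they do not show: robustness to coeluting
isobaric interference, retention-time drift, derivatization
incompleteness, deuterium exchange, or non-lognormal detector noise —
none of which the generator emulates. `apply_instrument_bias()` adds the
one instrument artifact the analysis logic must recognize: a constant
spectral floor (nominal-mass EI mode) that mechanically inflates low and
deflates high enrichment; the high-resolution mode is near-unbiased.

## 8. Problem sizes and limitations

The shipped tests run the pipeline at study scale (6 time points, 3
replicates, 4 fragments) and the parameter-recovery study at 200
simulated experiments × 3 replicates with 400 fitting starts each;
the full suite completes in well under a minute on one CPU. Known
limitations: only two measured substructures, hence positional
resolution stops at {1-C, 2,3-C₂} — no general isotopomer deconvolution;
steady-state fate-map predictions; no chromatogram processing (peak
picking, alignment and spectral matching are upstream of this package);
the 357-fragment formulas of the EI and APCI routes coincide after loss
arithmetic, so a single library entry serves both modes.
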