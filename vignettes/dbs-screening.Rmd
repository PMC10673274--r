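---
title: "Screening dried-blood-spot metabolomes against within-run controls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening dried-blood-spot metabolomes against within-run controls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metaboscreen)
```

## The problem and the model

Direct-infusion mass spectrometry (DIMS) of dried blood spots trades
chromatographic separation for speed: a 3-mm blood-spot punch is extracted,
infused, and scanned in positive and negative ion mode over m/z 70–600,
in triplicate. Every metabolite annotation therefore rests on accurate mass
alone, and the statistical unit of the screen is not an absolute
concentration but a *within-run* comparison: how far a patient's summed
annotation intensity sits from the distribution of the same quantity in 30
control samples measured in the same batch.

`metaboscreen` implements this screen as a deterministic composition of
small, separately tested stages:

1. **Adduct-aware matching** (`match_peaks()`): a peak matches a metabolite
   under an adduct iff `|mz_obs - mz_theo| / mz_theo * 1e6 <= ppm_tol`. The
   theoretical m/z is the neutral monoisotopic mass plus a fixed shift per
   adduct; five singly charged species are modelled ([M+H]+, [M+Na]+,
   [M+K]+, [M−H]−, [M+Cl]−). The relative window is symmetric and the
   inequality inclusive; the theoretical mass sits in the denominator so
   that the tolerance is a property of the reference, not of the scan.
2. **Isomer grouping** (`group_isobars()`): metabolites whose theoretical
   m/z agree within the tolerance for every shared adduct cannot be
   distinguished by DIMS and are merged into one annotation group
   (display names joined with `" | "`). Merging is single-linkage — chains
   of near-coincident masses collapse into one group — because any finer
   partition would be arbitrary when the instrument cannot resolve the
   members anyway.
3. **Intensity summing** (`summed_intensities()`): per injection, the
   intensities of all matched adduct peaks of a group are summed (absent
   adducts contribute zero); per sample, the triplicate injections are
   averaged. A peak that matches several members of the *same* group is
   counted once for that group — the group is one annotation, and double
   counting exact isomers would inflate every isomer group by its
   multiplicity. A peak matching members of *different* groups contributes
   to both; with accurate-mass-only evidence the ambiguity is real and is
   preserved in the provenance table.
4. **Origin filtering** (`filter_exogenous()`): groups whose members are
   all exogenous or drug metabolites are excluded. Mixed groups are kept,
   because dropping them would silently delete endogenous candidates that
   happen to share a mass with a food or drug compound.
5. **Z-scoring** (`zscore_table()`):
   `Z = (I_patient - mean(I_controls)) / sd(I_controls)` per annotation,
   with the sample SD (n − 1). Zero-spread rows yield `NA` with a warning,
   never ±Inf, and are dropped by the elevation filter.
6. **Elevation filtering** (`filter_elevated()`): keep annotations with
   `Z > threshold` (strictly) in *every* designated affected individual;
   the default threshold is 2.0. The dual-proband requirement is the
   screen's main false-positive control: under a null model the two
   probands' exceedances are nearly independent, so the expected number of
   false rows scales with `P(Z > 2)^2` rather than `P(Z > 2)`.
7. **Pathway labelling** (`annotate_pathways()`): a retained group is
   `pathway-mapped` if any member carries a pathway map, else `unmapped`;
   it is flagged `"+"` for PPi formation iff any member record says so.

The pipeline is exposed stage by stage and as `run_screen()`.

## Parameters that matter

| parameter | default | unit | why |
|---|---|---|---|
| `ppm_tol` | 5 | ppm | accuracy of a 140k-resolution Orbitrap-class scan; the annotation window and the isomer-merging radius |
| `threshold` | 2.0 | Z (dimensionless) | two control SDs above the control mean, applied strictly (`>`), in *both* probands |
| adduct shifts | +1.007276, +22.989218, +38.963158, −1.007276, +34.968853 | Da | fixed constants for the five singly charged species; verified against an independent elemental-mass calculation in the tests |
| `reducer` | mean | — | triplicate aggregation; `median` available for robustness to a single bad injection |
| `sd_method` | sample (n − 1) | — | unbiased default; population SD available |
| `log10_transform` | off | — | the Z formula is defined on raw summed intensities; a log option is provided because DIMS noise is multiplicative |

Two conventions deserve a note. First, the [M+Cl]− shift is the Cl-35
atomic mass; at m/z 215 the electron mass it omits amounts to ~2.5 ppm,
well inside the matching window, and the constant is what the tests pin.
Second, no multiple-testing correction is applied: the screen is a
fixed-cutoff filter whose specificity comes from requiring concordant
elevation in two affected individuals, not from an FDR procedure.

## What the synthetic cohort emulates — and what it does not

`generate_cohort()` is a first-class module, not a test shim. It emulates
the acquisition design: 30 within-run controls plus proband/carrier
samples, 3 injections × 2 polarities each, peaks only inside m/z 70–600.
Its noise model is:

- **Intensities**: per metabolite a cohort baseline (lognormal around 1e5
  arbitrary units — real per-metabolite DBS intensities are not
  publishable knowledge, so the baselines are arbitrary and only their
  *relative* structure matters); per sample a base-10 lognormal factor with
  `sigma_log10 = 0.1`, i.e. ~26% multiplicative noise, a typical
  between-extract spread for DIMS of DBS.
- **m/z**: Gaussian jitter with SD 1.5 ppm around the theoretical adduct
  mass, one-third of the matching window.
- **Adducts**: the primary pair ([M+H]+, [M−H]−) is always present; each
  salt adduct is present per (metabolite, sample) with probability 0.5,
  which exercises the "sum what is present" rule. The planted per-sample
  intensity is split across the present, in-scan-range adducts with fixed
  weights (primary 1, salt 0.3, renormalised), so the per-injection adduct
  sum reproduces the planted value exactly — with zero jitter and noise the
  whole pipeline closes the loop to the truth table at machine precision,
  which is asserted in the tests.
- **Spikes**: a spiked metabolite is planted in every affected sample at
  the *control median* times the fold-change. This makes the planted
  proband value deterministic given the controls (both probands receive the
  same value, so their Z-scores coincide on spiked rows); recovery is then
  a property of the noise model, not of proband-specific luck.
- **Decoys**: 200 unannotated peaks per injection and polarity, uniform in
  m/z — the simplest null for false-annotation behaviour.

It does **not** model isotope envelopes, chemical noise structure of real
plasma/blood extracts, intensity drift or batch effects, in-source
fragmentation, or multiply charged species. Passing the synthetic
acceptance checks therefore demonstrates that the *computational* pipeline
is correct and calibrated under its stated noise model — not that the
screen's wet-lab sensitivity in real DBS extracts is reproduced.

## Numerical and degenerate-input choices

- The ppm inequality is inclusive (`<=`); matching uses an interval search
  over the sorted theoretical masses, and the exact inequality makes the
  final decision, so the fast path is bit-identical to the brute-force
  all-pairs oracle (asserted on 100 random instances, including peaks
  planted at ±4.9, ±5.0 and ±5.2 ppm).
- Peaks outside the scan range are dropped on read with a warning and a
  count, never silently.
- Incomplete sample runs (missing injections or a polarity) are flagged
  and analysed with the injections present, averaging over what exists.
- Zero control SD yields `NA` Z-scores plus a warning; rows with `NA` in
  any affected individual are dropped by the filter (an undefined
  elevation is not evidence of elevation).
- The activity formula subtracts both the measurement blank (the 0 mM PPi
  well) and the curve intercept; the plate generator is built to the same
  contract (assay wells = buffer background + intercept + slope × Pi), so
  noiseless generation round-trips exactly. Negative activities are
  reported as-is and flagged, never clamped — clamping would bias replicate
  means upward at low activities.
- Flux-phase summaries use the mean of the four measuring points per
  phase; a `last`-point option is provided, a common flux-assay
  convention. Capacity is invariant under adding a constant to every
  cycle, which is asserted as a property.

## Design decisions that were genuinely open

- **Neutral masses + adduct arithmetic** rather than precomputed ion
  masses in the reference: one mass per metabolite plus five shared
  constants is smaller, and lets the tests verify the arithmetic against
  an independent elemental-mass oracle.
- **Summing adducts within injection first**, then averaging injections
  (rather than the reverse): summation is the physically meaningful
  operation per scan; with the mean reducer the order is immaterial, and
  the choice only matters for the median option.
- **Raw-intensity Z-scores** by default: the screening formula names
  intensities directly. Control-vs-control Z-scores under the lognormal
  model are close to standard normal (KS distance < 0.1 in the seeded
  calibration test) but mildly right-skewed, so single-proband tail
  probabilities run slightly above the Gaussian 2.3%; the dual-proband
  product keeps the false-positive count low, and the null calibration
  test checks the observed count against `N * P(Z>2)^2` with the
  exceedance probability estimated by Monte Carlo rather than assumed
  Gaussian.
- **Residual activity as a ratio of condition means**: the package
  computes `percent_of_control()` as 100 × test / mean(controls); on the
  reported condition means (patient 0.21, controls 1.03 nmol Pi/min/mg at
  0.1 mM PPi) this gives 20.4%. The originally reported rounder figure
  (22%) is a wet-lab aggregate whose exact averaging is not reconstructible
  from the printed summaries, so it is documented here as context, not
  recomputed.
- **Percent-of-baseline ECAR normalisation** (`normalize_ecar_percent()`)
  is the one defensible reading of per-measurement normalised flux units
  when the normalisation constant is not published; it is exact to invert
  and is kept separate from the capacity computation, which is
  normalisation-free.

## Problem sizes used by the tests

The acceptance suite runs the full screen on 100 seeded cohorts of 32
samples (~57,000 peaks each) for spike recovery, 20 cohorts for the null
calibration, 100 random instances for the matcher-vs-oracle equivalence,
and 100 seeded plates/traces for the assay simulations. These sizes give
binomial/SE tolerances tight enough to catch calibration errors of a few
percent while keeping the default `R CMD check`-style run in minutes.

## Known limitations

- Accurate mass alone cannot separate isomers; the report deliberately
  carries "|"-joined annotation groups rather than pretending to resolve
  them.
- The screen tests elevations only; depletion screening (Z < −2) is out of
  scope, as is batch/drift normalisation across runs.
- The feature universe of a real run (how many summed mass peaks survive
  annotation and origin filtering) is data-dependent; the bundled
  reference is a 70-entry stand-in (19 real screen hits + synthetic
  decoys), not a full metabolome database, so absolute feature counts are
  not comparable to a production HMDB-scale screen.
- Michaelis–Menten parameter fitting is intentionally absent: the assay
  module reproduces the reported raw activity-vs-concentration analysis,
  and a kinetic model would suggest a precision the end-point assay does
  not have.
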