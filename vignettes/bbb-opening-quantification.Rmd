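---
title: "Quantifying ultrasound-mediated blood-brain barrier opening"
author: "bbbopen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying ultrasound-mediated blood-brain barrier opening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bbbopen)
```

## The measurement problem

Pulsed focused ultrasound (pFUS) applied together with an intravenous
microbubble (MB) bolus transiently opens the blood-brain barrier (BBB).
Experiments of this kind vary the peak negative pressure (PNP, in MPa) and
the MB dose (in µL/kg) and then quantify the outcome through three
independent channels:

1. **Acoustic emissions (AE).** A passive cavitation detector records a
   voltage trace for every ultrasound burst. Stable bubble oscillation
   radiates harmonics of the 650 kHz excitation; stronger, potentially
   damaging cavitation radiates subharmonic (f0/2 = 325 kHz) and
   ultraharmonic energy.
2. **Contrast-enhanced MRI (CE-MRI).** Gadolinium leaks through the opened
   barrier, so T1-weighted signal rises focally in the sonicated
   hemisphere. The degree of opening is the ratio of mean ROI intensity at
   an enhancement peak to the mean of the mirrored contralateral ROI.
3. **Histology.** H&E sections are graded 0 to +5 from microhemorrhage
   counts and edema severity; immunohistochemistry counts activated
   microglia (Iba1, TMEM119) and astrocytes (GFAP) in rectangular ROIs of
   both hemispheres.

`bbbopen` implements each quantification rule exactly as defined,
a dose-response and trend-test statistical layer above them, and a seeded
synthetic-cohort generator so that every stage can be validated against
known ground truth without animal data.

## Acoustic emission scoring

Each burst's magnitude spectrum is the un-normalized FFT of the raw trace,
keeping the non-negative half-spectrum; no window function is applied (the
burst is treated as rectangular). All downstream metrics use **linear**
magnitudes and convert to dB (`20 log10`) only afterwards: averaging the
magnitude spectrum means averaging magnitudes, not decibels.

* **Noise floor** — the median linear magnitude over the whole spectrum,
  in dB.
* **Subharmonic level** — the mean magnitude over 325 kHz ± 2 kHz,
  *excluding* 325 kHz ± 100 Hz. A sonication is subharmonic-positive when
  this level is **at least 7 dB** (inclusive) above the noise floor.
* **Harmonic level** — the mean magnitude over 1.3 MHz ± 300 Hz. The
  per-animal harmonic baseline is the mean dB level of the five
  pre-injection bursts, and the harmonic increase series is each
  post-injection level minus that baseline; its maximum is the treatment's
  harmonic summary.

Three conventions deserve comment. First, at the production schedule
(10 ms burst, 6.58 MHz sampling) the spectral resolution is exactly
100 Hz, so the ± 100 Hz exclusion removes precisely the three bins at the
tonal subharmonic line; the definition is implemented as written, and a
configuration flag (`exclude_subharmonic_peak = FALSE`) is available for
sensitivity analysis. Second, whether harmonic levels are averaged in dB
or linear units before baseline subtraction is a genuinely open choice; we
average in dB, which makes the increase series a ratio measure and matches
how such baselines are usually plotted. Third, the maximum harmonic
increase is taken over *all* post-injection bursts rather than a 10–40 s
window: the bolus peak time is an observation, not a windowing rule.

Band membership is endpoint-inclusive for both the band and its exclusion
zone, and `band_average()` reports the number of contributing bins so that
an empty band is an explicit error rather than a silent zero.

## CE-MRI enhancement

Images are 2-D matrices with mm pixel spacing and a hemisphere midline
column; coordinates are 1-based (row, col) from the top-left, following R
matrix convention. ROI half-extents are `round(size/2/spacing)` pixels, so
ROIs always have odd pixel dimensions centered on a peak, and a 0.5 mm ROI
at 0.1 mm spacing covers exactly 5 × 5 pixels.

`find_enhancement_rois()` Gaussian-smooths the image (σ = 1 pixel by
default), collects local maxima in the sonicated hemisphere whose ROI and
mirrored ROI both fit in the image, ranks them by smoothed intensity with
(row, col) lexicographic tie-breaking, and greedily selects `n_rois = 2`
peaks at least 1 mm apart. A constant image is handled deterministically
by the tie-break rather than erroring. The mirrored ROI center column is
`2·midline − col`, an involution. The enhancement ratio is the sonicated
ROI mean divided by the mirrored ROI mean; the pre-contrast image is
retained in I/O but does not enter the ratio.

No published numeric criterion exists for calling "opening" from the
ratio, so `call_bbb_opening()` uses a declared package convention of an
inclusive 1.10 threshold, exposed as a parameter.

## Histopathology grading and glial activation

`grade_section()` maps a pathologist's annotation to the semiquantitative
scale: 0 for no findings; +1 for ≤ 3 microhemorrhages with minimal edema;
+2 / +3 for 4–10 microhemorrhages with mild / moderate edema; +4 / +5 for
more than ten with marked / severe regionally extensive edema.
Combinations outside these rows (for instance 4–10 microhemorrhages with
minimal edema, which the scale does not define) return an explicit
*ungradable* outcome instead of being interpolated. Edema severity is an
input annotation, matching the pathologist workflow, and the mapping is
monotone in both inputs across its defined domain.

Activated-cell counts from 1.32 × 0.72 mm ROIs (area 0.9504 mm²) become
densities per mm²; `hemisphere_deltas()` pairs each sonicated ROI with its
contralateral partner per animal, stain, and region, and errors on
unmatched ROIs rather than dropping them. `normalize_metrics()` supports
both normalization conventions that appear in this literature — dividing
each metric by its own global maximum, or dividing everything by the
global maximum relative enhancement — because the two are not equivalent
and published descriptions are ambiguous between them.

## Statistical layer

* **Gompertz dose-response.** Relative enhancement versus PNP is fitted by
  `y = c + A·exp(−exp(−k(p − p0)))` with Levenberg–Marquardt nonlinear
  least squares (`minpack.lm`), a zero lower bound on `c`, `A`, `k`, and a
  deterministic quartile-based initialization (baseline from the minimum
  response, amplitude from the range, `p0` from the mid-range crossing,
  `k` from the pressure spread). Fit quality is summarized by the mean
  absolute percent error. Non-convergence and boundary solutions
  (`A → 0` for a flat response) are flagged, never silently returned.
* **Kendall tau-b** (tie-corrected) with an exact permutation p-value by
  full `n!` enumeration for `n ≤ 8`, and the tie-corrected normal
  approximation above.
* **Fisher's exact test** for r × c tables by full enumeration of
  fixed-margin tables under the point-probability two-sided rule, with a
  seeded Monte-Carlo fallback (`r2dtable`) beyond 10^5 tables.
* **Wilcoxon signed-rank with the Pratt zero treatment**: zeros are ranked
  with everything else and then their signs discarded; exact `2^m`
  sign-flip null for `n ≤ 12`, normal approximation with zero and tie
  corrections above.
* **Jonckheere–Terpstra trend test**: sum of pairwise Mann–Whitney counts
  over ordered groups (ties ½); exact null by enumeration of group
  assignments for pooled `n ≤ 12` (cached per group-size signature for
  tie-free data), with normal-approximation and seeded Monte-Carlo paths
  above.

All exactness cutoffs are arguments. Exact p-values are validated in the
test suite against independent brute-force oracles, and approximate paths
against the corresponding base-R tests where those exist. Significance is
assessed at 0.05 and no multiple-testing correction is applied, matching
standard practice for this design. One known limitation: the two ROI pairs
per animal that enter the Wilcoxon tests are treated as exchangeable
units; a cluster-aware rank test would be the conservative alternative.

## The synthetic cohort

The generator is the package's ground-truth instrument, not a fixture. Its
defaults reproduce the study design: 10 µL/kg at PNPs
0.15/0.25/0.35/0.45 MPa and 250 µL/kg at 0.10–0.35 MPa, five animals per
group, plus ultrasound-only (0.35 MPa, saline) and untreated controls —
twelve groups, 60 animals. Pulse trains follow the production schedule of
five baseline bursts plus 120 post-injection bursts at 1 Hz (10 ms bursts,
6.58 MHz sampling); we read "120 s total" as the post-injection treatment
duration, so a train holds 125 traces.

Design choices, each made once:

* **Noise** is additive white Gaussian on traces and images — the simplest
  model with closed-form band statistics.
* **Component frequencies snap to DFT bin centers** by default so oracle
  peak magnitudes are closed-form (`a·N/2`); a flag allows off-bin tones.
* **Subharmonic emission is a finite-bandwidth comb** of 100 Hz-spaced
  lines within ± 1 kHz of 325 kHz. A single on-bin tone would fall
  entirely inside the detector's ± 100 Hz exclusion zone and be
  undetectable by the scoring rule itself; real subharmonic emissions have
  finite bandwidth, and the comb makes the amplitude-to-excess relation
  analytically predictable.
* **Harmonic bolus dynamics**: post-injection harmonic amplitudes follow
  `(t/tp)·exp(1 − t/tp)` with a 25 s peak — a modeling choice anchored
  only to the observation that harmonic emissions peak 10–40 s after the
  bolus.
* **Severity link**: latent severity `s = 18·PNP + 1.2·log10(dose/10) + ε`
  (ε ~ N(0, 0.5)) with fixed thresholds (4.3, 5.0, 5.7, 6.3, 6.9) mapping
  to grades 0–5. The log-dose term reproduces the qualitative interaction
  that a higher MB dose shifts lesion onset to lower pressures. Planted
  enhancement follows a Gompertz curve of PNP whose inflection pressure
  falls from 0.28 MPa (10 µL/kg) to 0.20 MPa (250 µL/kg), with 0.05
  response noise. Subharmonic amplitude is non-zero only above the
  grade ≥ +4 severity threshold, mirroring the empirical association of
  subharmonic AEs with marked/severe findings.
* **Histology**: annotations are drawn from the combinations that grade
  back to the true grade (self-consistency holds by construction), and
  activated counts are Poisson at the truth rates
  (`10 + 7·max(s, 0)` per mm² sonicated, 10 contralateral), two regions ×
  two hemispheres × three stains.
* **Seeding**: one master seed per cohort; per-animal and per-purpose
  seeds derive from it through a fixed congruential rule, so any subset of
  the simulation can be regenerated independently and repeat runs are
  byte-identical.

What the generator does *not* emulate — and therefore what passing tests
cannot show about real data: skull transmission and standing-wave pressure
fields, receiver transfer functions (flat by default; a band-pass flag
exists), anatomically realistic image content or registration error,
partial-volume and slice-placement effects in histology, and biological
variability beyond Poisson counting and Gaussian severity noise.

## A worked run

```{r, eval = FALSE}
cfg <- run_config(design = cohort_design(seed = 1))
report <- run_pipeline(cfg)
report
write_report(report, "bbb_report", figures = TRUE)
```

At the full design this takes on the order of ninety seconds. The unit
suite exercises the same pipeline on reduced schedules (3.29 MHz sampling,
which preserves the 100 Hz bin spacing and keeps both analysis bands below
Nyquist, with 8–15 post-injection bursts) and reduced cohorts; the
statistical property suites use 200 replicate fits at n = 30 per curve and
2000-replicate null simulations at the study's group sizes.

## Numerical conventions

Degenerate inputs are explicit errors, not coerced values: empty traces,
bands containing no bins, zero contralateral ROI means, zero-variance
regressors, all-tied rank inputs, tables with an empty margin, and
ungradable lesion combinations. Ties are handled by average ranks
(Wilcoxon), ½-counts (Jonckheere–Terpstra), and tau-b corrections
(Kendall); tie cases are pinned in the test suite. Exact-test boundary
comparisons use a 1e-9 slack on rank statistics and 1e-7 on table
log-probabilities so that floating-point noise can never flip an
inclusive boundary. The subharmonic 7 dB comparison is `>=`, and the
opening-call threshold is likewise inclusive.
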