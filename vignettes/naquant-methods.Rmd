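---
title: "Quantifying naphthenic acids from direct-infusion ESI(-) spectra: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying naphthenic acids from direct-infusion ESI(-) spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(naquant)
```

## The problem

Naphthenic acids (NAs) — the complex family of acyclic, cycloaliphatic and
aromatic carboxylic acids with classical composition CnH(2n+Z)O2 — occur in
crude oil and in the produced water co-extracted with it. They corrode
refinery equipment and are toxic to aquatic life, so the petroleum industry
needs fast concentration monitoring. Direct-infusion ESI(-) high-resolution
mass spectrometry sees NAs as [M-H]- anions in a single composite spectrum
per sample, but a spectrum is not a concentration: matrix effects,
interferents and run-to-run intensity drift defeat naive single-peak
calibration. `naquant` implements the multivariate route: align spectra onto
a fine m/z grid, normalize, and calibrate a PLS1 regression of total NA
concentration on the full spectral profile, with ordered predictor selection
(OPS) pruning the m/z variables.

## Pipeline and model

1. **Binning/alignment.** Each centroided spectrum is binned onto half-open
   bins of width 0.001 Th over m/z 100–400 (floor indexing, decimal-safe
   arithmetic; peaks sharing a bin are summed, conserving ion current).
   The matrix **X** keeps only the union of *occupied* bins across samples:
   a full grid would have 300,001 columns, while occupancy typically leaves
   a few hundred at desk scale (and tens of thousands on real instrument
   data), which matches how many variables a real alignment carries.
2. **Row normalization.** Default `"sum"` (each row divided by its total ion
   current), removing per-run spray-efficiency drift. `"max"`, `"vector"`
   and `"none"` are available.
3. **Column scaling.** `"autoscale"` (mean 0, sample SD 1, n−1 denominator —
   the chemometrics convention) or `"center"`, fitted on calibration rows
   only and applied unchanged to validation and unknown samples.
   Zero-variance calibration columns are dropped and recorded.
4. **PLS1 by NIPALS.** Per component `w = X'y/||X'y||`, `t = Xw`,
   `p = X't/t't`, `q = y't/t't`, deflation of X and y; the regression vector
   is `b = W(P'W)^{-1}q`. PLS1 weights are closed-form per component, so no
   iteration tolerance exists. Scores are mutually orthogonal and
   regression-vector predictions equal sequential-deflation predictions;
   both are enforced by property tests against an independent
   Krylov-subspace oracle.
5. **Model order by Monte-Carlo CV.** Random removal of `leave_out = 3`
   samples, scaler *refitted inside every split* (no information leak),
   held-out residuals pooled across splits into one RMSECV per latent
   variable count; minimum wins, ties to the smaller count. Rcv is the
   pooled-residual Pearson correlation (pooling, not per-split averaging,
   is the documented choice). The default 200 splits stabilizes RMSECV for
   24 calibration samples; time-critical callers can lower it.
6. **OPS.** A pilot PLS (order chosen by the same CV) supplies the
   informative vector — `|b|` by default, `|cor|` or their product as
   options; the choice is configurable because published work rarely states
   it. Variables are sorted by decreasing informativeness and nested
   prefixes of sizes 20, 25, 30, … up to 100% of the variables are each
   cross-validated with the *same* split seed; minimal RMSECV selects the
   subset and order, ties toward fewer variables then fewer components.
   Because the full set is itself a candidate at 100%, OPS can never report
   a worse RMSECV than the all-variable model. A single ordering pass is
   used; iterated re-sorting is deliberately out of scope.
7. **Split.** 36 samples go 24/12 into calibration/prediction, stratified by
   concentration level so both sets span the modeled range; the extreme
   levels always calibrate and, replicates permitting, also appear in the
   prediction set.
8. **Prediction of unknowns.** New spectra are binned onto the model's grid;
   normalization statistics use the spectrum's full in-range intensity (so
   signal landing outside the training bins still counts toward the total),
   then the stored scaler and regression vector produce PRED1 and
   `PRED2 = PRED1 × dilution factor` (20 for typical produced-water
   workups). Out-of-range predictions are flagged, never clipped, to keep
   residual diagnostics honest.

Model quality is summarized by RMSE (`sqrt(mean((y - yhat)^2))`) and the
Pearson correlation R on three sample sets: calibration (RMSEC/Rc),
cross-validation (RMSECV/Rcv) and prediction (RMSEP/Rp).

## The synthetic world

No instrument data ship with the package, so a seeded generator stands in.
What it states, once:

* **Panel.** The ten carboxylic-acid standards (cyclopentanecarboxylic,
  benzoic, cyclohexanebutyric, 1-naphthoic, 9-anthracenecarboxylic,
  pentadecanoic, decanoic, 3,5-dimethyladamantane-1-carboxylic,
  3,5-dimethyladamantane-1-acetic, 2-methyloctadecanoic acid) at their
  theoretical [M-H]- masses (monoisotopic atoms, minus a proton, electron
  mass included — 0.55 mDa matters at 3 ppm below m/z 200).
* **Design.** 12 levels (0.50–40.00 mg/L) × 3 replicates = 36 samples.
* **Concentration sharing.** The total concentration is split across the ten
  standards by equal mass by default. The originating protocol's "equimolar
  mixture at concentration c" is ambiguous (equal moles vs equal mass,
  per-compound vs total), so `share = "equimolar"` is an explicit switch
  rather than a guess.
* **Response.** Peak intensity = response factor × per-compound
  concentration × max(0, 1 + N(0, `intensity_cv`)); response factors are
  distinct fixed values (0.7–2 × 10^6 counts per mg/L) because ESI
  ionization efficiency is compound-specific. Noise is truncated at zero.
* **Mass accuracy.** Per-peak mass error ~ N(0, `sigma_ppm`), default 1 ppm
  — Orbitrap-realistic.
* **Background.** 100 contaminant ions drawn uniformly over m/z 100–400
  with exponential base intensities (mean 10^6 counts), **shared across the
  dataset** with per-sample intensity noise. Chemical background in direct
  infusion is a reproducible ion population (solvent clusters, plasticizers,
  fatty-acid contaminants), not fresh random masses per run; sharing the
  panel is both more realistic and what makes sum normalization meaningful —
  the analyte share of total ion current is then a stable, monotone function
  of concentration (background ≈ twice the analyte current at 40 mg/L).
* **Real-sample mode** adds 150 abundant interferent ions kept ≥ 0.005 Th
  away from every standard mass.
* **Determinism.** One master seed; each sample draws from a derived
  sub-stream, so datasets are byte-identical across runs.

What the generator does **not** emulate: isotopologues, adducts, in-source
fragmentation, ionization suppression between analytes, profile peak
shapes, and the sheer variable count of real alignments (~77k occupied bins
on instrument data vs a few hundred here). A green pipeline test therefore
establishes that the chain of algorithms is correct and stable under
realistic noise — not that any instrument will achieve the same figures.

## Numerical choices and degenerate inputs

* Bin indices use `floor(round(q, 9))` so printed decimal m/z values land in
  the bin their text implies rather than one below after binary round-off.
* Sample SD (n−1) in autoscaling; population SD would change coefficients.
* CV orders that exceed a split's numerical rank are skipped for that split
  and counted; a direct `fit_pls()` call past the rank raises an error.
* All-zero rows abort normalization with the offending sample named;
  zero-variance columns are dropped, not epsilon-padded.
* RMSECV ties break toward fewer latent variables; OPS ties toward fewer
  variables first. An optional parsimony rule was considered and rejected:
  minimum-RMSECV selection reproduces how published model orders are chosen.
* **Noise-free caveat:** with analyte-only spectra and zero noise, sum
  normalization maps every sample to the same composition — the
  concentration information lives entirely in the background share. The
  exact-recovery test therefore calibrates on raw intensities
  (`normalization = "none"`); this is a property of sum normalization, not
  of the implementation.

## Verification

Tests pit the NIPALS implementation against three independent oracles: a
closed-form Krylov-subspace PLS1 (conjugate-gradient equivalence), ordinary
least squares at full rank with maximal components, and a hand-rolled
leave-one-out loop. (No reference PLS package exists in the supported
library set, so the Krylov identity replaces a third-party implementation;
it shares no code with the NIPALS path.) The formula-assignment engine is
checked by round-tripping the standard panel and by even-hydrogen/integer
DBE properties; the dilution-correction arithmetic and its summary
statistics are checked against a packaged 12-sample reference comparison
table. `scripts/acceptance.R` recomputes every reported number at run time.

## Limitations

Quantification is of *total* NA concentration against a 10-standard panel;
speciation beyond Ox class and DBE–carbon summaries, N/S heteroatom
classes, Kendrick analyses, and vendor raw-file reading are out of scope.
Real-sample accuracy is bounded by how well the calibration matrix mimics
the produced-water background, which is exactly the systematic bias the
dilution-corrected comparison against LC-MS quantifies.
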