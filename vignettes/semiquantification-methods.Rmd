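---
title: "Semiquantification methods: models, corrections and quality management"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semiquantification methods: models, corrections and quality management}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(semiquantr)
library(dplyr)
```

## The problem

Targeted LC-MS/MS panels measure on the order of a hundred polar metabolites
in one short injection, across serum, tissue homogenates and cell pellets.
True quantification would require a stable-isotope-labeled internal standard
(IS) for every analyte; at panel scale that is neither affordable nor always
possible, so the field works *semiquantitatively*: an external aqueous
calibration curve per metabolite, a small set of class-representative labeled
IS (twelve in the packaged panel) shared across chemically similar analytes,
and an explicit *process-efficiency* correction for everything the shared IS
cannot absorb.

`semiquantr` implements the computational side of that workflow end to end:
parsing the vendor flat-file export, calibration-curve regression with
LLOQ/ULOQ determination, the multiplicative correction chain from raw ppb to
final concentrations, EMA-style validation statistics, batch layout and QC
drift surveillance, and a hierarchical log-normal model for population
reference medians. A seeded synthetic-data generator stands in for
instrument data so every stage is testable.

## Calibration

Standards are a serial dilution: 11 levels, two-fold steps, hence a
1024-fold dynamic range by default (`make_serial_dilution()`). Responses are
analyte/IS peak-area ratios, or raw areas for metabolites without an
assigned IS.

Over three decades of concentration, response variance grows roughly
proportionally with the signal. `fit_curve()` offers the two standard
remedies and treats them as mutually exclusive:

* **`1/x` weighting** of an untransformed linear or quadratic least-squares
  fit (weight `1/nominal_conc`), and
* the **log-log transform**, fitting `log(response) ~ log(conc)`; the log
  already stabilises proportional variance, so combining it with `1/x`
  weighting would correct the heteroscedasticity twice. When
  `transform = "loglog"` is requested, weighting is forced to `"none"`.

R² is reported on the *fitted* scale (weighted, transformed) and labeled as
such; it is not comparable across transforms and the package never mixes
scales silently.

`back_calculate()` inverts the curve. For quadratic fits the root inside
the calibrated range is taken; if both or neither root is inside, the root
nearest the range midpoint wins — an arbitrary but documented and
deterministic tie-break. Responses outside the invertible region come back
`NA` (non-quantifiable), never as an error, because a single saturated
injection must not abort a batch.

Accuracy per level is back-calculated/nominal (percent). A level passes
within ±15%, relaxed to ±20% at the lowest level, the conventional
relaxation at the quantification limit. The LLOQ and ULOQ are the ends of
the longest contiguous run of passing levels (`determine_loq()`); a curve
with no passing level is flagged rejected and the metabolite is reported,
not dropped. `select_model()` picks among candidate
(model, transform, weighting) configurations by maximising the count of
passing levels, breaking ties by higher R² and then by simplicity — linear
before quadratic, untransformed before log-log, unweighted before weighted —
so two near-equivalent fits always resolve the same way.

Carryover (`check_carryover()`) is residual blank signal after a
high-concentration injection, expressed as percent of the LLOQ-level peak
area, with a 20% acceptance threshold; the boundary value itself passes.

## The correction chain

`quantify_batch()` applies, in a fixed order:

1. concentration intake — reported ppb, or back-calculation through the
   calibration fit when starting from peak areas;
2. molecular-weight normalisation: µg/L ÷ g/mol = µmol/L;
3. process-efficiency correction: division by PE = recovery × matrix
   effect, taken from the panel file (default 1, i.e. no correction unless
   the laboratory supplies measured values — correction must be explicit,
   never guessed);
4. dilution correction (× dilution factor ≥ 1);
5. matrix-specific normalisation: tissue samples to µmol/g via
   `conc × V_extract / weight_g`, cell samples to µmol per 10⁶ cells via
   `conc × V_extract × 10⁶ / cells`; biofluids stay volumetric. The extract
   volume (default 100 µL) is a protocol parameter, not an instrument
   output, and must come from metadata.

All steps are multiplicative, so the order cannot change the value; it is
fixed anyway so that the provenance columns (`factor_mw`, `factor_pe`,
`factor_dilution`, `factor_matrix`) mean the same thing in every output, and
`value = raw × Πfactors` holds exactly for every cell. Values outside
`[LLOQ, ULOQ]` are flagged and retained — below-LLOQ is a reportable state,
never imputed or zeroed. The tissue conversion rejects weights ≥ 1000 g as
a unit-mismatch guard (a milligram figure passed as grams).

Phenotype-group statistics (`group_stats()`) use the sample SD (n−1);
RSD = 100·SD/mean. A value more than 1 SD from its group mean is marked
`outlier_1sd`, more than 2 SD additionally `outlier_2sd` — marking, not
trimming: the candidate point stays in the mean/SD it is judged against,
single-pass, no iterative re-exclusion. Flags are therefore invariant to
affine rescaling of the group. Groups of size one get no statistics and no
flags.

## Validation statistics

Recovery compares QC matrix spiked *before* extraction with matrix spiked
*after* extraction. Matrix carries endogenous analyte, so the endogenous
mean is subtracted from **both** spiked arms before forming the ratio —
both arms contain the same background, and subtracting from only one would
bias recovery toward 100%. Recovery is undefined (flagged) when the
after-extraction arm does not exceed background.

The matrix effect is the endogenous-subtracted after-extraction response
over the aqueous (pure solvent) response; the aqueous arm is *not*
endogenous-subtracted because solvent has no endogenous analyte by
construction. Below 1 is ion suppression, above 1 enhancement. Process
efficiency multiplies the two, and
`apply_process_efficiency(conc × PE, PE) = conc` closes the algebra.

Stability is stored/fresh mean ratio with an 85–115% default band.
Acceptance bands throughout (recovery 50–120% reliable, < 30% unreliable,
CV tiers 15/20/25%) are configuration defaults, all overridable.

## Batch design and QC surveillance

Samples are double-randomized — once before extraction, once before
injection — from one seeded generator, with a blocking guard that redraws an
injection order in which any phenotype group forms a contiguous block longer
than `ceiling(2·max group size / n groups)`. `build_layout()` places
calibration standards first, then a blank at every fifth post-standard
position and a pooled-serum QC after every tenth experimental sample. The
two cadences can collide; the blank keeps the slot and the QC shifts one
position later — deterministic and auditable. Blank cadence counts
post-standard positions only.

The QC history is a plain append-only CSV
(`qc_lot,batch_id,run_date,hmdb_id,conc_umol_l`); at a few hundred rows per
metabolite it needs no database engine. The drift reference is the
inter-day RSD: the CV of per-batch mean QC concentrations. A new batch
passes for a metabolite when its QC RSD ≤ historical RSD × (1 + tol/100),
with a default 20% relative tolerance (a configuration default — the choice
of tolerance is a laboratory policy, not a statistical necessity).
`reproducibility_summary()` reports per-metabolite CVs of QC concentration,
retention time and calibration R² across batches against 25% / 4% / 3%
tiers, the fingerprints of a stable platform.

## The reference-median model

Pooled-serum QC concentrations accumulate over years in distinct serum
*lots*. Lot-to-lot offsets are real composition differences, not noise, and
must not widen (or bias) a population reference estimate. Per metabolite:

$$\log y_{ij} = \mu + b_j + \varepsilon_{ij},\qquad
  b_j \sim N(0, \sigma_b^2),\qquad \varepsilon_{ij} \sim N(0, \sigma_e^2)$$

with a flat prior on µ and inverse-gamma(0.001, 0.001) priors on both
variances. All conditionals are conjugate and a Gibbs sampler
(`fit_reference()`, default 20 000 retained draws after 5 000 burn-in,
seeded) draws the posterior. The population median is the median of the
`exp(µ)` draws — transformation-consistent with the log-normal median,
unlike `exp(mean)` — and the 95% credibility interval is the 2.5/97.5
percentiles of the same draws.

Two numerical choices matter:

* **Blocked µ draw.** µ is drawn from its conditional with the lot effects
  integrated out (lot means are independent `N(µ, σ_b² + σ_e²/n_j)`), then
  `b | µ`. A single-site sampler is valid but mixes pathologically when
  σ_e → 0 (the flat-prior µ/b translation ridge), and recentring variants
  that sweep the lot-effect mean into µ destroy the interval: they make µ
  track the average of the *observed* lots, dropping the lot-sampling
  uncertainty `σ_b²/J` that dominates the width of the credibility interval
  when lots are few. The blocked draw keeps both mixing and coverage.
* **Priors.** IG(0.001, 0.001) is weakly informative, not non-informative:
  with few lots and noiseless data the interval width is prior-bound rather
  than zero. `prior_shape`/`prior_rate` are exposed; as they shrink, the
  posterior for constant data collapses onto the observed value.

Rows with non-positive concentrations cannot enter the log-normal
likelihood; they are dropped and counted (`n_dropped`). No Tobit-style
censoring extension is attempted for below-LLOQ values — a documented
limitation. Single-lot histories fall back to a no-lot model with a
warning. Estimates are exactly scale-equivariant under the same seed, and
the posterior lot deviations centre at zero by the hierarchical prior.

The packaged reference database (102 metabolites, 24 classes, medians with
95% credibility intervals in healthy adult serum) is a curated transcription
shipped as CSV package data; `reference_table()` re-emits it, or formats a
fresh fit, in the same class-grouped shape. Molecular weights in the panel
are curated average masses from public HMDB records; every unit test that
depends on a molecular weight uses synthetic panels, so package correctness
is independent of this fixture.

## What the synthetic generator emulates — and what it does not

`sim_config()` fixes the study conditions; every generator is a pure
function of (config, seed) and the session RNG state is restored afterwards.
Defaults describe a well-behaved serum assay:

| parameter | default | meaning |
|---|---|---|
| `noise_cv` | 5% | proportional (multiplicative Gaussian) measurement noise, truncated at −1 |
| `lot_sd_log` | 0.1 | QC lot random-effect SD, log scale |
| `qc_noise_sd_log` | 0.2 | QC residual SD, log scale |
| `extraction_efficiency` | 0.7 | true recovery fraction |
| `matrix_factor` | 1.2 | true matrix-effect ratio (mild enhancement) |
| `rt_drift_cv` | 1% | retention-time jitter |
| `carryover_frac` | 0 | blank residue as a fraction of the ULOQ standard's area |
| calibration | 1000 / 11 / 2 | top concentration, levels, dilution factor |

Noise is multiplicative rather than additive because proportional variance
is exactly the heteroscedasticity that motivates `1/x` weighting; a
generator with additive noise would make the weighting choices untestable.
Batches emit the exact flat-file dialect the parser reads (`Compound N:`
banners, tab-separated nine-column blocks), with observed ppb =
truth × MW × PE × noise, so the full correction chain is exercised, and the
synthetic panel writes the true PE into its `process_efficiency` column so
quantification undoes exactly the attenuation the generator applied. QC
histories use 6 lots × 90 replicates (~540 records) by default, the shape
of a multi-year QC database.

The generator does **not** emulate: chromatographic peak shapes or
integration errors, co-elution and isobaric interference, missingness
mechanisms correlated with concentration (below-LLOQ dropout), instrument
sensitivity drift *within* a batch, or heavy-tailed contamination. Passing
tests therefore demonstrate correctness of the computational pipeline under
a clean, known data-generating process — not robustness of the analytical
method itself to matrix pathology, which only wet-lab validation can show.

## Problem sizes used by the test-suite and acceptance script

Simulation sizes are chosen to give stable Monte-Carlo estimates at
interactive run times: 200 seeded curves for the linearity study, 100 seeded
6-lot × 90-replicate histories (4 000 retained draws after 1 000 burn-in
each) for the reference-model recovery and coverage study, single batches of
10–100 metabolites × 10–85 samples elsewhere. The default 20 000/5 000
sampler settings are used for single fits; the reduced draw count in the
replicated coverage study trades per-fit Monte-Carlo error (≪ the 4%
lot-sampling SE) for replication count, which is what the coverage estimate
actually needs.

## Known limitations

* Below-LLOQ values enter group statistics as reported numbers (flagged);
  no censored-likelihood treatment anywhere.
* The flat-file dialect is one fixed grammar; other vendor export dialects
  need adapters.
* The workbook output is a directory of CSV sheets (concentrations,
  QC summary, flags) — diff-able and version-controllable by design; the
  two outlier severities are distinct flag strings rather than cell colors.
* Drift is monitored, never corrected: no batch-effect regression is
  applied to concentrations.
* The reference model is univariate per metabolite; no cross-metabolite
  covariance.
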