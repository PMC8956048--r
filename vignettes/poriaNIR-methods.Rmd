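---
title: "Methods and design of the poriaNIR calibration pipeline"
author: "poriaNIR maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of the poriaNIR calibration pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poriaNIR)
```

# The problem

*Poria cocos* is traded from three Chinese cultivation regions (Yunnan,
Xiangqian, Dabie Mountains) whose products differ in the four quality
parameters used by pharmacopoeias: polysaccharides (PSC), water-soluble
extract (WSE), alcohol-soluble extract (ASE) and the sum of five triterpenoid
acids (SFT), all in mg/g of dry powder. The reference assays are slow wet-lab
procedures; NIR diffuse-reflectance spectra of the milled powder
(≈4,000–12,000 cm⁻¹, dominated by O–H/C–H/N–H overtone and combination
bands) carry enough compositional information to replace them after
chemometric calibration. This package implements that calibration workflow
end to end and a synthetic data generator that emulates the study design, so
every stage is testable without access to the original spectra.

# Pipeline stages and their assumptions

`runPipeline()` executes the stages in fixed order; a single seed fans out to
per-stage offsets (simulation `seed`, outlier detection `seed + 1000`,
cross-validation folds `seed + 2000`, forest `seed + 3000`), so disabling one
stage does not shift another's random stream.

## Pretreatment operators

Seven named pretreatments are compared: `Raw`, `MSC`, `SNV`, `Smooth`,
`Smooth+SNV`, `Smooth+MSC`, `SG-1D`. Choices a user should know:

* **SNV** uses the sample (n−1) standard deviation. Stated explicitly
  because either convention changes every transformed value.
* **MSC** regresses each spectrum on a reference by ordinary least squares
  and returns `(x − a)/b`. The reference is the column-mean spectrum of the
  *calibration* set; it is part of the fitted state and is re-applied
  unchanged to validation spectra, so no validation information leaks into
  the transform.
* **Smoothing is Savitzky–Golay** (local polynomial least squares,
  `deriv = 0`), not a moving average: the study's named smoothing method is
  SG, and a moving average is the degenerate `polyorder = 0` case anyway.
  Window and polynomial order are not stated in the source study; the
  defaults (window 11 points, polyorder 2) are common chemometrics practice
  and both are exposed on `PretreatmentSpec`.
* **SG-1D** output is scaled by the wavenumber step, so its units are
  absorbance per cm⁻¹ and results do not silently depend on the grid
  resolution. A first derivative on a non-uniform axis is refused (relative
  spacing tolerance 1e-6) rather than silently mis-scaled. Edges are handled
  by the polynomial fit over the one-sided window (the rows of the SG
  projection matrix), so the output keeps the input's shape.
* Composed names smooth first, then scatter-correct.

## Outlier elimination (MCCV)

For each response, `detectOutliersMCCV()` repeats `nRounds = 500` times:
draw a random 80% calibration subset, fit an inner 5-factor PLSR on the raw
spectra, record absolute prediction residuals of the held-out 20%. Each
sample then has a residual mean and residual SD across its held-out rounds.

Flagging is where this implementation makes a deliberate numerical choice:
thresholds `mean + 3·SD` are applied to the **log** residual statistics, and
are re-estimated on the not-yet-flagged population until a fixed point
(sequential rejection). Two measured failure modes of the linear-scale rule
motivated this. First, masking: one gross outlier inflates the SD enough to
hide the others (with three injected 10× artifacts, the linear rule flags
only the largest). Second, over-flagging: the concentration distributions
are strongly right-skewed, prediction error grows with distance from the
bulk, and the linear rule flags 3–8% of perfectly clean samples — the
flagged set should be empty on clean data. Residual magnitudes are positive
quantities with multiplicative dispersion, so the log scale is their natural
home; with it, the package's test suite measures all three injected
artifacts recovered and a clean-data false-flag rate under 1% across 20
seeds. The `meanK`/`sdK` multipliers (default 3) remain configurable.

A sample flagged for *any* response is excluded globally, mirroring a single
exclusion step before all downstream modelling. Samples never held out
across all rounds abort with advice to raise `nRounds`.

## Kennard–Stone splitting

Classical, unsupervised, deterministic: seed with the pair at maximal
Euclidean distance, then repeatedly add the sample maximizing its minimum
distance to the selected set; ties break toward the lowest sample index. The
calibration size is `round(n·r/(r+1))` — 108 of 135 at the study's 4:1
ratio. The split runs on the spectra as given (raw by default); because K-S
picks extremes for calibration, the validation set spans a narrower range
than the calibration set, which is the intended behavior of the method, not
a bug — but it also means validation error estimates are slightly
optimistic for samples near the hull.

## PLSR calibration

Single-response NIPALS (PLS1): mean-center X and y, then per factor take the
weight along `X'y`, score, and deflate both blocks; the latent regression
collapses to one coefficient vector via `R = W (P'W)⁻¹`. No autoscaling of X
— absorbance columns share units, and scaling would amplify noise-only
channels; this is switchable by pretreating with SNV. Factor count is chosen
by 10-fold cross-validation with a parsimony rule: the smallest count whose
RMSECV is within 2% of the global minimum (`margin = 0` recovers the strict
argmin). When a fold's training block is rank-exhausted, extraction stops
and the RMSECV curve is flat beyond that count, so low-rank noiseless
problems are handled without error.

Evaluation follows the standard definitions (RMSEC/RMSEP as root mean
squared residual per set; R² as 1 − SSres/SStot). Two aggregation choices
the source material leaves open are declared here: each set's R² uses **its
own** measured mean (switchable to the calibration mean via `yBar`), and the
reported RE is the **mean** of per-sample absolute relative errors over the
validation set. Validation samples with y = 0 make RE undefined and raise an
error rather than an infinity.

The pretreatment grid fits every candidate method (state on calibration
only), selects factors per method, and picks the method with minimal RMSEP
(ties: higher R²pre, then first listed). Note that RMSEP-based selection
reads validation responses — that is the study's own comparison design, so
the leakage guard in the tests asserts instead that *calibration* artifacts
are bit-identical when validation responses are poisoned.

## Region classification

A bagged random forest (500 trees, `floor(sqrt(p))` features per split,
unlimited depth, minimum leaf 1 — canonical settings, all configurable) on
SNV-pretreated spectra, the same pretreatment family as the regression grid.
Vote ties break by the fixed class order YN < XQ < DBM. Out-of-bag error is
available from the fitted forest as a sanity check against the held-out
estimate.

## Reference chemistry

The wet-lab arithmetic is implemented exactly: gravimetric extract content
`(W1 − W0) × f / S × 100%` with the aliquot factor generalized (2 for 25 of
50 mL; the ethanol variant reuses the same operation), OLS standard curves
with the n−2 residual SD, and ICH detection limits LOD = 3.3σ/slope,
LOQ = 10σ/slope — the convention is declared because the source tables print
values without formulas. Summary tables round to 2 decimals for display and
keep full precision in `*_full` columns.

# The synthetic generator

`SyntheticConfig()` defaults *are* the emulated study conditions:

| parameter | default | rationale |
|---|---|---|
| `nPerRegion` | 58 / 28 / 52 | published region counts |
| `axis` | 4,000–12,000 cm⁻¹, step 8 | stated range and resolution |
| `bandCenters` | 8256, 6880, 5610, 5180, 4800 cm⁻¹ | the five observed peaks |
| `bandWidths` | 160, 140, 100, 90, 110 cm⁻¹ | broad NIR combination bands |
| `regionParams` | published per-region mean/SD/min/max | published summary moments |
| `correlation` | extracts +0.5; SFT vs PSC −0.3 | reported co-variation |
| `backgroundAmplitude` | 1.0 AU | dominant dry-matter absorption |
| `scatterSlopeSd` | 0.05 | mild multiplicative scatter |
| `scatterOffsetSd`, `baselineSd` | 0.02, 0.01 AU | additive offsets |
| `noiseSd` | 0.005 AU | instrument white noise |

Concentrations are drawn by a Gaussian copula and clipped to the published
min/max. Clipping biases the mean, so the latent mean is **moment-matched**:
solved (closed-form clipped-normal mean, `uniroot`) so each region ×
constituent expectation equals the published mean. Spectra are Beer–Lambert
mixtures of per-constituent Gaussian-band profiles on a fixed background,
then `(mix + baseline)·(1 + slope) + offset + noise`.

The **background** deserves emphasis: real powder spectra are dominated by
bulk absorption common to all samples, and multiplicative scatter acts on
that bulk. Without it, spectra would be 100% analyte signal; SNV/MSC would
then divide out the concentration scale itself and scatter correction could
never beat raw spectra — an artifact of the simulation, not of the methods.
With the background, the generator reproduces the expected ordering:
scatter-corrective pretreatments win under strong scatter
(`scatterSlopeSd ≈ 0.3`), while at the mild default either choice works.

What the generator does **not** emulate: instrument line-shape and detector
response, wavelength-dependent scatter, temperature/moisture effects, any
region-specific spectral fingerprint beyond the four constituents'
concentration distributions, and the true (unpublished) spectral overlap of
the constituents — the loadings matrix is declared fiction calibrated only
to peak positions and balanced signal contributions. Passing tests therefore
demonstrate the *algorithms* behave correctly on data with the study's
statistical structure, not that the package reproduces the original
instrument's numbers. The five triterpene acids are fixed proportions of
SFT (their published Yunnan shares), so the sample table stays
schema-complete; they feed nothing downstream.

## The classification ceiling

One consequence is worth stating plainly. In the generator, region
membership influences spectra *only* through the concentration
distributions, which overlap heavily (e.g. WSE 25.2 ± 12.8 vs 24.0 ± 12.2
mg/g in two regions). A random forest given the true concentrations as
features — the best any spectral model could recover — reaches only about
72% out-of-bag accuracy, and the spectra-based forest about 50% on held-out
samples (both measured by this package's test suite). The ≈93% accuracy
reported on real spectra is therefore not reproducible from the published
summary statistics alone: real spectra must carry regional fingerprints
(matrix composition, particle properties, minor constituents) beyond the
four quality parameters. The classifier envelope test encodes the original
expectation and fails honestly on synthetic data; it documents this gap
rather than masking it.

# Numerical choices and degenerate inputs

* Wavenumber axes are stored strictly ascending; descending files are
  permuted on load. The two unit conventions quoted for the instrument
  (nm vs cm⁻¹) are inconsistent in the source; the package is axis-agnostic,
  validates only monotonicity, and ships `nmToWavenumber()` for users who
  need to compare ranges.
* Spectra round-trip to disk at 17 significant digits (`%.17g`), so
  write-then-read is exact.
* Constant spectra (SNV), constant references (MSC), zero-variance
  responses, rank-exceeding factor requests, single-class training sets and
  zero validation responses all raise immediate, named errors.
* `sft` is recomputed as the sum of the five acids when absent and verified
  to 1e-9 when present.
* Determinism: every stochastic routine takes an explicit integer seed;
  identical seeds give bit-identical results.

# Problem sizes in the test suite

Unit tests run on small matrices and a coarse 201-point axis where the
property under test does not depend on resolution; the acceptance-level
checks run the full study geometry (138 × 1001, five seeds for pipeline
recovery and classification, twenty seeds for the clean false-flag rate).
These sizes were chosen to exercise the study conditions while keeping the
suite convenient to run during development.

# Known limitations

* PLS1 only — one model per response, no multi-response PLS2, no interval
  or variable selection.
* No duplex/SPXY splitting and no leverage-based outlier diagnostics; MCCV
  is the only outlier route.
* The JCAMP-DX reader supports single-spectrum `(X++(Y..Y))` AFFN records
  only.
* Synthetic classification accuracy is capped well below the real-data
  reference (see above); conclusions about classifier quality on real
  *P. cocos* spectra cannot be drawn from this generator.
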