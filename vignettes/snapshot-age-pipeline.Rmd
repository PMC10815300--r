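---
title: "Estimating chronological age from SNaPshot methylation peak data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating chronological age from SNaPshot methylation peak data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snapAge)
```

## The measurement and the model

DNA methylation at a handful of CpG sites drifts with age predictably
enough to estimate how old the donor of a biological trace is — a question
forensic genetics frequently needs answered. snapAge implements the
assay-to-estimate chain for a five-locus buccal-swab clock built on
*ELOVL2*, *FHL2*, *KLF14*, *C1orf132* (also annotated *MIR29B2C*) and
*TRIM59*.

The laboratory chain is: bisulfite conversion (unmethylated C reads as T,
methylated C stays C), multiplex PCR, single-base extension (SNaPshot)
with dye-labelled terminators at the queried CpG, and capillary
electrophoresis. Each locus then shows up to two peaks — one per allele
state. For top-strand assays (ELOVL2, FHL2) the methylated allele is read
as C and the unmethylated as T; the other three loci are read on the
bottom strand as G versus A. The methylation level is the intensity ratio

$$\beta = \frac{I_{\text{meth}}}{I_{\text{meth}} + I_{\text{unmeth}}},$$

i.e. $I_C/(I_C+I_T)$ or $I_G/(I_G+I_A)$. Peak *height* (RFU) is the
default intensity measure, with area available as an option; the ratio is
dimensionless, confined to $[0,1]$ and invariant to rescaling both
channels, which is what makes it usable across runs of different overall
signal strength. When only one channel shows a peak the other contributes
zero intensity — a fully methylated or fully unmethylated template
legitimately produces a single peak — while a measurement with *no* peak
in either channel is treated as absent (`NA`), never as $0/0$.

Age is then modelled as an ordinary multivariate linear regression on the
five levels,

$$\widehat{\text{age}} = \beta_0 + \sum_{l} \beta_l \, x_l,$$

with no penalisation, no age transform and no clamping of outputs.
`publishedModel()` ships one such model for buccal swabs with its six
constants stored to the printed decimal digit; `fitAgeModel()` fits a new
one by QR-based least squares.

## Replicates and quality control

The assumed design measures every sample four times: two independent
bisulfite conversions, each amplified twice. Technical error enters at
both stages, but the conversion is the step most liable to produce a
systematic batch difference. The QC model is therefore:

* **Conversion homogeneity.** Per locus, levels from conversion 1 and
  conversion 2 (amplifications pooled within each conversion) are
  compared with a two-tailed two-sample *t*-test assuming equal
  variances. The default significance level is 0.05. Passing (p ≥ α)
  licenses averaging all four replicates into one profile per sample;
  failing flags the locus. By default flagged measurements are still
  averaged — the flag is information for the analyst, and discarding data
  automatically would hide a batch problem rather than surface it — while
  a per-sample test variant exists for troubleshooting individual
  samples (with only two values per group it has very little power, so
  it is off by default). Degenerate inputs are decided by contract, not
  arithmetic: zero pooled variance with equal means is a clean pass
  (t = 0, p = 1); zero pooled variance with different means is a certain
  rejection (p = 0) flagged as degenerate.
* **Conversion controls.** A fully methylated and a fully unmethylated
  control DNA are carried through the assay. The methylated control must
  score at least 0.9 and the unmethylated at most 0.1 at every locus;
  these bounds are this package's defaults (no community-standard numeric
  criterion exists) and are configurable. An absent locus in a control is
  unevaluable and raises a warning rather than silently passing.
* **Averaging** is the plain arithmetic mean over the replicates in which
  a locus was measurable; no inverse-variance weighting, since
  replicate-level variance estimates from two-by-two designs are too
  unstable to weight by.

## Data structures

Averaged profiles and ages live in a `MethCohort`, a thin
`SummarizedExperiment` subclass: the `methylation` assay is a 5 × n
matrix (loci in the canonical order `locusOrder()`), `colData` carries
`age_years` and `sex`. Models are `AgeModel` objects whose JSON
serialisation writes every value as the shortest decimal string that
parses back to the identical double — so the published constants survive
a round trip character-for-character, and fitted models round-trip
bit-exactly.

## Evaluation metrics

* **MAD** — the mean of |predicted − chronological| in years, overall and
  within inclusive integer age bins 23–30, 31–40, 41–50, 51–60, 61–70
  (ages outside every bin are reported under `"other"`). The n-weighted
  per-bin MADs recompose the overall MAD exactly.
* **Per-locus Pearson r** between methylation level and age, undefined
  (`NA` with a warning) under zero variance or fewer than three pairs.
* **R²** — defined as the *squared Pearson correlation* between predicted
  and chronological age, i.e. the R² of the fitted line through the
  prediction scatter, not 1 − SSE/SST against the identity line. The two
  differ for a biased predictor: a test set can show a higher
  correlation-R² than the training set while its predictions sit off the
  identity line. This definition matches how scatterplot regression lines
  are usually annotated in this assay literature.

## The synthetic generator

Cohort data of this kind are rarely depositable, so the package carries a
seeded generator used by all tests. It emulates:

* ages drawn as integers uniformly on 23–70 years (studies of this design
  report integer ages and integer-endpoint bins; no empirical age
  distribution is claimed beyond the range);
* true per-locus levels linear in age,
  $x_l = \mathrm{clamp}_{[0,1]}(b_{0l} + b_{1l}\,\text{age} +
  \varepsilon)$, $\varepsilon \sim N(0, \sigma_l^2)$, with defaults in
  `inst/extdata/default-sim-config.yaml` calibrated so the realized
  per-locus |r| at n = 60 falls in the moderate band (≈0.28–0.60) typical
  of single-locus buccal markers — C1orf132 declines with age, hence its
  negative slope and negative correlation;
* the 2 × 2 replicate design with per-replicate technical noise
  (default SD 0.01, a realistic percent-scale SNaPshot repeatability;
  designs like this one publish no replicate variance, so this is a free
  parameter), an optional between-conversion shift for power studies, and
  peak intensities built from a log-normal total (mean 4000 RFU, SD 1200)
  split between the two channels with multiplicative noise (CV 0.05),
  rounded to integer RFU and capped at a 32000 RFU instrument ceiling;
* fully methylated (0.98) and unmethylated (0.02) control samples.

What it deliberately does **not** emulate: PCR amplification bias, dye
mobility shifts, stutter, incomplete bisulfite conversion chemistry and
degradation dropout. Tests passing on these simulations therefore
establish that the *computational* chain is correct and well-calibrated,
not that the assay itself performs at any particular accuracy on real
swabs.

## Numerical and design choices

* OLS is solved by QR (`lm.fit`); rank deficiency and n < 7 complete
  samples are hard errors, incomplete profiles are excluded with a
  message.
* `splitCohort` draws a simple random partition (`ceiling(n·f)` to
  training) under a caller-supplied seed, restoring the global RNG state
  afterwards; age-stratified splitting is available but off by default
  because a plain random split is the usual validation design here.
* Duplicate peaks in one dye channel resolve deterministically: prefer
  peaks inside the locus fragment-size window, then the tallest, ties to
  the smaller fragment.
* No minimum peak-height threshold is imposed by default (configurable
  via `minHeight`), and predictions are never clamped — an implausible
  output (negative, or far above 100) is itself diagnostic, e.g. of a
  model transferred from the wrong tissue, and is reported with a
  message.
* External linear models can be loaded from the model-JSON format
  (`readAgeModel()`), but only the buccal five-locus model is bundled;
  bundling models whose coefficients we cannot verify would invite silent
  misuse across tissues.

## A full run

Problem sizes here mirror the assumed study design (60 samples, 4
replicates); everything below runs in a few seconds.

```{r pipeline, eval = FALSE}
cfg <- syntheticConfig(seed = 20)          # 60 samples, defaults
paths <- simulateStudy(tempdir(), cfg)     # metadata + truth + peaks

peaks <- readPeakTable(paths$peaks)
levels <- quantifyPeakTable(peaks)         # peak ratios, height as I

samples <- levels[!grepl("^CTRL", levels$sample_id), ]
cohortHomogeneity(samples)                 # conversion-batch QC per locus

avg <- averageReplicates(samples)
meta <- readCohortMetadata(paths$metadata)
cohort <- MethCohort(avg, age = meta)

parts <- splitCohort(cohort, 0.5, seed = 20)
fit <- fitAgeModel(parts$training)
evaluatePredictions(parts$test, model = fit)
```

## Limitations

The bundled published model is tissue- and population-specific (Italian
adult buccal swabs); applying it elsewhere is exactly the misuse the
prediction-range message is there to flag. The generator's linear
level–age model ignores the curvature some loci show at the extremes of
life, which is acceptable over 23–70 but not outside it. MAD carries no
confidence interval here, and correlations carry no tests — with n = 30
per split those intervals would be wide, and the package reports only
what the estimators themselves deliver.
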