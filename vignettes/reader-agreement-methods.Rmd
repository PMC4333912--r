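---
title: "Agreement analysis for digital-vs-optical IHC reader studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Agreement analysis for digital-vs-optical IHC reader studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathagree)
```

## The problem

When a laboratory considers replacing the light microscope with whole-slide
imaging for immunohistochemistry (IHC) scoring, the question is not whether
digital reads match a gold standard — for semi-quantitative IHC there is
none — but whether pathologists agree with *each other* under the digital
modality as well as they do under the optical one, and whether each
pathologist agrees with *themselves* across the two modalities.
`pathagree` implements that agreement analysis for multi-reader
multi-case (MRMC) studies in which every reader scores every case under
both modalities, for two scoring tasks:

* **HER2**: an ordinal categorical score in {0, 1+, 2+, 3+} plus an
  integer "continuous" score in [0, 100], binned at 25/50/75 (0–24 is 0,
  25–49 is 1+, 50–74 is 2+, 75–100 is 3+);
* **Ki-67**: a binary positive/negative call — positive iff strictly more
  than 10% of tumor cells stain — plus the continuous percentage, valid
  only when enough tumor cells are present (at least 500 on a whole
  slide, 100 in a TMA core).

Cases come in two specimen formats: whole slides (the reader searches the
section and integrates fields into one score) and tissue-microarray (TMA)
cores (a predefined field of view).

## Agreement statistics

Two measures are computed on every pair of aligned score vectors.

**Kendall's tau-b.** With $n$ cases there are $n_0 = n(n-1)/2$ case
pairs; $C$ of them are concordant (the two score vectors order the pair
the same way), $D$ discordant, and $n_1$, $n_2$ are tied within the first
and second vector respectively. Then
$$\tau_b = \frac{C - D}{\sqrt{(n_0 - n_1)(n_0 - n_2)}}.$$
`kendall_tau_b()` returns the full integer decomposition, computed in
exact arithmetic with the division performed last. When either vector is
constant a denominator factor vanishes and the statistic is *undefined* —
deliberately not 0 and not silently `NaN`; undefined values propagate as
an explicit state and are dropped (and counted) wherever pair values are
averaged. Integer scores produce many ties; no continuity correction is
applied.

**Percent correct agreement.** The overall form is the percentage of
cases on which two categorical vectors coincide. The category-specific
form for category $k$ divides the number of cases scored $k$ by *both*
readers by the number scored $k$ by *at least one* of them (a
Jaccard-style ratio), and is undefined when $k$ appears in neither
vector. `disagreement_crosstab()` gives the underlying $K \times K$
table with row-normalized percentages, the form behind statements like
"x% of cores scored 1+ under optical were scored 2+ under digital".

Tau-b on *categorical* scores is reported for the 4-level HER2 scale but
marked not-reported for binary scales such as Ki-67: with two levels the
tie counts dominate $n_0$ and the statistic, though usually finite,
carries little information. This is a reporting policy of
`build_report()`; `kendall_tau_b()` itself will happily compute it.

## Estimands

* **Interobserver agreement** (per modality): the metric is computed on
  every unordered pair of readers and averaged, unweighted, over the
  pairs with a defined value. Averaging pairs — rather than pooling cases
  across pairs — keeps every pair's contribution equal regardless of how
  many cases the two readers jointly scored; whether a complete-case
  weighting would be preferable is genuinely open, and the unweighted
  choice is ours.
* **Intermodality agreement**: per reader, the metric between that
  reader's optical and digital vectors, averaged unweighted over readers.
* **Difference**: interobserver(optical) minus interobserver(digital),
  with a paired bootstrap (both arms recomputed on the same resample).

## Missing data and exclusions

Readers may *defer* a score when a sample is inadequate. Three rules
apply, in order:

1. **Sufficiency** (`apply_sufficiency_rule()`): Ki-67 scores flagged as
   lacking tumor cells are masked to missing. Insufficiency stays
   distinguishable from deferral in the data file but collapses to the
   same missing state in analysis.
2. **Majority-deferral exclusion** (`exclude_majority_deferred()`): a
   case deferred by strictly more than half of the readers is removed
   entirely. "Strictly more than half" is our reading of "majority" — 4
   of 8 retains the case, 5 of 8 removes it. By default a reader counts
   as deferring if they deferred the case in *either* modality, giving
   one exclusion set per (biomarker, format); assessment within each
   modality separately is available via `majority_rule = "per_modality"`.
   The pooled default reflects that a study reports a single set of
   excluded cores per TMA; it is a configuration choice, not a claim
   about any particular study's procedure.
3. **Pairwise-complete deletion** (`pairwise_complete()`): every pairwise
   comparison is restricted to the cases scored by both units; a unit
   pair with fewer than two complete cases is flagged undefined. No
   imputation, ever.

The exclusion report prints the possible-score accounting per stratum as
readers × retained cases (e.g. 8 × 88 = 704) with residual deferral
counts, so the bookkeeping can be checked against the study design at a
glance.

Categorical and continuous scores are stored independently: readers
record both, and their recorded category can disagree with the bin of
their continuous score. The parser warns and `consistency_report()`
lists the records, but nothing is overwritten — the data keeps whatever
the readers said.

## Bootstrap confidence intervals

Every reported estimate carries a percentile CI from a **two-way
bootstrap**: readers and cases are resampled independently with
replacement (duplicates carried as distinct units), the estimand is
recomputed on each of B resampled studies, and the CI is the inverse-ECDF
(type-1) quantile interval of the defined replicates. Design details:

* Pairs formed from two copies of the same original reader are excluded
  from pairwise averages — self-pairs agree perfectly and would bias the
  average upward. A reader draw that leaves no valid pair is redrawn (up
  to `max_redraws`), then dropped.
* The point estimate always comes from the original data, never from the
  replicate mean.
* Replicates with an undefined statistic are dropped and counted; if more
  than half of B are undefined the CI itself is reported undefined.
* One global seed; each named statistic derives its own substream from
  (seed, statistic name), so adding a statistic to a report never
  perturbs the replicates of another, and repeated runs are
  byte-identical. Within a stratum, each metric family (e.g. both
  modality arms and their difference) shares one replicate stream, which
  is also what makes the difference CI paired.

The specific two-way scheme is our design choice: it is the simplest
resampling plan that exposes both case and reader variability. A *known
limitation* follows from it: for rank-based metrics that are invariant
to systematic reader shifts (tau-b is unchanged by any monotone
per-reader transform), the reader axis contributes interval width
without a matching component in the estimand's sampling variance, so
tau-b intervals are conservative — in our own simulations at the default
generator settings (8 readers, 90 cores, B = 200), two-way intervals for
mean pairwise tau-b over-cover a long-run target that case-only
resampling covers at close to the nominal 95%. Percent-agreement metrics
do respond to reader-level shifts, and there the reader axis carries
real variance. We keep the two-way default for all metrics rather than
silently switching schemes per metric; `resample_readers = FALSE`
reproduces the case-only interval when a calibrated tau-b interval
matters more than reader generalization.

## The synthetic-study generator

No reader-level scores from any real study ship with this package, so
`generate_study()` provides the test bed: a latent-trait model with the
factor structure the analysis assumes — by default 8 readers, 25 whole
slides plus 97 TMA cores per biomarker, both modalities.

For case $c$, reader $r$, modality $m$:
$$\text{score}_{rcm} = \mathrm{round}\big(\mathrm{clamp}_{[0,100]}(\theta_c + b_r + \delta\,[m = \text{digital}] + \varepsilon_{rcm})\big)$$
with $b_r \sim N(0, \sigma_b^2)$, $\varepsilon \sim N(0, \sigma_e^2)$,
and $\delta$ the modality shift. The categorical score is derived from
the continuous one through the scale, so the generator's two score types
are consistent by construction (real readers need not be — the analysis
does not assume it). Rounding happens after all additive effects.

Latent distributions: HER2 draws a category bin from mixture weights
(default 0.3/0.2/0.2/0.3) and then a uniform value across the bin's
integer range, so that rounding cannot carry a latent across its own
category boundary; Ki-67 draws from a two-component normal mixture
(defaults: 6 ± 3 and 30 ± 15, equal weights) chosen to straddle the 10%
threshold and give a non-trivial positive/negative balance.

Deferral is a *case* property, independent of the score value: a
configurable fraction of cases is "inadequate" (default about 9 of 97
TMA cores, none of the whole slides) and deferred with high probability
(default 0.9) by each reader in each modality; adequate cases defer at a
low base rate (defaults 1.5% for HER2, 12% for Ki-67, the order of
magnitude a TMA study of this design reports). Defaults for the noise
scales are $\sigma_b = 5$, $\sigma_e = 12$ on the 0–100 scale, which
put HER2 mean pairwise tau-b near 0.7, in the range reported for that
task. The Ki-67 latent mixture concentrates at low percentages, as
proliferation indices typically do; its smaller spread relative to the
same noise yields lower rank agreement (tau-b near 0.45) while keeping
the binary task's percent agreement high — a reminder that tau-b and
percent agreement answer different questions on a compressed scale.

What the generator does *not* emulate: reader-specific noise levels or
experience effects, session/washout ordering, correlation between
deferral and true expression, non-Gaussian disagreement, and any image
content. Passing tests therefore demonstrate that the *pipeline* is
correct under a plausible data-generating process, not that any
particular real study's numbers are recoverable. The Gaussian noise
choice is isolated behind the config so alternative noise models can be
added without touching the analysis.

## Numerical choices

* All pair counts (C, D, ties) use exact integer arithmetic; tau-b's
  division is the last operation. For up to ~2000 cases a compiled
  pair-enumeration kernel is used; beyond that a contingency-table
  method with suffix sums, O(K²) in the number of distinct values, keeps
  million-case characterization runs cheap. Both paths are tested
  against an independent brute-force oracle.
* Undefined is a state, not a number: constant-vector tau-b, empty
  categories, and sub-2-case overlaps all propagate as `NA` plus a
  `defined`/count field, and report tables render them blank.
* Percentile CIs use type-1 (inverse ECDF) quantiles so the interval is
  always an observed replicate value and exhaustive-enumeration checks
  are exact.
* Report CSVs round tau-b to 2 decimals and percentages to 1;
  `report.json` keeps full precision and contains no timestamps, so a
  seeded run is byte-reproducible.

## Scale of the built-in checks

The test suite exercises the pipeline with, among others: 1,000
random tied vectors against the brute-force tau-b oracle; exhaustive
enumeration of all case resamples at n = 3 against a 50,000-replicate
Monte-Carlo run; 200 simulated studies (8 readers, 90 cores, B = 200)
for CI coverage against a 10⁶-case long-run target; 50 seeds each at 25
vs 90 cases for the CI-width ordering; and two full-scale end-to-end
runs (8 readers, 25 + 97 cases, 2 biomarkers, 2 modalities, B = 1000)
compared byte-for-byte. These sizes were chosen to make the checks
statistically meaningful while keeping a full suite run in the
single-digit minutes.

## Worked example

```{r example, eval = FALSE}
library(pathagree)

full <- generate_full_study(seed = 42)
report <- build_report(full$dataset,
                       bootstrap_config(B = 1000, seed = 17))
print(report)
write_report(report, "analysis_out/")

# or, from a score CSV on disk:
run_analysis("scores.csv", out = "analysis_out/", B = 1000, seed = 17)
```

## Known limitations

* Two-way percentile intervals are conservative for reader-shift
  invariant metrics (see above); BCa or scheme-per-metric calibration
  would be the natural extension point.
* "Majority" deferral pooling across modalities is a configurable
  interpretation, not a universal standard.
* The package draws no superiority or non-inferiority conclusions —
  it reports estimates with intervals; reading CI overlap is left to
  the analyst.
* Reader experience (board-certified vs resident) is not modeled or
  analyzed.
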