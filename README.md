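# pathagree

Agreement analysis for multi-reader multi-case (MRMC) validation studies
of digital pathology: does a panel of pathologists scoring
immunohistochemistry (IHC) biomarkers agree with each other as well on a
calibrated display as they do at the microscope, and does each
pathologist agree with themselves across the two viewing modalities?

The package is written for biostatisticians and imaging scientists
running (or re-analyzing) reader studies in which every reader scores
every case under both optical and digital review, for tasks such as:

* **HER2** membranous staining: ordinal {0, 1+, 2+, 3+} plus an integer
  "continuous" score in [0, 100] binned at 25/50/75;
* **Ki-67** nuclear staining: positive iff strictly >10% of tumor cells
  stain, plus the continuous percentage, evaluable only with enough
  tumor cells (>= 500 on a whole slide, >= 100 per TMA core);

on whole slides and on tissue-microarray (TMA) cores.

## What it computes

**Kendall's tau-b with full ties decomposition.** For n cases, n0 =
n(n-1)/2 case pairs with C concordant, D discordant, and n1/n2 tied
within either score vector:

    tau_b = (C - D) / sqrt((n0 - n1) * (n0 - n2))

computed in exact integer arithmetic, undefined (not zero) when a vector
is constant.

**Percent correct agreement**, overall (share of coinciding categorical
scores) and category-specific (cases scored k by *both* readers over
cases scored k by *at least one*), plus row-normalized disagreement
cross-tabulations ("x% of cores scored 1+ under optical were scored 2+
under digital").

**Study-level estimands**: interobserver agreement per modality
(unweighted mean over reader pairs), intermodality agreement (mean over
readers of each reader's self-agreement across modalities), and their
optical-minus-digital difference, each with a 95% CI from a **two-way
percentile bootstrap** that resamples readers and cases independently
with replacement (paired across modality arms; self-pairs of duplicated
readers excluded).

**Study hygiene**: cell-sufficiency masking, majority-deferral case
exclusion with readers-times-cases accounting, pairwise-complete
deletion, and a consistency report for records whose categorical score
disagrees with the bin of their continuous score.

A latent-trait **synthetic study generator** (`generate_study()`)
produces reader studies with this exact factor structure — by default 8
readers, 25 whole slides + 97 TMA cores per biomarker, both modalities,
with tunable reader bias, score noise, modality shift, and a case-level
deferral model — so the whole pipeline is testable without any
reader-level data, none of which is publicly available for studies of
this kind.

## Worked example

```r
library(pathagree)

# the full decomposition of the statistic, on a 4-case toy pair
kendall_tau_b(c(1, 2, 3, 3), c(1, 3, 2, 3))
#> <tau_b> n = 4, C = 3, D = 1, n0 = 6, n1 = 1, n2 = 1
#>   tau_b = 0.4000

# a full synthetic study and the complete report
full <- generate_full_study(seed = 42)
report <- build_report(full$dataset, bootstrap_config(B = 1000, seed = 17))
print(report)
#> <study_report> 8 readers, B = 1000, alpha = 0.05
#> -- HER2 / whole_slide (25 cases retained) --
#>   interobserver tau-b (cont): optical 0.69 [0.56, 0.79], digital 0.69 [0.55, 0.79]
#>   intermodality tau-b (cont): 0.68 [0.57, 0.78]
#>   interobserver percent agreement: optical 60.3, digital 60.4
#> -- HER2 / tma_core (88 cases retained) --
#>   interobserver tau-b (cont): optical 0.68 [0.62, 0.72], digital 0.69 [0.63, 0.73]
#>   intermodality tau-b (cont): 0.68 [0.63, 0.72]
#>   interobserver percent agreement: optical 62.1, digital 64.2
#> -- Ki67 / whole_slide (24 cases retained) --
#>   interobserver tau-b (cont): optical 0.45 [0.18, 0.64], digital 0.44 [0.23, 0.62]
#>   intermodality tau-b (cont): 0.47 [0.24, 0.65]
#>   interobserver percent agreement: optical 70.6, digital 67.6
#> -- Ki67 / tma_core (88 cases retained) --
#>   interobserver tau-b (cont): optical 0.44 [0.34, 0.53], digital 0.49 [0.39, 0.57]
#>   intermodality tau-b (cont): 0.48 [0.40, 0.57]
#>   interobserver percent agreement: optical 68.4, digital 72.4

write_report(report, "analysis_out/")   # report.json, tables/*.csv,
                                        # exclusions.json, run.log
```

Reading the output: each stratum (biomarker x specimen format) shows the
pairwise-averaged interobserver tau-b on continuous scores per modality
with its 95% bootstrap interval, the per-reader-averaged intermodality
tau-b, and overall percent agreement. Note the whole-slide intervals are
much wider than the TMA ones (25 vs ~90 cases) — the sampling-size
effect the report is designed to expose. The 88 retained TMA cases
reflect majority-deferral exclusions out of 97; `exclusions.json` and
`run.log` carry the full accounting (e.g. "0 of 704 possible (8 readers
x 88 cases)").

From a shell, the same pipeline runs via the thin wrappers:

```sh
Rscript inst/exec/simulate.R --out scores.csv --truth truth.json --seed 42
Rscript inst/exec/analyze.R --scores scores.csv --out analysis_out/ \
    --bootstrap 1000 --seed 17
```

See the vignette in `vignettes/reader-agreement-methods.Rmd` for the
model, the missing-data rules, the bootstrap design and its known
limitations, and the generator's assumptions.

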