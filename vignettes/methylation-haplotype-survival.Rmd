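---
title: "Methylation haplotype load, differential methylation and survival modelling for plasma cfDNA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methylation haplotype load, differential methylation and survival modelling for plasma cfDNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Metastatic castration-resistant prostate cancer (mCRPC) lacks validated
molecular prognostic markers. Plasma cell-free DNA (cfDNA) carries a
tumor-derived fraction (ctDNA) whose methylation patterns are
tumor-specific, and methylation changes affect runs of neighbouring CpGs
on the same DNA fragment, so read-level (haplotype) statistics can detect
tumor signal at ctDNA fractions where per-CpG averages drown in the
background of leukocyte-derived DNA. `mhlsurv` implements the full
analysis path from read-level methylation haplotypes to a prognostic
survival nomogram, together with a seeded synthetic cohort generator so
every stage is testable without access to patient data.

## The statistics

**Methylation haplotype blocks (MHBs).** Within each targeted region,
pooled reads from all patients define, for every adjacent CpG pair, a
count-weighted 2×2 table of methylation states. Its linkage
disequilibrium is

$$ r^2 = \frac{(p_{11} - p_a p_b)^2}{p_a(1-p_a)\,p_b(1-p_b)}, $$

with a 1-df chi-square p-value on $n r^2$. A block is a maximal run of
consecutive CpGs in which every adjacent pair has defined $r^2 > 0.3$,
$p < 0.05$ and at least `min_pair_reads` informative reads; runs shorter
than the core window of 3 CpGs are discarded. A monomorphic site leaves
$r^2$ undefined and breaks any block through it. Blocks are then
filtered to those with ≥ 3 CpGs and median read support strictly above
50 across samples; blocks in positive/negative control regions are
labelled and excluded from the differential analysis but kept for
quality reporting.

**Methylation haplotype load (MHL).** For one sample's reads restricted
to a block's member CpGs,

$$ \mathrm{MHL} = \frac{\sum_{i=1}^{L} i\, P(\mathrm{MH}_i)}{\sum_{i=1}^{L} i},
   \qquad L = \min(10, \text{longest pattern}), $$

where $P(\mathrm{MH}_i)$ is the count-weighted fraction of length-$i$
CpG substrings that are fully methylated. MHL lies in [0, 1] and
weights long consecutive runs, which is what distinguishes coherent
tumor-derived hypermethylation from scattered background methylation.

**Differential screen.** Blocks with mean MHL ≤ 0.05 in localized
disease form the candidate tumor-derived stratum (blocks already
methylated in localized disease likely carry non-tumor signal and are
analysed separately). Each stratum is tested localized-vs-mHSPC and
mHSPC-vs-mCRPC with two-sided Welch t-tests at raw p < 0.05, and the
two significant sets are intersected.

**Risk scores and nomogram.** Common DMRs are screened by univariate
Cox models (Efron ties); the top 20 by the mHSPC-vs-mCRPC Welch p with
Cox p < 0.05 are collapsed to one block per gene (highest hazard ratio,
leftmost start on ties) and combined into a composite score
$C = \sum_i \beta_i M_i$. A multivariable Cox model over the composite,
log2 clinical biomarkers and the raw predicted ctDNA fraction yields the
risk score $R = \sum_j \beta_j x_j$; patients strictly above the median
are high-risk. Backward stepwise selection (drop the largest Wald p
until all retained p < 0.05) defines the nomogram model: each predictor
is mapped affinely to points so the strongest ($\max_j |\beta_j| \cdot
\mathrm{range}_j$) spans 0–100, total points are an affine bijection of
the linear predictor, and survival at 6/12/24 months is
$S_0(t)^{\exp(lp - lp_{\text{mean}})}$ with $S_0$ the Breslow baseline.
Discrimination is the cumulative-case/dynamic-control AUC with inverse
probability of censoring weights (Kaplan–Meier censoring estimator).

## Running the analysis

```{r}
library(mhlsurv)
res <- simulate_then_run(cohort_config(seed = 1))
res$bundle$funnel        # discovery -> filter -> DMR -> panel counts
res$recovery             # comparison against the simulated ground truth
```

The numbered scripts under `analysis/` run the same stages from files
(`01_simulate_cohort.R` … `06_nomogram.R`), writing tables under
`results/`.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `r2_cutoff`, `core_window`, `p_cutoff` | 0.3, 3, 0.05 | adjacent-pair LD block criterion |
| `min_pair_reads` | 10 | informative reads below which a pair fails (r² from fewer reads is noise; not stated by the source analysis, exposed here) |
| `min_cpgs`, `min_median_reads` | 3, 50 | block filter; the read bound is strict (median exactly 50 fails) |
| `max_missing_frac` | 0.8 | strict missingness bound on block columns |
| `k_neighbors` | 5 | KNN imputation neighbours (method named, k unstated by the source; standard default) |
| `localized_threshold` | 0.05 | stratification bound, inclusive into the low stratum |
| `alpha` | 0.05 | raw significance level of every screen (no multiplicity gate; a BH column is reported but never used) |
| `top_k` | 20 | panel size before the gene collapse |
| `min_fraction`, `min_nonmissing`, `r_cutoff` | 0.01, 0.5, 0.5 | ctDNA correlation screen: patients at ≤ 1% fraction excluded, > 50% observed values required, flags at r > 0.5 and p < alpha |
| `horizons` | 6, 12, 24 months | nomogram / AUC evaluation times |

## The synthetic world

`cohort_config()` states the cohort the analysis was designed around:
19 localized / 28 mHSPC / 49 mCRPC patients; 366 target, 29
positive-control and 42 negative-control regions; negative-binomial
depth with mean 96; an mCRPC ctDNA-fraction mixture placing about 17 of
49 patients below 1%; positive controls ~98% methylated per CpG and
negative controls ~0.2%.

Choices neither source states, fixed once as what a practitioner would
call realistic and not revisited:

* **Read coherence.** Each read draws a single methylation propensity
  from a Beta mixture (tumor reads centred at 0.85, background at 0.03)
  with within-read correlation `coherence = 0.67`; CpG calls are then
  conditionally independent. This produces the near-all-0 / near-all-1
  reads that MHL is designed to reward, and gives background regions
  adjacent-pair r² ≈ 0.45, so blocks exist cohort-wide — as in real
  cfDNA, where the screen's null blocks are discovered structures, not
  artifacts. An i.i.d. per-CpG background would leave non-planted
  regions blockless and make the null screen untestable.
* **Non-tumor methylation.** 20% of non-planted target regions carry
  constitutively elevated background methylation (propensity 0.35) in
  every disease state, standing in for leukocyte-derived signal; these
  populate the high-localized stratum that the screen sets aside, as a
  real cohort's does.
* **Disease-state fractions.** Localized U(0, 0.01); mHSPC U(0, 0.10);
  mCRPC a 17/49 : 32/49 mixture of U(0, 0.01) and a Beta(1.2, 3) scaled
  to (0.01, 0.7).
* **Survival.** Weibull proportional hazards with shape 1.3 and
  baseline median 110 months; log-hazard 6·fraction + 4·(expected DMR
  methylation), administrative censoring at the 47-month follow-up
  horizon plus 15% uniform early dropout. This yields mCRPC event
  counts near the reported 34/49 and deceased medians under 20 months.
* **Biomarkers.** PSA/LDH/ALP log-normal and increasing in fraction;
  hemoglobin/albumin weakly decreasing; the "predicted" fraction is the
  true fraction with 10% log-normal noise (the external predictor is an
  input, not simulated).

What the generator does **not** emulate: fragment-length and
copy-number signal, sequence context, batch effects, per-patient depth
correlation across regions, and non-proportional hazards. A green test
therefore establishes that the pipeline recovers the structure it
assumes, not that the published cohort's numbers are reproduced — those
depend on undeposited patient data.

## Numerical conventions

* Missing is distinct from zero throughout: a cell is missing exactly
  when no read informs the block, and empty input to `mhl()` returns
  `NA`.
* Substring lengths with no observed substring are omitted from both
  sums of the MHL ratio rather than counted as $P = 0$, so shallow
  samples are not deflated for lacking long reads.
* KNN distances are Euclidean over mutually observed, per-column
  standardised values, scaled by the number of shared columns; imputed
  values are clipped to [0, 1]; with fewer than k donors all available
  are used with a warning.
* Welch tests with a zero pooled standard error return p = 1 when the
  means agree and are flagged degenerate otherwise.
* Risk-score ties at the median go to the low-risk group ("greater than
  the median" read literally).
* KM median is the first time the curve reaches 0.5 or below; a group
  that never does is reported as not reached.
* The nomogram's point maps are exact affine functions; tabulations are
  for rendering only. Out-of-range covariates are clipped with an
  extrapolation warning. Baseline interpolation is right-continuous
  step.
* Stepwise selection is backward by default (forward available);
  perfectly collinear duplicates resolve to the first by input order.

## Design choices where the source was open

* The MHBDiscovery "p-value cutoff" is interpreted as a chi-square
  significance filter on each adjacent pair's LD — a documented
  decision, not an inferred fact about the original tool.
* The "top 20" panel ranking key is the mHSPC-vs-mCRPC Welch p-value
  (the transition that defines castration resistance); alternatives can
  be supplied by reordering the candidate table.
* The ctDNA fraction enters Cox models untransformed; its reported
  hazard-ratio magnitude in the source analysis is only consistent with
  a raw 0–1 scale.
* The IPCW (Uno-type) estimator is used for the time-dependent AUC;
  the source names only "time-dependent ROC".

## Scaling in the test suite

The acceptance checks that need many replicate cohorts keep the default
patient numbers and planted effect sizes but shrink region counts and
depth to desk-scale runtimes (null calibration: 10,000 4-CpG regions at
depth 24 across four seeds — depth chosen beforehand to preserve Welch
calibration; planted recovery: 30 regions at depth 60 over 20 seeds;
risk stratification: 12 regions at depth 40 over 100 seeds). The
log-rank/Cox score-test identity is asserted on untied survival times,
since the classical equivalence does not survive tied event times.

## Limitations

Raw p < 0.05 screening without multiplicity control matches the source
analysis but inflates family-wise error; the BH column is reported for
users. Cohort-level block discovery means block boundaries depend on
cohort composition. The nomogram extrapolates by clipping, and with 49
patients and ~34 events multivariable models with five predictors are
near the conventional events-per-variable limit — the same caveat the
source analysis carries.
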