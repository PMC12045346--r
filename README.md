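# mhlsurv

Prognostic analysis of targeted plasma cell-free DNA (cfDNA) methylation
in prostate cancer, from read-level methylation haplotypes to a survival
nomogram. The package is written for analysts working with mHap-style
read-level methylation data across disease states (here: localized
prostate cancer, metastatic hormone-sensitive [mHSPC], and metastatic
castration-resistant [mCRPC]) who need the whole chain — block
discovery, haplotype-load quantification, differential screening, risk
modelling — as tested, reusable functions rather than a one-off script
pile.

## What it computes

* **Methylation haplotype blocks (MHBs):** maximal runs of ≥ 3
  consecutive CpGs whose adjacent pairs are in linkage disequilibrium
  across the pooled reads of the whole cohort,
  `r² = (p₁₁ − pₐp_b)² / (pₐ(1−pₐ)p_b(1−p_b)) > 0.3` with a 1-df
  chi-square p < 0.05, then filtered to ≥ 3 CpGs and median read
  support strictly > 50.
* **Methylation haplotype load (MHL):** per sample and block,
  `MHL = Σᵢ i·P(MHᵢ) / Σᵢ i` over substring lengths i = 1..10, where
  `P(MHᵢ)` is the count-weighted fraction of fully methylated length-i
  CpG substrings. Cells with no informative read are missing, not
  zero; blocks > 80% missing are dropped and the rest KNN-imputed.
* **Differential screen:** blocks with localized mean MHL ≤ 0.05 are
  tested localized-vs-mHSPC and mHSPC-vs-mCRPC (two-sided Welch,
  raw p < 0.05) and the significant sets intersected.
* **Risk modelling:** univariate Cox per common DMR; a gene-unique
  top-20 panel; composite score `C = Σ βᵢMᵢ`; a multivariable risk
  score over composite, log2 clinical biomarkers (PSA/LDH/ALP) and raw
  predicted ctDNA fraction, median-split with Kaplan–Meier/log-rank;
  Pearson screen of MHL against ctDNA fraction (patients > 1% only).
* **Nomogram:** backward-stepwise multivariable Cox; points scaled so
  the strongest predictor spans 0–100; 6/12/24-month survival from the
  Breslow baseline; discrimination by IPCW time-dependent ROC AUC.

A seeded synthetic-cohort generator (`cohort_config()`,
`generate_cohort()`) emulates the statistical structure this analysis
assumes — three disease states (n = 19/28/49), ctDNA-fraction-scaled
coherent hypermethylation in a subset of regions, > 95% / < 0.5%
methylated control regions, ~96× depth, and Weibull proportional-hazards
survival — with ground truth emitted separately so recovery can be
scored. See the methods vignette
(`vignettes/methylation-haplotype-survival.Rmd`) for the model, the
synthetic world and its limits, and every numerical convention.

## Worked example

The numbered drivers under `analysis/` run the whole study on a
simulated cohort, writing tables under `results/`:

```sh
Rscript analysis/01_simulate_cohort.R 1   # seed 1
Rscript analysis/02_discover_blocks.R
Rscript analysis/03_mhl_matrix.R
Rscript analysis/04_dmr_screen.R
Rscript analysis/05_survival_risk.R
Rscript analysis/06_nomogram.R
```

Output of that exact run:

```
cohort: 96 patients, 437 regions, 4,031,570 reads
mCRPC patients at <=1% ctDNA fraction: 20 of 49
discovered 367 MHBs; 366 pass the CpG/read filter (1 dropped)
controls: positive median methylation 0.980, negative 0.00202
strata: 309 low-localized MHBs, 57 high-localized
low stratum DMRs: 79 (localized vs mHSPC), 86 (mHSPC vs mCRPC), 70 common
common DMRs with positive shift in both comparisons: 70 of 70
panel: 20 gene-unique MHBs from 70 common DMRs
median survival: high-risk 11.3 vs low-risk not reached months (log-rank p = 1.7e-07)
ctDNA screen: 29 eligible patients (> 1% fraction); 23.2% of tested MHBs correlate (r > 0.5, p < 0.05)
stepwise-retained predictors: composite
time-dependent AUC: 0.90 at 6 months, 0.91 at 12 months, 0.88 at 24 months
```

Reading it: the control regions behave as designed (sequencing sanity
check); most blocks are unmethylated in localized disease and 70 of
them hypermethylate monotonically toward mCRPC; the MHB composite built
from those blocks separates mCRPC survival sharply (high-risk median
11.3 months versus not reached) and carries most of the prognostic
signal — the stepwise model keeps the composite over the clinical
biomarkers — with time-dependent AUC around 0.9 at all three horizons.

The same analysis runs in one call from R:

```r
library(mhlsurv)
res <- simulate_then_run(cohort_config(seed = 1))
res$bundle$funnel   # stage-by-stage record counts
res$recovery        # DMR recall/precision, planted-hazard recovery, KM split
```

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the pipeline end-to-end on a freshly simulated default-scale
cohort under the given seed (discovery → MHL → DMR screen → risk
scores → nomogram), prints the stage funnel and the ground-truth
recovery summary, and writes the JSON report to `--out`.
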