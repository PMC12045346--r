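#!/usr/bin/env Rscript
# Stage 4: differential-methylation screen across disease states.
#
# Blocks are stratified by their mean MHL in localized disease (<= 0.05:
# candidate tumor-derived signal; > 0.05: candidate non-tumor signal,
# e.g. leukocyte-derived), then tested localized-vs-mHSPC and
# mHSPC-vs-mCRPC with two-sided Welch t-tests at raw p < 0.05, and the
# two significant sets intersected.

suppressPackageStartupMessages(library(mhlsurv))

out <- "results"
clinical <- as.data.frame(data.table::fread(
  file.path(out, "cohort", "clinical.csv")))
m3 <- read_mhl_matrix(file.path(out, "mhl_imputed.tsv"))
clinical <- clinical[match(m3$sample_ids, clinical$sample_id), ]

params <- pipeline_params()
strata <- stratify_by_localized(m3, clinical$state,
                                params$localized_threshold)
scr <- run_dmr_screen(m3, clinical$state, strata, alpha = params$alpha)
for (stratum in c("low", "high")) {
  res <- scr[[stratum]]$results
  if (nrow(as.data.frame(res))) {
    data.table::fwrite(res, file.path(out, sprintf("dmr_%s.tsv", stratum)),
                       sep = "\t")
  }
  writeLines(scr[[stratum]]$intersection,
             file.path(out, sprintf("dmr_%s_common.txt", stratum)))
}

cat(sprintf("strata: %d low-localized MHBs, %d high-localized\n",
            length(strata$low_localized), length(strata$high_localized)))
cat(sprintf("low stratum DMRs: %d (localized vs mHSPC), %d (mHSPC vs mCRPC), %d common\n",
            length(scr$low$significant$localized_vs_mhspc),
            length(scr$low$significant$mhspc_vs_mcrpc),
            length(scr$low$intersection)))
cat(sprintf("high stratum DMRs: %d and %d, %d common\n",
            length(scr$high$significant$localized_vs_mhspc),
            length(scr$high$significant$mhspc_vs_mcrpc),
            length(scr$high$intersection)))
shared <- scr$low$results[scr$low$results$mhb_id %in%
                            scr$low$intersection, ]
cat(sprintf("common DMRs with positive shift in both comparisons: %d of %d\n",
            sum(tapply(shared$mean_diff > 0, shared$mhb_id, all)),
            length(scr$low$intersection)))
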