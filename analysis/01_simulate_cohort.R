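#!/usr/bin/env Rscript
# Stage 1: simulate the plasma cfDNA methylation cohort.
#
# Emulates the study's stated world: 19 localized / 28 mHSPC / 49 mCRPC
# patients, 366 prostate-cancer target regions plus 29 positive and 42
# negative controls, ~96x mean depth, ctDNA-fraction-scaled coherent
# hypermethylation in a subset of target regions, and Weibull
# proportional-hazards survival driven by tumor burden.  Ground truth
# (true fractions, planted DMR flags, true risks) is written alongside
# but never read by later stages.
#
# Usage: Rscript analysis/01_simulate_cohort.R [seed]

suppressPackageStartupMessages(library(mhlsurv))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[[1]]) else 1L
out <- file.path("results", "cohort")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- cohort_config(seed = seed)
sim <- generate_cohort(cfg, out_dir = out)
data.table::fwrite(sim$truth_regions[c("name", "gene")],
                   file.path(out, "region_genes.tsv"), sep = "\t")

n_reads <- sum(vapply(sim$cohort, read_mass, numeric(1)))
lowfrac <- sum(sim$truth_patients$true_fraction[
  sim$truth_patients$state == "mCRPC"] <= 0.01)
cat(sprintf("cohort: %d patients, %d regions, %s reads\n",
            nrow(sim$clinical), nrow(sim$regions),
            format(n_reads, big.mark = ",")))
cat(sprintf("mCRPC patients at <=1%% ctDNA fraction: %d of %d\n",
            lowfrac, sum(sim$clinical$state == "mCRPC")))
cat(sprintf("mCRPC deaths observed: %d\n",
            sum(sim$clinical$os_event[sim$clinical$state == "mCRPC"])))
cat("wrote", out, "\n")
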