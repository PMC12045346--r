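#!/usr/bin/env Rscript
# Stage 2: discover methylation haplotype blocks (MHBs).
#
# Pools every patient's reads and scans each target region for maximal
# runs of consecutive CpGs whose adjacent pairs are in linkage
# disequilibrium (r^2 > 0.3, chi-square p < 0.05, >= 10 informative
# reads), then filters to blocks with >= 3 CpGs and median read support
# strictly above 50, labelling blocks in control regions.

suppressPackageStartupMessages(library(mhlsurv))

out <- "results"
cohort_dir <- file.path(out, "cohort")
regions <- read_regions(file.path(cohort_dir, "regions.tsv"),
                        file.path(cohort_dir, "cpg_map.tsv"))
files <- sort(list.files(file.path(cohort_dir, "haplotypes"),
                         full.names = TRUE))
cohort <- lapply(files, read_haplotypes, regions = regions)

params <- pipeline_params()
blocks_all <- discover_mhbs_cohort(cohort, regions,
                                   r2_cutoff = params$r2_cutoff,
                                   core_window = params$core_window,
                                   p_cutoff = params$p_cutoff,
                                   min_pair_reads = params$min_pair_reads)
supp <- block_read_support(cohort, blocks_all)
blocks <- filter_mhbs(blocks_all, supp, min_cpgs = params$min_cpgs,
                      min_median_reads = params$min_median_reads)
write_mhbs(blocks, file.path(out, "mhbs.bed"),
           file.path(out, "mhbs_cpgs.tsv"))

cat(sprintf("discovered %d MHBs; %d pass the CpG/read filter (%d dropped)\n",
            nrow(blocks_all), nrow(blocks), attr(blocks, "n_dropped")))
cat(sprintf("of these, %d overlap control regions and are excluded from the differential analysis\n",
            sum(blocks$is_control)))
cat(sprintf("MHB span: mean %.0f bp, mean %.1f CpGs\n",
            mean(blocks$end - blocks$start), mean(blocks$n_cpgs)))
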