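#!/usr/bin/env Rscript
# Stage 3: methylation haplotype load (MHL) per sample and block.
#
# MHL is the i-weighted mean over substring lengths i = 1..10 of the
# fraction of fully methylated length-i CpG substrings; cells with no
# informative read are missing (not zero).  Blocks with > 80% missing
# values are excluded and the remainder KNN-imputed (k = 5).  Control
# regions are summarised separately as a sequencing-quality report.

suppressPackageStartupMessages(library(mhlsurv))

out <- "results"
cohort_dir <- file.path(out, "cohort")
regions <- read_regions(file.path(cohort_dir, "regions.tsv"),
                        file.path(cohort_dir, "cpg_map.tsv"))
files <- sort(list.files(file.path(cohort_dir, "haplotypes"),
                         full.names = TRUE))
cohort <- lapply(files, read_haplotypes, regions = regions)
blocks <- read_mhbs(file.path(out, "mhbs_cpgs.tsv"), regions)

params <- pipeline_params()
m <- build_mhl_matrix(cohort, blocks[!blocks$is_control, , drop = FALSE])
write_mhl_matrix(m, file.path(out, "mhl_matrix.tsv"),
                 file.path(out, "mhl_read_support.tsv"))
m2 <- drop_high_missingness(m, params$max_missing_frac)
m3 <- suppressWarnings(knn_impute(m2, k = params$k_neighbors))
write_mhl_matrix(m3, file.path(out, "mhl_imputed.tsv"))

# control report: per-CpG methylation of positive / negative regions
ctrl <- regions[regions$class != "target", , drop = FALSE]
cb <- regions_as_blocks(ctrl)
cm <- build_mhl_matrix(cohort, cb)
pool <- pool_haplotypes(cohort)
rep_tab <- data.frame(
  region = cb$region_name, class = cb$region_class,
  median_mhl = apply(cm$values, 2, median, na.rm = TRUE),
  mean_methylation = vapply(cb$region_name, function(rn) {
    rr <- pool[pool$region == rn, ]
    mean_methylation(rr$pattern, rr$count)
  }, numeric(1)))
data.table::fwrite(rep_tab, file.path(out, "control_report.tsv"),
                   sep = "\t")

cat(sprintf("MHL matrix: %d samples x %d MHBs, %.1f%% missing\n",
            nrow(m$values), ncol(m$values), 100 * mean(is.na(m$values))))
cat(sprintf("%d MHBs dropped for >80%% missingness; %d cells imputed\n",
            attr(m2, "n_dropped"), sum(is.na(m2$values))))
cat(sprintf("controls: positive median methylation %.3f, negative %.5f\n",
            median(rep_tab$mean_methylation[rep_tab$class ==
                                              "positive_control"]),
            median(rep_tab$mean_methylation[rep_tab$class ==
                                              "negative_control"])))
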