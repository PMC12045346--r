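#!/usr/bin/env Rscript
# Stage 5: survival analysis in the mCRPC group.
#
# Univariate Cox per common DMR; reduce to a gene-unique panel of the
# top 20 (highest-HR block per gene); composite score C = sum(beta * M);
# multi-modal risk score over composite, log2 clinical biomarkers and
# raw ctDNA fraction; median split with Kaplan-Meier / log-rank; Pearson
# screen of MHL against predicted ctDNA fraction (> 1% patients only).

suppressPackageStartupMessages(library(mhlsurv))

out <- "results"
cohort_dir <- file.path(out, "cohort")
clinical <- as.data.frame(data.table::fread(
  file.path(cohort_dir, "clinical.csv")))
regions <- read_regions(file.path(cohort_dir, "regions.tsv"),
                        file.path(cohort_dir, "cpg_map.tsv"))
gene_map <- as.data.frame(data.table::fread(
  file.path(cohort_dir, "region_genes.tsv")))
blocks <- read_mhbs(file.path(out, "mhbs_cpgs.tsv"), regions)
m2 <- read_mhl_matrix(file.path(out, "mhl_matrix.tsv"),
                      file.path(out, "mhl_read_support.tsv"))
m3 <- read_mhl_matrix(file.path(out, "mhl_imputed.tsv"))
clinical <- clinical[match(m3$sample_ids, clinical$sample_id), ]
dmr_tab <- as.data.frame(data.table::fread(file.path(out, "dmr_low.tsv")))
common <- readLines(file.path(out, "dmr_low_common.txt"))

params <- pipeline_params()
mc <- which(clinical$state == "mCRPC")
time <- clinical$os_months[mc]
event <- clinical$os_event[mc]

fits <- lapply(common, function(id) {
  tryCatch(cox_univariate(m3$values[mc, id], time, event, name = id),
           error = function(e) NULL)
})
names(fits) <- common
ok <- !vapply(fits, is.null, logical(1))
uni <- do.call(rbind, lapply(fits[ok], function(f) {
  data.frame(mhb_id = f$name, beta = f$beta, hr = f$hr,
             ci_lower = f$ci_lower, ci_upper = f$ci_upper,
             p_value = f$p_value, flagged = f$flagged)
}))
data.table::fwrite(uni, file.path(out, "cox_univariate.tsv"), sep = "\t")

rk <- dmr_tab[dmr_tab$comparison == "mhspc_vs_mcrpc", ]
bi <- match(common[ok], blocks$mhb_id)
genes <- gene_map$gene[match(blocks$region_name[bi], gene_map$name)]
candidates <- data.frame(mhb_id = common[ok],
                         gene = ifelse(is.na(genes),
                                       blocks$region_name[bi], genes),
                         rank_p = rk$p_value[match(common[ok], rk$mhb_id)],
                         start = blocks$start[bi])
panel <- suppressWarnings(
  select_panel(candidates, fits[ok], top_k = params$top_k,
               alpha = params$alpha))
data.table::fwrite(panel, file.path(out, "panel.tsv"), sep = "\t")
cat(sprintf("panel: %d gene-unique MHBs from %d common DMRs (HR %.2f-%.2f)\n",
            nrow(panel), length(common), min(panel$hr), max(panel$hr)))

comp <- composite_score(panel, m3)[mc]
components <- data.frame(
  composite = comp,
  log2_psa = log2(clinical$psa[mc]),
  log2_ldh = log2(clinical$ldh[mc]),
  log2_alp = log2(clinical$alp[mc]),
  ctdna_fraction = clinical$ctdna_fraction[mc],
  row.names = clinical$sample_id[mc])
risk <- suppressWarnings(risk_score(components, time, event))
km <- km_logrank(risk$group, time, event)
data.table::fwrite(
  data.frame(sample_id = clinical$sample_id[mc], composite = comp,
             risk_score = risk$score,
             risk_group = as.character(risk$group)),
  file.path(out, "risk_scores.csv"))
data.table::fwrite(km$curves, file.path(out, "km_curves.tsv"), sep = "\t")
fmt_med <- function(x) if (is.na(x)) "not reached" else sprintf("%.1f", x)
cat(sprintf("median survival: high-risk %s vs low-risk %s months (log-rank p = %.2g)\n",
            fmt_med(km$medians[["high"]]), fmt_med(km$medians[["low"]]),
            km$p_value))

ctdna <- tryCatch(
  ctdna_correlation_screen(
    structure(list(values = m2$values[mc, , drop = FALSE],
                   read_support = m2$read_support[mc, , drop = FALSE],
                   sample_ids = m2$sample_ids[mc], mhb_ids = m2$mhb_ids),
              class = "mhl_matrix"),
    clinical$ctdna_fraction[mc], min_fraction = params$min_fraction,
    min_nonmissing = params$min_nonmissing, r_cutoff = params$r_cutoff,
    alpha = params$alpha),
  error = function(e) NULL)
if (!is.null(ctdna)) {
  data.table::fwrite(ctdna$table, file.path(out, "ctdna_screen.tsv"),
                     sep = "\t")
  cat(sprintf("ctDNA screen: %d eligible patients (> 1%% fraction); %.1f%% of tested MHBs correlate (r > 0.5, p < 0.05)\n",
              ctdna$n_eligible, 100 * ctdna$prop_flagged))
}
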