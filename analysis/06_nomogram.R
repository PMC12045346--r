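#!/usr/bin/env Rscript
# Stage 6: multi-modal survival nomogram and time-dependent ROC.
#
# Clinical biomarkers passing a univariate Cox gate (p < 0.05) enter a
# backward stepwise multivariable Cox model together with the MHB
# composite score and the predicted ctDNA fraction; the retained
# predictors define a points-based nomogram (strongest predictor spans
# 0-100) whose 6/12/24-month survival probabilities come from the
# Breslow baseline.  Discrimination is the IPCW time-dependent AUC.

suppressPackageStartupMessages(library(mhlsurv))

out <- "results"
clinical <- as.data.frame(data.table::fread(
  file.path(out, "cohort", "clinical.csv")))
risk_tab <- as.data.frame(data.table::fread(
  file.path(out, "risk_scores.csv")))
clinical <- clinical[match(risk_tab$sample_id, clinical$sample_id), ]
time <- clinical$os_months
event <- clinical$os_event

params <- pipeline_params()
clin <- data.frame(log2_psa = log2(clinical$psa),
                   log2_ldh = log2(clinical$ldh),
                   log2_alp = log2(clinical$alp))
uni_p <- vapply(names(clin), function(v) {
  tryCatch(cox_univariate(clin[[v]], time, event, v)$p_value,
           error = function(e) NA_real_)
}, numeric(1))
gated <- names(uni_p)[!is.na(uni_p) & uni_p < params$alpha]
cat(sprintf("clinical biomarkers passing the univariate gate: %s\n",
            if (length(gated)) paste(gated, collapse = ", ") else "none"))

candidates <- cbind(clin[gated],
                    composite = risk_tab$composite,
                    ctdna_fraction = clinical$ctdna_fraction)
sel <- suppressWarnings(
  stepwise_select(candidates, time, event, alpha = params$alpha,
                  direction = params$stepwise_direction))
if (sel$intercept_only) {
  stop("stepwise selection retained no predictor; no nomogram")
}
data.table::fwrite(sel$table, file.path(out, "nomogram_model.tsv"),
                   sep = "\t")
cat(sprintf("stepwise-retained predictors: %s\n",
            paste(sel$kept, collapse = ", ")))

spec <- build_nomogram(sel$fit, candidates[sel$kept],
                       horizons = params$horizons)
write_nomogram(spec, file.path(out, "nomogram.json"))

lp <- drop(as.matrix(candidates[sel$kept]) %*% sel$table$beta)
auc <- lapply(params$horizons, function(h) {
  time_dependent_auc(lp, time, event, h)
})
auc_tab <- data.frame(horizon_months = params$horizons,
                      auc = vapply(auc, `[[`, numeric(1), "auc"),
                      n_cases = vapply(auc, `[[`, numeric(1), "n_cases"),
                      n_controls = vapply(auc, `[[`, numeric(1),
                                          "n_controls"))
data.table::fwrite(auc_tab, file.path(out, "auc.tsv"), sep = "\t")
cat("time-dependent AUC:",
    paste(sprintf("%.2f at %g months", auc_tab$auc,
                  auc_tab$horizon_months), collapse = ", "), "\n")

# worked example: one patient read off the nomogram
p1 <- as.list(candidates[1, sel$kept, drop = FALSE])
pts <- nomogram_points(spec, p1)
cat(sprintf("example patient %s: total points %.1f; predicted survival %s\n",
            risk_tab$sample_id[1], pts[["total"]],
            paste(sprintf("%.2f@%gm",
                          vapply(params$horizons, function(h) {
                            predict_survival(spec, p1, h)
                          }, numeric(1)),
                          params$horizons), collapse = ", ")))
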