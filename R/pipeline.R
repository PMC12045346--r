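# End-to-end orchestration: simulate -> discover -> MHL -> DMR ->
# survival -> nomogram.  Every stage is a plain function above; this file
# wires them together, tracks the record funnel, and writes per-stage
# artifacts plus a manifest.  The pipeline itself draws no random
# numbers, so identical inputs give byte-identical outputs.

#' Pipeline parameters
#'
#' Every threshold defaults to the value the published analysis used
#' (LD r^2 > 0.3 with core window 3 and pair p < 0.05; > 3 CpGs and
#' median reads strictly > 50; 80% missingness bound; KNN with k = 5;
#' localized MHL stratification at 0.05; Welch and Cox screens at
#' alpha = 0.05; top 20 panel; ctDNA screen excluding fractions <= 1%
#' with Pearson r > 0.5; nomogram horizons 6/12/24 months).
#'
#' @param ... overrides of any default.
#' @return named list of parameters.
#' @export
pipeline_params <- function(...) {
  p <- list(
    r2_cutoff = 0.3, core_window = 3L, p_cutoff = 0.05,
    min_pair_reads = 10L,
    min_cpgs = 3L, min_median_reads = 50,
    max_missing_frac = 0.8, k_neighbors = 5L,
    localized_threshold = 0.05, alpha = 0.05, top_k = 20L,
    min_fraction = 0.01, min_nonmissing = 0.5, r_cutoff = 0.5,
    horizons = c(6, 12, 24),
    stepwise_direction = "backward"
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(p))
  if (length(unknown)) stop("unknown parameter(s): ",
                            paste(unknown, collapse = ", "))
  modifyList(p, over)
}

subset_mhl_matrix <- function(m, ids = NULL, rows = NULL) {
  if (is.null(ids)) ids <- m$mhb_ids
  if (is.null(rows)) rows <- seq_along(m$sample_ids)
  structure(list(values = m$values[rows, ids, drop = FALSE],
                 read_support = m$read_support[rows, ids, drop = FALSE],
                 sample_ids = m$sample_ids[rows], mhb_ids = ids),
            class = "mhl_matrix")
}

stage_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

#' Run the full analysis on in-memory objects
#'
#' @param regions `target_regions`.
#' @param cohort list of `hap_set`, one per sample.
#' @param clinical data.frame with `sample_id, state, os_months,
#'   os_event, psa, ldh, alp, albumin, hemoglobin, cfdna_ng_ml,
#'   ctdna_fraction`.
#' @param params [pipeline_params()].
#' @param gene_map optional data.frame `name, gene` mapping regions to
#'   genes (default: each region is its own gene).
#' @param out_dir optional directory for per-stage artifacts.
#' @return pipeline bundle: list with `blocks`, `mhl`, `mhl_imputed`,
#'   `control_report`, `strata`, `dmr`, `survival` (fits, panel,
#'   composite, risk, km, ctdna screen), `nomogram` (selection, spec,
#'   auc), `funnel`, `params`.
#' @export
run_pipeline <- function(regions, cohort, clinical,
                         params = pipeline_params(), gene_map = NULL,
                         out_dir = NULL) {
  ids <- vapply(cohort, `[[`, character(1), "sample_id")
  if (!setequal(ids, clinical$sample_id)) {
    stop("clinical table and haplotype samples disagree: ",
         paste(symdiff_chr(ids, clinical$sample_id), collapse = ", "))
  }
  clinical <- clinical[match(ids, clinical$sample_id), , drop = FALSE]
  funnel <- list(n_samples = length(cohort),
                 n_regions = nrow(regions),
                 read_mass = sum(vapply(cohort, read_mass, numeric(1))))

  ## 1. cohort-wide block discovery
  blocks_all <- discover_mhbs_cohort(
    cohort, regions, r2_cutoff = params$r2_cutoff,
    core_window = params$core_window, p_cutoff = params$p_cutoff,
    min_pair_reads = params$min_pair_reads)
  funnel$mhbs_discovered <- nrow(blocks_all)
  stage_log("discover", "%d MHBs in %d regions", nrow(blocks_all),
            length(unique(blocks_all$region_name)))

  ## 2. CpG-count / read-support filter
  supp <- block_read_support(cohort, blocks_all)
  blocks <- filter_mhbs(blocks_all, supp, min_cpgs = params$min_cpgs,
                        min_median_reads = params$min_median_reads)
  funnel$mhbs_filtered <- nrow(blocks)
  funnel$mhbs_control <- sum(blocks$is_control)
  funnel$mhbs_analyzed <- sum(!blocks$is_control)
  stage_log("filter", "%d MHBs pass (%d in control regions)",
            nrow(blocks), sum(blocks$is_control))

  ## 3. MHL matrix on analyzed (non-control) blocks
  mm <- build_mhl_matrix(cohort, blocks[!blocks$is_control, , drop = FALSE])

  ## control report at region level
  ctrl <- regions[regions$class != "target", , drop = FALSE]
  control_report <- NULL
  if (nrow(ctrl)) {
    cb <- regions_as_blocks(ctrl)
    cm <- build_mhl_matrix(cohort, cb)
    pool <- pool_haplotypes(cohort)
    mean_meth <- vapply(seq_len(nrow(cb)), function(b) {
      rr <- pool[pool$region == cb$region_name[b], , drop = FALSE]
      if (!nrow(rr)) return(NA_real_)
      mean_methylation(rr$pattern, rr$count)
    }, numeric(1))
    control_report <- data.frame(
      region = cb$region_name, class = cb$region_class,
      median_mhl = apply(cm$values, 2, median, na.rm = TRUE),
      mean_methylation = mean_meth, row.names = NULL)
    stage_log("controls",
              "median per-CpG methylation: positive %.3f, negative %.5f",
              median(control_report$mean_methylation[
                control_report$class == "positive_control"], na.rm = TRUE),
              median(control_report$mean_methylation[
                control_report$class == "negative_control"], na.rm = TRUE))
  }

  ## 4. missingness exclusion + KNN imputation
  mm2 <- drop_high_missingness(mm, params$max_missing_frac)
  funnel$mhbs_after_missingness <- length(mm2$mhb_ids)
  mm3 <- suppressWarnings(knn_impute(mm2, k = params$k_neighbors))
  stage_log("impute", "%d MHBs dropped for missingness; %d imputed cells",
            attr(mm2, "n_dropped"), sum(is.na(mm2$values)))

  ## 5. stratification and DMR screen
  states <- clinical$state
  strata <- stratify_by_localized(mm3, states, params$localized_threshold)
  funnel$mhbs_low_stratum <- length(strata$low_localized)
  funnel$mhbs_high_stratum <- length(strata$high_localized)
  dmr <- run_dmr_screen(mm3, states, strata, alpha = params$alpha)
  funnel$dmrs_localized_vs_mhspc <-
    length(dmr$low$significant$localized_vs_mhspc)
  funnel$dmrs_mhspc_vs_mcrpc <- length(dmr$low$significant$mhspc_vs_mcrpc)
  funnel$dmrs_common <- length(dmr$low$intersection)
  stage_log("dmr", "low stratum: %d / %d significant, %d common",
            funnel$dmrs_localized_vs_mhspc, funnel$dmrs_mhspc_vs_mcrpc,
            funnel$dmrs_common)

  ## 6. survival analyses in the mCRPC group
  gene_of <- function(rn) {
    if (is.null(gene_map)) return(rn)
    g <- gene_map$gene[match(rn, gene_map$name)]
    ifelse(is.na(g), rn, g)
  }
  mcrpc <- which(states == "mCRPC")
  surv_res <- NULL
  if (length(dmr$low$intersection) && sum(clinical$os_event[mcrpc]) >= 2) {
    time <- clinical$os_months[mcrpc]
    event <- clinical$os_event[mcrpc]
    cand_ids <- dmr$low$intersection
    res_mc <- dmr$low$results
    res_mc <- res_mc[res_mc$comparison == "mhspc_vs_mcrpc", , drop = FALSE]
    rank_p <- res_mc$p_value[match(cand_ids, res_mc$mhb_id)]
    binfo <- blocks[match(cand_ids, blocks$mhb_id), , drop = FALSE]
    fits <- lapply(cand_ids, function(id) {
      tryCatch(cox_univariate(mm3$values[mcrpc, id], time, event, name = id),
               error = function(e) NULL)
    })
    names(fits) <- cand_ids
    ok <- !vapply(fits, is.null, logical(1))
    candidates <- data.frame(
      mhb_id = cand_ids[ok],
      gene = gene_of(binfo$region_name[ok]),
      rank_p = rank_p[ok],
      start = binfo$start[ok],
      stringsAsFactors = FALSE)
    panel <- suppressWarnings(
      select_panel(candidates, fits[ok], top_k = params$top_k,
                   alpha = params$alpha))
    funnel$panel_size <- nrow(panel)
    stage_log("survival", "panel of %d gene-unique MHBs", nrow(panel))
    if (nrow(panel) >= 1) {
      comp <- composite_score(panel, subset_mhl_matrix(mm3, rows = mcrpc))
      components <- data.frame(
        composite = comp,
        log2_psa = log2(clinical$psa[mcrpc]),
        log2_ldh = log2(clinical$ldh[mcrpc]),
        log2_alp = log2(clinical$alp[mcrpc]),
        ctdna_fraction = clinical$ctdna_fraction[mcrpc],
        row.names = clinical$sample_id[mcrpc])
      risk <- suppressWarnings(risk_score(components, time, event))
      km <- km_logrank(risk$group, time, event)
      stage_log("survival",
                "median survival high-risk %.1f vs low-risk %.1f months, log-rank p = %.3g",
                km$medians[["high"]], km$medians[["low"]], km$p_value)
      ctdna <- tryCatch(
        ctdna_correlation_screen(
          subset_mhl_matrix(mm2, rows = mcrpc),
          clinical$ctdna_fraction[mcrpc],
          min_fraction = params$min_fraction,
          min_nonmissing = params$min_nonmissing,
          r_cutoff = params$r_cutoff, alpha = params$alpha),
        error = function(e) {
          stage_log("ctdna", "screen aborted: %s", conditionMessage(e))
          NULL
        })
      if (!is.null(ctdna)) {
        stage_log("ctdna", "%.1f%% of tested MHBs correlate with fraction",
                  100 * ctdna$prop_flagged)
      }
      surv_res <- list(fits = fits, candidates = candidates, panel = panel,
                       composite = comp, components = components,
                       risk = risk, km = km, ctdna = ctdna,
                       time = time, event = event,
                       sample_ids = clinical$sample_id[mcrpc])
    }
  } else {
    stage_log("survival", "skipped (no common DMRs or too few events)")
  }

  ## 7. nomogram on the mCRPC group
  nomo_res <- NULL
  if (!is.null(surv_res)) {
    time <- surv_res$time
    event <- surv_res$event
    clin_cand <- surv_res$components[c("log2_psa", "log2_ldh", "log2_alp")]
    uni_p <- vapply(names(clin_cand), function(v) {
      tryCatch(cox_univariate(clin_cand[[v]], time, event, v)$p_value,
               error = function(e) NA_real_)
    }, numeric(1))
    gated <- names(uni_p)[!is.na(uni_p) & uni_p < params$alpha]
    candidates <- surv_res$components[c(gated,
                                        c("composite", "ctdna_fraction"))]
    sel <- suppressWarnings(
      stepwise_select(candidates, time, event, alpha = params$alpha,
                      direction = params$stepwise_direction))
    if (!sel$intercept_only) {
      spec <- build_nomogram(sel$fit, candidates, horizons = params$horizons)
      lp <- drop(as.matrix(candidates[sel$kept]) %*% sel$table$beta)
      auc <- lapply(params$horizons, function(h) {
        time_dependent_auc(lp, time, event, h)
      })
      auc_tab <- data.frame(
        horizon_months = params$horizons,
        auc = vapply(auc, `[[`, numeric(1), "auc"),
        n_cases = vapply(auc, `[[`, numeric(1), "n_cases"),
        n_controls = vapply(auc, `[[`, numeric(1), "n_controls"))
      stage_log("nomogram", "predictors: %s; AUC %s",
                paste(sel$kept, collapse = ", "),
                paste(sprintf("%.2f@%gm", auc_tab$auc,
                              auc_tab$horizon_months), collapse = ", "))
      nomo_res <- list(selection = sel, spec = spec, auc = auc_tab,
                       scores = lp)
    } else {
      stage_log("nomogram", "skipped (no predictor retained)")
    }
  }

  bundle <- list(blocks_all = blocks_all, blocks = blocks, mhl = mm,
                 mhl_filtered = mm2, mhl_imputed = mm3,
                 control_report = control_report, strata = strata,
                 dmr = dmr, survival = surv_res, nomogram = nomo_res,
                 clinical = clinical, funnel = funnel, params = params)
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

symdiff_chr <- function(a, b) union(setdiff(a, b), setdiff(b, a))

#' Write the pipeline bundle to per-stage text artifacts
#'
#' @param bundle result of [run_pipeline()].
#' @param out_dir output directory (created if needed).
#' @export
write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(...) file.path(out_dir, ...)
  write_mhbs(bundle$blocks, fp("mhbs.bed"), fp("mhbs_cpgs.tsv"))
  write_mhl_matrix(bundle$mhl, fp("mhl_matrix.tsv"),
                   fp("mhl_read_support.tsv"))
  write_mhl_matrix(bundle$mhl_imputed, fp("mhl_imputed.tsv"))
  if (!is.null(bundle$control_report)) {
    fwrite(bundle$control_report, fp("control_report.tsv"), sep = "\t")
  }
  for (stratum in c("low", "high")) {
    res <- bundle$dmr[[stratum]]$results
    if (nrow(as.data.frame(res))) {
      fwrite(res, fp(sprintf("dmr_%s.tsv", stratum)), sep = "\t")
    }
    writeLines(bundle$dmr[[stratum]]$intersection,
               fp(sprintf("dmr_%s_common.txt", stratum)))
  }
  sv <- bundle$survival
  if (!is.null(sv)) {
    uni <- do.call(rbind, lapply(sv$fits[!vapply(sv$fits, is.null,
                                                 logical(1))], function(f) {
      data.frame(mhb_id = f$name, beta = f$beta, hr = f$hr,
                 ci_lower = f$ci_lower, ci_upper = f$ci_upper,
                 p_value = f$p_value, flagged = f$flagged)
    }))
    fwrite(uni, fp("cox_univariate.tsv"), sep = "\t")
    fwrite(sv$panel, fp("panel.tsv"), sep = "\t")
    fwrite(data.frame(sample_id = sv$sample_ids, composite = sv$composite,
                      risk_score = sv$risk$score,
                      risk_group = as.character(sv$risk$group)),
           fp("risk_scores.csv"))
    fwrite(sv$km$curves, fp("km_curves.tsv"), sep = "\t")
    if (!is.null(sv$ctdna)) {
      fwrite(sv$ctdna$table, fp("ctdna_screen.tsv"), sep = "\t")
    }
  }
  nm <- bundle$nomogram
  if (!is.null(nm)) {
    write_nomogram(nm$spec, fp("nomogram.json"))
    fwrite(nm$auc, fp("auc.tsv"), sep = "\t")
    fwrite(nm$selection$table, fp("nomogram_model.tsv"), sep = "\t")
  }
  manifest <- list(funnel = bundle$funnel, params = bundle$params)
  write_json(manifest, fp("manifest.json"), auto_unbox = TRUE,
             digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Run the pipeline from files on disk
#'
#' @param haplotype_dir directory of per-sample mHap-style files.
#' @param region_file,cpg_map_file region definitions (see
#'   [read_regions()]).
#' @param clinical_file patient table CSV.
#' @param params [pipeline_params()].
#' @param gene_map_file optional TSV `name, gene`.
#' @param out_dir optional artifact directory; the manifest then also
#'   records input file hashes.
#' @return pipeline bundle (see [run_pipeline()]).
#' @export
run_pipeline_files <- function(haplotype_dir, region_file, cpg_map_file,
                               clinical_file, params = pipeline_params(),
                               gene_map_file = NULL, out_dir = NULL) {
  if (!file.exists(clinical_file)) {
    stop("clinical table not found: ", clinical_file)
  }
  regions <- read_regions(region_file, cpg_map_file)
  files <- sort(list.files(haplotype_dir, full.names = TRUE))
  if (!length(files)) stop("no haplotype files in ", haplotype_dir)
  cohort <- lapply(files, read_haplotypes, regions = regions)
  clinical <- as.data.frame(fread(clinical_file))
  gene_map <- if (!is.null(gene_map_file)) {
    as.data.frame(fread(gene_map_file))
  }
  bundle <- run_pipeline(regions, cohort, clinical, params = params,
                         gene_map = gene_map, out_dir = out_dir)
  if (!is.null(out_dir)) {
    inputs <- c(files, region_file, cpg_map_file, clinical_file)
    hashes <- as.list(md5sum(inputs))
    manifest <- list(funnel = bundle$funnel, params = bundle$params,
                     input_md5 = hashes)
    write_json(manifest, file.path(out_dir, "manifest.json"),
               auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  bundle
}

#' Generate a synthetic cohort, analyse it, and score recovery
#'
#' Runs [generate_cohort()] then [run_pipeline()] and compares the
#' outputs against the emitted ground truth: region-level DMR
#' precision/recall of the intersection set, correlation-screen recovery,
#' Cox recovery of the planted log-hazard (a Cox fit on the true risk
#' should have coefficient near 1), and risk-group survival separation.
#'
#' @param config `cohort_config`.
#' @param params [pipeline_params()].
#' @param out_dir optional output directory (cohort files + artifacts).
#' @return list with `bundle`, `simulated`, `recovery`.
#' @export
simulate_then_run <- function(config = default_config(),
                              params = pipeline_params(),
                              out_dir = NULL) {
  sim <- generate_cohort(config, out_dir = out_dir)
  gene_map <- sim$truth_regions[c("name", "gene")]
  bundle <- run_pipeline(
    sim$regions, sim$cohort, sim$clinical, params = params,
    gene_map = gene_map,
    out_dir = if (!is.null(out_dir)) file.path(out_dir, "results"))

  planted <- sim$truth_regions$name[sim$truth_regions$is_dmr]
  called_blocks <- bundle$dmr$low$intersection
  called_regions <- unique(
    bundle$blocks$region_name[match(called_blocks, bundle$blocks$mhb_id)])
  recovery <- list(
    dmr_recall = if (length(planted)) {
      mean(planted %in% called_regions)
    } else NA_real_,
    dmr_precision = if (length(called_regions)) {
      mean(called_regions %in% planted)
    } else NA_real_
  )
  mcrpc <- sim$clinical$state == "mCRPC"
  if (sum(sim$clinical$os_event[mcrpc]) >= 2 &&
      sd(sim$truth_patients$true_risk[mcrpc]) > 0) {
    fit <- coxph(Surv(sim$clinical$os_months[mcrpc],
                      sim$clinical$os_event[mcrpc]) ~
                   sim$truth_patients$true_risk[mcrpc], ties = "efron")
    recovery$planted_risk_coef <- unname(coef(fit))
  }
  if (!is.null(bundle$survival)) {
    recovery$km_median_high <- bundle$survival$km$medians[["high"]]
    recovery$km_median_low <- bundle$survival$km$medians[["low"]]
    recovery$logrank_p <- bundle$survival$km$p_value
    if (!is.null(bundle$survival$ctdna)) {
      tab <- bundle$survival$ctdna$table
      tab$region <- bundle$blocks$region_name[match(tab$mhb_id,
                                                    bundle$blocks$mhb_id)]
      tested <- !tab$skipped
      recovery$ctdna_flag_rate_dmr <-
        mean(tab$flagged[tested & tab$region %in% planted])
      recovery$ctdna_flag_rate_null <-
        mean(tab$flagged[tested & !(tab$region %in% planted)])
    }
  }
  list(bundle = bundle, simulated = sim, recovery = recovery)
}
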