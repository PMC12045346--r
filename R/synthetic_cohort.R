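# Synthetic plasma-cfDNA methylation cohort.  The generator emulates the
# statistical structure the downstream analysis assumes: three disease
# states (localized / mHSPC / mCRPC), ctDNA-fraction-scaled coherent
# hypermethylation in a subset of target regions, positive-control regions
# > 95% methylated and negative controls < 0.5%, negative-binomial read
# depth around a target mean, and Weibull proportional-hazards survival
# whose log-hazard is linear in ctDNA fraction and tumor methylation
# burden.  Ground truth is emitted alongside the data and never consumed
# by the pipeline.

#' Synthetic cohort configuration
#'
#' Defaults state the cohort the analysis was designed around: 19 / 28 /
#' 49 patients (localized / mHSPC / mCRPC), 366 target + 29 positive-
#' control + 42 negative-control regions, 96x mean depth, and an mCRPC
#' ctDNA-fraction mixture putting about 17/49 patients below 1%.
#'
#' @param ... overrides of any default field.
#' @return `cohort_config` list.
#' @export
cohort_config <- function(...) {
  cfg <- list(
    n_localized = 19L, n_mhspc = 28L, n_mcrpc = 49L,
    n_target_regions = 366L, n_dmr_regions = 80L,
    n_pos_control = 29L, n_neg_control = 42L,
    mean_depth = 96, depth_dispersion = 8,
    cpgs_min = 6L, cpgs_max = 14L,
    read_span_mean = 6,
    tumor_meth_prob = 0.85, background_meth_prob = 0.03,
    high_background_frac = 0.2, high_background_meth_prob = 0.35,
    coherence = 0.67,
    pos_control_meth = 0.98, neg_control_meth = 0.002,
    frac_localized_max = 0.01, frac_mhspc_max = 0.10,
    mcrpc_low_mass = 17 / 49, frac_mcrpc_low_max = 0.01,
    frac_mcrpc_shape1 = 1.2, frac_mcrpc_shape2 = 3,
    frac_mcrpc_max = 0.7,
    predicted_fraction_sdlog = 0.1,
    hazard_coefficients = c(ctdna = 6, methylation = 4),
    weibull_shape = 1.3, baseline_median_months = 110,
    censor_horizon_months = 47, dropout_prob = 0.15,
    seed = 1L
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ",
                            paste(unknown, collapse = ", "))
  cfg <- modifyList(cfg, over)
  probs <- c(cfg$tumor_meth_prob, cfg$background_meth_prob,
             cfg$pos_control_meth, cfg$neg_control_meth,
             cfg$mcrpc_low_mass, cfg$dropout_prob)
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0, 1]")
  if (cfg$n_dmr_regions > cfg$n_target_regions) {
    stop("n_dmr_regions must be <= n_target_regions")
  }
  if (cfg$n_localized + cfg$n_mhspc + cfg$n_mcrpc < 1 ||
      cfg$n_target_regions + cfg$n_pos_control + cfg$n_neg_control < 1) {
    stop("degenerate config: zero patients or regions")
  }
  structure(cfg, class = "cohort_config")
}

#' Default synthetic cohort configuration
#'
#' @return `cohort_config` with all defaults (see [cohort_config()]).
#' @export
default_config <- function() cohort_config()

# Region scaffold: disjoint regions round-robin over chr1..chr22, each
# with cpgs_min..cpgs_max CpGs at 8-40 bp spacing.  Some target regions
# share a gene so the same-gene panel collapse is exercised.
build_region_scaffold <- function(cfg) {
  n_reg <- cfg$n_target_regions + cfg$n_pos_control + cfg$n_neg_control
  cls <- rep(c("target", "positive_control", "negative_control"),
             c(cfg$n_target_regions, cfg$n_pos_control, cfg$n_neg_control))
  prefix <- c(target = "T", positive_control = "P",
              negative_control = "N")[cls]
  idx_in_class <- as.integer(stats::ave(seq_len(n_reg), cls,
                                        FUN = seq_along))
  name <- sprintf("%s%04d", prefix, idx_in_class)
  chrom <- paste0("chr", (seq_len(n_reg) - 1L) %% 22L + 1L)
  n_cpg <- sample(seq(cfg$cpgs_min, cfg$cpgs_max), n_reg, replace = TRUE)
  # genes: a new gene starts with probability 0.75, so ~1/4 of target
  # regions share their gene with the previous target region
  gi <- cumsum(c(1L, rbinom(cfg$n_target_regions - 1L, 1L, 0.75)))
  gene <- rep(NA_character_, n_reg)
  gene[cls == "target"] <- sprintf("GENE%04d", gi)
  offset <- integer(22)
  start <- integer(n_reg)
  cpg_positions <- vector("list", n_reg)
  for (i in seq_len(n_reg)) {
    ch <- (i - 1L) %% 22L + 1L
    s <- 10000L + offset[ch]
    gaps <- if (n_cpg[i] > 1) sample(8:40, n_cpg[i] - 1L, replace = TRUE)
            else integer(0)
    pos <- s + cumsum(c(0L, gaps))
    start[i] <- s
    cpg_positions[[i]] <- as.integer(pos)
    offset[ch] <- offset[ch] + (pos[n_cpg[i]] - s) + 2000L
  }
  reg <- data.frame(chrom = chrom, start = start,
                    end = vapply(cpg_positions, max, integer(1)) + 50L,
                    name = name, class = cls, gene = gene,
                    stringsAsFactors = FALSE)
  reg$cpg_positions <- cpg_positions
  reg$n_cpgs <- n_cpg
  is_dmr <- logical(n_reg)
  tgt <- which(cls == "target")
  is_dmr[tgt[sample.int(length(tgt), cfg$n_dmr_regions)]] <- TRUE
  reg$is_dmr <- is_dmr
  # a share of non-DMR target regions carries constitutively elevated
  # (non-tumor, e.g. leukocyte-derived) methylation in every state;
  # these populate the high-localized stratum downstream
  is_high_bg <- logical(n_reg)
  pool_bg <- which(cls == "target" & !is_dmr)
  n_high <- round(cfg$high_background_frac * length(pool_bg))
  is_high_bg[pool_bg[sample.int(length(pool_bg), n_high)]] <- TRUE
  reg$is_high_background <- is_high_bg
  reg <- reg[order(reg$chrom, reg$start), , drop = FALSE]
  rownames(reg) <- NULL
  class(reg) <- c("target_regions", "data.frame")
  reg
}

draw_patients <- function(cfg) {
  n <- cfg$n_localized + cfg$n_mhspc + cfg$n_mcrpc
  state <- rep(c("localized", "mHSPC", "mCRPC"),
               c(cfg$n_localized, cfg$n_mhspc, cfg$n_mcrpc))
  sample_id <- sprintf("%s%03d",
                       c(localized = "L", mHSPC = "H", mCRPC = "C")[state],
                       as.integer(stats::ave(seq_len(n), state,
                                             FUN = seq_along)))
  f <- numeric(n)
  f[state == "localized"] <- runif(cfg$n_localized, 0, cfg$frac_localized_max)
  f[state == "mHSPC"] <- runif(cfg$n_mhspc, 0, cfg$frac_mhspc_max)
  im <- which(state == "mCRPC")
  low <- rbinom(length(im), 1L, cfg$mcrpc_low_mass) == 1L
  f[im[low]] <- runif(sum(low), 0, cfg$frac_mcrpc_low_max)
  f[im[!low]] <- 0.01 + (cfg$frac_mcrpc_max - 0.01) *
    rbeta(sum(!low), cfg$frac_mcrpc_shape1, cfg$frac_mcrpc_shape2)
  # tumor methylation burden a patient's DMR regions are expected to show
  tm <- f * cfg$tumor_meth_prob + (1 - f) * cfg$background_meth_prob
  risk <- cfg$hazard_coefficients[["ctdna"]] * f +
    cfg$hazard_coefficients[["methylation"]] * tm
  # Weibull PH: S(t) = exp(-log(2) (t / m0)^k e^risk)
  k <- cfg$weibull_shape
  u <- runif(n)
  t_event <- cfg$baseline_median_months *
    (-log(u) / log(2))^(1 / k) * exp(-risk / k)
  dropout <- ifelse(rbinom(n, 1L, cfg$dropout_prob) == 1L,
                    runif(n, 0, cfg$censor_horizon_months),
                    Inf)
  t_cens <- pmin(dropout, cfg$censor_horizon_months)
  os_months <- round(pmin(t_event, t_cens), 2)
  os_months <- pmax(os_months, 0.1)
  os_event <- as.integer(t_event <= t_cens)
  # clinical biomarkers: PSA/LDH/ALP log-normal, rising with fraction;
  # hemoglobin/albumin weakly falling; cfDNA concentration rising
  psa <- 2^(log2(5) + 5 * f + rnorm(n, 0, 1.5))
  ldh <- 2^(log2(200) + 1.5 * f + rnorm(n, 0, 0.35))
  alp <- 2^(log2(80) + 2.5 * f + rnorm(n, 0, 0.5))
  hemoglobin <- 14 - 3 * f + rnorm(n, 0, 1)
  albumin <- 4.1 - 0.5 * f + rnorm(n, 0, 0.25)
  cfdna_ng_ml <- 2^(log2(8) + 2 * f + rnorm(n, 0, 0.8))
  predicted <- pmin(1, f * exp(rnorm(n, 0, cfg$predicted_fraction_sdlog)))
  list(
    clinical = data.frame(
      sample_id = sample_id, state = state, os_months = os_months,
      os_event = os_event, psa = round(psa, 2), ldh = round(ldh, 1),
      alp = round(alp, 1), albumin = round(albumin, 2),
      hemoglobin = round(hemoglobin, 2),
      cfdna_ng_ml = round(cfdna_ng_ml, 2),
      ctdna_fraction = round(predicted, 5),
      stringsAsFactors = FALSE),
    truth = data.frame(
      sample_id = sample_id, state = state, true_fraction = f,
      tumor_methylation = tm, true_risk = risk,
      stringsAsFactors = FALSE)
  )
}

# Reads of one region for every sample at once. Each read covers a
# contiguous CpG window; its per-CpG methylation propensity is drawn once
# per read (beta mixture), which is what makes methylation runs cohere
# within a read.
simulate_region_reads <- function(region, cfg, fractions) {
  n_samples <- length(fractions)
  depth <- rnbinom(n_samples, size = cfg$depth_dispersion,
                   mu = cfg$mean_depth)
  N <- sum(depth)
  if (N == 0) return(NULL)
  sample_idx <- rep(seq_len(n_samples), depth)
  # coherence c in (0, 1) is the within-read correlation between CpG
  # states: propensity ~ Beta with concentration (1 - c) / c, so high
  # coherence gives near-0/near-1 reads and long methylation runs
  stopifnot(cfg$coherence > 0, cfg$coherence < 1)
  kk <- (1 - cfg$coherence) / cfg$coherence
  p_read <- switch(
    region$class,
    positive_control = rep(cfg$pos_control_meth, N),
    negative_control = rep(cfg$neg_control_meth, N),
    target = {
      bgp <- if (region$is_high_background) {
        cfg$high_background_meth_prob
      } else cfg$background_meth_prob
      bg <- rbeta(N, kk * bgp, kk * (1 - bgp))
      if (region$is_dmr) {
        tumor <- rbinom(N, 1L, fractions[sample_idx]) == 1L
        tu <- rbeta(N, kk * cfg$tumor_meth_prob,
                    kk * (1 - cfg$tumor_meth_prob))
        ifelse(tumor, tu, bg)
      } else bg
    })
  n_cpg <- region$n_cpgs
  span <- pmin(n_cpg, 1L + rpois(N, max(cfg$read_span_mean - 1, 0)))
  start_idx <- 1L + as.integer(floor(runif(N) * (n_cpg - span + 1L)))
  lmax <- max(span)
  bits <- matrix(rbinom(N * lmax, 1L, p_read), nrow = N)  # prob recycles by row
  full <- do.call(paste0, as.data.frame(matrix(as.character(bits), N, lmax)))
  pattern <- substr(full, 1L, span)
  dt <- data.table(sample = sample_idx, start_idx = start_idx,
                   pattern = pattern)
  dt <- dt[, list(count = .N), by = c("sample", "start_idx", "pattern")]
  pos <- region$cpg_positions[[1]]
  dt$chrom <- region$chrom
  dt$start <- pos[dt$start_idx]
  dt$end <- pos[dt$start_idx + nchar(dt$pattern) - 1L] + 1L
  dt$strand <- "*"
  dt$region <- region$name
  dt
}

#' Generate a synthetic cohort
#'
#' Draws regions, patients and read-level haplotypes under `config`
#' (all randomness flows from `config$seed`), optionally writing the
#' haplotype / region / clinical files in the formats the pipeline reads,
#' plus ground-truth tables the pipeline never consumes.
#'
#' @param config `cohort_config`.
#' @param out_dir if non-`NULL`, write `haplotypes/<sample>.mhap`,
#'   `regions.tsv`, `cpg_map.tsv`, `clinical.csv`,
#'   `ground_truth_patients.csv`, `ground_truth_regions.csv` there.
#' @return list with `regions` (`target_regions`, incl. `gene`, `is_dmr`),
#'   `cohort` (list of `hap_set`), `clinical`, `truth_patients`,
#'   `truth_regions`, `config`, and `paths` when written.
#' @export
generate_cohort <- function(config = default_config(), out_dir = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  regions <- build_region_scaffold(config)
  pts <- draw_patients(config)
  n <- nrow(pts$clinical)
  per_region <- lapply(seq_len(nrow(regions)), function(i) {
    simulate_region_reads(regions[i, , drop = FALSE], config,
                          pts$truth$true_fraction)
  })
  all_reads <- data.table::rbindlist(per_region[!vapply(per_region, is.null,
                                                        logical(1))])
  setorder(all_reads, sample, chrom, start, pattern)
  by_sample <- split(all_reads, all_reads$sample)
  cohort <- lapply(seq_len(n), function(s) {
    dt <- by_sample[[as.character(s)]]
    rec <- if (is.null(dt)) empty_records() else data.frame(
      chrom = dt$chrom, start = dt$start, end = dt$end,
      pattern = dt$pattern, count = dt$count, strand = dt$strand,
      region = dt$region, cpg_index = dt$start_idx,
      stringsAsFactors = FALSE)
    hap_set(pts$clinical$sample_id[s], rec, empty_records(),
            data.frame(line = integer(), reason = character()))
  })
  truth_regions <- data.frame(name = regions$name, gene = regions$gene,
                              is_dmr = regions$is_dmr,
                              is_high_background =
                                regions$is_high_background,
                              stringsAsFactors = FALSE)
  out <- list(regions = regions, cohort = cohort,
              clinical = pts$clinical, truth_patients = pts$truth,
              truth_regions = truth_regions, config = config)
  if (!is.null(out_dir)) {
    dir.create(file.path(out_dir, "haplotypes"), recursive = TRUE,
               showWarnings = FALSE)
    paths <- list(
      regions = file.path(out_dir, "regions.tsv"),
      cpg_map = file.path(out_dir, "cpg_map.tsv"),
      clinical = file.path(out_dir, "clinical.csv"),
      truth_patients = file.path(out_dir, "ground_truth_patients.csv"),
      truth_regions = file.path(out_dir, "ground_truth_regions.csv"),
      haplotype_dir = file.path(out_dir, "haplotypes")
    )
    write_regions(regions, paths$regions, paths$cpg_map)
    fwrite(pts$clinical, paths$clinical)
    fwrite(pts$truth, paths$truth_patients)
    fwrite(truth_regions, paths$truth_regions)
    for (s in cohort) {
      write_haplotypes(s, file.path(paths$haplotype_dir,
                                    paste0(s$sample_id, ".mhap")))
    }
    out$paths <- paths
  }
  out
}
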