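# Independent oracles and in-code fixtures.  Oracles deliberately use the
# most literal formulation available (substring enumeration, expanded
# read vectors, textbook formulas) so they share no code path with the
# implementation they check.

# MHL by literal substring enumeration: every substring of every pattern,
# tallied per length, count-weighted.
oracle_mhl <- function(patterns, counts = 1L, max_len = 10L) {
  if (length(patterns) == 0) return(NA_real_)
  counts <- rep_len(counts, length(patterns))
  L <- min(max_len, max(nchar(patterns)))
  tot <- met <- numeric(L)
  for (k in seq_along(patterns)) {
    p <- patterns[k]
    n <- nchar(p)
    for (i in seq_len(min(L, n))) {
      for (s in seq_len(n - i + 1)) {
        sub <- substr(p, s, s + i - 1)
        tot[i] <- tot[i] + counts[k]
        if (sub == strrep("1", i)) met[i] <- met[i] + counts[k]
      }
    }
  }
  keep <- tot > 0
  i <- seq_len(L)[keep]
  sum(i * met[keep] / tot[keep]) / sum(i)
}

# r^2 as the squared Pearson correlation of the expanded read-level 0/1
# vectors (each read repeated `count` times).
oracle_r2 <- function(n11, n10, n01, n00) {
  a <- rep(c(1, 1, 0, 0), c(n11, n10, n01, n00))
  b <- rep(c(1, 0, 1, 0), c(n11, n10, n01, n00))
  if (sd(a) == 0 || sd(b) == 0) return(NA_real_)
  cor(a, b)^2
}

# Two-group log-rank statistic by the direct observed-minus-expected
# formula over event times.
oracle_logrank <- function(time, event, group) {
  g <- as.integer(as.factor(group))
  ut <- sort(unique(time[event == 1]))
  O <- E <- V <- 0
  for (tk in ut) {
    at_risk <- time >= tk
    n <- sum(at_risk)
    n1 <- sum(at_risk & g == 1)
    d <- sum(event == 1 & time == tk)
    d1 <- sum(event == 1 & time == tk & g == 1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chisq <- (O - E)^2 / V
  list(chisq = chisq, p = pchisq(chisq, 1, lower.tail = FALSE))
}

# Empirical AUC of cases (event by t) vs controls (survive past t) on
# uncensored data: plain rank-sum concordance.
oracle_auc_uncensored <- function(scores, time, t) {
  sc <- scores[time <= t]
  sx <- scores[time > t]
  mean(outer(sc, sx, ">") + 0.5 * outer(sc, sx, "=="))
}

# ---- fixtures -------------------------------------------------------

random_patterns <- function(n, len_range = c(1, 20), count_range = c(1, 50)) {
  lens <- sample(len_range[1]:len_range[2], n, replace = TRUE)
  list(
    patterns = vapply(lens, function(l) {
      paste(sample(c("0", "1"), l, replace = TRUE), collapse = "")
    }, character(1)),
    counts = sample(count_range[1]:count_range[2], n, replace = TRUE)
  )
}

# A single-region scaffold with evenly spaced CpGs, plus a pool builder.
toy_region <- function(n_cpg, name = "T0001", class = "target",
                       chrom = "chr1", start = 1000L, gap = 20L) {
  pos <- start + gap * (seq_len(n_cpg) - 1L)
  reg <- data.frame(chrom = chrom, start = start,
                    end = max(pos) + 50L, name = name, class = class,
                    stringsAsFactors = FALSE)
  make_regions(reg, data.frame(chrom = chrom, pos = pos))
}

# Records data.frame in the internal (mapped) representation.
toy_pool <- function(patterns, counts = 1L, cpg_index = 1L,
                     region = "T0001", chrom = "chr1", start0 = 1000L,
                     gap = 20L) {
  if (length(patterns) == 0) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), pattern = character(),
                      count = integer(), strand = character(),
                      region = character(), cpg_index = integer(),
                      stringsAsFactors = FALSE))
  }
  counts <- rep_len(as.integer(counts), length(patterns))
  cpg_index <- rep_len(as.integer(cpg_index), length(patterns))
  start <- start0 + gap * (cpg_index - 1L)
  end <- start0 + gap * (cpg_index + nchar(patterns) - 2L) + 1L
  data.frame(chrom = chrom, start = start, end = end, pattern = patterns,
             count = counts, strand = "*", region = region,
             cpg_index = cpg_index, stringsAsFactors = FALSE)
}

toy_hap_set <- function(sample_id, records) {
  structure(list(sample_id = sample_id, records = records,
                 unmapped = records[0, ],
                 rejected = data.frame(line = integer(),
                                       reason = character())),
            class = "hap_set")
}

# Draw a pool of reads from a per-read-propensity model over a region's
# CpGs; used for planted-LD and calibration fixtures.
sim_pool <- function(n_reads, n_cpg, p_draw, span = n_cpg) {
  p <- p_draw(n_reads)
  sp <- pmin(span, n_cpg)
  start_idx <- sample.int(n_cpg - sp + 1L, n_reads, replace = TRUE)
  pats <- vapply(seq_len(n_reads), function(i) {
    paste(rbinom(sp, 1, p[i]), collapse = "")
  }, character(1))
  toy_pool(pats, 1L, cpg_index = start_idx)
}

# Scaled-down cohort config for tests: default patient numbers and planted
# effect sizes, fewer/smaller regions and lower depth to stay in budget
# (the read-support filter is scaled in proportion to depth).
test_cohort_config <- function(..., seed = 1L) {
  cohort_config(n_target_regions = 30L, n_dmr_regions = 8L,
                n_pos_control = 3L, n_neg_control = 3L,
                mean_depth = 60, cpgs_min = 5L, cpgs_max = 8L,
                seed = seed, ...)
}

test_params <- function(...) {
  pipeline_params(min_median_reads = 30, ...)
}
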