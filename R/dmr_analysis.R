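# Differential-methylation screen: MHBs are first stratified by their mean
# MHL in localized disease (blocks already methylated there likely carry
# non-tumor signal, e.g. leukocytes), then each stratum is tested between
# successive disease states with two-sided Welch t-tests at raw p < 0.05,
# and the two significant sets are intersected.

#' Stratify blocks by localized-state methylation
#'
#' Partitions blocks into a low stratum (localized mean MHL <= `threshold`;
#' candidate tumor-derived signal) and a high stratum (> `threshold`;
#' candidate non-tumor signal). A block exactly at the threshold is low.
#'
#' @param m `mhl_matrix` (imputed).
#' @param states character vector of disease states per sample, aligned
#'   with the matrix rows; the localized group is `"localized"`.
#' @param threshold localized mean-MHL boundary (default 0.05).
#' @return list with `low_localized`, `high_localized` (MHB id vectors)
#'   and `localized_mean` (named numeric).
#' @export
stratify_by_localized <- function(m, states, threshold = 0.05) {
  stopifnot(length(states) == nrow(m$values))
  loc <- states == "localized"
  if (!any(loc)) stop("localized group is empty")
  mu <- colMeans(m$values[loc, , drop = FALSE], na.rm = TRUE)
  list(low_localized = m$mhb_ids[mu <= threshold],
       high_localized = m$mhb_ids[mu > threshold],
       localized_mean = setNames(mu, m$mhb_ids))
}

#' Welch's unequal-variance t-test
#'
#' Two-sided t statistic with Welch–Satterthwaite degrees of freedom.
#' If both groups are degenerate (zero pooled standard error): identical
#' means give `t = 0, p = 1`; differing means are flagged (`degenerate`)
#' with `NA` statistics.
#'
#' @param a,b numeric vectors (each >= 2 non-missing values).
#' @return list with `mean_diff` (`mean(b) - mean(a)`), `t_stat`, `df`,
#'   `p_value`, `degenerate`.
#' @export
welch_test <- function(a, b) {
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) stop("each group needs >= 2 values")
  va <- var(a) / length(a)
  vb <- var(b) / length(b)
  d <- mean(b) - mean(a)
  se2 <- va + vb
  if (se2 == 0) {
    if (d == 0) {
      return(list(mean_diff = 0, t_stat = 0, df = NA_real_, p_value = 1,
                  degenerate = FALSE))
    }
    return(list(mean_diff = d, t_stat = NA_real_, df = NA_real_,
                p_value = NA_real_, degenerate = TRUE))
  }
  df <- se2^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  t <- d / sqrt(se2)
  list(mean_diff = d, t_stat = t, df = df,
       p_value = 2 * pt(-abs(t), df), degenerate = FALSE)
}

# Vectorized Welch over matrix columns: rows of `x` split by group masks.
welch_screen_cols <- function(x, g1, g2) {
  x1 <- x[g1, , drop = FALSE]
  x2 <- x[g2, , drop = FALSE]
  n1 <- colSums(!is.na(x1))
  n2 <- colSums(!is.na(x2))
  m1 <- colMeans(x1, na.rm = TRUE)
  m2 <- colMeans(x2, na.rm = TRUE)
  v1 <- apply(x1, 2, var, na.rm = TRUE) / n1
  v2 <- apply(x2, 2, var, na.rm = TRUE) / n2
  d <- m2 - m1
  se2 <- v1 + v2
  t <- d / sqrt(se2)
  df <- se2^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  p <- 2 * pt(-abs(t), df)
  zero <- !is.na(se2) & se2 == 0
  t[zero & d == 0] <- 0
  p[zero & d == 0] <- 1
  data.frame(mhb_id = colnames(x), mean_diff = d, t_stat = t, df = df,
             p_value = p, degenerate = zero & d != 0,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Differential-methylation screen across disease states
#'
#' For each stratum, tests every MHB between localized and mHSPC and
#' between mHSPC and mCRPC (Welch, two-sided), marks significance at raw
#' `p < alpha` as in the published screen, and intersects the two
#' significant sets. A Benjamini–Hochberg column (`p_bh`) is reported for
#' reference but never gates anything.
#'
#' @param m imputed `mhl_matrix`.
#' @param states per-sample disease state: `localized`, `mHSPC`, `mCRPC`.
#' @param strata output of [stratify_by_localized()]; only the
#'   corresponding columns are tested per stratum.
#' @param alpha significance level (default 0.05).
#' @return list of per-stratum results: each has `results` (long table,
#'   one row per MHB x comparison, with volcano columns `mean_diff` and
#'   `neg_log10_p`), `significant` (list of MHB id vectors per
#'   comparison), and `intersection`.
#' @export
run_dmr_screen <- function(m, states, strata, alpha = 0.05) {
  stopifnot(length(states) == nrow(m$values))
  comparisons <- list(
    localized_vs_mhspc = c("localized", "mHSPC"),
    mhspc_vs_mcrpc = c("mHSPC", "mCRPC")
  )
  run_stratum <- function(ids) {
    if (!length(ids)) {
      return(list(results = data.frame(), significant =
                    lapply(comparisons, function(.) character(0)),
                  intersection = character(0)))
    }
    x <- m$values[, ids, drop = FALSE]
    res <- lapply(names(comparisons), function(cmp) {
      gs <- comparisons[[cmp]]
      out <- welch_screen_cols(x, states == gs[1], states == gs[2])
      out$comparison <- cmp
      out$p_bh <- p.adjust(out$p_value, method = "BH")
      out$significant <- !is.na(out$p_value) & out$p_value < alpha
      out$neg_log10_p <- -log10(out$p_value)
      out
    })
    res <- do.call(rbind, res)
    sig <- lapply(names(comparisons), function(cmp) {
      res$mhb_id[res$comparison == cmp & res$significant]
    })
    names(sig) <- names(comparisons)
    list(results = res, significant = sig,
         intersection = intersect(sig[[1]], sig[[2]]))
  }
  list(low = run_stratum(strata$low_localized),
       high = run_stratum(strata$high_localized),
       alpha = alpha)
}
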