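# Methylation haplotype load (MHL): for substring lengths i = 1..L
# (L capped at 10), P(MH_i) is the count-weighted fraction of length-i CpG
# substrings that are fully methylated; MHL is the i-weighted mean of the
# P(MH_i).  Lengths with no observed substring are omitted from both the
# numerator and the denominator rather than treated as P = 0, so shallow
# samples are not deflated merely for lacking long reads.

#' Methylation haplotype load of a haplotype pool
#'
#' @param patterns character vector of haplotype patterns over `{0,1}`,
#'   already restricted to the CpGs of interest (e.g. an MHB's members).
#' @param counts integer read multiplicities, recycled if length 1.
#' @param max_len longest substring length considered (default 10).
#' @return A value in `[0, 1]`, or `NA_real_` for an empty pool ("no
#'   informative read" is missing, never zero).
#' @examples
#' mhl(c("111", "111"))        # 1
#' mhl("000")                  # 0
#' mhl(c("110", "011"))        # mixed
#' @export
mhl <- function(patterns, counts = 1L, max_len = 10L) {
  if (length(patterns) == 0) return(NA_real_)
  stopifnot(length(counts) == 1L || length(counts) == length(patterns))
  counts <- rep_len(as.numeric(counts), length(patterns))
  if (any(counts < 1)) stop("counts must be >= 1")
  if (!all(grepl("^[01]+$", patterns))) {
    stop("patterns must be non-empty strings over {0,1}")
  }
  mhl_fast(patterns, counts, max_len)
}

# validation-free kernel used by the matrix assembly hot loop
mhl_fast <- function(patterns, counts, max_len = 10L) {
  counts <- rep_len(as.numeric(counts), length(patterns))
  lens <- nchar(patterns)
  L <- min(max_len, max(lens))
  # runs of consecutive 1s; a run of length r contributes
  # max(0, r - i + 1) fully methylated substrings of length i
  runs <- lapply(strsplit(patterns, "", fixed = TRUE), function(b) {
    r <- rle(b)
    r$lengths[r$values == "1"]
  })
  runs_all <- unlist(runs, use.names = FALSE)
  w_all <- rep(counts, lengths(runs))
  tot <- met <- numeric(L)
  for (i in seq_len(L)) {
    tot[i] <- sum(counts * pmax(0, lens - i + 1))
    met[i] <- if (length(runs_all)) {
      sum(w_all * pmax(0, runs_all - i + 1))
    } else 0
  }
  keep <- tot > 0
  i <- seq_len(L)[keep]
  sum(i * met[keep] / tot[keep]) / sum(i)
}

#' Per-CpG mean methylation of a haplotype pool
#'
#' Count-weighted fraction of methylated CpG calls; used for
#' control-region reporting.
#'
#' @inheritParams mhl
#' @export
mean_methylation <- function(patterns, counts = 1L) {
  if (length(patterns) == 0) return(NA_real_)
  counts <- rep_len(as.numeric(counts), length(patterns))
  ones <- nchar(gsub("0", "", patterns, fixed = TRUE))
  sum(counts * ones) / sum(counts * nchar(patterns))
}

# Restrict a region's records to an MHB's member CpG index range
# [first_idx, last_idx] (1-based indices into the region's CpG map).
# Records overlapping no member CpG are dropped; others contribute their
# restricted sub-pattern.
restrict_to_block <- function(records, first_idx, last_idx) {
  if (nrow(records) == 0) {
    return(data.frame(pattern = character(), count = integer()))
  }
  rs <- records$cpg_index
  re <- rs + nchar(records$pattern) - 1L
  keep <- rs <= last_idx & re >= first_idx
  if (!any(keep)) {
    return(data.frame(pattern = character(), count = integer()))
  }
  r <- records[keep, , drop = FALSE]
  from <- pmax(first_idx, r$cpg_index) - r$cpg_index + 1L
  to <- pmin(last_idx, r$cpg_index + nchar(r$pattern) - 1L) - r$cpg_index + 1L
  data.frame(pattern = substr(r$pattern, from, to), count = r$count,
             stringsAsFactors = FALSE)
}

#' Assemble the cohort MHL matrix
#'
#' One [mhl()] evaluation per sample and block; a cell is missing (`NA`)
#' exactly when no read of that sample overlaps at least one member CpG of
#' the block, and the count-weighted number of informative reads is kept in
#' a parallel `read_support` matrix.
#'
#' @param cohort list of `hap_set` objects (one per sample).
#' @param blocks `mhb_set` from [discover_mhbs()]/[filter_mhbs()].
#' @param max_len substring-length cap passed to [mhl()].
#' @return An `mhl_matrix`: list with `values` and `read_support`
#'   (samples x blocks matrices with dimnames), `sample_ids`, `mhb_ids`.
#' @export
build_mhl_matrix <- function(cohort, blocks, max_len = 10L) {
  sample_ids <- vapply(cohort, function(s) s$sample_id, character(1))
  mhb_ids <- blocks$mhb_id
  vals <- matrix(NA_real_, length(cohort), nrow(blocks),
                 dimnames = list(sample_ids, mhb_ids))
  supp <- matrix(0, length(cohort), nrow(blocks),
                 dimnames = list(sample_ids, mhb_ids))
  for (s in seq_along(cohort)) {
    rec <- cohort[[s]]$records
    # flat vectors once per sample; per-cell work is pure vector ops
    idx_by_region <- split(seq_len(nrow(rec)), rec$region)
    pat <- rec$pattern
    cnt <- rec$count
    ci <- rec$cpg_index
    plen <- nchar(pat)
    for (b in seq_len(nrow(blocks))) {
      ii <- idx_by_region[[blocks$region_name[b]]]
      if (is.null(ii)) next
      first <- blocks$first_idx[b]
      last <- blocks$last_idx[b]
      keep <- ii[ci[ii] <= last & ci[ii] + plen[ii] - 1L >= first]
      if (!length(keep)) next
      from <- pmax(first, ci[keep]) - ci[keep] + 1L
      to <- pmin(last, ci[keep] + plen[keep] - 1L) - ci[keep] + 1L
      supp[s, b] <- sum(cnt[keep])
      vals[s, b] <- mhl_fast(substr(pat[keep], from, to), cnt[keep],
                             max_len = max_len)
    }
  }
  structure(list(values = vals, read_support = supp,
                 sample_ids = sample_ids, mhb_ids = mhb_ids),
            class = "mhl_matrix")
}

#' @export
print.mhl_matrix <- function(x, ...) {
  cat(sprintf("<mhl_matrix> %d samples x %d MHBs; %.1f%% missing\n",
              nrow(x$values), ncol(x$values),
              100 * mean(is.na(x$values))))
  invisible(x)
}

#' Drop blocks with excessive missingness
#'
#' Removes MHB columns whose fraction of missing MHL values is strictly
#' greater than `max_missing_frac` (a column at exactly the bound is kept).
#'
#' @param m `mhl_matrix`.
#' @param max_missing_frac missingness bound (default 0.8).
#' @return Filtered `mhl_matrix` with attribute `n_dropped`.
#' @export
drop_high_missingness <- function(m, max_missing_frac = 0.8) {
  miss <- colMeans(is.na(m$values))
  keep <- miss <= max_missing_frac
  out <- structure(list(values = m$values[, keep, drop = FALSE],
                        read_support = m$read_support[, keep, drop = FALSE],
                        sample_ids = m$sample_ids,
                        mhb_ids = m$mhb_ids[keep]),
                   class = "mhl_matrix")
  attr(out, "n_dropped") <- sum(!keep)
  attr(out, "dropped_ids") <- m$mhb_ids[!keep]
  out
}

#' K-nearest-neighbour imputation of missing MHL values
#'
#' Each missing cell is replaced by the mean of that block's observed
#' values among the `k` nearest samples. Distances are Euclidean over the
#' columns observed in both samples, after per-column standardisation
#' (mean/SD on observed values only), scaled by the number of shared
#' columns so samples with different missingness patterns are comparable.
#' Imputed values are clipped to `[0, 1]`.
#'
#' @param m `mhl_matrix` (no column may exceed the missingness bound;
#'   enforce with [drop_high_missingness()] first).
#' @param k neighbours (default 5). If fewer than `k` samples observe the
#'   target column, all available are used with a warning.
#' @return Complete `mhl_matrix` (no `NA` in `values`).
#' @export
knn_impute <- function(m, k = 5L) {
  x <- m$values
  if (!anyNA(x)) return(m)
  mu <- colMeans(x, na.rm = TRUE)
  sg <- apply(x, 2, sd, na.rm = TRUE)
  sg[!is.finite(sg) | sg == 0] <- 1
  z <- sweep(sweep(x, 2, mu), 2, sg, "/")
  obs <- !is.na(x)
  filled <- x
  warned <- FALSE
  for (j in which(colSums(!obs) > 0)) {
    donors <- which(obs[, j])
    if (length(donors) == 0) {
      stop("column ", colnames(x)[j], " has no observed value; ",
           "apply drop_high_missingness() first")
    }
    for (i in which(!obs[, j])) {
      shared <- obs[rep(i, length(donors)), , drop = FALSE] &
        obs[donors, , drop = FALSE]
      d <- vapply(seq_along(donors), function(t) {
        sh <- shared[t, ]
        if (!any(sh)) return(Inf)
        sqrt(mean((z[i, sh] - z[donors[t], sh])^2))
      }, numeric(1))
      usable <- donors[is.finite(d)]
      d <- d[is.finite(d)]
      if (length(usable) == 0) {
        filled[i, j] <- mean(x[donors, j])
        next
      }
      if (length(usable) < k && !warned) {
        warning("fewer than k=", k, " usable neighbours for some cells; ",
                "using all available")
        warned <- TRUE
      }
      nn <- usable[order(d, usable)][seq_len(min(k, length(usable)))]
      filled[i, j] <- mean(x[nn, j])
    }
  }
  filled <- pmin(pmax(filled, 0), 1)
  structure(list(values = filled, read_support = m$read_support,
                 sample_ids = m$sample_ids, mhb_ids = m$mhb_ids),
            class = "mhl_matrix")
}

#' Read an MHL matrix written by [write_mhl_matrix()]
#'
#' @param path values TSV path.
#' @param support_path optional read-support TSV; without it, support is
#'   reconstructed as 1 for observed cells and 0 for missing.
#' @return `mhl_matrix`.
#' @export
read_mhl_matrix <- function(path, support_path = NULL) {
  v <- as.data.frame(fread(path, sep = "\t", na.strings = "NA"))
  ids <- v$sample_id
  vals <- as.matrix(v[-1])
  rownames(vals) <- ids
  if (!is.null(support_path)) {
    s <- as.data.frame(fread(support_path, sep = "\t"))
    supp <- as.matrix(s[-1])
    rownames(supp) <- s$sample_id
    supp <- supp[ids, colnames(vals), drop = FALSE]
  } else {
    supp <- (!is.na(vals)) * 1
  }
  structure(list(values = vals, read_support = supp, sample_ids = ids,
                 mhb_ids = colnames(vals)),
            class = "mhl_matrix")
}

#' Write an MHL matrix (and its read support) as TSV
#'
#' Samples as rows, MHB ids as columns, `NA` for missing.
#'
#' @param m `mhl_matrix`.
#' @param path values TSV path.
#' @param support_path optional read-support TSV path.
#' @export
write_mhl_matrix <- function(m, path, support_path = NULL) {
  v <- data.table(sample_id = rownames(m$values))
  v <- cbind(v, as.data.table(m$values))
  fwrite(v, path, sep = "\t", na = "NA", quote = FALSE)
  if (!is.null(support_path)) {
    s <- data.table(sample_id = rownames(m$read_support))
    s <- cbind(s, as.data.table(m$read_support))
    fwrite(s, support_path, sep = "\t", quote = FALSE)
  }
  invisible(path)
}
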