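# Methylation haplotype blocks: maximal runs of consecutive CpGs whose
# adjacent pairs are in linkage disequilibrium (r^2 > cutoff, chi-square
# p < cutoff, enough informative reads) across the pooled reads of the
# whole cohort.  Discovery is cohort-level, never per patient.

#' Pool the haplotype records of many samples
#'
#' @param cohort list of `hap_set` objects.
#' @return data.frame of pooled records (all samples' mapped records).
#' @export
pool_haplotypes <- function(cohort) {
  do.call(rbind, lapply(cohort, function(s) s$records))
}

# Expand a region's pooled records into an integer matrix reads x CpGs
# (0/1, NA outside the read span) plus a weight vector of read counts.
hap_matrix <- function(records, n_cpg) {
  n <- nrow(records)
  m <- matrix(NA_integer_, n, n_cpg)
  if (n > 0) {
    lens <- nchar(records$pattern)
    bits <- strsplit(records$pattern, "", fixed = TRUE)
    rows <- rep(seq_len(n), lens)
    cols <- unlist(lapply(seq_len(n), function(i) {
      seq.int(records$cpg_index[i], length.out = lens[i])
    }), use.names = FALSE)
    m[cbind(rows, cols)] <- as.integer(unlist(bits, use.names = FALSE))
  }
  list(m = m, w = as.numeric(records$count))
}

# r^2 and chi-square p from a weighted 2x2 methylation table.
r2_from_counts <- function(n11, n10, n01, n00) {
  n <- n11 + n10 + n01 + n00
  if (n == 0) {
    return(list(r2 = NA_real_, p_value = NA_real_, n_reads = 0,
                defined = FALSE))
  }
  pa <- (n11 + n10) / n   # methylated at site a
  pb <- (n11 + n01) / n   # methylated at site b
  den <- pa * (1 - pa) * pb * (1 - pb)
  if (den == 0) {
    # monomorphic site: r^2 undefined, treated as failing any cutoff
    return(list(r2 = NA_real_, p_value = NA_real_, n_reads = n,
                defined = FALSE))
  }
  r2 <- (n11 / n - pa * pb)^2 / den
  list(r2 = r2, p_value = pchisq(n * r2, df = 1, lower.tail = FALSE),
       n_reads = n, defined = TRUE)
}

#' Pairwise linkage disequilibrium between two CpG sites
#'
#' Builds the count-weighted 2x2 table of methylation states over reads
#' covering both sites and returns
#' `r^2 = (p11 - pa pb)^2 / (pa (1-pa) pb (1-pb))` with a 1-df chi-square
#' p-value on `n_reads * r^2`. A monomorphic site leaves `r^2` undefined
#' (`defined = FALSE`), which downstream counts as failing the cutoff.
#'
#' @param records pooled records of one region (data.frame with `pattern`,
#'   `count`, `cpg_index`).
#' @param site_a,site_b 1-based CpG indices within the region's CpG map.
#' @return list with `site_a`, `site_b`, `r2`, `p_value`, `n_reads`,
#'   `defined`.
#' @export
pairwise_r2 <- function(records, site_a, site_b) {
  lens <- nchar(records$pattern)
  cover <- records$cpg_index <= min(site_a, site_b) &
    records$cpg_index + lens - 1L >= max(site_a, site_b)
  r <- records[cover, , drop = FALSE]
  a <- as.integer(substr(r$pattern, site_a - r$cpg_index + 1L,
                         site_a - r$cpg_index + 1L))
  b <- as.integer(substr(r$pattern, site_b - r$cpg_index + 1L,
                         site_b - r$cpg_index + 1L))
  w <- as.numeric(r$count)
  res <- r2_from_counts(sum(w[a == 1 & b == 1]), sum(w[a == 1 & b == 0]),
                        sum(w[a == 0 & b == 1]), sum(w[a == 0 & b == 0]))
  c(list(site_a = site_a, site_b = site_b), res)
}

#' Discover methylation haplotype blocks in one region
#'
#' Scans the region's CpG sites in order; a block is a maximal run of
#' consecutive CpGs in which every adjacent pair has defined
#' `r^2 > r2_cutoff`, `p < p_cutoff` and at least `min_pair_reads`
#' informative reads. Runs shorter than `core_window` CpGs are discarded.
#' Pooled input means blocks are cohort-wide.
#'
#' @param records pooled records of the region (all samples).
#' @param region one-row slice of a `target_regions` table.
#' @param r2_cutoff,core_window,p_cutoff,min_pair_reads block parameters
#'   (defaults 0.3, 3, 0.05, 10).
#' @return `mhb_set` data.frame: `mhb_id, chrom, start, end, region_name,
#'   region_class, first_idx, last_idx, n_cpgs` and list-column
#'   `cpg_positions`; empty (with a message) when the region has < 3
#'   mapped CpGs.
#' @export
discover_mhbs <- function(records, region, r2_cutoff = 0.3,
                          core_window = 3L, p_cutoff = 0.05,
                          min_pair_reads = 10L) {
  pos <- region$cpg_positions[[1]]
  n_cpg <- length(pos)
  if (n_cpg < 3) {
    message("region ", region$name, " has ", n_cpg,
            " mapped CpGs (<3); no blocks")
    return(empty_mhb_set())
  }
  hm <- hap_matrix(records, n_cpg)
  ok <- logical(n_cpg - 1L)
  for (j in seq_len(n_cpg - 1L)) {
    cover <- !is.na(hm$m[, j]) & !is.na(hm$m[, j + 1L])
    a <- hm$m[cover, j]
    b <- hm$m[cover, j + 1L]
    w <- hm$w[cover]
    res <- r2_from_counts(sum(w[a == 1 & b == 1]), sum(w[a == 1 & b == 0]),
                          sum(w[a == 0 & b == 1]), sum(w[a == 0 & b == 0]))
    ok[j] <- res$defined && res$n_reads >= min_pair_reads &&
      res$r2 > r2_cutoff && res$p_value < p_cutoff
  }
  # maximal runs of linked adjacent pairs -> runs of k pairs = k+1 CpGs
  runs <- rle(ok)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  out <- list()
  for (t in which(runs$values)) {
    first <- starts[t]
    last <- ends[t] + 1L
    if (last - first + 1L < core_window) next
    out[[length(out) + 1L]] <- data.frame(
      chrom = region$chrom,
      start = pos[first],
      end = pos[last] + 1L,
      region_name = region$name,
      region_class = region$class,
      first_idx = first,
      last_idx = last,
      n_cpgs = last - first + 1L,
      stringsAsFactors = FALSE
    )
  }
  if (!length(out)) return(empty_mhb_set())
  res <- do.call(rbind, out)
  res$mhb_id <- sprintf("%s:%d", res$region_name, seq_len(nrow(res)))
  res$cpg_positions <- lapply(seq_len(nrow(res)), function(i) {
    pos[res$first_idx[i]:res$last_idx[i]]
  })
  class(res) <- c("mhb_set", "data.frame")
  res[c("mhb_id", "chrom", "start", "end", "region_name", "region_class",
        "first_idx", "last_idx", "n_cpgs", "cpg_positions")]
}

empty_mhb_set <- function() {
  res <- data.frame(mhb_id = character(), chrom = character(),
                    start = integer(), end = integer(),
                    region_name = character(), region_class = character(),
                    first_idx = integer(), last_idx = integer(),
                    n_cpgs = integer(), stringsAsFactors = FALSE)
  res$cpg_positions <- list()
  class(res) <- c("mhb_set", "data.frame")
  res
}

#' Discover blocks across every region of a cohort
#'
#' @param cohort list of `hap_set` objects (pooled internally).
#' @param regions `target_regions` table.
#' @inheritParams discover_mhbs
#' @return `mhb_set` over all regions, sorted by `(chrom, start)`.
#' @export
discover_mhbs_cohort <- function(cohort, regions, r2_cutoff = 0.3,
                                 core_window = 3L, p_cutoff = 0.05,
                                 min_pair_reads = 10L) {
  pool <- pool_haplotypes(cohort)
  by_region <- split(pool, pool$region)
  res <- lapply(seq_len(nrow(regions)), function(i) {
    rec <- by_region[[regions$name[i]]]
    if (is.null(rec)) rec <- empty_records()
    suppressMessages(discover_mhbs(rec, regions[i, , drop = FALSE],
                                   r2_cutoff, core_window, p_cutoff,
                                   min_pair_reads))
  })
  out <- do.call(rbind, res)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("mhb_set", "data.frame")
  out
}

#' Treat whole regions as blocks
#'
#' Builds an `mhb_set` in which each region's full CpG range is one block;
#' used for control-region reporting and for calibration studies where the
#' unit of testing is the region itself.
#'
#' @param regions `target_regions` table.
#' @return `mhb_set` with one block per region having >= 1 CpG.
#' @export
regions_as_blocks <- function(regions) {
  keep <- lengths(regions$cpg_positions) >= 1
  reg <- regions[keep, , drop = FALSE]
  res <- data.frame(
    mhb_id = paste0(reg$name, ":R"),
    chrom = reg$chrom,
    start = vapply(reg$cpg_positions, min, integer(1)),
    end = vapply(reg$cpg_positions, max, integer(1)) + 1L,
    region_name = reg$name,
    region_class = reg$class,
    first_idx = 1L,
    last_idx = lengths(reg$cpg_positions),
    n_cpgs = lengths(reg$cpg_positions),
    stringsAsFactors = FALSE
  )
  res$cpg_positions <- reg$cpg_positions
  rownames(res) <- NULL
  class(res) <- c("mhb_set", "data.frame")
  res
}

#' Count-weighted read support of each block per sample
#'
#' @param cohort list of `hap_set` objects.
#' @param blocks `mhb_set`.
#' @return samples x blocks matrix of reads overlapping >= 1 member CpG.
#' @export
block_read_support <- function(cohort, blocks) {
  supp <- matrix(0, length(cohort), nrow(blocks),
                 dimnames = list(vapply(cohort, `[[`, character(1),
                                        "sample_id"),
                                 blocks$mhb_id))
  for (s in seq_along(cohort)) {
    rec <- cohort[[s]]$records
    by_region <- split(rec, rec$region)
    for (b in seq_len(nrow(blocks))) {
      rr <- by_region[[blocks$region_name[b]]]
      if (is.null(rr)) next
      re <- rr$cpg_index + nchar(rr$pattern) - 1L
      hit <- rr$cpg_index <= blocks$last_idx[b] & re >= blocks$first_idx[b]
      supp[s, b] <- sum(rr$count[hit])
    }
  }
  supp
}

#' Filter blocks on CpG count and median read support
#'
#' Retains blocks with at least `min_cpgs` member CpGs and a median (across
#' samples) read support strictly greater than `min_median_reads`; a block
#' at exactly the read bound is removed. Blocks overlapping control
#' regions are flagged (`is_control`) — they are excluded from the
#' differential analysis downstream but retained here for control
#' reporting.
#'
#' @param blocks `mhb_set`.
#' @param read_support samples x blocks matrix from
#'   [block_read_support()].
#' @param min_cpgs,min_median_reads thresholds (defaults 3, 50).
#' @return Filtered `mhb_set` with columns `median_reads`, `is_control`;
#'   attribute `n_dropped`.
#' @export
filter_mhbs <- function(blocks, read_support, min_cpgs = 3L,
                        min_median_reads = 50) {
  med <- apply(read_support[, blocks$mhb_id, drop = FALSE], 2, median)
  keep <- blocks$n_cpgs >= min_cpgs & med > min_median_reads
  out <- blocks[keep, , drop = FALSE]
  out$median_reads <- med[keep]
  out$is_control <- out$region_class != "target"
  rownames(out) <- NULL
  attr(out, "n_dropped") <- sum(!keep)
  class(out) <- c("mhb_set", "data.frame")
  out
}

#' Read blocks back from the TSV sidecar written by [write_mhbs()]
#'
#' @param sidecar_path sidecar TSV path.
#' @param regions `target_regions` the blocks were discovered in (used to
#'   re-index member CpGs against each region's CpG map).
#' @return `mhb_set`.
#' @export
read_mhbs <- function(sidecar_path, regions) {
  sc <- as.data.frame(fread(sidecar_path, sep = "\t"))
  pos_list <- lapply(strsplit(sc$cpg_positions, ",", fixed = TRUE),
                     as.integer)
  ri <- match(sc$region, regions$name)
  if (anyNA(ri)) stop("sidecar names regions absent from the region table")
  first_idx <- vapply(seq_len(nrow(sc)), function(i) {
    match(pos_list[[i]][1], regions$cpg_positions[[ri[i]]])
  }, integer(1))
  res <- data.frame(
    mhb_id = sc$mhb_id, chrom = regions$chrom[ri],
    start = vapply(pos_list, min, integer(1)),
    end = vapply(pos_list, max, integer(1)) + 1L,
    region_name = sc$region, region_class = sc$region_class,
    first_idx = first_idx,
    last_idx = first_idx + lengths(pos_list) - 1L,
    n_cpgs = sc$n_cpgs, stringsAsFactors = FALSE)
  res$cpg_positions <- pos_list
  if ("is_control" %in% names(sc)) res$is_control <- sc$is_control
  class(res) <- c("mhb_set", "data.frame")
  res
}

#' Write blocks as BED4 plus a TSV sidecar of member CpGs
#'
#' @param blocks `mhb_set`.
#' @param bed_path BED4 output (chrom, start, end, mhb_id).
#' @param sidecar_path TSV with n_cpgs and comma-joined member positions.
#' @export
write_mhbs <- function(blocks, bed_path, sidecar_path = NULL) {
  fwrite(data.table(chrom = blocks$chrom, start = blocks$start,
                    end = blocks$end, name = blocks$mhb_id),
         bed_path, sep = "\t", col.names = FALSE)
  if (!is.null(sidecar_path)) {
    sc <- data.table(
      mhb_id = blocks$mhb_id, region = blocks$region_name,
      region_class = blocks$region_class, n_cpgs = blocks$n_cpgs,
      cpg_positions = vapply(blocks$cpg_positions, paste,
                             character(1), collapse = ","))
    if ("is_control" %in% names(blocks)) sc$is_control <- blocks$is_control
    fwrite(sc, sidecar_path, sep = "\t")
  }
  invisible(bed_path)
}
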