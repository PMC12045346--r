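# All genomic coordinates in this package are 0-based half-open (BED
# convention); a CpG position is the coordinate of the C on the forward
# strand.  A haplotype pattern is a string over {0,1}, one symbol per CpG in
# [start, end), ordered by position.

REGION_CLASSES <- c("target", "positive_control", "negative_control")

#' Read target region definitions and their CpG map
#'
#' Regions come as a BED-like tab-separated file with columns
#' `chrom, start, end, name, class` (header required); the CpG map is a
#' two-column `chrom, pos` file listing every assayed CpG position.
#' Regions are validated (positive width, known class, no overlap on a
#' chromosome, CpGs inside their region) and returned sorted by
#' `(chrom, start)` with a `cpg_positions` list-column.
#'
#' @param path region file path.
#' @param cpg_map_path CpG map file path.
#' @return A `data.frame` of class `target_regions` with columns
#'   `chrom, start, end, name, class, n_cpgs` and list-column
#'   `cpg_positions`.
#' @export
read_regions <- function(path, cpg_map_path) {
  if (!file.exists(path)) stop("region file not found: ", path)
  if (!file.exists(cpg_map_path)) stop("CpG map file not found: ", cpg_map_path)
  reg <- as.data.frame(fread(path, sep = "\t", header = TRUE))
  need <- c("chrom", "start", "end", "name", "class")
  if (!all(need %in% names(reg))) {
    stop("region file must have columns: ", paste(need, collapse = ", "))
  }
  cpgs <- as.data.frame(fread(cpg_map_path, sep = "\t", header = TRUE))
  if (!all(c("chrom", "pos") %in% names(cpgs))) {
    stop("CpG map must have columns chrom, pos")
  }
  make_regions(reg[need], cpgs)
}

#' Construct a validated region table from in-memory data frames
#'
#' @param regions data.frame with chrom, start, end, name, class.
#' @param cpg_map data.frame with chrom, pos.
#' @return `target_regions` object (see [read_regions()]).
#' @export
make_regions <- function(regions, cpg_map) {
  reg <- as.data.frame(regions)
  bad <- reg$start >= reg$end
  if (any(bad)) {
    stop("regions with start >= end: ", paste(reg$name[bad], collapse = ", "))
  }
  if (anyDuplicated(reg$name)) stop("duplicate region names")
  unknown <- !(reg$class %in% REGION_CLASSES)
  if (any(unknown)) {
    stop("unknown region class label(s): ",
         paste(unique(reg$class[unknown]), collapse = ", "),
         " (allowed: ", paste(REGION_CLASSES, collapse = ", "), ")")
  }
  reg <- reg[order(reg$chrom, reg$start), , drop = FALSE]
  rownames(reg) <- NULL
  # overlap check per chromosome on the sorted table
  for (ch in unique(reg$chrom)) {
    r <- reg[reg$chrom == ch, , drop = FALSE]
    if (nrow(r) > 1) {
      ov <- which(r$start[-1] < r$end[-nrow(r)])
      if (length(ov)) {
        stop("overlapping regions on ", ch, ": ",
             r$name[ov[1]], " and ", r$name[ov[1] + 1])
      }
    }
  }
  cm <- as.data.frame(cpg_map)
  reg$cpg_positions <- lapply(seq_len(nrow(reg)), function(i) {
    p <- sort(unique(cm$pos[cm$chrom == reg$chrom[i]]))
    p[p >= reg$start[i] & p < reg$end[i]]
  })
  # CpGs claimed by no region are fine; a region-specific map entry outside
  # its region is caught when the map is given per region
  assigned <- sum(lengths(reg$cpg_positions))
  per_chr <- vapply(unique(reg$chrom), function(ch) {
    length(unique(cm$pos[cm$chrom == ch]))
  }, integer(1))
  reg$n_cpgs <- lengths(reg$cpg_positions)
  attr(reg, "n_cpgs_unassigned") <- sum(per_chr) - assigned
  class(reg) <- c("target_regions", "data.frame")
  reg
}

#' Write regions and their CpG map back to disk
#'
#' Inverse of [read_regions()]; used by the synthetic cohort generator.
#'
#' @param regions `target_regions` object.
#' @param path,cpg_map_path output paths.
#' @export
write_regions <- function(regions, path, cpg_map_path) {
  out <- as.data.frame(regions)[c("chrom", "start", "end", "name", "class")]
  fwrite(out, path, sep = "\t")
  cm <- data.table(
    chrom = rep(regions$chrom, lengths(regions$cpg_positions)),
    pos   = unlist(regions$cpg_positions, use.names = FALSE)
  )
  fwrite(cm, cpg_map_path, sep = "\t")
  invisible(path)
}

#' Read one sample's read-level methylation haplotypes
#'
#' Parses an mHap-style tab-separated file with columns
#' `chrom, start, end, pattern, count, strand` (no header). Each record is
#' mapped to the target region containing its first CpG; the pattern length
#' is cross-checked against the number of mapped CpG positions in
#' `[start, end)`. Malformed records are not silently dropped: they are
#' returned in the `rejected` table with line numbers and reasons, and
#' records overlapping no region are tallied as `unmapped`.
#'
#' @param path haplotype file path.
#' @param regions `target_regions` from [read_regions()].
#' @param sample_id identifier for the sample; defaults to the file stem.
#' @return A `hap_set`: list with `sample_id`, `records` (data.frame with
#'   `chrom, start, end, pattern, count, strand, region, cpg_index`),
#'   `unmapped` (data.frame of well-formed but unassignable records),
#'   `rejected` (data.frame `line, reason`).
#' @export
read_haplotypes <- function(path, regions, sample_id = NULL) {
  if (!file.exists(path)) stop("haplotype file not found: ", path)
  if (is.null(sample_id)) {
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  }
  if (file.size(path) == 0) {
    return(hap_set(sample_id, empty_records(), empty_records(),
                   data.frame(line = integer(), reason = character())))
  }
  raw <- fread(path, sep = "\t", header = FALSE, colClasses = "character",
               fill = TRUE)
  if (ncol(raw) < 6) {
    stop("haplotype file must be tab-separated with 6 columns: ", path)
  }
  df <- data.frame(
    chrom   = raw[[1]],
    start   = suppressWarnings(as.integer(raw[[2]])),
    end     = suppressWarnings(as.integer(raw[[3]])),
    pattern = raw[[4]],
    count   = suppressWarnings(as.integer(raw[[5]])),
    strand  = raw[[6]],
    stringsAsFactors = FALSE
  )
  df$line <- seq_len(nrow(df))
  reason <- rep(NA_character_, nrow(df))
  bad_num <- is.na(df$start) | is.na(df$end) | is.na(df$count)
  reason[bad_num] <- "non-numeric coordinate or count"
  bad_pat <- !grepl("^[01]+$", df$pattern)
  reason[is.na(reason) & bad_pat] <- "pattern contains characters outside {0,1}"
  ok <- is.na(reason)
  reason[ok & df$count < 1] <- "count < 1"
  reason[is.na(reason) & df$start >= df$end] <- "start >= end"
  reason[is.na(reason) & !(df$strand %in% c("+", "-", "*"))] <-
    "invalid strand"
  ok <- is.na(reason)

  ass <- assign_records(df[ok, , drop = FALSE], regions)
  rejected <- rbind(
    data.frame(line = df$line[!ok], reason = reason[!ok]),
    ass$rejected
  )
  rejected <- rejected[order(rejected$line), , drop = FALSE]
  rownames(rejected) <- NULL
  if (nrow(rejected)) {
    warning(sprintf("%s: %d malformed record(s), e.g. line %d: %s",
                    basename(path), nrow(rejected), rejected$line[1],
                    rejected$reason[1]))
  }
  hap_set(sample_id, ass$records, ass$unmapped, rejected)
}

hap_set <- function(sample_id, records, unmapped, rejected) {
  structure(list(sample_id = sample_id, records = records,
                 unmapped = unmapped, rejected = rejected),
            class = "hap_set")
}

empty_records <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             pattern = character(), count = integer(), strand = character(),
             region = character(), cpg_index = integer(),
             stringsAsFactors = FALSE)
}

#' @export
print.hap_set <- function(x, ...) {
  cat(sprintf(
    "<hap_set> sample %s: %d records (%s reads) in %d regions; %d unmapped, %d rejected\n",
    x$sample_id, nrow(x$records), format(sum(x$records$count)),
    length(unique(x$records$region)), nrow(x$unmapped), nrow(x$rejected)))
  invisible(x)
}

# Map records to the region containing their first CpG and index the pattern
# against the region CpG map.  Records whose pattern length disagrees with
# the map are rejected with context; records in no region go to `unmapped`.
assign_records <- function(df, regions) {
  n <- nrow(df)
  region <- rep(NA_character_, n)
  cpg_index <- rep(NA_integer_, n)
  reason <- rep(NA_character_, n)
  if (n > 0) {
    for (i in seq_len(nrow(regions))) {
      hit <- which(df$chrom == regions$chrom[i] &
                     df$start >= regions$start[i] &
                     df$start < regions$end[i])
      if (!length(hit)) next
      pos <- regions$cpg_positions[[i]]
      idx <- match(df$start[hit], pos)
      # first coordinate must itself be a mapped CpG
      bad_anchor <- is.na(idx)
      reason[hit[bad_anchor]] <- sprintf(
        "start %d is not a mapped CpG in region %s",
        df$start[hit[bad_anchor]], regions$name[i])
      good <- hit[!bad_anchor]
      idx <- idx[!bad_anchor]
      if (!length(good)) next
      # number of map CpGs in [start, end) must equal pattern length
      n_in_span <- vapply(seq_along(good), function(k) {
        sum(pos >= df$start[good[k]] & pos < df$end[good[k]])
      }, integer(1))
      plen <- nchar(df$pattern[good])
      mism <- plen != n_in_span
      reason[good[mism]] <- sprintf(
        "pattern length %d but %d CpGs mapped in span (region %s)",
        plen[mism], n_in_span[mism], regions$name[i])
      keep <- good[!mism]
      region[keep] <- regions$name[i]
      cpg_index[keep] <- idx[!mism]
    }
  }
  rejected_idx <- which(!is.na(reason))
  mapped_idx <- which(!is.na(region))
  unmapped_idx <- setdiff(which(is.na(region)), rejected_idx)
  rec <- df[mapped_idx, , drop = FALSE]
  rec$region <- region[mapped_idx]
  rec$cpg_index <- cpg_index[mapped_idx]
  rec$line <- NULL
  unm <- df[unmapped_idx, , drop = FALSE]
  unm$region <- rep(NA_character_, nrow(unm))
  unm$cpg_index <- rep(NA_integer_, nrow(unm))
  unm$line <- NULL
  rownames(rec) <- rownames(unm) <- NULL
  list(
    records = rec,
    unmapped = unm,
    rejected = data.frame(line = df$line[rejected_idx],
                          reason = reason[rejected_idx])
  )
}

#' Write a sample's haplotype records as mHap-style text
#'
#' Round-trip property: reading the written file against the same regions
#' reproduces the record set exactly.
#'
#' @param set `hap_set` from [read_haplotypes()] or the simulator.
#' @param path output path.
#' @export
write_haplotypes <- function(set, path) {
  rec <- set$records
  out <- data.table(chrom = rec$chrom, start = rec$start, end = rec$end,
                    pattern = rec$pattern, count = rec$count,
                    strand = rec$strand)
  fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Total read mass of a haplotype set
#'
#' Sum of record multiplicities over mapped plus unmapped records; conserved
#' through parsing and region assignment.
#'
#' @param set `hap_set`.
#' @export
read_mass <- function(set) {
  sum(set$records$count) + sum(set$unmapped$count)
}
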