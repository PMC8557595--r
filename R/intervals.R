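#' Genomic interval tables
#'
#' All genomic coordinates in this package are 0-based, half-open
#' (BED convention): an interval covers bases `start .. end - 1`. Interval
#' tables are plain tibbles with at least the columns `chrom` (character),
#' `start` and `end` (integers, `0 <= start < end`). Extra columns (signal,
#' names, scores) ride along untouched unless documented otherwise.
#'
#' @name interval-tables
NULL

# Validate an interval tibble; errors name the offending row so malformed
# BED records are traceable.
validate_intervals <- function(x, arg = "x", require_cols = character()) {
  if (!is.data.frame(x)) {
    abort(sprintf("`%s` must be a data frame of intervals", arg))
  }
  x <- as_tibble(x)
  needed <- c("chrom", "start", "end", require_cols)
  missing <- setdiff(needed, names(x))
  if (length(missing) > 0) {
    abort(sprintf(
      "`%s` is missing interval column(s): %s",
      arg, paste(missing, collapse = ", ")
    ))
  }
  if (nrow(x) == 0) {
    return(x)
  }
  if (!is.character(x$chrom) && !is.factor(x$chrom)) {
    abort(sprintf("`%s$chrom` must be character", arg))
  }
  x$chrom <- as.character(x$chrom)
  x$start <- as.integer(round(x$start))
  x$end <- as.integer(round(x$end))
  bad <- which(is.na(x$chrom) | !nzchar(x$chrom) |
    is.na(x$start) | is.na(x$end) |
    x$start < 0L | x$end <= x$start)
  if (length(bad) > 0) {
    i <- bad[1]
    abort(sprintf(
      "`%s` row %d is not a valid interval: chrom=%s start=%s end=%s (need start >= 0, end > start)",
      arg, i, as.character(x$chrom[i]), as.character(x$start[i]), as.character(x$end[i])
    ))
  }
  x
}

# tibble (0-based half-open) -> GRanges (1-based closed)
as_granges <- function(x) {
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end)
  )
}

granges_to_tibble <- function(gr) {
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
}

empty_intervals <- function() {
  tibble(chrom = character(), start = integer(), end = integer())
}

#' Merge intervals within a gap tolerance
#'
#' Collapses a set of intervals into their union: intervals on the same
#' chromosome that overlap, abut, or are separated by at most `min_gap`
#' bases are merged transitively into one envelope interval. This is the
#' operation used to collapse per-stage super-enhancer calls into one
#' merged universe.
#'
#' @param x Interval tibble (`chrom`, `start`, `end`); extra columns are
#'   dropped.
#' @param min_gap Non-negative integer: two intervals separated by a gap of
#'   at most `min_gap` bases are merged. `min_gap = 0` merges overlapping
#'   and bookended intervals only.
#' @return A tibble of disjoint intervals sorted by (`chrom`, `start`);
#'   consecutive intervals on a chromosome are separated by more than
#'   `min_gap` bases.
#' @examples
#' merge_intervals(tibble::tibble(
#'   chrom = "chr1", start = c(100L, 150L), end = c(200L, 300L)
#' ))
#' @export
merge_intervals <- function(x, min_gap = 0L) {
  x <- validate_intervals(x)
  if (length(min_gap) != 1 || is.na(min_gap) || min_gap < 0) {
    abort("`min_gap` must be a single non-negative integer")
  }
  if (nrow(x) == 0) {
    return(empty_intervals())
  }
  red <- GenomicRanges::reduce(as_granges(x), min.gapwidth = as.integer(min_gap) + 1L)
  arrange(granges_to_tibble(red), .data$chrom, .data$start)
}

#' Pairwise interval overlap test
#'
#' Two intervals overlap iff they are on the same chromosome and share at
#' least one base under half-open arithmetic; bookended intervals
#' (`end == start`) do not overlap.
#'
#' @param a,b Interval tibbles with the same number of rows (or one of them
#'   single-row, which is recycled). Tested row-by-row.
#' @return Logical vector.
#' @export
intervals_overlap <- function(a, b) {
  a <- validate_intervals(a, "a")
  b <- validate_intervals(b, "b")
  if (nrow(a) != nrow(b)) {
    if (nrow(a) == 1) a <- a[rep(1L, nrow(b)), ] else if (nrow(b) == 1) b <- b[rep(1L, nrow(a)), ]
    else abort("`a` and `b` must have the same number of rows (or one row)")
  }
  a$chrom == b$chrom & a$start < b$end & b$start < a$end
}

# For each row of `query`, the number of `subject` intervals overlapping it
# by >= 1 base. Internal workhorse for presence/absence set logic.
count_region_overlaps <- function(query, subject) {
  query <- validate_intervals(query, "query")
  subject <- validate_intervals(subject, "subject")
  if (nrow(query) == 0) {
    return(integer())
  }
  if (nrow(subject) == 0) {
    return(rep(0L, nrow(query)))
  }
  GenomicRanges::countOverlaps(as_granges(query), as_granges(subject), minoverlap = 1L)
}

#' Genes within a window of a region
#'
#' Returns every gene whose body lies within `window` bases of `region`
#' (distance 0 if overlapping, otherwise the gap between nearest edges),
#' strand-agnostic. Used to attach neighboring genes to super-enhancers
#' ("genes within 50 kb").
#'
#' @param genes Gene annotation tibble with columns `gene_id`, `chrom`,
#'   `start`, `end` (and optionally `tss`, `biotype`).
#' @param region Single-row interval tibble.
#' @param window Non-negative integer window in bases.
#' @return The matching rows of `genes` plus a `distance` column, sorted by
#'   distance then `gene_id` (lexicographic tie-break).
#' @export
genes_within_window <- function(genes, region, window = 50000L) {
  genes <- validate_intervals(genes, "genes", require_cols = "gene_id")
  region <- validate_intervals(region, "region")
  if (nrow(region) != 1) {
    abort("`region` must be a single-row interval tibble")
  }
  if (length(window) != 1 || is.na(window) || window < 0) {
    abort("`window` must be a single non-negative integer")
  }
  if (nrow(genes) == 0) {
    return(mutate(genes, distance = integer()))
  }
  gap <- pmax(0L, pmax(region$start - genes$end, genes$start - region$end))
  out <- genes[genes$chrom == region$chrom & gap <= window, , drop = FALSE]
  out$distance <- gap[genes$chrom == region$chrom & gap <= window]
  arrange(out, .data$distance, .data$gene_id)
}

#' Depth-normalized signal over regions
#'
#' Sums a per-base signal track over each region and rescales by sequencing
#' depth: `signal = (per-base sum) * scale_constant / library_size`. The
#' track is a bedGraph-like tibble of constant-value bins; a base covered by
#' a bin of value v contributes v.
#'
#' @param regions Interval tibble.
#' @param track bedGraph-like tibble: `chrom`, `start`, `end`, `value`.
#' @param library_size Positive real (e.g. mapped reads); doubling it halves
#'   every signal.
#' @param scale_constant Normalization scale; default `1e6` (per-million).
#' @return `regions` with a `signal` column appended (non-negative reals).
#'   Regions on chromosomes absent from the track get signal 0 with a
#'   warning.
#' @export
quantify_signal <- function(regions, track, library_size, scale_constant = 1e6) {
  regions <- validate_intervals(regions, "regions")
  track <- validate_intervals(track, "track", require_cols = "value")
  if (length(library_size) != 1 || is.na(library_size) || library_size <= 0) {
    abort("`library_size` must be a single positive number")
  }
  if (nrow(track) > 0 && any(track$value < 0)) {
    abort("`track$value` must be non-negative")
  }
  if (nrow(regions) == 0) {
    return(mutate(regions, signal = numeric()))
  }
  missing_chrom <- setdiff(unique(regions$chrom), unique(track$chrom))
  if (length(missing_chrom) > 0) {
    warn(sprintf(
      "no signal for chromosome(s) %s; their regions get signal 0",
      paste(missing_chrom, collapse = ", ")
    ))
  }
  sums <- numeric(nrow(regions))
  if (nrow(track) > 0) {
    gr_r <- as_granges(regions)
    gr_t <- as_granges(track)
    hits <- GenomicRanges::findOverlaps(gr_r, gr_t, minoverlap = 1L)
    if (length(hits) > 0) {
      qi <- S4Vectors::queryHits(hits)
      si <- S4Vectors::subjectHits(hits)
      ov <- pmin(regions$end[qi], track$end[si]) - pmax(regions$start[qi], track$start[si])
      contrib <- ov * track$value[si]
      agg <- rowsum(contrib, group = qi)
      sums[as.integer(rownames(agg))] <- agg[, 1]
    }
  }
  mutate(regions, signal = sums * scale_constant / library_size)
}

#' Read and write BED-family files
#'
#' Tab-delimited, headerless BED3+ reader preserving 0-based half-open
#' coordinates; `track`, `browser` and `#` comment lines are skipped.
#' Optional columns 4 and 5 are returned as `name` and `score`.
#' `read_bedgraph()` reads 4-column signal tracks (`chrom`, `start`, `end`,
#' `value`). `write_bed()` round-trips: `read_bed(write_bed(x))` equals `x`.
#'
#' @param path File path.
#' @return A tibble of intervals.
#' @export
read_bed <- function(path) {
  parse_bed_lines(path, value_col = FALSE)
}

#' @rdname read_bed
#' @export
read_bedgraph <- function(path) {
  parse_bed_lines(path, value_col = TRUE)
}

parse_bed_lines <- function(path, value_col) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path))
  }
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0) {
    out <- empty_intervals()
    if (value_col) out$value <- numeric()
    return(out)
  }
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  min_fields <- if (value_col) 4L else 3L
  if (any(nf < min_fields)) {
    abort(sprintf(
      "%s line %d: expected >= %d tab-delimited fields",
      path, idx[which(nf < min_fields)[1]], min_fields
    ))
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start_chr <- vapply(fields, `[[`, "", 2L)
  end_chr <- vapply(fields, `[[`, "", 3L)
  bad <- which(!grepl("^-?[0-9]+$", start_chr) | !grepl("^-?[0-9]+$", end_chr))
  if (length(bad) > 0) {
    abort(sprintf("%s line %d: non-integer coordinates", path, idx[bad[1]]))
  }
  start <- as.integer(start_chr)
  end <- as.integer(end_chr)
  bad <- which(start < 0L | end <= start)
  if (length(bad) > 0) {
    abort(sprintf(
      "%s line %d: invalid interval (start %d, end %d)",
      path, idx[bad[1]], start[bad[1]], end[bad[1]]
    ))
  }
  out <- tibble(chrom = chrom, start = start, end = end)
  if (value_col) {
    value <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 4L)))
    if (anyNA(value)) {
      abort(sprintf(
        "%s line %d: non-numeric signal value", path,
        idx[which(is.na(value))[1]]
      ))
    }
    out$value <- value
  } else {
    if (all(nf >= 4L)) out$name <- vapply(fields, `[[`, "", 4L)
    if (all(nf >= 5L)) {
      out$score <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 5L)))
    }
  }
  out
}

#' @rdname read_bed
#' @param x Interval tibble; `chrom`, `start`, `end` plus optional `name`,
#'   `score` (BED) or `value` (bedGraph) columns are written, in that order.
#' @export
write_bed <- function(x, path) {
  x <- validate_intervals(x, "x")
  cols <- intersect(c("chrom", "start", "end", "name", "score", "value"), names(x))
  utils::write.table(
    x[, cols, drop = FALSE], path,
    sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}
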