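#' Super-enhancer calling configuration
#'
#' Parameters of rank-ordering super-enhancer identification. Defaults
#' mirror the standard ROSE-style run used for H3K27ac: peaks within
#' 12,500 bp are stitched into one candidate region, peaks fully contained
#' in a 250 bp exclusion zone either side of an annotated TSS are removed
#' (H3K27ac marks active promoters as well as enhancers), and signal is
#' depth-normalized per million.
#'
#' @param stitch_distance Non-negative integer: maximum gap (bp) bridged
#'   when stitching peaks.
#' @param tss_exclusion Non-negative integer: half-width (bp) of the TSS
#'   exclusion zone; a peak fully contained in `[tss - tss_exclusion,
#'   tss + tss_exclusion)` of any TSS is dropped. `0` disables exclusion.
#' @param scale_constant Positive real used by depth normalization.
#' @return A list of class `se_config`.
#' @export
se_config <- function(stitch_distance = 12500L, tss_exclusion = 250L,
                      scale_constant = 1e6) {
  if (stitch_distance < 0 || tss_exclusion < 0 || scale_constant <= 0) {
    abort("invalid se_config: need stitch_distance >= 0, tss_exclusion >= 0, scale_constant > 0")
  }
  structure(
    list(
      stitch_distance = as.integer(stitch_distance),
      tss_exclusion = as.integer(tss_exclusion),
      scale_constant = scale_constant
    ),
    class = "se_config"
  )
}

#' Remove TSS-proximal peaks
#'
#' Drops peaks whose interval is fully contained within the exclusion zone
#' `[tss - tss_exclusion, tss + tss_exclusion)` of any annotated TSS.
#' Peaks that merely overlap the zone are retained (containment semantics:
#' a broad enhancer peak spanning a promoter is kept).
#'
#' @param peaks Peak tibble (`chrom`, `start`, `end`, `signal`, ...).
#' @param genes Gene annotation tibble with a `tss` column (base position).
#' @param tss_exclusion Zone half-width in bp; `0` is a no-op.
#' @return The retained rows of `peaks`.
#' @export
exclude_tss_peaks <- function(peaks, genes, tss_exclusion = 250L) {
  peaks <- validate_intervals(peaks, "peaks")
  if (tss_exclusion < 0) abort("`tss_exclusion` must be >= 0")
  if (tss_exclusion == 0 || is.null(genes) || nrow(peaks) == 0) {
    return(peaks)
  }
  genes <- as_tibble(genes)
  if (!all(c("chrom", "tss") %in% names(genes))) {
    abort("`genes` must have `chrom` and `tss` columns")
  }
  if (nrow(genes) == 0) {
    return(peaks)
  }
  zones <- tibble(
    chrom = genes$chrom,
    start = pmax(0L, as.integer(genes$tss) - as.integer(tss_exclusion)),
    end = as.integer(genes$tss) + as.integer(tss_exclusion)
  )
  hits <- GenomicRanges::findOverlaps(
    as_granges(peaks), as_granges(zones),
    type = "within", minoverlap = 1L
  )
  drop <- unique(S4Vectors::queryHits(hits))
  if (length(drop) > 0) peaks <- peaks[-drop, , drop = FALSE]
  peaks
}

#' Stitch peaks into candidate enhancer regions
#'
#' Peaks on the same chromosome separated by at most `stitch_distance`
#' bases are merged transitively into one stitched region whose signal is
#' the sum of its constituents.
#'
#' @param peaks Peak tibble with a non-negative `signal` column.
#' @param stitch_distance Maximum bridged gap in bp.
#' @return Tibble of stitched regions: `chrom`, `start`, `end`,
#'   `n_constituents`, `signal`, sorted by (`chrom`, `start`).
#' @export
stitch_peaks <- function(peaks, stitch_distance = 12500L) {
  peaks <- validate_intervals(peaks, "peaks", require_cols = "signal")
  if (nrow(peaks) > 0 && any(is.na(peaks$signal) | peaks$signal < 0)) {
    abort("`peaks$signal` must be non-negative")
  }
  merged <- merge_intervals(peaks[, c("chrom", "start", "end")], min_gap = stitch_distance)
  if (nrow(merged) == 0) {
    return(mutate(merged, n_constituents = integer(), signal = numeric()))
  }
  hits <- GenomicRanges::findOverlaps(as_granges(peaks), as_granges(merged),
    type = "within", minoverlap = 1L
  )
  idx <- S4Vectors::subjectHits(hits) # one merged region per peak
  merged$n_constituents <- as.integer(tabulate(idx, nbins = nrow(merged)))
  sums <- rowsum(peaks$signal[S4Vectors::queryHits(hits)], group = idx)
  merged$signal <- 0
  merged$signal[as.integer(rownames(sums))] <- sums[, 1]
  merged
}

#' Hockey-stick signal cutoff
#'
#' Separates super-enhancers from typical enhancers on the rank-signal
#' curve. Ranks and signals are each min-max rescaled to `[0, 1]`; scanning
#' from the low-signal end, the cutoff is the signal at the first point
#' where the two-point finite-difference slope of the scaled curve exceeds
#' 1 (the point where a tangent of slope 1 touches the curve). Regions with
#' signal strictly above the cutoff are super-enhancers.
#'
#' @param signals Numeric vector of non-negative signals (any order; sorted
#'   ascending internally). Needs at least 2 values.
#' @return The cutoff signal value. All-equal signals return the maximum
#'   (no region exceeds it) with a warning.
#' @export
hockey_stick_cutoff <- function(signals) {
  if (length(signals) < 2) {
    abort("hockey_stick_cutoff needs at least 2 signals")
  }
  if (anyNA(signals)) abort("`signals` must not contain NA")
  y <- sort(as.numeric(signals))
  n <- length(y)
  rng <- y[n] - y[1]
  if (rng == 0) {
    warn("all signals equal; cutoff set to the maximum (no super-enhancers)")
    return(y[n])
  }
  ys <- (y - y[1]) / rng
  # x is rank index scaled to [0,1]; segment slope = delta(ys) * (n - 1)
  slopes <- diff(ys) * (n - 1)
  idx <- which(slopes > 1)[1]
  if (is.na(idx)) {
    warn("rank-signal curve never exceeds slope 1; cutoff set to the maximum")
    return(y[n])
  }
  y[idx]
}

#' Call super-enhancers from peaks
#'
#' The full rank-ordering pipeline: TSS-proximal peak exclusion, peak
#' stitching, descending signal ranking, and hockey-stick thresholding.
#'
#' @param peaks Peak tibble (`chrom`, `start`, `end`, `signal`).
#' @param genes Optional gene annotation with `tss` for TSS exclusion
#'   (`NULL` disables exclusion).
#' @param config An [se_config()].
#' @return A tibble of class `se_calls`, sorted by rank: `chrom`, `start`,
#'   `end`, `n_constituents`, `signal`, `rank`, `is_super`. Rank ties are
#'   broken by (`chrom`, `start`) for a stable permutation. The cutoff is
#'   stored in `attr(, "cutoff")`. A single stitched region is degenerate:
#'   it is returned rank 1, `is_super = FALSE`, with a warning.
#' @export
call_super_enhancers <- function(peaks, genes = NULL, config = se_config()) {
  stopifnot(inherits(config, "se_config"))
  kept <- exclude_tss_peaks(peaks, genes, config$tss_exclusion)
  regions <- stitch_peaks(kept, config$stitch_distance)
  if (nrow(regions) == 0) {
    out <- mutate(regions, rank = integer(), is_super = logical())
    return(new_se_calls(out, cutoff = NA_real_, config = config))
  }
  if (nrow(regions) == 1) {
    warn("only one stitched region; hockey-stick cutoff undefined, region returned as typical")
    out <- mutate(regions, rank = 1L, is_super = FALSE)
    return(new_se_calls(out, cutoff = NA_real_, config = config))
  }
  cutoff <- hockey_stick_cutoff(regions$signal)
  ord <- order(-regions$signal, regions$chrom, regions$start)
  out <- regions[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out$is_super <- out$signal > cutoff
  new_se_calls(out, cutoff = cutoff, config = config)
}

new_se_calls <- function(x, cutoff, config) {
  structure(as_tibble(x),
    cutoff = cutoff, config = config,
    class = c("se_calls", class(as_tibble(x)))
  )
}

#' @export
print.se_calls <- function(x, ...) {
  cutoff <- attr(x, "cutoff")
  cat(sprintf(
    "<se_calls> %d stitched regions, %d super-enhancers (signal cutoff %s)\n",
    nrow(x), sum(x$is_super), format(cutoff, digits = 4)
  ))
  NextMethod()
}

#' Super-enhancer regions from a call table
#'
#' Convenience accessor: the `chrom`/`start`/`end` rows flagged
#' `is_super`, sorted by coordinate.
#'
#' @param calls An `se_calls` tibble (or any tibble with an `is_super`
#'   column).
#' @return Interval tibble of super-enhancer regions.
#' @export
se_regions <- function(calls) {
  calls <- as_tibble(calls)
  if ("is_super" %in% names(calls)) calls <- calls[calls$is_super, , drop = FALSE]
  arrange(calls[, c("chrom", "start", "end")], .data$chrom, .data$start)
}

#' Quantify a merged super-enhancer universe across stages
#'
#' Collapses every stage's super-enhancer regions into one merged universe
#' (zero-gap union), quantifies each stage's depth-normalized signal over
#' every universe region, and computes pseudocount-stabilized fold changes
#' between all ordered stage pairs.
#'
#' @param stage_calls Named list (one per stage, in progression order) of
#'   `se_calls` tibbles or plain interval tibbles of SE regions.
#' @param stage_tracks Named list of bedGraph-like signal tibbles, same
#'   names as `stage_calls`.
#' @param library_sizes Named numeric vector of per-stage sequencing depths.
#' @param pseudocount Added to numerator and denominator of every fold
#'   change (in normalized signal units) so zero-signal stages stay finite.
#' @param scale_constant Depth-normalization scale, as in
#'   [quantify_signal()].
#' @return Tibble with one row per universe region: `chrom`, `start`,
#'   `end`, one `signal_<stage>` column per stage, and
#'   `fc_<later>_vs_<earlier>` columns for every ordered stage pair.
#' @export
quantify_universe <- function(stage_calls, stage_tracks, library_sizes,
                              pseudocount = 1, scale_constant = 1e6) {
  stages <- names(stage_calls)
  if (is.null(stages) || any(!nzchar(stages))) {
    abort("`stage_calls` must be a named list (stage names in progression order)")
  }
  if (!all(stages %in% names(stage_tracks)) || !all(stages %in% names(library_sizes))) {
    abort("`stage_tracks` and `library_sizes` must cover every stage in `stage_calls`")
  }
  universe <- merge_intervals(bind_rows(lapply(stage_calls, se_regions)), min_gap = 0L)
  out <- universe
  for (s in stages) {
    q <- quantify_signal(universe, stage_tracks[[s]],
      library_size = library_sizes[[s]], scale_constant = scale_constant
    )
    out[[paste0("signal_", s)]] <- q$signal
  }
  if (length(stages) >= 2) {
    for (i in seq_along(stages)[-length(stages)]) {
      for (j in seq((i + 1), length(stages))) {
        a <- out[[paste0("signal_", stages[i])]]
        b <- out[[paste0("signal_", stages[j])]]
        out[[sprintf("fc_%s_vs_%s", stages[j], stages[i])]] <-
          (b + pseudocount) / (a + pseudocount)
      }
    }
  }
  out
}
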