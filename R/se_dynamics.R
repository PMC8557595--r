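#' Stage-wise super-enhancer set logic
#'
#' A progression series is an ordered, named list of interval tibbles,
#' baseline (normal) stage first. "Present at a stage" means overlapping
#' (>= 1 bp) any super-enhancer of that stage; stitched boundaries shift
#' between samples, so identity of coordinates is never required, and a
#' region overlapping two later-stage regions still counts once.
#'
#' @name se-dynamics
NULL

check_series <- function(series) {
  if (!is.list(series) || length(series) < 2) {
    abort("`series` must be a list of >= 2 stage interval tables (baseline first)")
  }
  nm <- names(series)
  if (is.null(nm) || any(!nzchar(nm)) || anyDuplicated(nm) > 0) {
    abort("`series` must have unique, non-empty stage names")
  }
  out <- lapply(seq_along(series), function(i) validate_intervals(series[[i]], nm[i]))
  names(out) <- nm
  out
}

#' Super-enhancers acquired at a stage
#'
#' Regions of stage `k` that overlap no super-enhancer of any earlier
#' stage (including the baseline). Acquired regions are reported with the
#' coordinates from the stage of acquisition.
#'
#' @param series Ordered named list of per-stage SE interval tibbles,
#'   baseline first.
#' @param k Stage position, `2 <= k <= length(series)` (the baseline,
#'   position 1, has no acquisition).
#' @return Interval tibble of newly acquired regions.
#' @export
acquired_at_stage <- function(series, k) {
  series <- check_series(series)
  if (length(k) != 1 || is.na(k) || k < 2 || k > length(series)) {
    abort("`k` must index a non-baseline stage (2 .. length(series))")
  }
  stage <- series[[k]]
  earlier <- bind_rows(series[seq_len(k - 1)])
  stage[count_region_overlaps(stage, earlier) == 0L, , drop = FALSE]
}

#' Super-enhancers lost relative to baseline
#'
#' Baseline regions that overlap no super-enhancer of `stage`.
#'
#' @param baseline Interval tibble of the baseline (normal) stage's SEs.
#' @param stage Interval tibble of a later stage's SEs.
#' @return Interval tibble of lost regions (baseline coordinates).
#' @export
lost_at_stage <- function(baseline, stage) {
  baseline <- validate_intervals(baseline, "baseline")
  stage <- validate_intervals(stage, "stage")
  baseline[count_region_overlaps(baseline, stage) == 0L, , drop = FALSE]
}

#' Classify acquired, retained and lost super-enhancers across a series
#'
#' For every non-baseline stage, newly acquired regions (present at that
#' stage, absent from all earlier stages) are labeled `"retained"` if they
#' overlap a super-enhancer at every later stage through the final one and
#' `"acquired"` otherwise (regions acquired at the final stage are
#' trivially retained). Separately, for every non-baseline stage, baseline
#' regions absent from that stage are labeled `"lost"` (one row per stage
#' at which they are missing, baseline coordinates).
#'
#' @inheritParams acquired_at_stage
#' @return Tibble: `chrom`, `start`, `end`, `stage`, `status` in
#'   `{"acquired", "retained", "lost"}`.
#' @export
classify_se_dynamics <- function(series) {
  series <- check_series(series)
  nm <- names(series)
  n <- length(series)
  rows <- list()
  for (k in 2:n) {
    acq <- acquired_at_stage(series, k)
    if (nrow(acq) > 0) {
      retained <- rep(TRUE, nrow(acq))
      if (k < n) {
        for (j in seq(k + 1, n)) {
          retained <- retained & count_region_overlaps(acq, series[[j]]) > 0L
        }
      }
      rows[[length(rows) + 1]] <- mutate(
        acq[, c("chrom", "start", "end")],
        stage = nm[k],
        status = ifelse(retained, "retained", "acquired")
      )
    }
    lost <- lost_at_stage(series[[1]], series[[k]])
    if (nrow(lost) > 0) {
      rows[[length(rows) + 1]] <- mutate(
        lost[, c("chrom", "start", "end")],
        stage = nm[k], status = "lost"
      )
    }
  }
  if (length(rows) == 0) {
    return(mutate(empty_intervals(), stage = character(), status = character()))
  }
  bind_rows(rows)
}

#' Patient-cohort representation of regions
#'
#' For each query region, the number of cohort patients carrying at least
#' one super-enhancer overlapping it (e.g. "a super-enhancer region in
#' 34/47 ER+ patients").
#'
#' @param cohort Tibble of patient SE intervals with a `patient_id` column.
#' @param regions Interval tibble of query regions (one count per row).
#' @return `regions` with `count` (patients carrying an overlapping SE) and
#'   `total` (cohort size) columns.
#' @export
cohort_representation <- function(cohort, regions) {
  cohort <- validate_intervals(cohort, "cohort", require_cols = "patient_id")
  regions <- validate_intervals(regions, "regions")
  patients <- unique(cohort$patient_id)
  if (length(patients) == 0) {
    abort("`cohort` has no patients")
  }
  counts <- rep(0L, nrow(regions))
  for (p in patients) {
    pset <- cohort[cohort$patient_id == p, , drop = FALSE]
    counts <- counts + as.integer(count_region_overlaps(regions, pset) > 0L)
  }
  mutate(regions, count = counts, total = length(patients))
}
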