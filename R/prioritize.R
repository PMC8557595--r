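#' Prioritization cascade configuration
#'
#' Tunable parameters of the cis-candidate funnel. Fold-change cutoffs are
#' linear-scale and interpreted inclusively on the log2 scale
#' (`|log2 FC| >= log2(cutoff)`); the neighbor window is measured between
#' gene bodies (nearest edges), strand-agnostic.
#'
#' @param fc_cutoff Linear fold-change cutoff for the differential filter
#'   and for "co-changing" neighbor mRNAs (default 2).
#' @param top_fc_cutoff Linear cutoff for the highest-differential branch
#'   (default 10); must be `>= fc_cutoff`.
#' @param window_bp Neighbor window in bases, both upstream and downstream
#'   (default 50,000).
#' @param r_cutoff Absolute Pearson correlation cutoff in patient samples,
#'   inclusive (default 0.5).
#' @param first_stage,last_stage Stage (column) names contrasted by every
#'   fold change; `NULL` means the first/last stage column of each table.
#' @param pseudocount Intensity units added to both stages before the log
#'   ratio (default 1; array-scale values make it negligible except at
#'   zero).
#' @param neighbor_biotypes Biotypes eligible as neighbor targets
#'   (default `"mRNA"`; add `"miRNA"` to scan microRNA neighbors too).
#' @return A list of class `cascade_config`.
#' @export
cascade_config <- function(fc_cutoff = 2, top_fc_cutoff = 10, window_bp = 50000L,
                           r_cutoff = 0.5, first_stage = NULL, last_stage = NULL,
                           pseudocount = 1, neighbor_biotypes = "mRNA") {
  if (fc_cutoff <= 0 || top_fc_cutoff < fc_cutoff) {
    abort("need fc_cutoff > 0 and top_fc_cutoff >= fc_cutoff")
  }
  if (window_bp <= 0) abort("`window_bp` must be positive")
  if (r_cutoff <= 0 || r_cutoff > 1) abort("`r_cutoff` must be in (0, 1]")
  structure(
    list(
      fc_cutoff = fc_cutoff, top_fc_cutoff = top_fc_cutoff,
      window_bp = as.integer(window_bp), r_cutoff = r_cutoff,
      first_stage = first_stage, last_stage = last_stage,
      pseudocount = pseudocount, neighbor_biotypes = neighbor_biotypes
    ),
    class = "cascade_config"
  )
}

stage_cols <- function(table) {
  setdiff(names(table), c("feature_id", "biotype"))
}

check_expression_table <- function(table, arg = "table") {
  if (!is.data.frame(table)) abort(sprintf("`%s` must be a data frame", arg))
  table <- as_tibble(table)
  if (!"feature_id" %in% names(table)) {
    abort(sprintf("`%s` needs a `feature_id` column", arg))
  }
  sc <- stage_cols(table)
  if (length(sc) < 2) {
    abort(sprintf("`%s` needs at least two stage columns", arg))
  }
  vals <- as.matrix(table[, sc])
  if (nrow(table) > 0 && (any(!is.finite(vals)) || any(vals < 0))) {
    abort(sprintf("`%s` stage values must be finite and non-negative", arg))
  }
  table
}

#' Log2 fold change between two stages
#'
#' `log2((value_b + pseudocount) / (value_a + pseudocount))` per feature;
#' antisymmetric under swapping the stages.
#'
#' @param table Expression tibble: `feature_id`, optional `biotype`, one
#'   column of linear-scale values per stage.
#' @param stage_a,stage_b Stage column names (defaults: first and last
#'   stage column).
#' @param pseudocount Stabilizing offset added to both values.
#' @return Tibble `feature_id`, `log2_fc` (stage_b versus stage_a).
#' @export
log2_fold_change <- function(table, stage_a = NULL, stage_b = NULL, pseudocount = 1) {
  table <- check_expression_table(table)
  sc <- stage_cols(table)
  stage_a <- stage_a %||% sc[1]
  stage_b <- stage_b %||% sc[length(sc)]
  if (!stage_a %in% sc || !stage_b %in% sc) {
    abort(sprintf("unknown stage name(s): %s", paste(setdiff(c(stage_a, stage_b), sc), collapse = ", ")))
  }
  tibble(
    feature_id = table$feature_id,
    log2_fc = log2((table[[stage_b]] + pseudocount) / (table[[stage_a]] + pseudocount))
  )
}

cfg_fold_changes <- function(table, config) {
  log2_fold_change(table,
    stage_a = config$first_stage, stage_b = config$last_stage,
    pseudocount = config$pseudocount
  )
}

#' Differential-expression filter
#'
#' Retains features whose first-to-last stage fold change meets the cutoff:
#' `|log2 FC| >= log2(fc_cutoff)`, boundary inclusive.
#'
#' @inheritParams log2_fold_change
#' @param config A [cascade_config()].
#' @return Tibble `feature_id`, `log2_fc` of retained features, in input
#'   order.
#' @export
filter_differential <- function(table, config = cascade_config()) {
  fc <- cfg_fold_changes(table, config)
  fc[abs(fc$log2_fc) >= log2(config$fc_cutoff), , drop = FALSE]
}

#' Pair lncRNAs with co-changing neighbor genes
#'
#' For each retained lncRNA, finds annotation features of the configured
#' neighbor biotypes whose gene body lies within `window_bp` of the lncRNA
#' gene body (nearest-edge distance, 0 if overlapping) and whose own
#' first-to-last fold change passes `fc_cutoff`. lncRNAs with no
#' qualifying neighbor are dropped; lncRNAs missing from the annotation
#' are skipped with a warning.
#'
#' @param lnc_ids Character vector of retained lncRNA ids.
#' @param annotation Gene annotation tibble: `gene_id`, `chrom`, `start`,
#'   `end`, `tss`, `biotype`.
#' @param lnc_table,mrna_table Expression tibbles for lncRNAs and candidate
#'   target genes.
#' @param config A [cascade_config()].
#' @return Tibble of candidate pairs: `lncrna_id`, `mrna_id`,
#'   `distance_bp`, `lncrna_log2_fc`, `mrna_log2_fc`, sorted by
#'   (`lncrna_id`, `mrna_id`).
#' @export
pair_neighbors <- function(lnc_ids, annotation, lnc_table, mrna_table,
                           config = cascade_config()) {
  annotation <- validate_intervals(annotation, "annotation",
    require_cols = c("gene_id", "biotype")
  )
  lnc_fc <- cfg_fold_changes(lnc_table, config)
  mrna_fc <- cfg_fold_changes(mrna_table, config)
  changing <- mrna_fc$feature_id[abs(mrna_fc$log2_fc) >= log2(config$fc_cutoff)]
  targets <- annotation[annotation$biotype %in% config$neighbor_biotypes &
    annotation$gene_id %in% changing, , drop = FALSE]
  missing <- setdiff(lnc_ids, annotation$gene_id)
  if (length(missing) > 0) {
    warn(sprintf(
      "%d lncRNA id(s) missing from annotation, skipped: %s",
      length(missing), paste(utils::head(missing, 5), collapse = ", ")
    ))
  }
  pairs <- purrr::map_dfr(sort(intersect(lnc_ids, annotation$gene_id)), function(id) {
    locus <- annotation[annotation$gene_id == id, , drop = FALSE][1, ]
    hits <- genes_within_window(targets, locus[, c("chrom", "start", "end")],
      window = config$window_bp
    )
    if (nrow(hits) == 0) {
      return(NULL)
    }
    tibble(
      lncrna_id = id, mrna_id = hits$gene_id, distance_bp = hits$distance,
      lncrna_log2_fc = lnc_fc$log2_fc[match(id, lnc_fc$feature_id)],
      mrna_log2_fc = mrna_fc$log2_fc[match(hits$gene_id, mrna_fc$feature_id)]
    )
  })
  if (nrow(pairs) == 0) {
    return(tibble(
      lncrna_id = character(), mrna_id = character(),
      distance_bp = integer(), lncrna_log2_fc = numeric(), mrna_log2_fc = numeric()
    ))
  }
  arrange(pairs, .data$lncrna_id, .data$mrna_id)
}

#' Flag pairs whose lncRNA is annotated in an external atlas
#'
#' Membership in the patient-expression atlas (e.g. a TANRIC id list) is an
#' injected input, never fetched.
#'
#' @param pairs Candidate-pair tibble from [pair_neighbors()].
#' @param annotated_ids Character vector of atlas-annotated lncRNA ids.
#' @return `pairs` with a logical `annotated` column.
#' @export
crossref_annotation <- function(pairs, annotated_ids) {
  mutate(as_tibble(pairs), annotated = .data$lncrna_id %in% annotated_ids)
}

#' Pearson product-moment correlation
#'
#' A contract-checking wrapper around [stats::cor()]: vectors must be the
#' same length (>= 3), finite, and non-constant.
#'
#' @param x,y Numeric vectors.
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length")
  if (length(x) < 3) abort("need at least 3 paired observations")
  if (any(!is.finite(x)) || any(!is.finite(y))) abort("inputs must be finite")
  if (sd(x) == 0 || sd(y) == 0) {
    abort("correlation undefined for a constant vector")
  }
  cor(x, y)
}

#' Patient-correlation filter
#'
#' Computes the Pearson correlation of each pair's members across patient
#' samples and flags pairs meeting `|r| >= r_cutoff` (boundary inclusive).
#' Pairs with either member absent from the matrix keep `pearson_r = NA`
#' and are left for the trend-concordance branch rather than discarded.
#'
#' @param pairs Candidate-pair tibble.
#' @param patient_matrix Numeric matrix, features in rownames, one column
#'   per patient.
#' @param config A [cascade_config()].
#' @return `pairs` with `pearson_r` and logical `correlated` columns
#'   (`correlated` is `NA` when a member is absent).
#' @export
correlation_filter <- function(pairs, patient_matrix, config = cascade_config()) {
  pairs <- as_tibble(pairs)
  if (nrow(pairs) == 0) {
    return(mutate(pairs, pearson_r = numeric(), correlated = logical()))
  }
  if (is.null(rownames(patient_matrix))) {
    abort("`patient_matrix` must have feature ids as rownames")
  }
  r <- purrr::map2_dbl(pairs$lncrna_id, pairs$mrna_id, function(a, b) {
    if (!a %in% rownames(patient_matrix) || !b %in% rownames(patient_matrix)) {
      return(NA_real_)
    }
    pearson_r(patient_matrix[a, ], patient_matrix[b, ])
  })
  mutate(pairs,
    pearson_r = r,
    correlated = ifelse(is.na(r), NA, abs(r) >= config$r_cutoff)
  )
}

as_direction_vector <- function(x, arg) {
  if (is.data.frame(x)) {
    if (!all(c("mrna_id", "direction") %in% names(x))) {
      abort(sprintf("`%s` must have `mrna_id` and `direction` columns", arg))
    }
    x <- setNames(x$direction, x$mrna_id)
  }
  if (is.null(names(x)) || !all(x %in% c(-1, 0, 1))) {
    abort(sprintf("`%s` must be named directions in {-1, 0, +1}", arg))
  }
  x
}

#' Trend-concordance filter
#'
#' Retains pairs whose neighbor gene changes in the same direction from
#' normal to tumor in patient samples as across the progression series
#' (sign agreement; a zero direction on either side fails). Pairs whose
#' gene is missing from either mapping are dropped with a warning.
#'
#' @param pairs Candidate-pair tibble.
#' @param patient_direction,series_direction Named vectors (or tibbles with
#'   `mrna_id`, `direction`) mapping gene id to a direction in
#'   `{-1, 0, +1}`.
#' @return The concordant subset of `pairs`, with a `trend_concordant`
#'   column (all `TRUE`).
#' @export
trend_concordance_filter <- function(pairs, patient_direction, series_direction) {
  pairs <- as_tibble(pairs)
  pd <- as_direction_vector(patient_direction, "patient_direction")
  sdir <- as_direction_vector(series_direction, "series_direction")
  known <- pairs$mrna_id %in% names(pd) & pairs$mrna_id %in% names(sdir)
  if (any(!known)) {
    warn(sprintf(
      "%d pair(s) dropped: gene absent from a direction mapping",
      sum(!known)
    ))
  }
  pairs <- pairs[known, , drop = FALSE]
  keep <- pd[pairs$mrna_id] == sdir[pairs$mrna_id] & pd[pairs$mrna_id] != 0
  mutate(pairs[keep, , drop = FALSE], trend_concordant = TRUE)
}

#' Highest-differential annotated features
#'
#' Features passing the extreme fold-change cutoff
#' (`|log2 FC| >= log2(top_fc_cutoff)`, inclusive) that are also
#' atlas-annotated.
#'
#' @inheritParams filter_differential
#' @param annotated_ids Atlas-annotated feature ids.
#' @return Tibble `feature_id`, `log2_fc`.
#' @export
top_differential <- function(table, annotated_ids, config = cascade_config()) {
  fc <- cfg_fold_changes(table, config)
  fc[abs(fc$log2_fc) >= log2(config$top_fc_cutoff) &
    fc$feature_id %in% annotated_ids, , drop = FALSE]
}

#' Run the cis-candidate prioritization funnel
#'
#' Executes the full cascade: differential filter on the lncRNA table,
#' neighbor pairing against co-changing genes within the window,
#' atlas-annotation cross-reference, then the patient-correlation filter
#' with pairs failing (or unmeasurable in) the correlation step re-tested
#' by trend concordance. A separate highest-differential branch keeps
#' atlas-annotated extreme responders. The shortlist is the union of the
#' correlation-retained, trend-retained, and highest-differential lncRNAs.
#'
#' @param lnc_table,mrna_table Expression tibbles (`feature_id`,
#'   `biotype`, one column per stage).
#' @param annotation Gene annotation tibble (`gene_id`, `chrom`, `start`,
#'   `end`, `tss`, `biotype`) covering both biotypes.
#' @param annotated_ids Character vector: lncRNA ids annotated in the
#'   patient atlas.
#' @param patient_matrix Feature-by-patient numeric matrix (rownames =
#'   feature ids).
#' @param patient_direction Named directions (or tibble) of each gene's
#'   normal-to-tumor change in patients, in `{-1, 0, +1}`.
#' @param config A [cascade_config()].
#' @return An object of class `cascade_report`: a list with `steps` (tibble
#'   of per-step lncRNA and pair counts in funnel order), `pairs` (all
#'   candidate pairs with filter flags), `correlated_pairs`,
#'   `trend_pairs`, `top` (highest-differential features), `shortlist`
#'   (character vector of candidate lncRNA ids) and `config`. Deterministic
#'   and invariant to input row order.
#' @export
run_cascade <- function(lnc_table, mrna_table, annotation, annotated_ids,
                        patient_matrix, patient_direction,
                        config = cascade_config()) {
  lnc_table <- check_expression_table(lnc_table, "lnc_table")
  mrna_table <- check_expression_table(mrna_table, "mrna_table")

  differential <- filter_differential(lnc_table, config)
  pairs <- pair_neighbors(differential$feature_id, annotation,
    lnc_table, mrna_table,
    config = config
  )
  pairs <- crossref_annotation(pairs, annotated_ids)
  annotated <- pairs[pairs$annotated, , drop = FALSE]
  annotated <- correlation_filter(annotated, patient_matrix, config)
  correlated <- annotated[!is.na(annotated$correlated) & annotated$correlated, , drop = FALSE]
  remaining <- annotated[is.na(annotated$correlated) | !annotated$correlated, , drop = FALSE]

  mrna_fc <- cfg_fold_changes(mrna_table, config)
  series_direction <- setNames(sign(mrna_fc$log2_fc), mrna_fc$feature_id)
  trend <- trend_concordance_filter(remaining, patient_direction, series_direction)

  top <- top_differential(lnc_table, annotated_ids, config)
  shortlist <- sort(unique(c(correlated$lncrna_id, trend$lncrna_id, top$feature_id)))

  steps <- tibble(
    step = c(
      "input", "differential", "paired", "annotated",
      "correlated", "trend_concordant", "top_differential", "shortlist"
    ),
    n_lncrnas = c(
      nrow(lnc_table), nrow(differential),
      length(unique(pairs$lncrna_id)), length(unique(annotated$lncrna_id)),
      length(unique(correlated$lncrna_id)), length(unique(trend$lncrna_id)),
      nrow(top), length(shortlist)
    ),
    n_pairs = c(
      NA_integer_, NA_integer_, nrow(pairs), nrow(annotated),
      nrow(correlated), nrow(trend), NA_integer_, NA_integer_
    )
  )
  structure(
    list(
      steps = steps, pairs = pairs, correlated_pairs = correlated,
      trend_pairs = trend, top = top, shortlist = shortlist, config = config
    ),
    class = "cascade_report"
  )
}

#' @export
print.cascade_report <- function(x, ...) {
  cat("<cascade_report>\n")
  print(x$steps, n = nrow(x$steps))
  cat(sprintf(
    "shortlist (%d): %s\n", length(x$shortlist),
    paste(utils::head(x$shortlist, 8), collapse = ", ")
  ))
  invisible(x)
}
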