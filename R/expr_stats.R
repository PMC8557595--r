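#' qPCR Ct tables
#'
#' Long-format Ct tables carry one row per well: `gene_id`, `condition`,
#' `replicate`, `ct`, and optionally `fraction` (one of `"whole"`,
#' `"nuclear"`, `"cytoplasmic"`, `"none"`) and `sample_id`. Ct values at or
#' above the detectability floor (40 cycles by default) are treated as
#' near-undetectable and flag downstream results.
#'
#' @name ct-tables
NULL

check_ct <- function(ct_data, arg = "ct_data") {
  if (!is.data.frame(ct_data)) abort(sprintf("`%s` must be a data frame", arg))
  ct_data <- as_tibble(ct_data)
  needed <- c("gene_id", "ct")
  missing <- setdiff(needed, names(ct_data))
  if (length(missing) > 0) {
    abort(sprintf("`%s` missing column(s): %s", arg, paste(missing, collapse = ", ")))
  }
  if (nrow(ct_data) > 0 && any(!is.finite(ct_data$ct))) {
    abort(sprintf("`%s$ct` must be finite", arg))
  }
  ct_data
}

mean_ct <- function(ct_data, genes, condition = NULL, fraction = NULL) {
  x <- ct_data[ct_data$gene_id %in% genes, , drop = FALSE]
  if (!is.null(condition)) x <- x[x$condition == condition, , drop = FALSE]
  if (!is.null(fraction)) x <- x[x$fraction == fraction, , drop = FALSE]
  x
}

#' Relative expression by the delta-delta-Ct method
#'
#' Per condition, `dCt = Ct_target - mean(Ct_references)` (multiple
#' reference genes are combined by the arithmetic mean of their Ct values,
#' i.e. the geometric mean of their relative quantities); then
#' `ddCt = dCt_condition - dCt_control` and
#' `fold_change = 2^(-ddCt)`. Per-replicate fold changes (each replicate's
#' target Ct against the condition's pooled reference mean and the
#' control's mean dCt) are returned for dispersion estimates.
#'
#' @param ct_data Long Ct tibble (see [ct-tables]); rows for fractionated
#'   samples should be pre-filtered to one fraction.
#' @param target Target gene id.
#' @param reference_genes Character vector of reference (housekeeping)
#'   gene ids; all must be measured in both conditions.
#' @param condition,control_condition Condition labels contrasted as
#'   condition versus control.
#' @param detect_ct Detectability floor in cycles; any involved Ct at or
#'   above it flags the result `low_confidence`.
#' @return One-row tibble: `gene_id`, `condition`, `control`,
#'   `delta_delta_ct`, `fold_change`, `low_confidence`, and a list column
#'   `rep_fold_changes`.
#' @export
delta_delta_ct <- function(ct_data, target, reference_genes, condition,
                           control_condition, detect_ct = 40) {
  ct_data <- check_ct(ct_data)
  if (!"condition" %in% names(ct_data)) abort("`ct_data` needs a `condition` column")
  if (length(reference_genes) < 1) abort("need at least one reference gene")
  pieces <- list(
    tgt_cond = mean_ct(ct_data, target, condition),
    tgt_ctrl = mean_ct(ct_data, target, control_condition),
    ref_cond = mean_ct(ct_data, reference_genes, condition),
    ref_ctrl = mean_ct(ct_data, reference_genes, control_condition)
  )
  empty <- names(pieces)[vapply(pieces, nrow, 0L) == 0]
  if (length(empty) > 0) {
    abort(sprintf(
      "missing Ct measurements for %s (target %s, conditions %s vs %s)",
      paste(empty, collapse = ", "), target, condition, control_condition
    ))
  }
  ref_means <- vapply(reference_genes, function(g) {
    c(
      nrow(mean_ct(ct_data, g, condition)) > 0,
      nrow(mean_ct(ct_data, g, control_condition)) > 0
    )
  }, logical(2))
  if (!all(ref_means)) {
    abort("every reference gene must be measured in both conditions")
  }
  # per-condition reference mean: mean over reference genes of per-gene mean Ct
  ref_mean <- function(piece) {
    mean(vapply(
      reference_genes,
      function(g) mean(piece$ct[piece$gene_id == g]), 0
    ))
  }
  dct_cond <- mean(pieces$tgt_cond$ct) - ref_mean(pieces$ref_cond)
  dct_ctrl <- mean(pieces$tgt_ctrl$ct) - ref_mean(pieces$ref_ctrl)
  ddct <- dct_cond - dct_ctrl
  rep_dct <- pieces$tgt_cond$ct - ref_mean(pieces$ref_cond)
  tibble(
    gene_id = target, condition = condition, control = control_condition,
    delta_delta_ct = ddct, fold_change = 2^(-ddct),
    low_confidence = any(vapply(pieces, function(p) any(p$ct >= detect_ct), TRUE)),
    rep_fold_changes = list(2^(-(rep_dct - dct_ctrl)))
  )
}

#' Nuclear/cytoplasmic localization call
#'
#' Converts each fraction's Ct to a relative abundance `2^(-dCt)` (against
#' the mean of per-fraction reference genes when supplied, else the raw
#' `2^(-Ct)`), normalizes within the transcript across the two fractions,
#' and calls the transcript `nuclear` when the nuclear share is at least
#' `nuclear_cutoff`, `cytoplasmic` when at most `cytoplasmic_cutoff`, and
#' `undetermined` otherwise or when the transcript is near-undetectable in
#' both fractions (all Ct at or above `detect_ct`).
#'
#' @param ct_data Long Ct tibble with a `fraction` column containing
#'   `"nuclear"` and `"cytoplasmic"` rows for `gene`.
#' @param gene Transcript id to call.
#' @param reference_genes Optional per-fraction reference gene ids used to
#'   correct for fraction RNA recovery.
#' @param nuclear_cutoff,cytoplasmic_cutoff Share thresholds (defaults
#'   0.6 / 0.4).
#' @param detect_ct Detectability floor in cycles.
#' @return One-row tibble: `gene_id`, `nuclear_share`, `call`.
#' @export
localization_call <- function(ct_data, gene, reference_genes = NULL,
                              nuclear_cutoff = 0.6, cytoplasmic_cutoff = 0.4,
                              detect_ct = 40) {
  ct_data <- check_ct(ct_data)
  if (!"fraction" %in% names(ct_data)) abort("`ct_data` needs a `fraction` column")
  nuc <- mean_ct(ct_data, gene, fraction = "nuclear")
  cyt <- mean_ct(ct_data, gene, fraction = "cytoplasmic")
  if (nrow(nuc) == 0 || nrow(cyt) == 0) {
    abort(sprintf("gene %s must be measured in both nuclear and cytoplasmic fractions", gene))
  }
  if (all(c(nuc$ct, cyt$ct) >= detect_ct)) {
    return(tibble(gene_id = gene, nuclear_share = NA_real_, call = "undetermined"))
  }
  dct <- function(piece, fraction) {
    ct <- mean(piece$ct)
    if (is.null(reference_genes)) {
      return(ct)
    }
    refs <- mean_ct(ct_data, reference_genes, fraction = fraction)
    if (nrow(refs) == 0) {
      abort(sprintf("reference genes missing in %s fraction", fraction))
    }
    ct - mean(vapply(
      unique(refs$gene_id),
      function(g) mean(refs$ct[refs$gene_id == g]), 0
    ))
  }
  abundance_nuc <- 2^(-dct(nuc, "nuclear"))
  abundance_cyt <- 2^(-dct(cyt, "cytoplasmic"))
  share <- abundance_nuc / (abundance_nuc + abundance_cyt)
  call <- if (share >= nuclear_cutoff) {
    "nuclear"
  } else if (share <= cytoplasmic_cutoff) {
    "cytoplasmic"
  } else {
    "undetermined"
  }
  tibble(gene_id = gene, nuclear_share = share, call = call)
}

#' One-way ANOVA with Tukey HSD correction
#'
#' Overall F-test across groups followed by all pairwise comparisons
#' adjusted by Tukey's honest significant difference (studentized-range
#' distribution), via [stats::aov()] and [stats::TukeyHSD()].
#'
#' @param data Long tibble with a value column and a group column.
#' @param value,group Column names (strings) of the response and grouping
#'   variables.
#' @return Object of class `anova_tukey`: list with `overall` (one-row
#'   tibble: `f_statistic`, `df_between`, `df_within`, `p_value`) and
#'   `pairwise` (tibble: `comparison`, `estimate`, `p_adj`). Every group
#'   needs at least 2 values.
#' @export
one_way_anova_tukey <- function(data, value = "value", group = "group") {
  data <- as_tibble(data)
  if (!all(c(value, group) %in% names(data))) {
    abort(sprintf("`data` needs columns `%s` and `%s`", value, group))
  }
  g <- factor(data[[group]])
  v <- data[[value]]
  if (nlevels(g) < 2) abort("need at least 2 groups")
  sizes <- table(g)
  if (any(sizes < 2)) {
    abort(sprintf(
      "every group needs >= 2 values (offending: %s)",
      paste(names(sizes)[sizes < 2], collapse = ", ")
    ))
  }
  fit <- aov(v ~ g)
  an <- summary(fit)[[1]]
  hsd <- TukeyHSD(fit)$g
  structure(
    list(
      overall = tibble(
        f_statistic = an[["F value"]][1],
        df_between = an[["Df"]][1], df_within = an[["Df"]][2],
        p_value = an[["Pr(>F)"]][1]
      ),
      pairwise = tibble(
        comparison = rownames(hsd),
        estimate = hsd[, "diff"], p_adj = hsd[, "p adj"]
      )
    ),
    class = "anova_tukey"
  )
}

#' @export
print.anova_tukey <- function(x, ...) {
  cat(sprintf(
    "One-way ANOVA: F(%d, %d) = %.3f, p = %.3g\n",
    x$overall$df_between, x$overall$df_within,
    x$overall$f_statistic, x$overall$p_value
  ))
  print(x$pairwise)
  invisible(x)
}

#' Student's t-test (classical form)
#'
#' Two-sided Student t-test: unpaired with the classical pooled
#' equal-variance form, or paired on the within-pair differences. Errors
#' (rather than returning p = NaN) when the relevant variance is zero.
#'
#' @param a,b Numeric vectors (`n >= 2` each; equal length if paired).
#' @param paired Logical.
#' @return One-row tibble: `statistic`, `df`, `p_value`.
#' @export
t_test <- function(a, b, paired = FALSE) {
  if (length(a) < 2 || length(b) < 2) abort("need n >= 2 per sample")
  if (paired && length(a) != length(b)) abort("paired test needs equal lengths")
  if (paired) {
    if (sd(a - b) == 0) abort("paired differences have zero variance; t undefined")
  } else if (sd(a) == 0 && sd(b) == 0) {
    abort("zero pooled variance; t undefined")
  }
  fit <- t.test(a, b, paired = paired, var.equal = TRUE)
  tibble(
    statistic = unname(fit$statistic), df = unname(fit$parameter),
    p_value = fit$p.value
  )
}
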