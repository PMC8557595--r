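# Independent brute-force oracles. These deliberately avoid the package's
# code paths (no GRanges, no vectorized scans) so agreement is evidence,
# not tautology.

rand_intervals <- function(n, chroms = c("chr1", "chr2"), max_pos = 10000L,
                           max_len = 500L) {
  start <- sample.int(max_pos, n, replace = TRUE) - 1L
  tibble::tibble(
    chrom = sample(chroms, n, replace = TRUE),
    start = start,
    end = start + sample.int(max_len, n, replace = TRUE)
  )
}

# O(n^2) pairwise absorption: repeatedly merge any two intervals on the
# same chromosome within min_gap until a fixed point.
oracle_merge <- function(x, min_gap = 0L) {
  recs <- lapply(seq_len(nrow(x)), function(i) {
    list(chrom = x$chrom[i], start = x$start[i], end = x$end[i])
  })
  repeat {
    merged_any <- FALSE
    i <- 1
    while (i <= length(recs)) {
      j <- i + 1
      while (j <= length(recs)) {
        a <- recs[[i]]
        b <- recs[[j]]
        if (a$chrom == b$chrom &&
          max(a$start, b$start) - min(a$end, b$end) <= min_gap) {
          recs[[i]] <- list(
            chrom = a$chrom,
            start = min(a$start, b$start), end = max(a$end, b$end)
          )
          recs[[j]] <- NULL
          merged_any <- TRUE
        } else {
          j <- j + 1
        }
      }
      i <- i + 1
    }
    if (!merged_any) break
  }
  out <- do.call(rbind, lapply(recs, function(r) {
    data.frame(chrom = r$chrom, start = r$start, end = r$end)
  }))
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  tibble::as_tibble(out)
}

# explicit base-set membership: bases covered by interval row i
oracle_bases <- function(chrom, start, end) {
  if (end <= start) {
    return(character())
  }
  paste0(chrom, ":", seq(start, end - 1L))
}

oracle_overlap <- function(a, b) {
  length(intersect(
    oracle_bases(a$chrom, a$start, a$end),
    oracle_bases(b$chrom, b$start, b$end)
  )) >= 1
}

# exhaustive nearest-edge distance scan
oracle_window_scan <- function(genes, region, window) {
  hits <- list()
  for (i in seq_len(nrow(genes))) {
    if (genes$chrom[i] != region$chrom) next
    if (genes$start[i] >= region$end) {
      d <- genes$start[i] - region$end
    } else if (genes$end[i] <= region$start) {
      d <- region$start - genes$end[i]
    } else {
      d <- 0L
    }
    if (d <= window) {
      hits[[length(hits) + 1]] <- data.frame(gene_id = genes$gene_id[i], distance = d)
    }
  }
  if (length(hits) == 0) {
    return(data.frame(gene_id = character(), distance = integer()))
  }
  out <- do.call(rbind, hits)
  out[order(out$distance, out$gene_id), , drop = FALSE]
}

# per-base signal summation loop
oracle_signal_sum <- function(region, track) {
  total <- 0
  for (i in seq_len(nrow(track))) {
    if (track$chrom[i] != region$chrom) next
    for (pos in seq(track$start[i], track$end[i] - 1L)) {
      if (pos >= region$start && pos < region$end) {
        total <- total + track$value[i]
      }
    }
  }
  total
}

# scalar re-statement of the hockey-stick rule: min-max scale, walk the
# sorted curve, stop at the first segment steeper than the diagonal
oracle_hockey_cutoff <- function(signals) {
  y <- sort(signals)
  n <- length(y)
  lo <- y[1]
  hi <- y[n]
  if (hi == lo) {
    return(hi)
  }
  for (i in 1:(n - 1)) {
    y_i <- (y[i] - lo) / (hi - lo)
    y_next <- (y[i + 1] - lo) / (hi - lo)
    x_i <- (i - 1) / (n - 1)
    x_next <- i / (n - 1)
    if ((y_next - y_i) / (x_next - x_i) > 1) {
      return(y[i])
    }
  }
  hi
}

# two-pass product-moment formula
oracle_pearson <- function(x, y) {
  mx <- sum(x) / length(x)
  my <- sum(y) / length(y)
  sxy <- sum((x - mx) * (y - my))
  sxx <- sum((x - mx)^2)
  syy <- sum((y - my)^2)
  sxy / sqrt(sxx * syy)
}

# textbook one-way ANOVA F statistic
oracle_anova_f <- function(groups) {
  k <- length(groups)
  n <- sum(lengths(groups))
  grand <- mean(unlist(groups))
  ss_between <- sum(vapply(groups, function(g) length(g) * (mean(g) - grand)^2, 0))
  ss_within <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  (ss_between / (k - 1)) / (ss_within / (n - k))
}

# pooled-variance two-sample t statistic
oracle_student_t <- function(a, b) {
  sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
    (length(a) + length(b) - 2)
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
}

# small random expression tables for cascade property tests
rand_cascade_inputs <- function(n_lnc = 20, n_mrna = 20, stages = c("S1", "S2", "S3")) {
  lnc_ids <- sprintf("L%02d", seq_len(n_lnc))
  mrna_ids <- sprintf("M%02d", seq_len(n_mrna))
  mk_table <- function(ids, biotype) {
    out <- tibble::tibble(feature_id = ids, biotype = biotype)
    for (s in stages) out[[s]] <- runif(length(ids), 1, 1000)
    out
  }
  pos_l <- sort(sample.int(5e6, n_lnc)) * 2L
  pos_m <- sort(sample.int(5e6, n_mrna)) * 2L
  annotation <- dplyr::bind_rows(
    tibble::tibble(
      gene_id = lnc_ids, chrom = "chr1", start = pos_l,
      end = pos_l + 1000L, tss = pos_l, biotype = "lncRNA"
    ),
    tibble::tibble(
      gene_id = mrna_ids, chrom = "chr1", start = pos_m,
      end = pos_m + 1000L, tss = pos_m, biotype = "mRNA"
    )
  )
  mat <- matrix(rnorm((n_lnc + n_mrna) * 10), ncol = 10)
  rownames(mat) <- c(lnc_ids, mrna_ids)
  list(
    lnc_table = mk_table(lnc_ids, "lncRNA"),
    mrna_table = mk_table(mrna_ids, "mRNA"),
    annotation = annotation,
    annotated_ids = sample(lnc_ids, ceiling(n_lnc / 2)),
    patient_matrix = mat,
    patient_direction = tibble::tibble(
      mrna_id = mrna_ids,
      direction = sample(c(-1, 0, 1), n_mrna, replace = TRUE)
    )
  )
}

shuffle_rows <- function(df) df[sample.int(nrow(df)), , drop = FALSE]
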