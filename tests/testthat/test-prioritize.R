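mk_expr <- function(ids, biotype, first, last, mid = NULL) {
  tibble::tibble(
    feature_id = ids, biotype = biotype,
    S1 = first, S2 = if (is.null(mid)) (first + last) / 2 else mid, S3 = last
  )
}

test_that("log2 fold change follows the pseudocount formula and is antisymmetric", {
  tab <- mk_expr(c("a", "b"), "lncRNA", c(100, 100), c(100, 400))
  fc <- log2_fold_change(tab)
  expect_equal(fc$log2_fc[1], 0)
  expect_equal(fc$log2_fc[2], log2(401 / 101)) # exact formula, pseudocount 1
  rev_fc <- log2_fold_change(tab, stage_a = "S3", stage_b = "S1")
  expect_equal(rev_fc$log2_fc, -fc$log2_fc)
  expect_error(log2_fold_change(tab, stage_a = "S9"), "unknown stage")

  set.seed(13)
  vals <- matrix(runif(40, 0, 1000), ncol = 2)
  tab2 <- tibble::tibble(
    feature_id = sprintf("f%02d", 1:20), biotype = "mRNA",
    S1 = vals[, 1], S3 = vals[, 2]
  )
  expect_equal(
    log2_fold_change(tab2)$log2_fc,
    log2((vals[, 2] + 1) / (vals[, 1] + 1))
  )
})

test_that("differential filter is boundary-inclusive at the fold-change cutoff", {
  # (199 + 1) / (99 + 1) is exactly 2; 190/100 is below the cutoff
  tab <- mk_expr(c("exact", "below", "down"), "lncRNA",
    first = c(99, 99, 399), last = c(199, 189, 99)
  )
  kept <- filter_differential(tab)
  expect_setequal(kept$feature_id, c("exact", "down"))

  # planted 10 changed among 90 flat
  set.seed(23)
  flat_base <- runif(90, 100, 900)
  changed_base <- runif(10, 100, 900)
  tab2 <- mk_expr(
    sprintf("f%02d", 1:100), "lncRNA",
    first = c(flat_base, changed_base),
    last = c(flat_base * runif(90, 0.9, 1.1), changed_base * 3)
  )
  expect_setequal(
    filter_differential(tab2)$feature_id,
    sprintf("f%02d", 91:100)
  )
})

test_that("neighbor pairing enforces the window and the mRNA fold-change cutoff", {
  ann <- dplyr::bind_rows(
    tibble::tibble(
      gene_id = "L1", chrom = "chr1", start = 100000L, end = 102000L,
      tss = 100000L, biotype = "lncRNA"
    ),
    tibble::tibble(
      gene_id = c("M_near", "M_far", "M_flat"), chrom = "chr1",
      start = c(130000L, 162100L, 140000L),
      end = c(131000L, 163000L, 141000L),
      tss = c(130000L, 162100L, 140000L), biotype = "mRNA"
    )
  )
  lnc <- mk_expr("L1", "lncRNA", 100, 500)
  mrna <- mk_expr(c("M_near", "M_far", "M_flat"), "mRNA",
    first = c(100, 100, 100), last = c(500, 500, 110)
  )
  pairs <- pair_neighbors("L1", ann, lnc, mrna)
  # M_far is 60,100 bp from the lncRNA gene body; M_flat does not co-change
  expect_equal(pairs$mrna_id, "M_near")
  expect_equal(pairs$distance_bp, 28000L)

  overlapping <- dplyr::mutate(ann[2, ], gene_id = "M_over", start = 101000L, end = 103000L, tss = 101000L)
  pairs2 <- pair_neighbors(
    "L1", dplyr::bind_rows(ann[1, ], overlapping),
    lnc, mk_expr("M_over", "mRNA", 100, 500)
  )
  expect_equal(pairs2$distance_bp, 0L)
  expect_warning(
    none <- pair_neighbors("L_missing", ann, lnc, mrna),
    "missing from annotation"
  )
  expect_equal(nrow(none), 0)
})

test_that("planted cis pairs are recovered exactly among decoys", {
  set.seed(33)
  n_cis <- 5
  n_decoy <- 50
  slot <- 50000L + (seq_len(n_cis + n_decoy) - 1L) * 200000L
  lnc_ids <- sprintf("L%02d", seq_len(n_cis))
  dec_ids <- sprintf("D%02d", seq_len(n_decoy))
  ann <- dplyr::bind_rows(
    tibble::tibble(
      gene_id = lnc_ids, chrom = "chr1", start = slot[seq_len(n_cis)],
      end = slot[seq_len(n_cis)] + 2000L, tss = slot[seq_len(n_cis)], biotype = "lncRNA"
    ),
    tibble::tibble( # cis mRNAs 20 kb away
      gene_id = paste0("M", lnc_ids), chrom = "chr1",
      start = slot[seq_len(n_cis)] + 22000L, end = slot[seq_len(n_cis)] + 23000L,
      tss = slot[seq_len(n_cis)] + 22000L, biotype = "mRNA"
    ),
    tibble::tibble( # decoy mRNAs in distant slots
      gene_id = dec_ids, chrom = "chr1", start = slot[n_cis + seq_len(n_decoy)],
      end = slot[n_cis + seq_len(n_decoy)] + 1000L,
      tss = slot[n_cis + seq_len(n_decoy)], biotype = "mRNA"
    )
  )
  lnc <- mk_expr(lnc_ids, "lncRNA", rep(100, n_cis), rep(500, n_cis))
  mrna <- mk_expr(c(paste0("M", lnc_ids), dec_ids), "mRNA",
    first = rep(100, n_cis + n_decoy),
    last = c(rep(500, n_cis), runif(n_decoy, 300, 900))
  )
  pairs <- pair_neighbors(lnc_ids, ann, lnc, mrna)
  expect_equal(pairs$lncrna_id, lnc_ids)
  expect_equal(pairs$mrna_id, paste0("M", lnc_ids))
})

test_that("annotation cross-reference is plain set membership", {
  pairs <- tibble::tibble(lncrna_id = c("a", "b", "c"), mrna_id = "m")
  expect_equal(sum(crossref_annotation(pairs, character())$annotated), 0)
  expect_equal(sum(crossref_annotation(pairs, c("a", "b", "c"))$annotated), 3)
  set.seed(43)
  ids <- sample(letters, 10)
  out <- crossref_annotation(tibble::tibble(lncrna_id = letters, mrna_id = "m"), ids)
  expect_setequal(out$lncrna_id[out$annotated], ids)
})

test_that("pearson_r matches the two-pass formula and rejects bad input", {
  expect_equal(pearson_r(1:5, 2 * (1:5) + 1), 1)
  expect_equal(pearson_r(1:5, -(1:5)), -1)
  x <- c(1, 2, 3, 4)
  y <- c(1, 3, 2, 4)
  expect_equal(pearson_r(x, y), oracle_pearson(x, y))
  set.seed(53)
  for (rep in 1:50) {
    x <- rnorm(20)
    y <- rnorm(20)
    expect_equal(pearson_r(x, y), oracle_pearson(x, y), tolerance = 1e-12)
  }
  expect_error(pearson_r(c(1, 1, 1), 1:3), "constant")
  expect_error(pearson_r(1:3, 1:4), "equal length")
  expect_error(pearson_r(1:2, 1:2), "at least 3")
})

test_that("correlation filter keeps |r| >= 0.5 inclusively and routes absent pairs", {
  # cor(c(1,2,3), c(1,3,2)) is exactly 1/2
  mat <- rbind(
    L1 = c(1, 2, 3), M1 = c(1, 3, 2),
    L2 = c(1, 2, 3), M2 = c(2, 9, 4)
  )
  expect_equal(pearson_r(mat["L1", ], mat["M1", ]), 0.5)
  pairs <- tibble::tibble(
    lncrna_id = c("L1", "L2", "L3"), mrna_id = c("M1", "M2", "M3")
  )
  out <- correlation_filter(pairs, mat)
  expect_true(out$correlated[1]) # boundary inclusive
  expect_false(out$correlated[2])
  expect_true(is.na(out$correlated[3])) # absent member: routed onward, not dropped
})

test_that("planted correlations survive the filter and noise pairs do not", {
  set.seed(63)
  f <- rnorm(50)
  mat <- rbind(
    Lp = sqrt(0.9) * f + sqrt(0.1) * rnorm(50),
    Mp = sqrt(0.9) * f + sqrt(0.1) * rnorm(50),
    Ln = rnorm(50), Mn = rnorm(50)
  )
  pairs <- tibble::tibble(lncrna_id = c("Lp", "Ln"), mrna_id = c("Mp", "Mn"))
  out <- correlation_filter(pairs, mat)
  expect_true(out$correlated[1])
  expect_false(out$correlated[2])
})

test_that("trend concordance requires equal nonzero signs", {
  pairs <- tibble::tibble(lncrna_id = "L", mrna_id = c("up", "down", "zero", "gone"))
  patient <- c(up = 1, down = 1, zero = 0, gone = 1)
  series <- c(up = 1, down = -1, zero = 0)
  expect_warning(out <- trend_concordance_filter(pairs, patient, series), "dropped")
  expect_equal(out$mrna_id, "up")
  set.seed(73)
  ids <- sprintf("g%02d", 1:40)
  p <- sample(c(-1, 0, 1), 40, replace = TRUE)
  s <- sample(c(-1, 0, 1), 40, replace = TRUE)
  out2 <- trend_concordance_filter(
    tibble::tibble(lncrna_id = "L", mrna_id = ids),
    setNames(p, ids), setNames(s, ids)
  )
  expect_setequal(out2$mrna_id, ids[p == s & p != 0])
})

test_that("top-differential branch needs the extreme cutoff and annotation", {
  # (999+1)/(99+1) is exactly 10
  tab <- mk_expr(c("exact", "big_unannot", "mild"), "lncRNA",
    first = c(99, 50, 100), last = c(999, 800, 300)
  )
  out <- top_differential(tab, c("exact", "mild"))
  expect_equal(out$feature_id, "exact")
})

test_that("an empty lncRNA table yields an all-zero cascade report", {
  stages <- c("S1", "S2", "S3")
  empty_tab <- tibble::tibble(
    feature_id = character(), biotype = character(),
    S1 = numeric(), S2 = numeric(), S3 = numeric()
  )
  mrna <- mk_expr("M1", "mRNA", 100, 500)
  ann <- tibble::tibble(
    gene_id = "M1", chrom = "chr1", start = 0L, end = 1000L,
    tss = 0L, biotype = "mRNA"
  )
  rep <- run_cascade(
    empty_tab, mrna, ann,
    annotated_ids = character(),
    patient_matrix = matrix(0, 0, 0), patient_direction = c(M1 = 1)
  )
  expect_true(all(rep$steps$n_lncrnas == 0))
  expect_length(rep$shortlist, 0)
})

test_that("cascade counts are monotone along the funnel on random inputs", {
  set.seed(83)
  for (rep in 1:100) {
    inp <- rand_cascade_inputs()
    report <- suppressWarnings(run_cascade(
      inp$lnc_table, inp$mrna_table, inp$annotation,
      inp$annotated_ids, inp$patient_matrix, inp$patient_direction
    ))
    s <- setNames(report$steps$n_lncrnas, report$steps$step)
    p <- setNames(report$steps$n_pairs, report$steps$step)
    expect_lte(s[["differential"]], s[["input"]])
    expect_lte(s[["paired"]], s[["differential"]])
    expect_lte(s[["annotated"]], s[["paired"]])
    expect_lte(s[["correlated"]], s[["annotated"]])
    expect_lte(s[["trend_concordant"]], s[["annotated"]])
    # at the pair level the two branches partition the annotated set
    expect_lte(p[["trend_concordant"]], p[["annotated"]] - p[["correlated"]])
    expect_lte(s[["shortlist"]], s[["correlated"]] + s[["trend_concordant"]] + s[["top_differential"]])
    # shortlist is the union of the three terminal branches, no duplicates
    expect_setequal(report$shortlist, unique(c(
      report$correlated_pairs$lncrna_id, report$trend_pairs$lncrna_id,
      report$top$feature_id
    )))
  }
})

test_that("the cascade is invariant to input row order", {
  set.seed(93)
  for (rep in 1:10) {
    inp <- rand_cascade_inputs()
    r1 <- suppressWarnings(run_cascade(
      inp$lnc_table, inp$mrna_table, inp$annotation,
      inp$annotated_ids, inp$patient_matrix, inp$patient_direction
    ))
    r2 <- suppressWarnings(run_cascade(
      shuffle_rows(inp$lnc_table), shuffle_rows(inp$mrna_table),
      shuffle_rows(inp$annotation), sample(inp$annotated_ids),
      inp$patient_matrix[sample.int(nrow(inp$patient_matrix)), , drop = FALSE],
      shuffle_rows(inp$patient_direction)
    ))
    expect_equal(r1$steps, r2$steps)
    expect_equal(r1$shortlist, r2$shortlist)
    expect_equal(
      dplyr::arrange(r1$pairs, lncrna_id, mrna_id),
      dplyr::arrange(r2$pairs, lncrna_id, mrna_id)
    )
  }
})

test_that("tidy and glance summarise a cascade report", {
  inp <- rand_cascade_inputs(n_lnc = 10, n_mrna = 10)
  report <- suppressWarnings(run_cascade(
    inp$lnc_table, inp$mrna_table, inp$annotation,
    inp$annotated_ids, inp$patient_matrix, inp$patient_direction
  ))
  expect_equal(tidy(report), report$steps)
  g <- glance(report)
  expect_equal(nrow(g), 1)
  expect_equal(g$n_input, 10)
  expect_s3_class(autoplot(report), "ggplot")
})
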