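#' Synthetic-data configuration
#'
#' Seeded, deterministic generators for every input the pipeline consumes,
#' with planted ground truth recorded alongside. Defaults emulate the study
#' conditions of a four-stage breast-cancer progression series: a few
#' hundred decoy enhancer peaks per stage with a few dozen planted
#' super-enhancer clusters acquired or lost at known stages, an expression
#' screen with planted cis lncRNA-mRNA pairs among co-located-uncorrelated,
#' correlated-but-distal and flat decoys, a 50-patient correlation matrix,
#' and triplicate qPCR Ct tables with planted fold changes and
#' nuclear/cytoplasmic splits.
#'
#' @param seed Integer seed; a fixed seed makes every generator
#'   byte-identical across calls.
#' @param stage_names Ordered stage labels, baseline (normal) first.
#' @param n_decoy_peaks Decoy (typical-enhancer) peaks per stage.
#' @param n_planted_clusters Planted super-enhancer clusters (groups of
#'   3-8 peaks within 12.5 kb).
#' @param cluster_signal Baseline per-peak signal of planted clusters, in
#'   normalized units; decoy signals are Exp(1) so the default 50 puts
#'   clusters far above the hockey-stick elbow.
#' @param n_decoy_lnc Decoy lncRNAs in the expression screen (>= 80; split
#'   across co-located-uncorrelated, unannotated, distal-correlated and
#'   flat classes).
#' @param n_planted_cis_pairs Planted true cis lncRNA-mRNA pairs; about a
#'   quarter are planted without patient-matrix rows so they exercise the
#'   trend-concordance branch.
#' @param n_extreme_fc Planted extreme responders (|fold change| >= 10,
#'   atlas-annotated, no qualifying neighbor).
#' @param n_patients Synthetic patients in the correlation matrix.
#' @param cis_r_target Target Pearson correlation of planted pairs across
#'   patients.
#' @param noise_sd Gaussian qPCR noise, in cycles.
#' @param qpcr_replicates Replicates per qPCR condition.
#' @param n_cohort_patients Patients in the synthetic SE cohort used for
#'   representation counts.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(seed = 1L,
                         stage_names = c("MCF10A", "AT1", "DCIS", "CA1"),
                         n_decoy_peaks = 400L, n_planted_clusters = 25L,
                         cluster_signal = 50,
                         n_decoy_lnc = 200L, n_planted_cis_pairs = 8L,
                         n_extreme_fc = 4L, n_patients = 50L,
                         cis_r_target = 0.9, noise_sd = 0.05,
                         qpcr_replicates = 3L, n_cohort_patients = 47L) {
  if (length(stage_names) < 2 || anyDuplicated(stage_names) > 0) {
    abort("`stage_names` must be >= 2 unique labels")
  }
  if (n_decoy_lnc < 80) abort("`n_decoy_lnc` must be >= 80 (decoy classes need members)")
  if (n_planted_cis_pairs < 0 || n_extreme_fc < 0 || n_planted_clusters < 0) {
    abort("planted counts must be >= 0")
  }
  if (cis_r_target <= 0.5 || cis_r_target > 1) {
    abort("`cis_r_target` must be in (0.5, 1] to stay recoverable at the 0.5 cutoff")
  }
  if (noise_sd < 0) abort("`noise_sd` must be >= 0")
  structure(
    list(
      seed = as.integer(seed), stage_names = stage_names,
      n_decoy_peaks = as.integer(n_decoy_peaks),
      n_planted_clusters = as.integer(n_planted_clusters),
      cluster_signal = cluster_signal,
      n_decoy_lnc = as.integer(n_decoy_lnc),
      n_planted_cis_pairs = as.integer(n_planted_cis_pairs),
      n_extreme_fc = as.integer(n_extreme_fc),
      n_patients = as.integer(n_patients),
      cis_r_target = cis_r_target, noise_sd = noise_sd,
      qpcr_replicates = as.integer(qpcr_replicates),
      n_cohort_patients = as.integer(n_cohort_patients)
    ),
    class = "synth_config"
  )
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_rng_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Presence windows (first, last stage index) recycled over a fixed pattern
# order so every dynamics class (constitutive, baseline-lost, acquired,
# transient, late-acquired) is planted.
cluster_schedule <- function(n_clusters, n_stages) {
  firsts <- integer()
  lasts <- integer()
  for (f in seq_len(n_stages)) {
    for (l in seq(f, n_stages)) {
      firsts <- c(firsts, f)
      lasts <- c(lasts, l)
    }
  }
  # lead with fully-constitutive and fully-retained patterns
  ord <- order(-(lasts - firsts), firsts)
  idx <- rep(ord, length.out = n_clusters)
  tibble(first_idx = firsts[idx], last_idx = lasts[idx])
}

#' Synthetic stage-ordered ChIP-seq peak and signal series
#'
#' Plants `n_planted_clusters` super-enhancer clusters (3-8 peaks spanning
#' under 12.5 kb, per-peak signal `cluster_signal + Exp(1)`) on one
#' chromosome, each present over a scheduled stage window, among
#' `n_decoy_peaks` isolated low-signal (Exp(1)) decoy peaks per stage on a
#' second chromosome, plus a handful of TSS-proximal promoter peaks that
#' the TSS-exclusion step should remove. Cluster, decoy and promoter zones
#' are separated by much more than the stitch distance so planted truth is
#' unambiguous.
#'
#' @param cfg A [synth_config()].
#' @return A list of class `synth_chipseq`: `peaks` (named list per stage:
#'   `chrom`, `start`, `end`, `signal`), `tracks` (named list of
#'   bedGraph-like tibbles at 50 bp bins), `library_sizes` (named vector),
#'   `genes` (TSS annotation tibble), `truth` (one row per planted cluster:
#'   coordinates, `first_stage`, `last_stage`, `acquired_stage`,
#'   `retained`) and `config`.
#' @export
gen_chipseq_series <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  stages <- cfg$stage_names
  n_stages <- length(stages)
  with_rng_seed(cfg$seed, {
    sched <- cluster_schedule(cfg$n_planted_clusters, n_stages)
    # fixed geometry per cluster, shared by all stages where present
    clusters <- purrr::map(seq_len(cfg$n_planted_clusters), function(i) {
      anchor <- 50000L + (i - 1L) * 100000L
      k <- sample(3:8, 1)
      widths <- sample(seq(500L, 1000L, by = 50L), k, replace = TRUE)
      gaps <- sample(seq(100L, 300L, by = 50L), k, replace = TRUE)
      starts <- anchor + cumsum(c(0L, (widths + gaps)[-k]))
      tibble(chrom = "chr1", start = starts, end = starts + widths)
    })
    spans <- bind_rows(
      empty_intervals(),
      purrr::map_dfr(clusters, function(p) {
        tibble(chrom = "chr1", start = min(p$start), end = max(p$end))
      })
    )
    stopifnot(all(spans$end - spans$start <= 12500L))
    decoy_geom <- tibble(
      chrom = "chr2",
      start = 50000L + (seq_len(cfg$n_decoy_peaks) - 1L) * 20000L
    )
    decoy_geom$end <- decoy_geom$start +
      sample(seq(500L, 2000L, by = 50L), cfg$n_decoy_peaks, replace = TRUE)
    n_tss <- 5L
    tss_pos <- 3500000L + (seq_len(n_tss) - 1L) * 50000L
    genes <- tibble(
      gene_id = sprintf("PROM%02d", seq_len(n_tss)),
      chrom = "chr1", start = tss_pos, end = tss_pos + 2000L,
      tss = tss_pos, biotype = "mRNA"
    )
    peaks <- list()
    tracks <- list()
    for (s in seq_len(n_stages)) {
      present <- which(sched$first_idx <= s & sched$last_idx >= s)
      cl <- purrr::map_dfr(present, function(i) {
        p <- clusters[[i]]
        p$signal <- cfg$cluster_signal + rexp(nrow(p))
        p
      })
      dec <- mutate(decoy_geom, signal = rexp(cfg$n_decoy_peaks))
      prom <- tibble(
        chrom = "chr1", start = tss_pos - 100L, end = tss_pos + 100L,
        signal = 5 + rexp(n_tss)
      )
      stage_peaks <- arrange(
        bind_rows(cl, dec, prom),
        .data$chrom, .data$start
      )
      peaks[[stages[s]]] <- stage_peaks
      tracks[[stages[s]]] <- peaks_to_track(stage_peaks)
    }
    truth <- mutate(spans,
      cluster_id = sprintf("SE%02d", seq_len(cfg$n_planted_clusters)),
      first_idx = sched$first_idx, last_idx = sched$last_idx,
      first_stage = stages[sched$first_idx], last_stage = stages[sched$last_idx],
      acquired_stage = ifelse(sched$first_idx == 1L, NA_character_, stages[sched$first_idx]),
      retained = sched$first_idx > 1L & sched$last_idx == n_stages
    )
    structure(
      list(
        peaks = peaks, tracks = tracks,
        library_sizes = setNames(rep(1e6, n_stages), stages),
        genes = genes, truth = truth, config = cfg
      ),
      class = "synth_chipseq"
    )
  })
}

# Tile each peak with 50-bp bins whose value is the per-base signal
# density, so summing the track over the peak recovers its signal exactly
# (peak coordinates are multiples of 50).
peaks_to_track <- function(peaks) {
  purrr::map_dfr(seq_len(nrow(peaks)), function(i) {
    w <- peaks$end[i] - peaks$start[i]
    starts <- seq(peaks$start[i], peaks$end[i] - 50L, by = 50L)
    tibble(
      chrom = peaks$chrom[i], start = starts, end = starts + 50L,
      value = peaks$signal[i] / w
    )
  })
}

#' Synthetic expression screen with planted cis pairs
#'
#' Builds lncRNA and mRNA stage tables, a gene annotation, an
#' atlas-annotated id list, a patient expression matrix, and a
#' patient trend-direction table, with planted truth:
#' `n_planted_cis_pairs` true cis pairs (lncRNA and mRNA within 50 kb,
#' both passing the fold-change cutoff; most given patient-matrix rows
#' correlated near `cis_r_target`, the rest left out of the matrix but
#' trend-concordant so they exercise the trend branch),
#' `n_extreme_fc` annotated extreme responders with no qualifying
#' neighbor, and decoys that each fail exactly one filter: co-located
#' co-changing but uncorrelated and trend-discordant, co-located but
#' unannotated, correlated but outside the window, or flat. Stage-extreme
#' values are exact (jitter only on intermediate stages) and decoy/planted
#' patient correlations are redrawn away from the 0.5 boundary, so planted
#' truth is recovered under any seed.
#'
#' @param cfg A [synth_config()].
#' @return A list of class `synth_expression`: `lnc_table`, `mrna_table`,
#'   `annotation`, `annotated_ids`, `patient_matrix`,
#'   `patient_direction`, `truth` (list: `features`, `pairs`,
#'   `shortlist`) and `config`.
#' @export
gen_expression <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  stages <- cfg$stage_names
  n_stages <- length(stages)
  n_cis <- cfg$n_planted_cis_pairs
  n_trend <- if (n_cis >= 2) max(1L, round(n_cis / 4)) else 0L
  n_corr <- n_cis - n_trend
  n_a <- 30L # co-located, co-changing, annotated, uncorrelated, anti-trend
  n_d <- 20L # co-located, co-changing, NOT atlas-annotated
  n_b <- 30L # correlated in patients but outside the window
  n_flat <- cfg$n_decoy_lnc - n_a - n_d - n_b
  with_rng_seed(cfg$seed + 1L, {
    roles <- c(
      rep("cis_correlated", n_corr), rep("cis_trend", n_trend),
      rep("extreme", cfg$n_extreme_fc),
      rep("colocated_uncorrelated", n_a), rep("unannotated", n_d),
      rep("distal_correlated", n_b), rep("flat", n_flat)
    )
    n_lnc <- length(roles)
    lnc_ids <- sprintf("LNC%03d", seq_len(n_lnc))
    has_partner <- roles %in% c(
      "cis_correlated", "cis_trend", "colocated_uncorrelated",
      "unannotated", "distal_correlated"
    ) | (roles == "flat" & seq_len(n_lnc) %% 2L == 0L)
    mrna_ids <- ifelse(has_partner, sprintf("MRNA%03d", seq_len(n_lnc)), NA_character_)

    slot <- 50000L + (seq_len(n_lnc) - 1L) * 250000L
    lnc_start <- slot + 100000L
    dist <- ifelse(roles == "distal_correlated",
      sample(seq(60000L, 120000L, by = 1000L), n_lnc, replace = TRUE),
      sample(seq(5000L, 40000L, by = 500L), n_lnc, replace = TRUE)
    )
    annotation <- bind_rows(
      tibble(
        gene_id = lnc_ids, chrom = "chr1",
        start = lnc_start, end = lnc_start + 2000L,
        tss = lnc_start, biotype = "lncRNA"
      ),
      tibble(
        gene_id = mrna_ids[has_partner], chrom = "chr1",
        start = (lnc_start + 2000L + dist)[has_partner],
        end = (lnc_start + 2000L + dist)[has_partner] + 1500L,
        tss = (lnc_start + 2000L + dist)[has_partner], biotype = "mRNA"
      )
    )

    lnc_sign <- sample(c(-1, 1), n_lnc, replace = TRUE)
    lnc_mag <- dplyr::case_when(
      roles %in% c("cis_correlated", "cis_trend") ~ runif(n_lnc, 2.5, 6),
      roles == "extreme" ~ runif(n_lnc, 12, 20),
      roles == "flat" ~ runif(n_lnc, 0.87, 1.15),
      .default = runif(n_lnc, 2.5, 6)
    )
    lnc_fc <- ifelse(roles == "flat", lnc_mag, lnc_mag^lnc_sign)
    mrna_sign <- ifelse(roles %in% c("cis_correlated", "cis_trend"),
      lnc_sign, sample(c(-1, 1), n_lnc, replace = TRUE)
    )
    mrna_fc <- ifelse(roles == "flat", runif(n_lnc, 0.87, 1.15),
      runif(n_lnc, 2.5, 6)^mrna_sign
    )

    lnc_table <- expression_series(lnc_ids, "lncRNA", lnc_fc, stages)
    mrna_table <- expression_series(
      mrna_ids[has_partner], "mRNA", mrna_fc[has_partner], stages
    )

    annotated_ids <- sort(c(
      lnc_ids[roles %in% c(
        "cis_correlated", "cis_trend", "extreme",
        "colocated_uncorrelated", "distal_correlated"
      )],
      utils::head(lnc_ids[roles == "flat"], 20L)
    ))

    in_matrix <- roles %in% c("cis_correlated", "colocated_uncorrelated", "distal_correlated")
    rows <- list()
    for (i in which(in_matrix)) {
      correlated_pair <- roles[i] %in% c("cis_correlated", "distal_correlated")
      repeat {
        if (correlated_pair) {
          a <- sqrt(cfg$cis_r_target)
          f <- rnorm(cfg$n_patients)
          x <- a * f + sqrt(1 - a^2) * rnorm(cfg$n_patients)
          y <- a * f + sqrt(1 - a^2) * rnorm(cfg$n_patients)
          if (pearson_r(x, y) >= 0.6) break
        } else {
          x <- rnorm(cfg$n_patients)
          y <- rnorm(cfg$n_patients)
          if (abs(pearson_r(x, y)) <= 0.45) break
        }
      }
      rows[[lnc_ids[i]]] <- x
      rows[[mrna_ids[i]]] <- y
    }
    for (i in which(roles == "extreme")) rows[[lnc_ids[i]]] <- rnorm(cfg$n_patients)
    patient_matrix <- do.call(rbind, rows)

    direction <- ifelse(roles == "colocated_uncorrelated", -mrna_sign,
      ifelse(roles == "flat", 0, mrna_sign)
    )
    patient_direction <- tibble(
      mrna_id = mrna_ids[has_partner],
      direction = direction[has_partner]
    )

    truth_pairs <- tibble(
      lncrna_id = lnc_ids[has_partner], mrna_id = mrna_ids[has_partner],
      class = roles[has_partner], distance_bp = dist[has_partner]
    )
    truth <- list(
      features = tibble(feature_id = lnc_ids, role = roles),
      pairs = truth_pairs[truth_pairs$class %in% c("cis_correlated", "cis_trend"), ],
      decoy_pairs = truth_pairs[!truth_pairs$class %in% c("cis_correlated", "cis_trend"), ],
      shortlist = sort(lnc_ids[roles %in% c("cis_correlated", "cis_trend", "extreme")])
    )
    structure(
      list(
        lnc_table = lnc_table, mrna_table = mrna_table,
        annotation = annotation, annotated_ids = annotated_ids,
        patient_matrix = patient_matrix, patient_direction = patient_direction,
        truth = truth, config = cfg
      ),
      class = "synth_expression"
    )
  })
}

# Stage series with exact first/last values (baseline b, final b * fc) and
# bounded multiplicative jitter only on intermediate stages, so planted
# fold changes survive any seed.
expression_series <- function(ids, biotype, fc, stage_names) {
  n <- length(ids)
  n_stages <- length(stage_names)
  base <- runif(n, 200, 1000)
  out <- tibble(feature_id = ids, biotype = biotype)
  for (s in seq_len(n_stages)) {
    v <- base * fc^((s - 1) / (n_stages - 1))
    if (s > 1 && s < n_stages) v <- v * runif(n, 0.97, 1.03)
    out[[stage_names[s]]] <- v
  }
  out
}

#' Synthetic qPCR Ct tables with planted truth
#'
#' A fold-change panel (planted linear fold changes implemented as target
#' Ct shifts of `-log2(fc)` in the test condition, three stable reference
#' genes) and a localization panel (planted nuclear shares implemented as
#' cytoplasmic-minus-nuclear Ct offsets `log2(s / (1 - s))`, plus one
#' near-undetectable transcript). Gaussian noise of `noise_sd` cycles is
#' added to every well.
#'
#' @param cfg A [synth_config()].
#' @return A list of class `synth_qpcr`: `ct` (long tibble: `sample_id`,
#'   `gene_id`, `fraction`, `condition`, `replicate`, `ct`),
#'   `reference_genes`, `truth_fc` (gene, planted fold change),
#'   `truth_localization` (gene, planted share, expected call) and
#'   `config`.
#' @export
gen_qpcr <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  control <- cfg$stage_names[1]
  tumor <- cfg$stage_names[length(cfg$stage_names)]
  reps <- cfg$qpcr_replicates
  refs <- c(RNA18S = 10, ACTB = 18, GAPDH = 20)
  planted_fc <- c(TGT1 = 2, TGT2 = 0.5, TGT3 = 4, TGT4 = 1)
  planted_share <- c(NUC1 = 0.9, NUC2 = 0.8, CYT1 = 0.2, MID1 = 0.5)
  with_rng_seed(cfg$seed + 2L, {
    well <- function(gene, condition, fraction, base) {
      tibble(
        sample_id = paste(condition, fraction, sep = "_"),
        gene_id = gene, fraction = fraction, condition = condition,
        replicate = seq_len(reps),
        ct = base + rnorm(reps, sd = cfg$noise_sd)
      )
    }
    fc_rows <- list()
    for (g in names(refs)) {
      fc_rows[[length(fc_rows) + 1]] <- well(g, control, "whole", refs[[g]])
      fc_rows[[length(fc_rows) + 1]] <- well(g, tumor, "whole", refs[[g]])
    }
    base_ct <- runif(length(planted_fc), 22, 28)
    for (i in seq_along(planted_fc)) {
      g <- names(planted_fc)[i]
      fc_rows[[length(fc_rows) + 1]] <- well(g, control, "whole", base_ct[i])
      fc_rows[[length(fc_rows) + 1]] <- well(
        g, tumor, "whole", base_ct[i] - log2(planted_fc[[i]])
      )
    }
    loc_rows <- list()
    for (i in seq_along(planted_share)) {
      g <- names(planted_share)[i]
      s <- planted_share[[i]]
      base <- runif(1, 23, 26)
      loc_rows[[length(loc_rows) + 1]] <- well(g, control, "nuclear", base)
      loc_rows[[length(loc_rows) + 1]] <- well(
        g, control, "cytoplasmic", base + log2(s / (1 - s))
      )
    }
    loc_rows[[length(loc_rows) + 1]] <- well("LOW1", control, "nuclear", 41)
    loc_rows[[length(loc_rows) + 1]] <- well("LOW1", control, "cytoplasmic", 41.5)
    expected_call <- function(s) {
      if (s >= 0.6) "nuclear" else if (s <= 0.4) "cytoplasmic" else "undetermined"
    }
    structure(
      list(
        ct = bind_rows(c(fc_rows, loc_rows)),
        reference_genes = names(refs),
        control_condition = control, test_condition = tumor,
        truth_fc = tibble(
          gene_id = names(planted_fc), fold_change = unname(planted_fc)
        ),
        truth_localization = bind_rows(
          tibble(
            gene_id = names(planted_share),
            nuclear_share = unname(planted_share),
            call = unname(vapply(planted_share, expected_call, ""))
          ),
          tibble(gene_id = "LOW1", nuclear_share = NA_real_, call = "undetermined")
        ),
        config = cfg
      ),
      class = "synth_qpcr"
    )
  })
}

#' Synthetic patient super-enhancer cohort with planted representation
#'
#' Builds a cohort of patient SE interval sets and a panel of focal
#' regions, each carried (overlapped by an SE, jittered within half a
#' region width) by an exact planted number of patients. Every patient
#' also carries background SEs in a separate coordinate zone.
#'
#' @param cfg A [synth_config()].
#' @param n_regions Number of focal regions.
#' @return A list of class `synth_cohort`: `cohort` (tibble `patient_id`,
#'   `chrom`, `start`, `end`), `regions`, `truth` (region, planted
#'   `count`, `total`) and `config`.
#' @export
gen_patient_cohort <- function(cfg = synth_config(), n_regions = 10L) {
  stopifnot(inherits(cfg, "synth_config"))
  n_pat <- cfg$n_cohort_patients
  if (n_pat < 1) abort("cohort needs >= 1 patient")
  with_rng_seed(cfg$seed + 3L, {
    width <- 20000L
    regions <- tibble(
      region_id = sprintf("REG%02d", seq_len(n_regions)),
      chrom = "chr1",
      start = 100000L + (seq_len(n_regions) - 1L) * 200000L
    )
    regions$end <- regions$start + width
    counts <- round(n_pat * seq_len(n_regions) / (n_regions + 1))
    patients <- sprintf("P%02d", seq_len(n_pat))
    rows <- list()
    for (i in seq_len(n_regions)) {
      carriers <- sample(patients, counts[i])
      if (length(carriers) > 0) {
        shift <- sample(seq(-width %/% 2L, width %/% 2L, by = 500L),
          length(carriers),
          replace = TRUE
        )
        rows[[length(rows) + 1]] <- tibble(
          patient_id = carriers, chrom = "chr1",
          start = regions$start[i] + shift, end = regions$end[i] + shift
        )
      }
    }
    # background SEs on a separate chromosome keep every patient non-empty
    rows[[length(rows) + 1]] <- tibble(
      patient_id = patients, chrom = "chr9",
      start = sample(seq(1e6L, 5e6L, by = 1000L), n_pat, replace = TRUE)
    ) |> mutate(end = .data$start + width)
    structure(
      list(
        cohort = arrange(bind_rows(rows), .data$patient_id, .data$chrom, .data$start),
        regions = regions,
        truth = mutate(regions, count = counts, total = n_pat),
        config = cfg
      ),
      class = "synth_cohort"
    )
  })
}
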