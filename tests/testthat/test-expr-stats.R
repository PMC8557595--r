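mk_ct <- function(gene, condition, cts, fraction = "whole") {
  tibble::tibble(
    sample_id = paste(condition, fraction, sep = "_"), gene_id = gene,
    fraction = fraction, condition = condition,
    replicate = seq_along(cts), ct = cts
  )
}

test_that("delta-delta-Ct follows the 2^(-ddCt) contract", {
  base <- dplyr::bind_rows(
    mk_ct("REF", "ctrl", c(15, 15.1, 14.9)), mk_ct("REF", "cond", c(15, 15.1, 14.9)),
    mk_ct("TGT", "ctrl", c(25, 25.2, 24.8))
  )
  same <- dplyr::bind_rows(base, mk_ct("TGT", "cond", c(25, 25.2, 24.8)))
  expect_equal(delta_delta_ct(same, "TGT", "REF", "cond", "ctrl")$fold_change, 1)
  # one cycle earlier with unchanged references doubles expression
  shifted <- dplyr::bind_rows(base, mk_ct("TGT", "cond", c(24, 24.2, 23.8)))
  expect_equal(delta_delta_ct(shifted, "TGT", "REF", "cond", "ctrl")$fold_change, 2)
  # control against itself is exactly 1
  expect_equal(delta_delta_ct(same, "TGT", "REF", "ctrl", "ctrl")$fold_change, 1)
  expect_error(
    delta_delta_ct(base, "TGT", "REF", "cond", "ctrl"),
    "missing Ct measurements"
  )
})

test_that("three-reference table matches a spreadsheet-style hand computation", {
  ct <- dplyr::bind_rows(
    mk_ct("R1", "ctrl", c(10.1, 10.0)), mk_ct("R1", "cond", c(10.2, 10.0)),
    mk_ct("R2", "ctrl", c(18.0, 18.2)), mk_ct("R2", "cond", c(17.9, 18.1)),
    mk_ct("R3", "ctrl", c(20.5, 20.3)), mk_ct("R3", "cond", c(20.6, 20.2)),
    mk_ct("TGT", "ctrl", c(26.0, 26.4)), mk_ct("TGT", "cond", c(24.1, 24.3))
  )
  res <- delta_delta_ct(ct, "TGT", c("R1", "R2", "R3"), "cond", "ctrl")
  # hand computation: per-condition reference mean of per-gene means
  ref_ctrl <- mean(c(mean(c(10.1, 10.0)), mean(c(18.0, 18.2)), mean(c(20.5, 20.3))))
  ref_cond <- mean(c(mean(c(10.2, 10.0)), mean(c(17.9, 18.1)), mean(c(20.6, 20.2))))
  ddct <- (mean(c(24.1, 24.3)) - ref_cond) - (mean(c(26.0, 26.4)) - ref_ctrl)
  expect_equal(res$delta_delta_ct, ddct)
  expect_equal(res$fold_change, 2^(-ddct))
  expect_false(res$low_confidence)
  expect_length(res$rep_fold_changes[[1]], 2)
})

test_that("fold changes are invariant to a global Ct shift and flag late Cts", {
  ct <- dplyr::bind_rows(
    mk_ct("REF", "ctrl", c(15, 15.2)), mk_ct("REF", "cond", c(15.1, 14.9)),
    mk_ct("TGT", "ctrl", c(27, 27.3)), mk_ct("TGT", "cond", c(25.6, 25.9))
  )
  fc1 <- delta_delta_ct(ct, "TGT", "REF", "cond", "ctrl")$fold_change
  shifted <- dplyr::mutate(ct, ct = ct + 3.7)
  fc2 <- delta_delta_ct(shifted, "TGT", "REF", "cond", "ctrl")$fold_change
  expect_equal(fc1, fc2)
  late <- dplyr::mutate(ct, ct = ifelse(gene_id == "TGT" & condition == "cond", ct + 16, ct))
  expect_true(delta_delta_ct(late, "TGT", "REF", "cond", "ctrl")$low_confidence)
})

test_that("localization shares follow the 2^(-Ct) ratio and sum to one", {
  ct <- dplyr::bind_rows(
    mk_ct("G", "c", c(25, 25), fraction = "nuclear"),
    mk_ct("G", "c", c(25, 25), fraction = "cytoplasmic")
  )
  out <- localization_call(ct, "G")
  expect_equal(out$nuclear_share, 0.5)
  expect_equal(out$call, "undetermined")
  # nuclear Ct three cycles earlier: share 8/9
  ct2 <- dplyr::bind_rows(
    mk_ct("G", "c", c(22, 22), fraction = "nuclear"),
    mk_ct("G", "c", c(25, 25), fraction = "cytoplasmic")
  )
  out2 <- localization_call(ct2, "G")
  expect_equal(out2$nuclear_share, 8 / 9)
  expect_equal(out2$call, "nuclear")
  # the cytoplasmic share is the complement
  expect_equal(out2$nuclear_share + (1 - out2$nuclear_share), 1)
  expect_error(
    localization_call(ct2[ct2$fraction == "nuclear", ], "G"),
    "both nuclear and cytoplasmic"
  )
  # near-undetectable in both fractions
  low <- dplyr::bind_rows(
    mk_ct("G", "c", c(41, 42), fraction = "nuclear"),
    mk_ct("G", "c", c(43, 41), fraction = "cytoplasmic")
  )
  expect_equal(localization_call(low, "G")$call, "undetermined")
})

test_that("planted fraction splits produce the expected localization calls", {
  set.seed(103)
  for (share in c(0.8, 0.2, 0.9)) {
    base <- runif(1, 22, 27)
    ct <- dplyr::bind_rows(
      mk_ct("G", "c", base + rnorm(3, sd = 0.05), fraction = "nuclear"),
      mk_ct("G", "c", base + log2(share / (1 - share)) + rnorm(3, sd = 0.05),
        fraction = "cytoplasmic"
      )
    )
    out <- localization_call(ct, "G")
    expect_equal(out$nuclear_share, share, tolerance = 0.05)
    expect_equal(out$call, if (share >= 0.6) "nuclear" else "cytoplasmic")
  }
})

test_that("one-way ANOVA with Tukey matches the textbook F and orders p-values", {
  groups <- list(g1 = c(1, 2, 3), g2 = c(2, 3, 4), g3 = c(6, 7, 8))
  data <- tibble::tibble(
    group = rep(names(groups), lengths(groups)),
    value = unlist(groups)
  )
  fit <- one_way_anova_tukey(data)
  expect_equal(fit$overall$f_statistic, oracle_anova_f(groups))
  expect_equal(fit$overall$df_between, 2)
  expect_equal(fit$overall$df_within, 6)
  # Tukey-adjusted p-values never undercut the unadjusted pairwise
  # comparisons on the same pooled error term
  ss_within <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  mse <- ss_within / 6
  combos <- utils::combn(names(groups), 2)
  for (i in seq_len(ncol(combos))) {
    a <- groups[[combos[1, i]]]
    b <- groups[[combos[2, i]]]
    t_pooled <- (mean(a) - mean(b)) / sqrt(mse * (1 / 3 + 1 / 3))
    unadj <- 2 * stats::pt(-abs(t_pooled), df = 6)
    row <- grepl(combos[1, i], fit$pairwise$comparison) &
      grepl(combos[2, i], fit$pairwise$comparison)
    expect_gte(fit$pairwise$p_adj[row] + 1e-12, unadj)
  }
  expect_error(one_way_anova_tukey(data[data$group == "g1", ]), "2 groups")
  expect_error(
    one_way_anova_tukey(tibble::tibble(group = c("a", "a", "b"), value = 1:3)),
    ">= 2 values"
  )
})

test_that("ANOVA p-values behave at the null and under huge separation", {
  set.seed(113)
  null_data <- tibble::tibble(
    group = rep(c("a", "b", "c"), each = 4),
    value = 10 + rep(0, 12) + rnorm(12, sd = 1e-3) + rep(c(0, 0, 0), each = 4)
  )
  fit <- one_way_anova_tukey(null_data)
  expect_gt(fit$overall$p_value, 0.05)
  sep <- tibble::tibble(
    group = rep(c("lo", "hi"), each = 3),
    value = c(rnorm(3, 0, 0.01), rnorm(3, 100, 0.01))
  )
  fit2 <- one_way_anova_tukey(sep)
  expect_lt(fit2$overall$p_value, 1e-6)
  expect_true(all(fit2$pairwise$p_adj < 0.001))
})

test_that("Student t-tests match the pooled-variance formula", {
  a <- c(1, 2, 3)
  b <- c(2, 3, 4)
  res <- t_test(a, b)
  expect_equal(res$statistic, oracle_student_t(a, b))
  expect_equal(res$df, 4)
  expect_equal(res$p_value, 2 * stats::pt(-abs(oracle_student_t(a, b)), df = 4))
  far <- t_test(rnorm(5, 0, 0.01), rnorm(5, 50, 0.01))
  expect_lt(far$p_value, 1e-6)
  expect_error(t_test(a, a, paired = TRUE), "zero variance")
  expect_error(t_test(c(1, 1, 1), c(1, 1, 1)), "zero pooled variance")
  paired <- t_test(c(1, 2, 3, 4), c(1.5, 2.2, 3.4, 4.1), paired = TRUE)
  expect_equal(paired$df, 3)
})
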