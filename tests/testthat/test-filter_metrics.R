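# Truth-set evaluation, metric formulas, cutoff grid search, filtering,
# and QUAL concordance between call sets.

test_that("confusion counts classify a hand-built set correctly", {
  calls <- make_calls(qual = c(30, 10, 30, 10), dp = c(6, 6, 6, 2))
  truth <- make_truth(calls, c("validated", "validated", "failed",
                               "failed"))
  cc <- confusion_counts(calls, truth, qual_min = 28, dp_min = 5)
  expect_equal(cc, list(tp = 1L, fp = 1L, tn = 1L, fn = 1L))

  # with no cutoffs and all keys present, everything is predicted
  cc0 <- confusion_counts(calls, truth, 0, 0)
  expect_equal(cc0$fp, 2L)
  expect_equal(cc0$fn, 0L)

  # truth variants absent from the call set are FN if validated, TN if not
  extra <- rbind(truth,
                 data.frame(chrom = "chr1", pos = 900:901, ref = "A",
                            alt = "G", sample_id = "S1",
                            status = c("validated", "failed")))
  cc1 <- confusion_counts(calls, extra, 0, 0)
  expect_equal(cc1$fn, 1L)
  expect_equal(cc1$tn, 1L)
})

test_that("confusion counts agree with a per-variant loop oracle", {
  res <- gen_variant_set(variant_sim_params("tier1-snv", n_true = 90,
                                            n_false = 110, seed = 21),
                         dir = tempfile())
  for (cut in list(c(28, 5), c(17, 3), c(0, 0), c(35, 15))) {
    expect_equal(
      confusion_counts(res$calls, res$truth_df, cut[1], cut[2]),
      brute_confusion(res$calls, res$truth_df, cut[1], cut[2]),
      info = paste(cut, collapse = ","))
  }
})

test_that("metric formulas reproduce published validation-study cells", {
  # SNV set filtered at QUAL>=28, DP>=5
  m <- compute_metrics(list(tp = 50, fp = 9, tn = 85, fn = 15))
  expect_equal(round(m$recall, 4), 0.7692)       # 50/65 = 76.92%
  expect_equal(round(m$accuracy, 4), 0.8475)     # 50/59 = 84.75%
  expect_equal(round(m$f_score, 4), 0.8065)
  # indel set filtered at QUAL>=17, DP>=3
  m2 <- compute_metrics(list(tp = 12, fp = 1, tn = 9, fn = 0))
  expect_equal(m2$recall, 1.0)
  expect_equal(round(m2$accuracy, 4), 0.9231)    # 12/13 = 92.31%
  # unfiltered recalibrated SNV set
  m3 <- compute_metrics(list(tp = 65, fp = 80, tn = 14, fn = 0))
  expect_equal(m3$recall, 1.0)
  expect_equal(round(m3$accuracy, 4), 0.4483)    # 65/145 = 44.83%
  expect_equal(round(m3$validate_rate, 4), 0.4088)
})

test_that("zero denominators yield undefined (NA) metrics, never 0", {
  m <- compute_metrics(list(tp = 0, fp = 0, tn = 5, fn = 0))
  expect_true(is.na(m$recall))
  expect_true(is.na(m$accuracy))
  expect_true(is.na(m$f_score))
  expect_equal(m$validate_rate, 0)
})

test_that("F score identity and bounds hold across random counts", {
  set.seed(42)
  for (i in 1:200) {
    cc <- list(tp = sample(0:50, 1), fp = sample(0:50, 1),
               tn = sample(0:50, 1), fn = sample(0:50, 1))
    m <- compute_metrics(cc)
    if (!is.na(m$f_score) && !is.na(m$recall) && !is.na(m$accuracy)) {
      harmonic <- if (m$recall + m$accuracy == 0) 0 else
        2 * m$recall * m$accuracy / (m$recall + m$accuracy)
      expect_equal(m$f_score, harmonic, tolerance = 1e-12)
      expect_gte(m$f_score, min(m$recall, m$accuracy) - 1e-12)
      expect_lte(m$f_score, max(m$recall, m$accuracy) + 1e-12)
    }
  }
})

test_that("validation rate matches published worked examples", {
  expect_equal(round(validation_rate(65, 159), 4), 0.4088)
  # 12/22 is printed as 54.54% (truncated); compare at printed precision
  expect_equal(validation_rate(12, 22), 0.5454, tolerance = 2e-4)
  expect_equal(validation_rate(0, 10), 0)
  expect_error(validation_rate(0, 0), "zero")
})

test_that("grid search is exhaustive and matches a brute-force loop", {
  res <- gen_variant_set(variant_sim_params("tier1-snv", n_true = 60,
                                            n_false = 80, seed = 5),
                         dir = tempfile())
  gr <- grid_search(res$calls, res$truth_df, 15:35, 3:15)
  expect_equal(nrow(gr$table), 21 * 13)
  # independent double loop over the same grid
  best_f <- -Inf
  for (q in 15:35) {
    for (d in 3:15) {
      cc <- brute_confusion(res$calls, res$truth_df, q, d)
      f <- if (2 * cc$tp + cc$fp + cc$fn == 0) NA_real_ else
        2 * cc$tp / (2 * cc$tp + cc$fp + cc$fn)
      row <- gr$table[gr$table$qual_min == q & gr$table$dp_min == d, ]
      expect_equal(row$f_score, f)
      if (!is.na(f) && f > best_f) best_f <- f
    }
  }
  expect_equal(gr$best$f_score[1], best_f)
  expect_true(all(gr$best$f_score == best_f))
})

test_that("grid search recovers a planted QUAL/DP separation with F = 1", {
  for (seed in 1:3) {
    res <- gen_variant_set(variant_sim_params("separable", seed = seed),
                           dir = tempfile())
    gr <- grid_search(res$calls, res$truth_df)
    expect_equal(max(gr$best$f_score), 1)
    # some maximizer must sit inside the planted window
    in_window <- gr$best$qual_min > 25 & gr$best$qual_min <= 30 &
      gr$best$dp_min > 4 & gr$best$dp_min <= 6
    expect_true(any(in_window))
  }
})

test_that("counts conserve, cutoffs are monotone, validate rate is fixed", {
  res <- gen_variant_set(variant_sim_params("tier1-snv", seed = 8),
                         dir = tempfile())
  gr <- grid_search(res$calls, res$truth_df)
  tab <- gr$table
  expect_true(all(tab$tp + tab$fp + tab$tn + tab$fn == nrow(res$truth_df)))
  vr <- compute_metrics(as.list(tab[1, c("tp", "fp", "tn",
                                         "fn")]))$validate_rate
  for (i in seq_len(nrow(tab))) {
    m <- compute_metrics(as.list(tab[i, c("tp", "fp", "tn", "fn")]))
    expect_equal(m$validate_rate, vr)
  }
  # raising either cutoff never increases tp or fp
  for (d in c(3, 8)) {
    sub <- tab[tab$dp_min == d, ]
    sub <- sub[order(sub$qual_min), ]
    expect_true(all(diff(sub$tp) <= 0))
    expect_true(all(diff(sub$fp) <= 0))
  }
  for (q in c(15, 25)) {
    sub <- tab[tab$qual_min == q, ]
    sub <- sub[order(sub$dp_min), ]
    expect_true(all(diff(sub$tp) <= 0))
    expect_true(all(diff(sub$fp) <= 0))
  }
})

test_that("a degenerate grid (nothing defined) raises an error", {
  calls <- make_calls(qual = c(5, 6), dp = c(1, 1))
  truth <- make_truth(calls, c("failed", "failed"))
  # tp = 0 everywhere and fp + fn = 0 at high cutoffs never happens here;
  # force full degeneracy with an empty-prediction truth of failed-only
  # variants absent from the call set
  truth2 <- truth
  truth2$pos <- truth2$pos + 1000L
  expect_error(grid_search(calls[0, ], truth2[0, ]), "degenerate|entries")
})

test_that("depth-bound filtering keeps records inside [dp_min, dp_max]", {
  calls <- make_calls(qual = c(10, 10, 10, 50), dp = c(2, 3, 10000, 10001))
  kept <- apply_filter(calls, qual_min = 0, dp_min = 3, dp_max = 10000)
  expect_equal(kept$dp, c(3L, 10000L))
  # identity configuration
  same <- apply_filter(calls, qual_min = 0, dp_min = 0, dp_max = Inf)
  expect_equal(same$pos, calls$pos)
  # loop oracle on a synthetic set
  res <- gen_variant_set(variant_sim_params("tier1-snv", seed = 13),
                         dir = tempfile())
  kept2 <- apply_filter(res$calls, qual_min = 20, dp_min = 3,
                        dp_max = 10000)
  n_manual <- 0L
  for (i in seq_len(nrow(res$calls))) {
    if (res$calls$qual[i] >= 20 && res$calls$dp[i] >= 3 &&
        res$calls$dp[i] <= 10000) n_manual <- n_manual + 1L
  }
  expect_equal(nrow(kept2), n_manual)
})

test_that("QUAL concordance matches its closed-form definition", {
  a <- make_calls(qual = c(10, 20, 30, 40), dp = 10)
  expect_equal(qual_concordance(a, a),
               list(pearson_r = 1.0, frac_a_higher = 0.0, n_matched = 4L))
  b <- a
  b$qual <- a$qual - 1
  cc <- qual_concordance(a, b)
  expect_equal(cc$pearson_r, 1.0)
  expect_equal(cc$frac_a_higher, 1.0)

  set.seed(99)
  x <- make_calls(qual = runif(100, 10, 60), dp = 10, pos = 1:100)
  y <- x
  y$qual <- x$qual + rnorm(100, 0, 2)
  cc2 <- qual_concordance(x, y)
  num <- mean(x$qual * y$qual) - mean(x$qual) * mean(y$qual)
  den <- sqrt((mean(x$qual^2) - mean(x$qual)^2) *
              (mean(y$qual^2) - mean(y$qual)^2))
  expect_equal(cc2$pearson_r, num / den, tolerance = 1e-12)
  expect_equal(cc2$frac_a_higher, mean(x$qual > y$qual))

  expect_error(qual_concordance(a[1, ], a[1, ]), "2 matched")
})
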