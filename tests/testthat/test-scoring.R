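test_that("SYN recovers planted shifts with the documented sign convention", {
  ref <- gen_ref_lrn(seed = 1)
  expect_equal(compute_syn(ref, ref)$syn_ms, 0)

  delayed <- gen_for_response(ref, 250, 0, 1)
  s <- compute_syn(ref, delayed)
  expect_equal(s$syn_ms, 250)
  expect_gt(s$peak_corr, 0.99)

  advanced <- gen_for_response(ref, -100, 0, 1)
  expect_equal(compute_syn(ref, advanced)$syn_ms, -100)
})

test_that("SYN agrees with a brute-force lag scan on noisy trials", {
  ref <- gen_ref_lrn(seed = 2)
  for (seed in 1:5) {
    f <- gen_for_response(ref, 120, noise_sd = 2, seed = seed)
    s <- compute_syn(ref, f)
    o <- oracle_best_lag(ref$samples, f$samples, 80, 3)
    expect_equal(s$lag_samples, unname(o["lag"]))
    expect_equal(s$peak_corr, unname(o["r"]), tolerance = 1e-12)
  }
})

test_that("degenerate trials raise a typed condition", {
  ref <- gen_ref_lrn(seed = 1)
  flat <- force_trace(rep(10, 1440), 80)
  expect_error(compute_syn(ref, flat), class = "degenerate_trial")
  expect_error(compute_rmse(ref, ref, 12000), class = "degenerate_trial")
})

test_that("lag-aligned RMSE isolates spatial error from timing error", {
  ref <- gen_ref_lrn(seed = 1)
  expect_equal(compute_rmse(ref, ref, 0), 0)
  offset <- force_trace(ref$samples + 2, 80)
  expect_equal(compute_rmse(ref, offset, 0), 2)
  shifted <- gen_for_response(ref, 250, 0, 1)
  expect_lt(compute_rmse(ref, shifted, 250), 1e-9)
  # advanced copies align too
  shifted_neg <- gen_for_response(ref, -137.5, 0, 1)
  s <- compute_syn(ref, shifted_neg)
  expect_lt(compute_rmse(ref, shifted_neg, s$syn_ms), 1e-9)
})

test_that("cohort scoring respects the trial arithmetic and block means", {
  cohort <- gen_behaviour_cohort(n_per_group = 2, days = c("d1", "d2"),
                                 seed = 3)
  sc <- score_cohort(cohort)
  d1 <- sc$trials[sc$trials$day == "d1", ]
  expect_equal(nrow(d1), 72)                      # 2*(9+9) + 2*18
  expect_equal(sum(d1$condition == "LRN"), 18)    # 2 subjects x 9 trials
  for (subj in unique(d1$subject)) {
    tab <- table(d1$condition[d1$subject == subj])
    grp <- unique(d1$group[d1$subject == subj])
    if (grp == "LRN") {
      expect_equal(as.integer(tab[c("LRN", "SMP")]), c(9L, 9L))
    } else {
      expect_equal(as.integer(tab["SMP"]), 18L)  # complex blocks replaced
    }
  }
  bm <- sc$block_means[1, ]
  tri <- sc$trials[sc$trials$subject == bm$subject & sc$trials$day == bm$day &
                   sc$trials$condition == bm$condition &
                   sc$trials$block == bm$block, ]
  expect_equal(bm$syn_ms, mean(tri$syn_ms))
  expect_equal(nrow(tri), 3)
})

test_that("noiseless planted lags are recovered exactly at sample resolution", {
  sched <- default_behaviour_schedule(c("d1"))
  sched$noise_sd <- 0
  cohort <- gen_behaviour_cohort(n_per_group = 1, schedule = sched,
                                 days = "d1", seed = 7)
  sc <- score_cohort(cohort)
  gt <- cohort$ground_truth$planted
  merged <- merge(sc$trials, gt[c("trace_id", "planted_lag_ms")],
                  by = "trace_id")
  expected <- round(merged$planted_lag_ms / 12.5) * 12.5
  expect_equal(merged$syn_ms, expected)
})

test_that("scoring is invariant to metadata row order", {
  cohort <- gen_behaviour_cohort(n_per_group = 2, days = "d1", seed = 5)
  sc1 <- score_cohort(cohort)
  set.seed(99)
  cohort2 <- cohort
  cohort2$table <- cohort$table[sample(nrow(cohort$table)), ]
  sc2 <- score_cohort(cohort2)
  key <- function(df) df[order(df$subject, df$day, df$condition), ]
  expect_equal(key(sc1$day_means)$syn_ms, key(sc2$day_means)$syn_ms)
})

test_that("outlier exclusion follows the two-day two-SD rule", {
  # deterministic small jitter: z-scores of a linear sequence stay < 2
  sc <- synthetic_day_means(n_per_cell = 10, seed = 11)
  dm <- sc$day_means
  dm$syn_ms <- 100 + 0.01 * as.integer(factor(dm$subject))
  dm$rmse <- 5 + 0.001 * as.integer(factor(dm$subject))
  sc$day_means <- dm

  expect_length(exclude_outliers(sc)$excluded_subjects, 0)

  # identical subjects: zero deviations, no exclusions
  sc0 <- sc
  sc0$day_means$syn_ms <- 100; sc0$day_means$rmse <- 5
  expect_length(exclude_outliers(sc0)$excluded_subjects, 0)

  # plant one subject far out on three days (either metric counts)
  sc3 <- sc
  rows <- sc3$day_means$subject == "LRN_01" &
    sc3$day_means$condition == "LRN" &
    sc3$day_means$day %in% c("d1", "d2", "d3")
  sc3$day_means$syn_ms[rows] <- sc3$day_means$syn_ms[rows] + 200
  out3 <- exclude_outliers(sc3)
  expect_equal(out3$excluded_subjects, "LRN_01")
  expect_true(all(out3$scores$day_means$excluded[
    out3$scores$day_means$subject == "LRN_01"]))

  # a single offending day is not enough
  sc1 <- sc
  rows1 <- sc1$day_means$subject == "LRN_01" &
    sc1$day_means$condition == "LRN" & sc1$day_means$day == "d1"
  sc1$day_means$syn_ms[rows1] <- sc1$day_means$syn_ms[rows1] + 200
  expect_false("LRN_01" %in% exclude_outliers(sc1)$excluded_subjects)
})

test_that("outlier exclusion refuses unstable groups", {
  sc <- synthetic_day_means(n_per_cell = 2)
  expect_error(exclude_outliers(sc), "3 subjects")
})
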