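days6 <- c("d1", "d2", "d3", "d4", "d5", "d17")

test_that("baseline t test matches an independent implementation", {
  set.seed(31)
  bm <- expand.grid(subject = sprintf("s%02d", 1:16), day = "d1",
                    condition = "SMP", block = 1, stringsAsFactors = FALSE)
  bm$group <- rep(c("LRN", "SMP"), each = 8)
  bm$syn_ms <- rnorm(16, 100, 20)
  bm$rmse <- rnorm(16, 5, 1)
  sc <- structure(list(block_means = bm), class = "cohort_scores")
  res <- baseline_ttest(sc)

  for (metric in c("syn_ms", "rmse")) {
    x <- bm[[metric]][bm$group == "LRN"]; y <- bm[[metric]][bm$group == "SMP"]
    # Welch statistic written out by hand
    se <- sqrt(var(x) / 8 + var(y) / 8)
    t_manual <- (mean(x) - mean(y)) / se
    df_manual <- se^4 / ((var(x) / 8)^2 / 7 + (var(y) / 8)^2 / 7)
    row <- res[res$metric == metric, ]
    expect_equal(row$t, t_manual, tolerance = 1e-10)
    expect_equal(row$df, df_manual, tolerance = 1e-10)
    expect_equal(row$p, 2 * pt(-abs(t_manual), df_manual), tolerance = 1e-10)
  }

  bm$syn_ms <- rep(rnorm(8, 100, 20), 2)  # identical groups
  bm$rmse <- 5
  sc2 <- structure(list(block_means = bm), class = "cohort_scores")
  res2 <- baseline_ttest(sc2)
  expect_equal(res2$t, c(0, 0))
  expect_equal(res2$p, c(1, 1))
})

test_that("mixed ANOVA agrees with the multivariate-lm reference route", {
  sc <- synthetic_day_means(n_per_cell = 8, seed = 42)
  for (dv in c("syn_ms", "rmse")) {
    res <- rm_anova(sc, dv)
    ora <- oracle_rm_anova(sc, dv, days6)

    expect_equal(res$F[res$effect == "trace_type"],
                 ora$between$`F value`[1], tolerance = 1e-8)
    expect_equal(res$p[res$effect == "trace_type"],
                 ora$between$`Pr(>F)`[1], tolerance = 1e-8)

    w <- ora$within
    expect_equal(res$F[res$effect == "day"], w[["F"]][1], tolerance = 1e-8)
    expect_equal(res$F[res$effect == "day:trace_type"], w[["F"]][2],
                 tolerance = 1e-8)
    expect_equal(attr(res, "epsilon_gg"), ora$eps_gg, tolerance = 1e-8)
    expect_equal(attr(res, "epsilon_gg"), ora$heading_gg, tolerance = 1e-4)
    expect_equal(min(1, attr(res, "epsilon_hf")), min(1, ora$eps_hf),
                 tolerance = 1e-8)
    expect_equal(attr(res, "mauchly_w"), unname(ora$mauchly$statistic),
                 tolerance = 1e-8)
    expect_equal(attr(res, "mauchly_p"), ora$mauchly$p.value,
                 tolerance = 1e-8)
    # uncorrected p of within effects
    if (all(res$correction == "none")) {
      expect_equal(res$p[res$effect == "day"], w[["Pr(>F)"]][1],
                   tolerance = 1e-8)
    }
  }
})

test_that("ANOVA degenerates correctly when all cells are equal", {
  sc <- synthetic_day_means(n_per_cell = 5, seed = 1)
  sc$day_means$syn_ms <- 7
  res <- rm_anova(sc, "syn_ms")
  expect_equal(res$F, rep(0, 3))
})

test_that("compound-symmetric data need no sphericity correction", {
  set.seed(8)
  days <- c("d1", "d2", "d3", "d4")
  out <- list()
  for (grp in c("LRN", "SMP")) for (i in 1:30) {
    subj_eff <- rnorm(1, 0, 5)  # shared across days: compound symmetry
    out[[length(out) + 1L]] <- data.frame(
      subject = sprintf("%s%02d", grp, i), group = grp, day = days,
      condition = "SMP", syn_ms = 100 + subj_eff + rnorm(4, 0, 3),
      rmse = 5, excluded = FALSE)
  }
  sc <- structure(list(day_means = do.call(rbind, out)),
                  class = "cohort_scores")
  res <- rm_anova(sc, "syn_ms", coding = "group2")
  expect_gt(attr(res, "epsilon_gg"), 0.85)
  expect_true(all(res$correction == "none"))
  # uncorrected dfs preserved
  expect_equal(res$df_num[res$effect == "day"], 3)
})

test_that("Tukey consecutive-day tests match TukeyHSD", {
  sc <- synthetic_day_means(n_per_cell = 8, seed = 42)
  tk <- tukey_consecutive(sc, "syn_ms")
  dm <- sc$day_means
  sub <- dm[dm$group == "LRN" & dm$condition == "LRN", ]
  fit <- stats::aov(syn_ms ~ factor(subject) +
                      factor(day, levels = days6), data = sub)
  hsd <- stats::TukeyHSD(fit, "factor(day, levels = days6)")[[1]]
  for (pair in list(c("d1", "d2"), c("d2", "d3"), c("d5", "d17"))) {
    row <- tk[tk$trace_type == "LRN" & tk$day_from == pair[1] &
                tk$day_to == pair[2], ]
    ref <- hsd[paste0(pair[2], "-", pair[1]), ]
    expect_equal(row$diff, unname(ref["diff"]), tolerance = 1e-8)
    expect_equal(row$p_tukey, unname(ref["p adj"]), tolerance = 1e-8)
  }
})

test_that("Tukey detects a planted early improvement only where planted", {
  sc <- synthetic_day_means(
    n_per_cell = 12, seed = 9,
    effects = list(LRN = c(60, 10, 10, 10, 10, 10),
                   LRN_SMP = rep(10, 6), SMP = rep(10, 6)),
    subject_sd = 5, resid_sd = 4)
  tk <- tukey_consecutive(sc, "syn_ms")
  lrn_d12 <- tk[tk$trace_type == "LRN" & tk$day_from == "d1", ]
  smp <- tk[tk$trace_type == "SMP", ]
  expect_lt(lrn_d12$p_tukey, 0.001)
  expect_true(all(smp$p_tukey > 0.05))
})

test_that("flat data yield no significant Tukey pairs", {
  sc <- synthetic_day_means(n_per_cell = 6, seed = 10,
                            effects = list(LRN = rep(0, 6),
                                           LRN_SMP = rep(0, 6),
                                           SMP = rep(0, 6)))
  tk <- tukey_consecutive(sc, "syn_ms")
  expect_true(all(tk$p_tukey > 0.05))
})
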