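# Hand-built EC stack: `n` subjects per group, values drawn iid, with an
# optional per-group offset added to chosen voxels on chosen days.
toy_stack <- function(n_per_group = 6, grid = c(8, 8, 8), n_mask = 200,
                      days = c("d1", "d5"), seed = 1, offset = NULL) {
  set.seed(seed)
  mask <- array(FALSE, grid)
  mask[seq_len(n_mask)] <- TRUE
  subjects <- sprintf("s%02d", seq_len(2 * n_per_group))
  groups <- stats::setNames(rep(c("LRN", "SMP"), each = n_per_group),
                            subjects)
  ec <- list()
  for (d in days) {
    M <- matrix(rnorm(2 * n_per_group * n_mask, 0, 0.01),
                2 * n_per_group, n_mask)
    rownames(M) <- subjects
    if (!is.null(offset) && d %in% offset$days) {
      M[groups[subjects] == offset$group, offset$voxels] <-
        M[groups[subjects] == offset$group, offset$voxels] + offset$value
    }
    ec[[d]] <- M
  }
  list(stack = structure(list(ec = ec, mask = mask, subjects = subjects),
                         class = "ec_stack"),
       groups = groups)
}

test_that("the four stages and two directions enumerate the eight contrasts", {
  all8 <- all_stage_contrasts()
  expect_length(all8, 8)
  pairs <- unique(t(sapply(all8, function(s) s$day_pair)))
  expect_equal(nrow(pairs), 4)
  expect_equal(stage_contrast("fast")$day_pair, c("d1", "d2"))
  expect_equal(stage_contrast("slow")$day_pair, c("d2", "d5"))
  expect_equal(stage_contrast("overall")$day_pair, c("d1", "d5"))
  expect_equal(stage_contrast("retention")$day_pair, c("d5", "d17"))
})

test_that("interaction t-maps are sign-symmetric across directions", {
  ts <- toy_stack(seed = 2)
  dec <- interaction_tmap(ts$stack, ts$groups, stage_contrast("overall", "decrease"))
  inc <- interaction_tmap(ts$stack, ts$groups, stage_contrast("overall", "increase"))
  expect_equal(dec$t, -inc$t)
  expect_equal(dec$df, 10)
  # flipping every subject's change negates the map
  flipped <- ts$stack
  flipped$ec$d5 <- 2 * flipped$ec$d1 - flipped$ec$d5
  dec2 <- interaction_tmap(flipped, ts$groups, stage_contrast("overall", "decrease"))
  expect_equal(dec2$t, -dec$t, tolerance = 1e-10)
})

test_that("null change maps give a central t distribution", {
  ts <- toy_stack(n_per_group = 10, n_mask = 400, seed = 5)
  tm <- interaction_tmap(ts$stack, ts$groups, stage_contrast("overall", "decrease"))
  ks <- suppressWarnings(stats::ks.test(tm$t, stats::pt, df = tm$df))
  expect_gt(ks$p.value, 0.01)
})

test_that("a planted learning-group decrease raises in-region t for the decrease contrast", {
  vox <- 1:20
  ts <- toy_stack(seed = 7, offset = list(group = "LRN", days = "d5",
                                          voxels = vox, value = -0.05))
  tm <- interaction_tmap(ts$stack, ts$groups, stage_contrast("overall", "decrease"))
  expect_gt(mean(tm$t[vox]), mean(tm$t[-vox]) + 3)
})

test_that("cluster inference finds a planted suprathreshold cube exactly", {
  grid <- c(10, 10, 10)
  mask <- array(TRUE, grid)
  cube <- array(FALSE, grid)
  cube[3:7, 4:6, 5:6] <- TRUE          # 5 x 3 x 2 = 30 voxels
  n <- 12
  set.seed(11)
  delta <- matrix(rnorm(n * prod(grid), 0, 0.01), n, prod(grid))
  grp <- rep(c("LRN", "SMP"), each = 6)
  delta[grp == "LRN", as.vector(cube)] <- delta[grp == "LRN", as.vector(cube)] - 1
  tm <- structure(list(t = col_t <- motorecm:::col_t_stat(delta, grp == "SMP"),
                       df = n - 2L, mask = mask,
                       stage = stage_contrast("overall", "decrease"),
                       delta = delta, groups = grp, sided = "one"),
                  class = "tmap")
  cl <- cluster_inference(tm, n_perm = 100, seed = 1)
  # the planted cube is recovered exactly as the largest cluster; chance
  # suprathreshold singletons from the noise floor may accompany it
  expect_equal(cl$size[1], 30)
  expect_true(cl$significant[1])
  expect_true(all(cl$size[-1] <= 2))
  expect_setequal(which(mask)[attr(cl, "voxels")[[1]]], which(cube))
})

test_that("an all-zero t-map yields a well-formed empty cluster list", {
  ts <- toy_stack(seed = 3)
  tm <- interaction_tmap(ts$stack, ts$groups, stage_contrast("overall", "decrease"))
  tm$t[] <- 0
  cl <- cluster_inference(tm, n_perm = 100, seed = 1)
  expect_s3_class(cl, "cluster_result")
  expect_equal(nrow(cl), 0)
})

test_that("connectivity variants agree with their neighbourhood definitions", {
  m <- array(FALSE, c(3, 3, 3))
  m[1, 1, 1] <- TRUE; m[2, 2, 1] <- TRUE   # edge neighbours, not face
  expect_equal(motorecm:::label_components(m, 6)$n, 2)
  expect_equal(motorecm:::label_components(m, 18)$n, 1)
  m2 <- array(FALSE, c(3, 3, 3))
  m2[1, 1, 1] <- TRUE; m2[2, 2, 2] <- TRUE # corner neighbours
  expect_equal(motorecm:::label_components(m2, 18)$n, 2)
  expect_equal(motorecm:::label_components(m2, 26)$n, 1)
})

test_that("baseline group comparison detects only planted differences", {
  # identical maps for every subject: degenerate t, no clusters
  ts0 <- toy_stack(seed = 13)
  ts0$stack$ec$d1 <- matrix(rep(ts0$stack$ec$d1[1, ], each = 12), 12)
  rownames(ts0$stack$ec$d1) <- ts0$stack$subjects
  bt0 <- baseline_ec_test(ts0$stack, ts0$groups, "d1", n_perm = 100)
  expect_equal(nrow(bt0$clusters), 0)
  expect_true(all(bt0$tmap$t == 0))

  # planted offset at baseline in a compact block of voxels
  vox <- 1:25
  ts1 <- toy_stack(seed = 14, offset = list(group = "LRN", days = "d1",
                                            voxels = vox, value = 0.08))
  bt1 <- baseline_ec_test(ts1$stack, ts1$groups, "d1", n_perm = 100)
  expect_gt(nrow(bt1$clusters), 0)
  hit <- unlist(attr(bt1$clusters, "voxels")[bt1$clusters$significant])
  expect_gt(length(intersect(hit, vox)) / length(vox), 0.5)
})

test_that("ROI trajectories summarize per-group change with t-based CIs", {
  ts <- toy_stack(seed = 15, offset = list(group = "LRN", days = "d5",
                                           voxels = 1:10, value = -0.05))
  st <- stage_contrast("overall", "decrease")
  traj <- roi_trajectory(ts$stack, 1:10, ts$groups, stage = st)
  expect_equal(nrow(traj$per_day), 4)   # 2 groups x 2 days
  d <- traj$delta
  lrn <- d[d$group == "LRN", ]
  expect_lt(lrn$mean, -0.03)
  # CI95 = mean +/- t-quantile * SEM
  expect_equal(lrn$ci_hi - lrn$mean, qt(0.975, lrn$n - 1) * lrn$sem)

  # all-identical subjects: zero SEM and zero-width CI
  ts2 <- toy_stack(seed = 16)
  for (d2 in names(ts2$stack$ec)) {
    ts2$stack$ec[[d2]] <- matrix(rep(ts2$stack$ec[[d2]][1, ], each = 12), 12)
    rownames(ts2$stack$ec[[d2]]) <- ts2$stack$subjects
  }
  t2 <- roi_trajectory(ts2$stack, 1:10, ts2$groups, stage = st)
  expect_equal(t2$delta$sem, c(0, 0))
  expect_equal(t2$delta$ci_lo, t2$delta$ci_hi)

  # single-subject groups are flagged, not silently summarized
  ts3 <- toy_stack(n_per_group = 1, seed = 17)
  t3 <- roi_trajectory(ts3$stack, 1:10, ts3$groups, stage = st)
  expect_true(all(t3$delta$degenerate_n))
  expect_true(all(is.na(t3$delta$sem)))
})

test_that("specificity classification implements the CI-based rule", {
  mk <- function(lm, ll, lh, sm, sl, sh) {
    data.frame(group = c("LRN", "SMP"), mean = c(lm, sm),
               ci_lo = c(ll, sl), ci_hi = c(lh, sh))
  }
  # learning group drives, control flat: sequence-specific
  v <- classify_specificity(mk(-0.10, -0.14, -0.06, 0.03, -0.02, 0.08))
  expect_equal(v$driving_group, "LRN")
  expect_true(v$sequence_specific)
  # control group drives: not specific
  v2 <- classify_specificity(mk(0.02, -0.04, 0.08, -0.13, -0.17, -0.10))
  expect_equal(v2$driving_group, "SMP")
  expect_false(v2$sequence_specific)
  # both flat: no driver
  v3 <- classify_specificity(mk(0, -0.05, 0.05, 0, -0.04, 0.04))
  expect_equal(v3$driving_group, "none")
  expect_false(v3$sequence_specific)
  # both exclude zero: larger magnitude wins, tie recorded
  v4 <- classify_specificity(mk(0.06, 0.02, 0.11, -0.12, -0.19, -0.06))
  expect_equal(v4$driving_group, "SMP")
  expect_true(v4$both_excluded)
  expect_false(v4$sequence_specific)
  # even a driving learning group is not sequence-specific if control moves
  v5 <- classify_specificity(mk(-0.2, -0.25, -0.15, 0.1, 0.05, 0.15))
  expect_false(v5$sequence_specific)
})

test_that("reports serialize round-trippably and handle empty results", {
  empty <- stage_report(list())
  expect_equal(nrow(empty$clusters), 0)
  expect_equal(nrow(empty$group_changes), 0)

  ts <- toy_stack(seed = 19, offset = list(group = "LRN", days = "d5",
                                           voxels = 1:25, value = -0.08))
  res <- run_interaction_analyses(ts$stack, ts$groups,
                                  stages = list(overall_decrease =
                                                  stage_contrast("overall", "decrease")),
                                  n_perm = 100, seed = 1)
  dir <- withr::local_tempdir()
  rep <- stage_report(res, dir)
  expect_true(file.exists(file.path(dir, "clusters.tsv")))
  expect_true(file.exists(file.path(dir, "report.json")))
  back <- jsonlite::read_json(file.path(dir, "report.json"),
                              simplifyVector = TRUE)
  expect_equal(back$clusters$size, rep$clusters$size)
  expect_equal(back$group_changes$mean, rep$group_changes$mean,
               tolerance = 1e-12)
  expect_gt(nrow(rep$clusters), 0)
})
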