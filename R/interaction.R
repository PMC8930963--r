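#' Learning-stage contrasts
#'
#' The four learning stages map onto day pairs: fast learning (d1, d2),
#' slow learning (d2, d5), overall learning (d1, d5) and retention
#' (d5, d17). Each stage is tested in both directions (centrality decrease
#' or increase relative to the learning group), giving the eight
#' directional interaction contrasts.
#'
#' @param name One of `"fast"`, `"slow"`, `"overall"`, `"retention"`.
#' @param direction `"decrease"` or `"increase"` (relative to the learning
#'   group).
#' @return An object of class `stage_contrast` with fields `name`,
#'   `day_pair`, `direction`.
#' @export
stage_contrast <- function(name = c("fast", "slow", "overall", "retention"),
                           direction = c("decrease", "increase")) {
  name <- match.arg(name)
  direction <- match.arg(direction)
  pairs <- list(fast = c("d1", "d2"), slow = c("d2", "d5"),
                overall = c("d1", "d5"), retention = c("d5", "d17"))
  structure(list(name = name, day_pair = pairs[[name]],
                 direction = direction),
            class = "stage_contrast")
}

#' @rdname stage_contrast
#' @export
all_stage_contrasts <- function() {
  out <- list()
  for (n in c("fast", "slow", "overall", "retention")) {
    for (d in c("decrease", "increase")) {
      out[[paste(n, d, sep = "_")]] <- stage_contrast(n, d)
    }
  }
  out
}

#' Stack per-session EC maps into day-wise subject matrices
#'
#' @param maps Nested list `[[subject]][[day]]` of `ec_map` objects sharing
#'   one grid.
#' @return A list of class `ec_stack`: `ec` (named list per day of
#'   subjects x voxels matrices over the common mask), `mask` (3D logical
#'   intersection mask), `subjects`.
#' @export
stack_ec_maps <- function(maps) {
  subjects <- names(maps)
  days <- names(maps[[1]])
  mask <- NULL
  for (s in subjects) for (d in days) {
    m <- maps[[s]][[d]]$mask
    mask <- if (is.null(mask)) m else mask & m
  }
  ec <- list()
  for (d in days) {
    ec[[d]] <- do.call(rbind, lapply(subjects, function(s) {
      maps[[s]][[d]]$map[mask]
    }))
    rownames(ec[[d]]) <- subjects
  }
  structure(list(ec = ec, mask = mask, subjects = subjects),
            class = "ec_stack")
}

# Pooled-variance two-sample t per column: group1 minus group2.
# Zero-variance columns get t = 0.
col_t_stat <- function(X, g1) {
  n1 <- sum(g1); n2 <- sum(!g1)
  m1 <- colMeans(X[g1, , drop = FALSE])
  m2 <- colMeans(X[!g1, , drop = FALSE])
  ss1 <- colSums(X[g1, , drop = FALSE]^2) - n1 * m1^2
  ss2 <- colSums(X[!g1, , drop = FALSE]^2) - n2 * m2^2
  sp2 <- (ss1 + ss2) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t <- (m1 - m2) / se
  t[!is.finite(t)] <- 0
  t
}

#' Voxel-wise group-by-time interaction t-map
#'
#' For a balanced two-group, two-occasion design the group-by-time
#' interaction of a factorial longitudinal model is equivalent to a
#' two-sample t test on per-subject change maps, which also permits exact
#' group-label permutation. Per subject the EC change over the stage's day
#' pair is computed; groups are then compared per voxel with a pooled
#' two-sample t, signed so that positive t matches the stage's direction
#' relative to the learning group (e.g. for a `decrease` contrast, voxels
#' where the learning group's centrality drops more than the control
#' group's get positive t).
#'
#' @param stack An `ec_stack` (see [stack_ec_maps()]).
#' @param groups Named character vector subject -> group (`"LRN"`/`"SMP"`).
#' @param stage A [stage_contrast()].
#' @return An object of class `tmap`: `t` (per-voxel statistic), `df`
#'   (`n_LRN + n_SMP - 2`), `mask`, `stage`, plus the per-subject change
#'   matrix and group labels needed for permutation inference.
#' @export
interaction_tmap <- function(stack, groups, stage) {
  stopifnot(inherits(stack, "ec_stack"), inherits(stage, "stage_contrast"))
  pair <- stage$day_pair
  missing_days <- setdiff(pair, names(stack$ec))
  if (length(missing_days)) {
    stop_invalid("EC stack lacks day(s): %s", paste(missing_days, collapse = ", "))
  }
  subj <- stack$subjects
  if (!all(subj %in% names(groups))) {
    stop_invalid("missing group labels for: %s",
                 paste(setdiff(subj, names(groups)), collapse = ", "))
  }
  delta <- stack$ec[[pair[2]]] - stack$ec[[pair[1]]]
  g <- groups[subj]
  if (length(unique(g)) < 2) stop_invalid("both groups must be present")
  is_lrn <- g == "LRN"
  # decrease relative to LRN: positive t when SMP change exceeds LRN change
  t <- if (stage$direction == "decrease") col_t_stat(delta, !is_lrn)
       else col_t_stat(delta, is_lrn)
  structure(list(t = t, df = length(subj) - 2L, mask = stack$mask,
                 stage = stage, delta = delta, groups = g,
                 sided = "one"),
            class = "tmap")
}

#' Baseline between-group EC comparison
#'
#' Voxelwise two-sample t test of the groups' EC maps at a single
#' (pre-training) day, with two-sided cluster inference, used to verify
#' that the groups did not differ before training.
#'
#' @param stack An `ec_stack` containing `day`.
#' @param groups Named character vector subject -> group.
#' @param day Day to compare (e.g. `"d0"` or `"d1"`).
#' @inheritParams cluster_inference
#' @return A list with `tmap` and `clusters` (see [cluster_inference()]).
#' @export
baseline_ec_test <- function(stack, groups, day, primary_p = 0.001,
                             cluster_alpha = 0.05, n_perm = 1000,
                             connectivity = 18, seed = 1) {
  stopifnot(day %in% names(stack$ec))
  g <- groups[stack$subjects]
  if (length(unique(g)) < 2) stop_invalid("both groups must be present")
  X <- stack$ec[[day]]
  tm <- structure(list(t = col_t_stat(X, g == "LRN"),
                       df = nrow(X) - 2L, mask = stack$mask,
                       stage = NULL, delta = X, groups = g,
                       sided = "two"),
                  class = "tmap")
  list(tmap = tm,
       clusters = cluster_inference(tm, primary_p = primary_p,
                                    cluster_alpha = cluster_alpha,
                                    n_perm = n_perm,
                                    connectivity = connectivity, seed = seed))
}

# Neighbor offsets for 6/18/26-connectivity.
conn_offsets <- function(connectivity) {
  stopifnot(connectivity %in% c(6, 18, 26))
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  nz <- rowSums(off != 0)
  keep <- switch(as.character(connectivity),
                 "6" = nz == 1, "18" = nz >= 1 & nz <= 2, "26" = nz >= 1)
  off[keep, , drop = FALSE]
}

# Label connected components of a 3D logical array. Returns an integer
# array (0 = background) and the number of components.
label_components <- function(mask3d, connectivity = 18) {
  d <- dim(mask3d)
  lab <- array(0L, d)
  off <- conn_offsets(connectivity)
  idx <- which(mask3d)
  if (!length(idx)) return(list(labels = lab, n = 0L))
  coords <- arrayInd(idx, d)
  lookup <- array(0L, d)
  lookup[idx] <- seq_along(idx)
  visited <- logical(length(idx))
  current <- 0L
  for (start in seq_along(idx)) {
    if (visited[start]) next
    current <- current + 1L
    queue <- start
    visited[start] <- TRUE
    while (length(queue)) {
      i <- queue[[1]]; queue <- queue[-1]
      lab[idx[i]] <- current
      nb <- sweep(off, 2, coords[i, ], "+")
      ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
            nb[, 3] >= 1 & nb[, 3] <= d[3]
      nb <- nb[ok, , drop = FALSE]
      j <- lookup[nb]
      j <- j[j > 0]
      j <- j[!visited[j]]
      if (length(j)) {
        visited[j] <- TRUE
        queue <- c(queue, j)
      }
    }
  }
  list(labels = lab, n = current)
}

# Suprathreshold cluster sizes of a statistic vector mapped into the mask.
supra_cluster_sizes <- function(stat, mask, thr, connectivity) {
  supra <- stat > thr
  if (!any(supra)) return(integer(0))
  m3 <- array(FALSE, dim(mask))
  m3[which(mask)[supra]] <- TRUE
  lab <- label_components(m3, connectivity)
  if (lab$n == 0) return(integer(0))
  tabulate(lab$labels[lab$labels > 0], lab$n)
}

#' Permutation cluster-level inference on a t-map
#'
#' Thresholds the map at the one-sided t quantile of the primary p-value
#' (two-sided for baseline maps), forms connected components under the
#' requested connectivity, and assigns each observed cluster an
#' uncorrected p-value from a group-label permutation null in which all
#' suprathreshold cluster sizes are pooled across permutations (with +1
#' smoothing). Benjamini-Hochberg FDR is then applied across the observed
#' clusters. When the number of distinct group labelings is at most
#' 10,000, the null is enumerated exactly; otherwise `n_perm` random
#' relabelings are drawn.
#'
#' @param tmap A `tmap` (see [interaction_tmap()]).
#' @param primary_p Primary voxel-level threshold (default 0.001).
#' @param cluster_alpha FDR level declaring a cluster significant
#'   (default 0.05).
#' @param n_perm Number of permutations when sampling (>= 100).
#' @param connectivity 6, 18 (default) or 26.
#' @param seed Integer seed for the permutation draw.
#' @return A data frame of class `cluster_result` with one row per
#'   observed suprathreshold cluster: `label`, `size`, `peak_t`,
#'   `peak_x/y/z` (1-based voxel indices), `p_uncorrected`, `q_fdr`,
#'   `significant`. Cluster voxel indices (into the in-mask columns) are
#'   attached as attribute `voxels`; the t threshold, permutation count
#'   and null sizes as further attributes. No suprathreshold voxels
#'   yields an empty (zero-row) result.
#' @export
cluster_inference <- function(tmap, primary_p = 0.001, cluster_alpha = 0.05,
                              n_perm = 1000, connectivity = 18, seed = 1) {
  stopifnot(inherits(tmap, "tmap"))
  if (n_perm < 100) stop_invalid("n_perm must be >= 100")
  two_sided <- identical(tmap$sided, "two")
  thr <- if (two_sided) stats::qt(1 - primary_p / 2, tmap$df)
         else stats::qt(1 - primary_p, tmap$df)
  stat <- if (two_sided) abs(tmap$t) else tmap$t
  mask <- tmap$mask
  d <- dim(mask)
  mask_idx <- which(mask)

  empty <- data.frame(label = integer(0), size = integer(0),
                      peak_t = numeric(0), peak_x = integer(0),
                      peak_y = integer(0), peak_z = integer(0),
                      p_uncorrected = numeric(0), q_fdr = numeric(0),
                      significant = logical(0))

  supra <- stat > thr
  if (!any(supra)) {
    attr(empty, "threshold") <- thr
    class(empty) <- c("cluster_result", "data.frame")
    return(empty)
  }
  m3 <- array(FALSE, d)
  m3[mask_idx[supra]] <- TRUE
  lab <- label_components(m3, connectivity)
  lab_in_mask <- lab$labels[mask_idx]

  clusters <- lapply(seq_len(lab$n), function(k) {
    vox <- which(lab_in_mask == k)
    peak <- vox[which.max(stat[vox])]
    co <- arrayInd(mask_idx[peak], d)
    list(vox = vox, size = length(vox), peak_t = tmap$t[peak], coord = co)
  })

  # permutation null of cluster sizes
  g <- tmap$groups
  is_a <- g == unique(g)[1]
  n <- length(g); n1 <- sum(is_a)
  n_distinct <- choose(n, n1)
  X <- tmap$delta
  null_sizes <- integer(0)
  perm_stat <- function(sel) {
    t <- col_t_stat(X, sel)
    if (two_sided) abs(t) else t
  }
  if (n_distinct <= 10000) {
    combs <- utils::combn(n, n1)
    for (j in seq_len(ncol(combs))) {
      sel <- rep(FALSE, n); sel[combs[, j]] <- TRUE
      null_sizes <- c(null_sizes,
                      supra_cluster_sizes(perm_stat(sel), mask, thr, connectivity))
    }
    n_perm_used <- ncol(combs)
  } else {
    with_seed(seed, {
      for (j in seq_len(n_perm)) {
        sel <- rep(FALSE, n); sel[sample.int(n, n1)] <- TRUE
        null_sizes <- c(null_sizes,
                        supra_cluster_sizes(perm_stat(sel), mask, thr,
                                            connectivity))
      }
    })
    n_perm_used <- n_perm
  }

  sizes <- vapply(clusters, function(cl) cl$size, 0L)
  p_unc <- vapply(sizes, function(K) {
    (1 + sum(null_sizes >= K)) / (1 + length(null_sizes))
  }, 0)
  q <- stats::p.adjust(p_unc, method = "BH")

  res <- data.frame(
    label = seq_along(clusters),
    size = sizes,
    peak_t = vapply(clusters, function(cl) cl$peak_t, 0),
    peak_x = vapply(clusters, function(cl) cl$coord[1], 0L),
    peak_y = vapply(clusters, function(cl) cl$coord[2], 0L),
    peak_z = vapply(clusters, function(cl) cl$coord[3], 0L),
    p_uncorrected = p_unc,
    q_fdr = q,
    significant = q < cluster_alpha
  )
  ord <- order(-res$size)
  res <- res[ord, , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "voxels") <- lapply(clusters[ord], function(cl) cl$vox)
  attr(res, "threshold") <- thr
  attr(res, "n_perm") <- n_perm_used
  attr(res, "null_sizes") <- null_sizes
  class(res) <- c("cluster_result", "data.frame")
  res
}

#' Per-group centrality trajectory within a region of interest
#'
#' Computes, per subject, the mean EC within the cluster for every day,
#' then per group the mean, standard error and t-based 95% confidence
#' interval of the per-day values and of the stage's EC change. Used to
#' determine which group drives an interaction effect.
#'
#' @param stack An `ec_stack`.
#' @param voxels Cluster voxel indices into the in-mask columns (e.g. from
#'   `attr(clusters, "voxels")[[1]]`), or a 3D logical ROI mask.
#' @param groups Named character vector subject -> group.
#' @param stage Optional [stage_contrast()]; when given, the stage's
#'   per-subject change is summarized too.
#' @param conf_level Confidence level (default 0.95).
#' @return An object of class `group_trajectory`: data frames `per_day`
#'   and (when `stage` is given) `delta`, each with group, n, mean, sem,
#'   ci_lo, ci_hi. Single-subject groups get `NA` SEM/CI and a flag.
#' @export
roi_trajectory <- function(stack, voxels, groups, stage = NULL,
                           conf_level = 0.95) {
  stopifnot(inherits(stack, "ec_stack"))
  if (is.array(voxels)) {
    if (!identical(dim(voxels), dim(stack$mask))) {
      stop_invalid("ROI mask grid does not match the EC stack")
    }
    if (any(voxels & !stack$mask)) stop_invalid("ROI extends outside the analysis mask")
    voxels <- match(which(voxels), which(stack$mask))
  }
  if (!length(voxels)) stop_invalid("empty ROI")
  g <- groups[stack$subjects]

  summarize <- function(x, grp) {
    out <- lapply(sort(unique(grp)), function(gg) {
      v <- x[grp == gg]
      n <- length(v)
      m <- mean(v)
      if (n < 2) {
        data.frame(group = gg, n = n, mean = m, sem = NA_real_,
                   ci_lo = NA_real_, ci_hi = NA_real_, degenerate_n = TRUE)
      } else {
        sem <- stats::sd(v) / sqrt(n)
        tq <- stats::qt(1 - (1 - conf_level) / 2, n - 1)
        data.frame(group = gg, n = n, mean = m, sem = sem,
                   ci_lo = m - tq * sem, ci_hi = m + tq * sem,
                   degenerate_n = FALSE)
      }
    })
    do.call(rbind, out)
  }

  roi_mean <- vapply(stack$ec, function(M) {
    rowMeans(M[, voxels, drop = FALSE])
  }, numeric(length(stack$subjects)))
  # roi_mean: subjects x days

  per_day <- do.call(rbind, lapply(colnames(roi_mean), function(d) {
    cbind(day = d, summarize(roi_mean[, d], g))
  }))

  delta <- NULL
  if (!is.null(stage)) {
    ch <- roi_mean[, stage$day_pair[2]] - roi_mean[, stage$day_pair[1]]
    delta <- summarize(ch, g)
    delta$day_from <- stage$day_pair[1]
    delta$day_to <- stage$day_pair[2]
  }
  structure(list(per_day = per_day, delta = delta, n_voxels = length(voxels),
                 conf_level = conf_level),
            class = "group_trajectory")
}

#' Classify an interaction effect as sequence-specific or not
#'
#' Implements the formalized specificity criterion: among the groups whose
#' confidence interval for the stage's EC change excludes zero, the group
#' with the larger absolute mean change is the driving group (none when
#' neither CI excludes zero; when both do, the larger absolute mean wins
#' and the tie is recorded). The effect is sequence-specific exactly when
#' the learning group drives it and the control group shows little to no
#' change (its CI contains zero).
#'
#' @param x A `group_trajectory` with a `delta` table, or a data frame
#'   with columns `group`, `mean`, `ci_lo`, `ci_hi` (one row per group) —
#'   e.g. published summary statistics.
#' @param stage Optional [stage_contrast()] recorded in the verdict.
#' @return An object of class `specificity_verdict`: `driving_group`
#'   (`"LRN"`, `"SMP"`, `"none"` or the winning group with a recorded
#'   tie), `sequence_specific`, and `rationale` (the comparisons made).
#' @export
classify_specificity <- function(x, stage = NULL) {
  df <- if (inherits(x, "group_trajectory")) {
    if (is.null(x$delta)) stop_invalid("trajectory lacks a stage change summary")
    x$delta
  } else {
    as.data.frame(x)
  }
  need <- c("group", "mean", "ci_lo", "ci_hi")
  if (!all(need %in% names(df))) {
    stop_invalid("need columns: %s", paste(need, collapse = ", "))
  }
  for (grp in c("LRN", "SMP")) {
    if (!grp %in% df$group) stop_invalid("missing group '%s'", grp)
  }
  df <- df[match(c("LRN", "SMP"), df$group), , drop = FALSE]
  excludes0 <- df$ci_lo > 0 | df$ci_hi < 0
  tie <- FALSE
  if (!any(excludes0)) {
    driving <- "none"
  } else if (sum(excludes0) == 1) {
    driving <- df$group[excludes0]
  } else {
    tie <- TRUE
    driving <- df$group[which.max(abs(df$mean))]
  }
  smp_flat <- !excludes0[df$group == "SMP"]
  specific <- identical(driving, "LRN") && smp_flat
  rationale <- sprintf(
    "LRN change %.4g [%.4g, %.4g] (%s 0); SMP change %.4g [%.4g, %.4g] (%s 0)%s",
    df$mean[1], df$ci_lo[1], df$ci_hi[1],
    if (excludes0[1]) "excludes" else "contains",
    df$mean[2], df$ci_lo[2], df$ci_hi[2],
    if (excludes0[2]) "excludes" else "contains",
    if (tie) "; both exclude 0, larger |mean| wins" else "")
  structure(list(driving_group = driving, sequence_specific = specific,
                 both_excluded = tie, rationale = rationale,
                 stage = stage, comparisons = df),
            class = "specificity_verdict")
}

#' @export
print.specificity_verdict <- function(x, ...) {
  cat(sprintf("<specificity_verdict> driving = %s, sequence_specific = %s\n  %s\n",
              x$driving_group, x$sequence_specific, x$rationale))
  invisible(x)
}

#' Run all directional interaction contrasts on an EC stack
#'
#' Convenience wrapper: for every stage contrast whose day pair is present
#' in the stack, computes the interaction t-map, permutation cluster
#' inference, and, for each significant cluster, the ROI trajectory and
#' specificity verdict.
#'
#' @inheritParams interaction_tmap
#' @inheritParams cluster_inference
#' @param stages List of [stage_contrast()]s (default all eight).
#' @return Named list (per contrast) of lists with `stage`, `tmap`,
#'   `clusters`, `rois` (per significant cluster: `voxels`, `trajectory`,
#'   `verdict`).
#' @export
run_interaction_analyses <- function(stack, groups,
                                     stages = all_stage_contrasts(),
                                     primary_p = 0.001, cluster_alpha = 0.05,
                                     n_perm = 1000, connectivity = 18,
                                     seed = 1) {
  out <- list()
  for (nm in names(stages)) {
    st <- stages[[nm]]
    if (!all(st$day_pair %in% names(stack$ec))) next
    tm <- interaction_tmap(stack, groups, st)
    cl <- cluster_inference(tm, primary_p = primary_p,
                            cluster_alpha = cluster_alpha, n_perm = n_perm,
                            connectivity = connectivity,
                            seed = child_seed(seed, match(nm, names(stages))))
    rois <- list()
    vox_list <- attr(cl, "voxels")
    sig <- which(cl$significant)
    for (k in sig) {
      traj <- roi_trajectory(stack, vox_list[[k]], groups, stage = st)
      rois[[as.character(cl$label[k])]] <-
        list(voxels = vox_list[[k]], trajectory = traj,
             verdict = classify_specificity(traj, st))
    }
    out[[nm]] <- list(stage = st, tmap = tm, clusters = cl, rois = rois)
  }
  out
}

#' Summary tables for a set of interaction analyses
#'
#' Produces a cluster table (one row per suprathreshold cluster: contrast,
#' FDR-corrected p, size, peak t, peak voxel indices) and a per-group
#' change-summary table for significant clusters (mean, SEM, 95% CI,
#' driving group, specificity flag), optionally written as TSV and JSON.
#' Peak coordinates are 1-based voxel indices (stated in the TSV header
#' comment); phantoms share a grid by construction, so no template
#' registration is involved.
#'
#' @param results Output of [run_interaction_analyses()].
#' @param dir Optional output directory for `clusters.tsv`,
#'   `group_changes.tsv` and `report.json`.
#' @return A list with data frames `clusters` and `group_changes` (both
#'   possibly zero-row).
#' @export
stage_report <- function(results, dir = NULL) {
  cl_rows <- list(); gc_rows <- list()
  for (nm in names(results)) {
    res <- results[[nm]]
    cl <- res$clusters
    if (nrow(cl)) {
      cl_rows[[nm]] <- cbind(contrast = nm,
                             stage = res$stage$name,
                             direction = res$stage$direction,
                             as.data.frame(cl))
    }
    for (lab in names(res$rois)) {
      roi <- res$rois[[lab]]
      dd <- roi$trajectory$delta
      gc_rows[[paste(nm, lab)]] <- data.frame(
        contrast = nm, cluster = as.integer(lab), group = dd$group,
        n = dd$n, mean = dd$mean, sem = dd$sem,
        ci_lo = dd$ci_lo, ci_hi = dd$ci_hi,
        driving_group = roi$verdict$driving_group,
        sequence_specific = roi$verdict$sequence_specific)
    }
  }
  clusters <- if (length(cl_rows)) do.call(rbind, cl_rows) else
    data.frame(contrast = character(0), stage = character(0),
               direction = character(0), label = integer(0),
               size = integer(0), peak_t = numeric(0), peak_x = integer(0),
               peak_y = integer(0), peak_z = integer(0),
               p_uncorrected = numeric(0), q_fdr = numeric(0),
               significant = logical(0))
  rownames(clusters) <- NULL
  group_changes <- if (length(gc_rows)) do.call(rbind, gc_rows) else
    data.frame(contrast = character(0), cluster = integer(0),
               group = character(0), n = integer(0), mean = numeric(0),
               sem = numeric(0), ci_lo = numeric(0), ci_hi = numeric(0),
               driving_group = character(0), sequence_specific = logical(0))
  rownames(group_changes) <- NULL

  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv_commented <- function(df, path, comment) {
      con <- file(path, "w")
      writeLines(paste0("# ", comment), con)
      utils::write.table(df, con, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      close(con)
    }
    write_tsv_commented(clusters, file.path(dir, "clusters.tsv"),
                        "peak coordinates are 1-based voxel indices")
    write_tsv_commented(group_changes, file.path(dir, "group_changes.tsv"),
                        "per-group EC change within significant clusters")
    jsonlite::write_json(list(clusters = clusters,
                              group_changes = group_changes),
                         file.path(dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
  }
  list(clusters = clusters, group_changes = group_changes)
}
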