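#' Temporal synchronization (SYN) of a tracking trial
#'
#' Computes the Pearson-normalized cross-correlation between the reference
#' (REF) and participant (FOR) force traces at every integer sample lag in
#' `[-max_lag_s, +max_lag_s]`, and returns the lag maximizing the
#' correlation, in milliseconds. A score of 0 denotes perfectly synchronized
#' performance; positive values mean the participant lags behind the
#' reference. Ties are broken toward the smaller absolute lag, then toward
#' the positive lag.
#'
#' @param ref,force [force_trace()] objects with equal length and sampling
#'   rate.
#' @param max_lag_s Half-width of the lag search window in seconds (must be
#'   less than half the trial duration).
#' @return A list with `syn_ms` (signed lag in ms), `peak_corr` (correlation
#'   at that lag) and `lag_samples`.
#' @export
compute_syn <- function(ref, force, max_lag_s = 3) {
  stopifnot(inherits(ref, "force_trace"), inherits(force, "force_trace"))
  if (length(ref$samples) != length(force$samples) || ref$fs != force$fs) {
    stop_invalid("ref and force must share length and sampling rate")
  }
  if (max_lag_s >= ref$duration / 2) {
    stop_invalid("max_lag_s must be less than half the trial duration")
  }
  if (stats::sd(ref$samples) == 0 || stats::sd(force$samples) == 0) {
    degenerate_trial("zero-variance trace; SYN undefined")
  }
  L <- floor(max_lag_s * ref$fs)
  lags <- -L:L
  r <- vapply(lags, function(k) lagged_cor(ref$samples, force$samples, k), 0)
  r[!is.finite(r)] <- -Inf
  best <- max(r)
  cand <- which(r >= best - 1e-12)
  cand <- cand[order(abs(lags[cand]), -sign(lags[cand]))]
  k <- lags[cand[1L]]
  list(syn_ms = k * 1000 / ref$fs, peak_corr = r[cand[1L]], lag_samples = k)
}

# Pearson correlation between ref and force at lag k (positive k = force
# delayed, i.e. force[i + k] aligned with ref[i]), over the overlap.
lagged_cor <- function(ref, force, k) {
  n <- length(ref)
  if (k >= 0) {
    a <- ref[seq_len(n - k)]
    b <- force[seq_len(n - k) + k]
  } else {
    a <- ref[seq_len(n + k) - k]
    b <- force[seq_len(n + k)]
  }
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  stats::cor(a, b)
}

#' Lag-aligned root mean squared error (RMSE)
#'
#' Shifts the participant trace by the previously estimated lag so that the
#' two traces are temporally aligned, then computes the root mean squared
#' force deviation over the overlapping support only. RMSE captures spatial
#' (force-level) accuracy once timing differences are removed.
#'
#' @param ref,force [force_trace()] objects with equal length and sampling
#'   rate.
#' @param syn_ms The trial's SYN estimate in milliseconds (see
#'   [compute_syn()]).
#' @return RMSE in force units (% max force).
#' @export
compute_rmse <- function(ref, force, syn_ms) {
  stopifnot(inherits(ref, "force_trace"), inherits(force, "force_trace"))
  if (length(ref$samples) != length(force$samples) || ref$fs != force$fs) {
    stop_invalid("ref and force must share length and sampling rate")
  }
  n <- length(ref$samples)
  k <- round(syn_ms / 1000 * ref$fs)
  if (n - abs(k) < 0.5 * n) {
    degenerate_trial("lag-aligned overlap shorter than 50% of the trial")
  }
  if (k >= 0) {
    a <- ref$samples[seq_len(n - k)]
    b <- force$samples[seq_len(n - k) + k]
  } else {
    a <- ref$samples[seq_len(n + k) - k]
    b <- force$samples[seq_len(n + k)]
  }
  sqrt(mean((a - b)^2))
}

degenerate_trial <- function(msg) {
  stop(structure(
    class = c("degenerate_trial", "error", "condition"),
    list(message = msg, call = NULL)
  ))
}

#' Score a behavioural cohort
#'
#' Computes per-trial SYN and lag-aligned RMSE for every scored (non-rest)
#' trial of a cohort, plus per-block and per-day means by subject and
#' condition. Degenerate trials (zero variance, insufficient alignment
#' overlap) are flagged and excluded from the means. Trials are matched to
#' their reference sequence through the `condition` column.
#'
#' @param cohort A cohort as returned by [gen_behaviour_cohort()], or a list
#'   with fields `table` (metadata data frame with columns subject, group,
#'   day, block, trial, condition, trace_id), `traces` (named list of
#'   numeric force vectors) and `refs` (named list of [force_trace()]
#'   reference sequences per condition).
#' @param max_lag_s Lag search window for [compute_syn()].
#' @return An object of class `cohort_scores` with data frames `trials`,
#'   `block_means` and `day_means`.
#' @export
score_cohort <- function(cohort, max_lag_s = 3) {
  stopifnot(is.list(cohort), !is.null(cohort$table), !is.null(cohort$refs))
  md <- cohort$table
  scored <- md[md$condition %in% names(cohort$refs), , drop = FALSE]

  syn <- rmse <- pk <- rep(NA_real_, nrow(scored))
  degen <- rep(FALSE, nrow(scored))
  for (i in seq_len(nrow(scored))) {
    id <- scored$trace_id[i]
    tr <- cohort$traces[[id]]
    if (is.null(tr)) {
      stop_invalid("missing trace '%s' (subject %s, day %s, block %d, trial %d)",
                   id, scored$subject[i], scored$day[i],
                   scored$block[i], scored$trial[i])
    }
    ref <- cohort$refs[[scored$condition[i]]]
    force <- if (inherits(tr, "force_trace")) tr else force_trace(tr, ref$fs)
    res <- tryCatch({
      s <- compute_syn(ref, force, max_lag_s)
      list(syn = s$syn_ms, pk = s$peak_corr,
           rmse = compute_rmse(ref, force, s$syn_ms))
    }, degenerate_trial = function(e) NULL)
    if (is.null(res)) {
      degen[i] <- TRUE
    } else {
      syn[i] <- res$syn; pk[i] <- res$pk; rmse[i] <- res$rmse
    }
  }
  trials <- cbind(scored,
                  data.frame(syn_ms = syn, rmse = rmse, peak_corr = pk,
                             degenerate = degen, excluded = FALSE))
  ok <- trials[!trials$degenerate, , drop = FALSE]

  block_means <- stats::aggregate(
    cbind(syn_ms, rmse) ~ subject + group + day + condition + block,
    data = ok, FUN = mean)
  day_means <- stats::aggregate(
    cbind(syn_ms, rmse) ~ subject + group + day + condition,
    data = ok, FUN = mean)
  day_means$excluded <- FALSE

  structure(list(trials = trials, block_means = block_means,
                 day_means = day_means),
            class = "cohort_scores")
}

#' @export
print.cohort_scores <- function(x, ...) {
  cat(sprintf("<cohort_scores> %d scored trials (%d degenerate), %d subjects\n",
              nrow(x$trials), sum(x$trials$degenerate),
              length(unique(x$trials$subject))))
  invisible(x)
}

#' Flag behavioural outlier subjects
#'
#' A subject is excluded when, for either metric (SYN or RMSE), their
#' per-day mean deviates from the corresponding group mean by more than
#' `k_sd` group standard deviations on at least `min_days` distinct days.
#' Deviations are assessed within each (group, condition, day) cell so the
#' learning and control sequences are judged against their own references.
#' Flagged rows are retained but marked.
#'
#' @param scores A `cohort_scores` object (see [score_cohort()]).
#' @param k_sd Deviation threshold in group standard deviations.
#' @param min_days Minimum number of offending days for exclusion.
#' @return A list with `scores` (flags set in `day_means` and `trials`) and
#'   `excluded_subjects` (character vector).
#' @export
exclude_outliers <- function(scores, k_sd = 2, min_days = 2) {
  stopifnot(inherits(scores, "cohort_scores"))
  dm <- scores$day_means
  n_per_group <- tapply(dm$subject, dm$group, function(s) length(unique(s)))
  if (any(n_per_group < 3)) {
    stop_invalid("outlier detection requires at least 3 subjects per group")
  }

  offending <- list()
  for (metric in c("syn_ms", "rmse")) {
    cells <- split(dm, interaction(dm$group, dm$condition, dm$day, drop = TRUE))
    days_hit <- lapply(cells, function(cell) {
      mu <- mean(cell[[metric]])
      sdev <- stats::sd(cell[[metric]])
      if (!is.finite(sdev) || sdev == 0) return(NULL)
      hit <- abs(cell[[metric]] - mu) > k_sd * sdev
      if (!any(hit)) return(NULL)
      data.frame(subject = cell$subject[hit], day = cell$day[hit])
    })
    hits <- do.call(rbind, days_hit)
    if (!is.null(hits) && nrow(hits)) {
      per_subj <- tapply(hits$day, hits$subject,
                         function(d) length(unique(d)))
      offending[[metric]] <- names(per_subj)[per_subj >= min_days]
    }
  }
  excluded <- sort(unique(unlist(offending)))

  scores$day_means$excluded <- scores$day_means$subject %in% excluded
  scores$trials$excluded <- scores$trials$subject %in% excluded
  list(scores = scores, excluded_subjects = excluded)
}
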