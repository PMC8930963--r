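#' Default lag-learning schedule for the synthetic behavioural cohort
#'
#' Maps each (group, condition, day) cell to the mean planted lag (ms), its
#' between-trial standard deviation, and the force noise level. The defaults
#' emulate the characteristic behavioural pattern of sequence-specific
#' learning: the learning group's lag on the complex sequence decreases
#' steeply from day 1 to day 3 and then plateaus, while performance on the
#' simple sinusoidal sequence is near-flat in both groups.
#'
#' @param days Character vector of training days.
#' @return Data frame with columns group, condition, day, mean_lag_ms,
#'   lag_sd_ms, noise_sd.
#' @export
default_behaviour_schedule <- function(days = c("d1", "d2", "d3", "d4", "d5", "d17")) {
  lrn_lag <- c(d1 = 150, d2 = 90, d3 = 60, d4 = 60, d5 = 60, d17 = 65)
  lrn_smp_lag <- c(d1 = 60, d2 = 50, d3 = 45, d4 = 45, d5 = 45, d17 = 45)
  smp_lag <- c(d1 = 40, d2 = 40, d3 = 40, d4 = 40, d5 = 40, d17 = 40)
  rows <- rbind(
    data.frame(group = "LRN", condition = "LRN", day = days,
               mean_lag_ms = unname(lrn_lag[days])),
    data.frame(group = "LRN", condition = "SMP", day = days,
               mean_lag_ms = unname(lrn_smp_lag[days])),
    data.frame(group = "SMP", condition = "SMP", day = days,
               mean_lag_ms = unname(smp_lag[days]))
  )
  rows$lag_sd_ms <- 25
  rows$noise_sd <- 1.5
  rows
}

#' Generate a synthetic behavioural cohort
#'
#' Simulates the trial structure of the sequential pinch force task for a
#' two-group longitudinal design. On each day every subject performs 3
#' blocks; in the learning (LRN) group each block holds 3 simple (SMP), 3
#' rest (RST) and 3 complex (LRN) trials, while the control (SMP) group
#' replaces the complex trials with further simple trials — 9 scored trials
#' per condition per day, with total motor effort matched across groups.
#' Rest trials carry no force traces. Every scored trial's response is
#' generated by [gen_for_response()] with a lag drawn from the schedule, and
#' the planted lag is recorded in the ground truth.
#'
#' @param n_per_group Subjects per group.
#' @param schedule Data frame as from [default_behaviour_schedule()].
#' @param seed Integer seed; the cohort is a pure function of its arguments.
#' @param days Days to simulate (subset of the schedule's days).
#' @param refs Optional list with `LRN` and `SMP` reference
#'   [force_trace()]s; generated from `seed` when omitted.
#' @return A list of class `behaviour_cohort` with fields `table` (long
#'   metadata, one row per trial including rest trials), `traces` (named
#'   list of response [force_trace()]s), `refs`, and `ground_truth` (data
#'   frame of planted lags plus the group assignment).
#' @export
gen_behaviour_cohort <- function(n_per_group = 20,
                                 schedule = default_behaviour_schedule(),
                                 seed = 1,
                                 days = unique(schedule$day),
                                 refs = NULL) {
  stopifnot(n_per_group >= 1)
  days <- as.character(days)
  if (!all(days %in% c("d1", "d2", "d3", "d4", "d5", "d17"))) {
    stop_invalid("days must lie in d1..d5, d17")
  }
  needed <- rbind(
    expand.grid(group = "LRN", condition = c("LRN", "SMP"), day = days,
                stringsAsFactors = FALSE),
    expand.grid(group = "SMP", condition = "SMP", day = days,
                stringsAsFactors = FALSE)
  )
  key <- function(df) paste(df$group, df$condition, df$day)
  missing <- setdiff(key(needed), key(schedule))
  if (length(missing)) {
    stop_invalid("schedule is missing cells: %s",
                 paste(missing, collapse = "; "))
  }
  sched <- schedule
  rownames(sched) <- key(sched)

  if (is.null(refs)) {
    lrn <- gen_ref_lrn(seed = child_seed(seed, 1))
    refs <- list(LRN = lrn, SMP = gen_ref_smp(lrn)$smp_ref)
  }

  subjects <- sprintf("sub%02d", seq_len(2 * n_per_group))
  groups <- rep(c("LRN", "SMP"), each = n_per_group)
  names(groups) <- subjects

  rows <- list(); truths <- list(); traces <- list()
  idx <- 0L
  for (s in seq_along(subjects)) {
    subj <- subjects[s]; grp <- groups[s]
    for (day in days) {
      for (block in 1:3) {
        conds <- if (grp == "LRN") c(rep("SMP", 3), rep("RST", 3), rep("LRN", 3))
                 else c(rep("SMP", 3), rep("RST", 3), rep("SMP", 3))
        for (j in seq_along(conds)) {
          cond <- conds[j]
          idx <- idx + 1L
          trial <- ((j - 1L) %% 3L) + 1L
          if (cond == "RST") {
            rows[[idx]] <- data.frame(
              subject = subj, group = grp, day = day, block = block,
              trial = trial, condition = cond, trace_id = NA_character_)
            next
          }
          cell <- sched[paste(grp, cond, day), ]
          sd_i <- child_seed(seed, idx + 1000)
          lag <- with_seed(sd_i, stats::rnorm(1, cell$mean_lag_ms, cell$lag_sd_ms))
          id <- sprintf("%s_%s_b%d_t%d_%s_%d", subj, day, block, trial, cond, j)
          traces[[id]] <- gen_for_response(refs[[cond]], lag, cell$noise_sd,
                                           seed = child_seed(seed, idx + 2000))
          rows[[idx]] <- data.frame(
            subject = subj, group = grp, day = day, block = block,
            trial = trial, condition = cond, trace_id = id)
          truths[[length(truths) + 1L]] <- data.frame(
            subject = subj, group = grp, day = day, block = block,
            trial = trial, condition = cond, trace_id = id,
            planted_lag_ms = lag, planted_noise_sd = cell$noise_sd)
        }
      }
    }
  }
  structure(
    list(table = do.call(rbind, rows),
         traces = traces,
         refs = refs,
         ground_truth = list(planted = do.call(rbind, truths),
                             group_assignment = groups)),
    class = "behaviour_cohort"
  )
}

#' @export
print.behaviour_cohort <- function(x, ...) {
  cat(sprintf("<behaviour_cohort> %d subjects, %d trial rows (%d scored)\n",
              length(x$ground_truth$group_assignment), nrow(x$table),
              sum(x$table$condition != "RST")))
  invisible(x)
}

#' Write a behavioural cohort to disk
#'
#' Traces are written one TSV per trial (columns `time_s`, `ref`, `force`)
#' and the metadata as a single long-format TSV with a `trace_path` column.
#'
#' @param cohort A `behaviour_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the path to the metadata TSV.
#' @export
write_behaviour_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "traces"), recursive = TRUE, showWarnings = FALSE)
  md <- cohort$table
  md$trace_path <- NA_character_
  for (i in seq_len(nrow(md))) {
    id <- md$trace_id[i]
    if (is.na(id)) next
    ref <- cohort$refs[[md$condition[i]]]
    tr <- cohort$traces[[id]]
    path <- file.path("traces", paste0(id, ".tsv"))
    df <- data.frame(
      time_s = (seq_along(tr$samples) - 1) / tr$fs,
      ref = ref$samples, force = tr$samples)
    utils::write.table(df, file.path(dir, path), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    md$trace_path[i] <- path
  }
  out <- file.path(dir, "cohort.tsv")
  utils::write.table(md, out, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}

#' Read a behavioural cohort written by [write_behaviour_cohort()]
#'
#' @param path Path to the metadata TSV.
#' @param fs Sampling rate of the stored traces (Hz).
#' @return A `behaviour_cohort`-compatible list (reference traces are
#'   recovered from the stored `ref` columns).
#' @export
read_behaviour_cohort <- function(path, fs = 80) {
  md <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  base <- dirname(path)
  traces <- list(); refs <- list()
  for (i in seq_len(nrow(md))) {
    if (is.na(md$trace_path[i])) next
    df <- utils::read.table(file.path(base, md$trace_path[i]), sep = "\t",
                            header = TRUE)
    traces[[md$trace_id[i]]] <- force_trace(df$force, fs)
    cond <- md$condition[i]
    if (is.null(refs[[cond]])) refs[[cond]] <- force_trace(df$ref, fs)
  }
  structure(list(table = md, traces = traces, refs = refs),
            class = "behaviour_cohort")
}
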