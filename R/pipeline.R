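#' Pipeline configuration
#'
#' Assembles all tunables of the end-to-end analysis with defaults anchored
#' to the published processing choices: 5 initial volumes dropped, 0.01-0.1
#' Hz band-pass, 2.4 mm FWHM smoothing, voxel-level primary threshold
#' p < 0.001 and cluster-level FDR at 0.05. Configurations round-trip
#' through YAML unchanged.
#'
#' @param seed Master seed; all pipeline randomness derives from it.
#' @param phantom List of phantom parameters passed to
#'   [gen_bold_cohort()].
#' @param behaviour List of behavioural-cohort parameters.
#' @param cleaning List: `n_drop`, `band`, `fwhm_mm`, `n_compcor`.
#' @param ecm List: `tol`, `max_iter`, `similarity`.
#' @param inference List: `primary_p`, `cluster_alpha`, `n_perm`,
#'   `connectivity`.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1,
                            phantom = list(grid_shape = c(16, 16, 16),
                                           n_per_group = 6,
                                           days = c("d1", "d2", "d5", "d17"),
                                           n_volumes = 120, tr = 1.13),
                            behaviour = list(n_per_group = 6,
                                             days = c("d1", "d2", "d3", "d4",
                                                      "d5", "d17")),
                            cleaning = list(n_drop = 5, band = c(0.01, 0.1),
                                            fwhm_mm = 2.4, n_compcor = 5),
                            ecm = list(tol = 1e-9, max_iter = 1000,
                                       similarity = "add1half"),
                            inference = list(primary_p = 0.001,
                                             cluster_alpha = 0.05,
                                             n_perm = 200,
                                             connectivity = 18)) {
  structure(list(seed = seed, phantom = phantom, behaviour = behaviour,
                 cleaning = cleaning, ecm = ecm, inference = inference),
            class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @param config A `pipeline_config`.
#' @return `read_pipeline_config()` returns a `pipeline_config`;
#'   `write_pipeline_config()` returns `path` invisibly.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- pipeline_config()
  for (nm in names(raw)) {
    if (is.list(cfg[[nm]]) && is.list(raw[[nm]])) {
      for (k in names(raw[[nm]])) cfg[[nm]][[k]] <- raw[[nm]][[k]]
    } else {
      cfg[[nm]] <- raw[[nm]]
    }
  }
  cfg
}

#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the full synthetic-data analysis pipeline
#'
#' Simulates a behavioural cohort and a BOLD phantom cohort, scores and
#' analyses the behaviour, cleans every BOLD session (confound regression
#' with motion and spike regressors, detrend, variance-normalize,
#' band-pass, Gaussian smoothing), computes EC maps, runs all applicable
#' directional interaction contrasts plus baseline group comparisons, and
#' writes a consolidated report. Every step appends one record (name,
#' parameters, outputs with MD5 digests, wall time) to `run_log.json`.
#'
#' @param config A `pipeline_config` (or path to a YAML one).
#' @param out_dir Output directory.
#' @return Invisibly, a list with the behavioural statistics, the
#'   interaction report tables and the run log.
#' @export
run_full_pipeline <- function(config = pipeline_config(), out_dir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- list()
  step <- function(name, params, code) {
    t0 <- proc.time()[["elapsed"]]
    res <- code
    log[[length(log) + 1L]] <<- list(
      step = name, params = params,
      outputs = if (is.character(res$files %||% character(0))) {
        lapply(res$files, function(f)
          list(path = f, md5 = unname(tools::md5sum(f))))
      } else list(),
      wall_s = round(proc.time()[["elapsed"]] - t0, 3))
    res$value
  }

  # --- behaviour ---
  beh <- step("simulate_behaviour", config$behaviour, {
    cohort <- do.call(gen_behaviour_cohort,
                      c(config$behaviour, list(seed = child_seed(config$seed, 1))))
    list(value = cohort)
  })
  scores <- step("score_behaviour", list(), list(value = score_cohort(beh)))
  excl <- exclude_outliers(scores)
  beh_stats <- step("behaviour_statistics", list(), {
    stats <- list(
      baseline = baseline_ttest(excl$scores),
      anova_syn = as.data.frame(rm_anova(excl$scores, "syn_ms")),
      anova_rmse = as.data.frame(rm_anova(excl$scores, "rmse")),
      tukey_syn = tukey_consecutive(excl$scores, "syn_ms"),
      excluded_subjects = excl$excluded_subjects)
    f <- file.path(out_dir, "behaviour_stats.json")
    jsonlite::write_json(stats, f, auto_unbox = TRUE, digits = NA, na = "null")
    list(value = stats, files = f)
  })

  # --- imaging ---
  ph <- step("simulate_bold", config$phantom, {
    cohort <- do.call(gen_bold_cohort,
                      c(config$phantom, list(seed = child_seed(config$seed, 2))))
    list(value = cohort)
  })
  maps <- step("preprocess_and_ecm",
               c(config$cleaning, config$ecm), {
    maps <- list()
    for (subj in names(ph$datasets)) {
      maps[[subj]] <- list()
      for (day in names(ph$datasets[[subj]])) {
        b <- drop_initial_volumes(ph$datasets[[subj]][[day]],
                                  config$cleaning$n_drop)
        gs <- rowMeans(mask_matrix(b$data, b$brain_mask))
        spikes <- detect_spikes(b$motion, gs)
        physio <- list(high_variance_confounds(b, b$wm_mask,
                                               config$cleaning$n_compcor),
                       high_variance_confounds(b, b$csf_mask,
                                               config$cleaning$n_compcor))
        conf <- build_confounds(b, spikes, physio)
        cl <- clean_timeseries(b, conf, band = config$cleaning$band)
        cl <- smooth_gaussian(cl, config$cleaning$fwhm_mm)
        maps[[subj]][[day]] <- fast_ecm(cl, tol = config$ecm$tol,
                                        max_iter = config$ecm$max_iter,
                                        similarity = config$ecm$similarity)
      }
    }
    list(value = maps)
  })
  stack <- stack_ec_maps(maps)

  inter <- step("interaction_analyses", config$inference, {
    res <- run_interaction_analyses(
      stack, ph$groups, primary_p = config$inference$primary_p,
      cluster_alpha = config$inference$cluster_alpha,
      n_perm = config$inference$n_perm,
      connectivity = config$inference$connectivity,
      seed = child_seed(config$seed, 3))
    rep <- stage_report(res, file.path(out_dir, "interaction"))
    list(value = list(results = res, report = rep),
         files = file.path(out_dir, "interaction",
                           c("clusters.tsv", "group_changes.tsv",
                             "report.json")))
  })

  baseline_day <- intersect(c("d0", "d1"), names(stack$ec))
  baseline <- if (length(baseline_day)) {
    step("baseline_ec_test", list(day = baseline_day[1]), {
      bt <- baseline_ec_test(stack, ph$groups, baseline_day[1],
                             primary_p = config$inference$primary_p,
                             n_perm = config$inference$n_perm,
                             connectivity = config$inference$connectivity,
                             seed = child_seed(config$seed, 4))
      list(value = bt)
    })
  }

  logf <- file.path(out_dir, "run_log.json")
  jsonlite::write_json(log, logf, auto_unbox = TRUE, digits = NA)
  cfgf <- file.path(out_dir, "config.yaml")
  write_pipeline_config(config, cfgf)

  invisible(list(behaviour = beh_stats,
                 interaction = inter$report,
                 baseline = baseline,
                 run_log = log,
                 out_dir = out_dir))
}
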