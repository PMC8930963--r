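# Shared fixtures and independent oracles for the test suite.

# Brute-force lag scan: plain loop over every integer lag, Pearson
# correlation on the overlap. Independent of the package's scorer.
oracle_best_lag <- function(ref, force, fs, max_lag_s) {
  L <- floor(max_lag_s * fs)
  best <- c(lag = NA, r = -Inf)
  n <- length(ref)
  for (k in -L:L) {
    if (k >= 0) {
      a <- ref[1:(n - k)]; b <- force[(1 + k):n]
    } else {
      a <- ref[(1 - k):n]; b <- force[1:(n + k)]
    }
    r <- suppressWarnings(stats::cor(a, b))
    if (is.finite(r) &&
        (r > best["r"] + 1e-12 ||
         (abs(r - best["r"]) <= 1e-12 &&
          (abs(k) < abs(best["lag"]) ||
           (abs(k) == abs(best["lag"]) && k > best["lag"]))))) {
      best <- c(lag = k, r = r)
    }
  }
  best
}

# Small region-structured timecourse matrix (t x V) for ECM tests.
correlated_voxels <- function(n_voxels, n_time, seed, n_latent = 4,
                              noise_sd = 0.8) {
  set.seed(seed)
  L <- matrix(rnorm(n_time * n_latent), n_time, n_latent)
  W <- matrix(runif(n_latent * n_voxels), n_latent, n_voxels)
  L %*% W + matrix(rnorm(n_time * n_voxels, 0, noise_sd), n_time, n_voxels)
}

# Synthetic per-day behavioural means table wrapped as cohort_scores,
# bypassing trace generation (for the statistics tests).
synthetic_day_means <- function(n_per_cell = 8, days = c("d1", "d2", "d3",
                                                         "d4", "d5", "d17"),
                                effects = NULL, seed = 42,
                                subject_sd = 15, resid_sd = 8) {
  set.seed(seed)
  effects <- effects %||% list(
    LRN = c(50, 30, 10, 5, 5, 8),
    LRN_SMP = c(20, 15, 10, 8, 8, 8),
    SMP = rep(10, length(days)))
  cells <- list(c("LRN", "LRN"), c("LRN", "SMP"), c("SMP", "SMP"))
  names(cells) <- names(effects)
  out <- list()
  for (nm in names(cells)) {
    grp <- cells[[nm]][1]; cond <- cells[[nm]][2]
    for (i in seq_len(n_per_cell)) {
      base <- rnorm(1, 100, subject_sd)
      out[[length(out) + 1L]] <- data.frame(
        subject = sprintf("%s_%02d", grp, i), group = grp, day = days,
        condition = cond,
        syn_ms = base + effects[[nm]] + rnorm(length(days), 0, resid_sd),
        rmse = rnorm(length(days), 5, 1), excluded = FALSE)
    }
  }
  structure(list(day_means = do.call(rbind, out)), class = "cohort_scores")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Reference split-plot ANOVA via base R's multivariate linear model
# machinery (anova.mlm with sphericity tests) - an independent route from
# the package's sums-of-squares implementation.
oracle_rm_anova <- function(scores, dv, days) {
  dm <- scores$day_means
  dm$unit <- paste(dm$subject, dm$condition, sep = ".")
  dm$level <- ifelse(dm$group == "SMP", "SMP",
                     ifelse(dm$condition == "LRN", "LRN", "LRN_SMP"))
  wide <- stats::reshape(dm[c("unit", "level", "day", dv)],
                         idvar = c("unit", "level"), timevar = "day",
                         direction = "wide")
  Y <- as.matrix(wide[paste(dv, days, sep = ".")])
  lev <- factor(wide$level)
  fit <- stats::lm(Y ~ lev)
  idata <- data.frame(day = factor(days, levels = days))
  within <- stats::anova(fit, X = ~1, idata = idata, test = "Spherical")
  mau <- stats::mauchly.test(fit, X = ~1, idata = idata)
  between <- stats::anova(stats::lm(rowMeans(Y) ~ lev))
  # epsilons from the error SSD of the fitted mlm
  K <- length(days)
  ssd <- stats::SSD(fit)
  C <- qr.Q(qr(cbind(1, stats::contr.helmert(K))))[, -1, drop = FALSE]
  Tm <- t(C) %*% (ssd$SSD / ssd$df) %*% C
  gg <- sum(diag(Tm))^2 / ((K - 1) * sum(Tm^2))
  hf <- ((ssd$df + 1) * (K - 1) * gg - 2) /
    ((K - 1) * (ssd$df - (K - 1) * gg))
  list(within = within, mauchly = mau, between = between,
       eps_gg = gg, eps_hf = hf,
       heading_gg = as.numeric(sub(".*epsilon: +", "",
         grep("Greenhouse", attr(within, "heading"), value = TRUE))))
}

mini_phantom <- function(grid = c(16, 16, 16), n_per_group = 2,
                         days = c("d1", "d5"), n_volumes = 100, seed = 1,
                         null_effect = FALSE) {
  eff <- if (null_effect) default_effect_spec(days, start = 0.6, end = 0.6)
         else default_effect_spec(days)
  gen_bold_cohort(grid_shape = grid, n_per_group = n_per_group, days = days,
                  n_volumes = n_volumes, effect_spec = eff, seed = seed)
}

ec_stack_from_cohort <- function(cohort, ...) {
  maps <- lapply(cohort$datasets, function(dd) lapply(dd, fast_ecm, ...))
  stack_ec_maps(maps)
}
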