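#' Baseline group comparison on first-block simple-sequence performance
#'
#' Welch two-sample t tests comparing the groups on the average of the first
#' block (three trials) of the simple control sequence on the first training
#' day, for both SYN and RMSE. Used to verify that groups did not differ
#' behaviourally before training.
#'
#' @param scores A `cohort_scores` object.
#' @param day Day of the baseline block (default first training day).
#' @return Data frame with one row per metric: t, df, p and group means.
#' @export
baseline_ttest <- function(scores, day = "d1") {
  stopifnot(inherits(scores, "cohort_scores"))
  bm <- scores$block_means
  base <- bm[bm$day == day & bm$block == 1 & bm$condition == "SMP", , drop = FALSE]
  if (length(unique(base$group)) < 2 || !nrow(base)) {
    stop_invalid("both groups need first-block SMP data on %s", day)
  }
  out <- lapply(c("syn_ms", "rmse"), function(metric) {
    x <- base[[metric]][base$group == "LRN"]
    y <- base[[metric]][base$group == "SMP"]
    if (stats::sd(c(x, y)) == 0) {
      return(data.frame(metric = metric, t = 0, df = length(x) + length(y) - 2,
                        p = 1, mean_LRN = mean(x), mean_SMP = mean(y)))
    }
    tt <- stats::t.test(x, y)
    data.frame(metric = metric, t = unname(tt$statistic),
               df = unname(tt$parameter), p = tt$p.value,
               mean_LRN = mean(x), mean_SMP = mean(y))
  })
  do.call(rbind, out)
}

# Build the unit x day matrix of per-day means for the mixed ANOVA.
# Units are performance traces: LRN-group complex trials (LRN), LRN-group
# simple trials (LRN_SMP) and SMP-group simple trials (SMP); with the
# 2-level coding, units are subjects (conditions averaged).
anova_units <- function(scores, dv, coding) {
  dm <- scores$day_means
  dm <- dm[!dm$excluded, , drop = FALSE]
  if (coding == "trace3") {
    dm$unit <- paste(dm$subject, dm$condition, sep = ".")
    dm$level <- ifelse(dm$group == "SMP", "SMP",
                       ifelse(dm$condition == "LRN", "LRN", "LRN_SMP"))
  } else {
    agg <- stats::aggregate(dm[c("syn_ms", "rmse")],
                            by = dm[c("subject", "group", "day")], FUN = mean)
    agg$excluded <- FALSE
    dm <- agg
    dm$unit <- dm$subject
    dm$level <- dm$group
  }
  days <- intersect(DAY_LEVELS, unique(dm$day))
  wide <- stats::reshape(
    dm[c("unit", "level", "day", dv)],
    idvar = c("unit", "level"), timevar = "day", direction = "wide")
  ycols <- paste(dv, days, sep = ".")
  complete <- stats::complete.cases(wide[ycols])
  if (any(!complete)) {
    warning(sprintf("dropping %d unit(s) with missing days", sum(!complete)))
    wide <- wide[complete, , drop = FALSE]
  }
  list(Y = as.matrix(wide[ycols]), level = factor(wide$level), days = days)
}

# Orthonormal contrast matrix (k x (k-1)) orthogonal to the constant.
contr_orthonormal <- function(k) {
  qr.Q(qr(cbind(1, stats::contr.helmert(k))))[, -1L, drop = FALSE]
}

#' Mixed repeated-measures ANOVA on behavioural day means
#'
#' Split-plot ANOVA with a within-subject factor day and a between factor
#' over performance-trace types. With the default 3-level coding the between
#' factor distinguishes the learning group's complex-sequence trials, the
#' learning group's simple-sequence trials, and the control group's
#' simple-sequence trials; `coding = "group2"` collapses to a plain
#' two-group comparison. Sphericity is assessed with Mauchly's test; when it
#' rejects (p < 0.05) the degrees of freedom of within effects are corrected
#' with Greenhouse-Geisser if the GG epsilon is below 0.75 and with
#' Huynh-Feldt otherwise, following common practice in behavioural reports.
#'
#' @param scores A `cohort_scores` object (exclusion flags respected).
#' @param dv Dependent variable, `"syn_ms"` or `"rmse"`.
#' @param coding `"trace3"` (default) or `"group2"`.
#' @param mauchly_alpha Significance level of Mauchly's test that triggers
#'   the correction.
#' @return Data frame of class `rm_anova` with one row per effect
#'   (between factor, day, day-by-factor interaction): `F`, `df_num`,
#'   `df_den` (corrected when a correction is applied), `p`, `eta_sq`
#'   (partial), `epsilon` and `correction`. Mauchly's W and p are attached
#'   as attributes `mauchly_w`, `mauchly_p`.
#' @export
rm_anova <- function(scores, dv = c("syn_ms", "rmse"),
                     coding = c("trace3", "group2"), mauchly_alpha = 0.05) {
  dv <- match.arg(dv)
  coding <- match.arg(coding)
  stopifnot(inherits(scores, "cohort_scores"))
  u <- anova_units(scores, dv, coding)
  Y <- u$Y
  grp <- u$level
  N <- nrow(Y); K <- ncol(Y); g <- nlevels(grp)
  if (K < 2 || g < 2) stop_invalid("need >= 2 levels in both factors")
  if (N - g < 1) stop_invalid("not enough units for error degrees of freedom")

  between_name <- if (coding == "trace3") "trace_type" else "group"

  # ---- between-units stratum (on unit means, scaled by K) ----
  ybar <- rowMeans(Y)
  grand <- mean(ybar)
  gm <- tapply(ybar, grp, mean)
  ss_b <- K * sum(tapply(ybar, grp, length) * (gm - grand)^2)
  ss_be <- K * sum((ybar - gm[grp])^2)
  df_b <- g - 1; df_be <- N - g
  scale_b <- max(mean(ybar^2) * N * K, .Machine$double.xmin)
  F_b <- if (ss_be < 1e-12 * scale_b) {
    if (ss_b < 1e-12 * scale_b) 0 else Inf
  } else (ss_b / df_b) / (ss_be / df_be)
  p_b <- stats::pf(F_b, df_b, df_be, lower.tail = FALSE)

  # ---- within-units stratum via orthonormal day contrasts ----
  C <- contr_orthonormal(K)
  U <- Y %*% C
  X <- stats::model.matrix(~grp)
  q1 <- qr(matrix(1, N, 1))
  qX <- qr(X)
  H_day <- crossprod(qr.fitted(q1, U))
  H_int <- crossprod(qr.fitted(qX, U)) - H_day
  E <- crossprod(qr.resid(qX, U))

  df_day <- K - 1
  df_int <- (g - 1) * (K - 1)
  df_err <- (N - g) * (K - 1)
  ss_day <- sum(diag(H_day)); ss_int <- sum(diag(H_int)); ss_err <- sum(diag(E))
  # guard against numerically-zero strata (e.g. all cells equal)
  ss_scale <- max(mean(Y^2) * N * K, .Machine$double.xmin)
  is0 <- function(ss) ss < 1e-12 * ss_scale
  ratio_F <- function(ss_eff, df_eff) {
    if (is0(ss_err)) return(if (is0(ss_eff)) 0 else Inf)
    (ss_eff / df_eff) / (ss_err / df_err)
  }
  F_day <- ratio_F(ss_day, df_day)
  F_int <- ratio_F(ss_int, df_int)

  # ---- sphericity: Mauchly's W and GG / HF epsilons ----
  Sigma <- E / (N - g)
  k1 <- K - 1
  tr_s <- sum(diag(Sigma))
  eps_gg <- if (sum(Sigma^2) == 0) 1 else tr_s^2 / (k1 * sum(Sigma^2))
  eps_hf <- min(1, ((df_be + 1) * k1 * eps_gg - 2) /
                     (k1 * (df_be - k1 * eps_gg)))
  detS <- det(Sigma)
  W <- if (tr_s == 0) 1 else detS / (tr_s / k1)^k1
  if (!is.finite(W) || W <= 0) {
    mauchly_p <- 0; W <- max(W, 0)
  } else if (K == 2) {
    mauchly_p <- 1  # sphericity trivially holds with one contrast
  } else {
    # chi-square approximation with the standard second-order correction
    nn <- df_be
    rho <- 1 - (2 * k1^2 + k1 + 2) / (6 * k1 * nn)
    w2 <- (k1 + 2) * (k1 - 1) * (k1 - 2) *
      (2 * k1^3 + 6 * k1^2 + 3 * K + 2) / (288 * (nn * k1 * rho)^2)
    z <- -nn * rho * log(W)
    f <- k1 * (k1 + 1) / 2 - 1
    mauchly_p <- stats::pchisq(z, f, lower.tail = FALSE) +
      w2 * (stats::pchisq(z, f + 4, lower.tail = FALSE) -
              stats::pchisq(z, f, lower.tail = FALSE))
  }
  eps_used <- if (eps_gg < 0.75) eps_gg else eps_hf
  corr_name <- if (eps_gg < 0.75) "greenhouse-geisser" else "huynh-feldt"
  correct <- is.finite(mauchly_p) && mauchly_p < mauchly_alpha && K > 2

  within_row <- function(effect, F, df1, df2, ss_eff) {
    if (correct) {
      df1c <- eps_used * df1; df2c <- eps_used * df2
      data.frame(effect = effect, F = F, df_num = df1c, df_den = df2c,
                 p = stats::pf(F, df1c, df2c, lower.tail = FALSE),
                 eta_sq = if (ss_eff + ss_err == 0) 0 else ss_eff / (ss_eff + ss_err),
                 epsilon = eps_used, correction = corr_name)
    } else {
      data.frame(effect = effect, F = F, df_num = df1, df_den = df2,
                 p = stats::pf(F, df1, df2, lower.tail = FALSE),
                 eta_sq = if (ss_eff + ss_err == 0) 0 else ss_eff / (ss_eff + ss_err),
                 epsilon = min(1, eps_gg), correction = "none")
    }
  }

  res <- rbind(
    data.frame(effect = between_name, F = F_b, df_num = df_b, df_den = df_be,
               p = p_b,
               eta_sq = if (ss_b + ss_be == 0) 0 else ss_b / (ss_b + ss_be),
               epsilon = 1, correction = "none"),
    within_row("day", F_day, df_day, df_err, ss_day),
    within_row(paste0("day:", between_name), F_int, df_int, df_err, ss_int)
  )
  attr(res, "mauchly_w") <- W
  attr(res, "mauchly_p") <- mauchly_p
  attr(res, "epsilon_gg") <- eps_gg
  attr(res, "epsilon_hf") <- eps_hf
  attr(res, "dv") <- dv
  class(res) <- c("rm_anova", "data.frame")
  res
}

#' Tukey post hoc tests between consecutive days
#'
#' For each performance-trace type, compares the per-day means of
#' consecutive days (d1-d2, d2-d3, ..., d5-d17) with Tukey's honestly
#' significant difference procedure, using the within-units error of a
#' subject-blocked design.
#'
#' @param scores A `cohort_scores` object.
#' @param dv `"syn_ms"` or `"rmse"`.
#' @param coding As in [rm_anova()].
#' @return Data frame with one row per (trace type, consecutive day pair):
#'   mean difference (later minus earlier day), t, Tukey-adjusted p.
#' @export
tukey_consecutive <- function(scores, dv = c("syn_ms", "rmse"),
                              coding = c("trace3", "group2")) {
  dv <- match.arg(dv)
  coding <- match.arg(coding)
  u <- anova_units(scores, dv, coding)
  days <- u$days
  K <- length(days)
  if (K < 2) stop_invalid("need >= 2 day levels")
  pairs <- cbind(days[-K], days[-1L])

  out <- list()
  for (lev in levels(u$level)) {
    Y <- u$Y[u$level == lev, , drop = FALSE]
    n <- nrow(Y)
    if (n < 2) next
    # subject-blocked one-way ANOVA residual (interaction MS)
    res <- Y - rowMeans(Y) -
      matrix(colMeans(Y), n, K, byrow = TRUE) + mean(Y)
    mse <- sum(res^2) / ((n - 1) * (K - 1))
    dfe <- (n - 1) * (K - 1)
    m <- colMeans(Y)
    se <- sqrt(2 * mse / n)
    for (r in seq_len(nrow(pairs))) {
      i <- match(pairs[r, 1], days); j <- match(pairs[r, 2], days)
      diff <- m[j] - m[i]
      tval <- if (se == 0) 0 else diff / se
      padj <- if (se == 0) 1 else
        stats::ptukey(sqrt(2) * abs(tval), K, dfe, lower.tail = FALSE)
      out[[length(out) + 1L]] <- data.frame(
        trace_type = lev, day_from = pairs[r, 1], day_to = pairs[r, 2],
        diff = unname(diff), t = unname(tval), p_tukey = unname(padj))
    }
  }
  do.call(rbind, out)
}
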