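#' Default region layout for BOLD phantoms
#'
#' Builds a spherical brain mask with four disjoint cubic regions inside it
#' (a connectivity `hub`, an `effect` region carrying the planted
#' group-by-time change, and two control regions), plus small white-matter
#' and CSF compartments in opposite corners of the grid, outside the brain
#' mask.
#'
#' @param grid_shape Length-3 integer grid size.
#' @return A list with `brain_mask`, `wm_mask`, `csf_mask` and
#'   `region_masks` (named list of 3D logical arrays).
#' @export
default_region_spec <- function(grid_shape = c(24, 24, 24)) {
  g <- as.integer(grid_shape)
  stopifnot(length(g) == 3L, all(g >= 12L))
  ctr <- (g + 1) / 2
  ax <- lapply(1:3, function(i) seq_len(g[i]) - ctr[i])
  dist2 <- outer(outer(ax[[1]]^2, ax[[2]]^2, "+"), ax[[3]]^2, "+")
  radius <- 0.42 * min(g)
  brain <- dist2 <= radius^2

  side <- max(3L, round(min(g) / 6))
  half <- (side - 1) / 2
  cube <- function(center) {
    m <- array(FALSE, g)
    idx <- lapply(1:3, function(i) {
      v <- round((center[i] - half)):round((center[i] + half))
      v[v >= 1 & v <= g[i]]
    })
    m[idx[[1]], idx[[2]], idx[[3]]] <- TRUE
    m
  }
  off <- radius * 0.55
  regions <- list(
    hub = cube(ctr),
    effect = cube(ctr + c(off, 0, 0)),
    ctrlA = cube(ctr + c(-off, 0, 0)),
    ctrlB = cube(ctr + c(0, off, 0))
  )
  regions <- lapply(regions, function(m) m & brain)

  corner <- function(lo) {
    m <- array(FALSE, g)
    m[lo[1]:(lo[1] + 2), lo[2]:(lo[2] + 2), lo[3]:(lo[3] + 2)] <- TRUE
    m & !brain
  }
  wm <- corner(c(1, 1, 1))
  csf <- corner(c(g[1] - 2, g[2] - 2, g[3] - 2))

  list(brain_mask = brain, wm_mask = wm, csf_mask = csf,
       region_masks = regions)
}

#' Default planted group-by-time effect
#'
#' The learning group's connectivity between the `effect` region and the
#' `hub` ramps down linearly (on the day number) from 0.6 on day 1 to 0.2
#' on day 5 and stays there at retention, while the control group's stays
#' at 0.6 on every day: a sequence-specific centrality decrease during
#' overall learning.
#'
#' @param days Days to cover.
#' @param start,end Ramp endpoints (correlation at d1 and d5).
#' @param group Group carrying the ramp.
#' @return A list with `region`, `partner`, `group` and `ramp` (named
#'   per-day correlation).
#' @export
default_effect_spec <- function(days = c("d0", "d1", "d2", "d5", "d17"),
                                start = 0.6, end = 0.2, group = "LRN") {
  num <- pmin(pmax(day_number(days), 1), 5)
  ramp <- start + (end - start) * (num - 1) / 4
  names(ramp) <- days
  list(region = "effect", partner = "hub", group = group, ramp = ramp)
}

# Inter-region target correlation matrix for one (group, day).
session_corr_matrix <- function(regions, effect_spec, group, day,
                                base = NULL) {
  m <- length(regions)
  base <- base %||% c(hub_ctrl = 0.4, effect_ctrl = 0.2, ctrl_ctrl = 0.2,
                      hub_effect = 0.6)
  R <- diag(m)
  dimnames(R) <- list(regions, regions)
  set <- function(a, b, v) { R[a, b] <<- v; R[b, a] <<- v }
  for (a in regions) for (b in regions) {
    if (a >= b) next
    pair <- sort(c(a, b))
    v <- if (setequal(pair, c(effect_spec$partner, effect_spec$region))) {
      if (group == effect_spec$group) unname(effect_spec$ramp[day])
      else base[["hub_effect"]]
    } else if (effect_spec$partner %in% pair) base[["hub_ctrl"]]
    else if (effect_spec$region %in% pair) base[["effect_ctrl"]]
    else base[["ctrl_ctrl"]]
    set(a, b, v)
  }
  R
}

# Band-limited latent signals (t x m) with sample correlation exactly R.
latent_signals <- function(nt, R, tr, band = c(0.01, 0.1)) {
  m <- ncol(R)
  L0 <- matrix(stats::rnorm(nt * m), nt, m)
  L0 <- bandpass_matrix(L0, band, 1 / tr)
  L0 <- sweep(L0, 2, colMeans(L0), "-")
  Q <- qr.Q(qr(L0))
  ch <- tryCatch(chol(R), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  sqrt(nt) * Q %*% ch
}

#' Generate one synthetic BOLD session
#'
#' Every voxel's timecourse is `loading` times its region's latent signal
#' plus white noise (plus optional linear drift and motion-coupled
#' component); latent region signals are band-limited (0.01-0.1 Hz, so
#' cleaning does not destroy the planted structure) and realized with
#' empirical inter-region correlations exactly equal to the target matrix.
#' White-matter and CSF compartments receive their own structured noise.
#'
#' @param spec Region layout (see [default_region_spec()]).
#' @param R Target inter-region correlation matrix (symmetric, unit
#'   diagonal, positive semidefinite).
#' @param n_volumes Number of volumes (>= 50).
#' @param tr Repetition time in seconds.
#' @param noise Noise specification: `voxel_sd` (white noise on region
#'   voxels), `loading`, `background_sd` (non-region brain voxels),
#'   `tissue_sd`, `drift_amp` (peak-to-peak linear drift), `motion_amp`
#'   (random-walk step, mm) and `motion_coupling`.
#' @param seed Integer seed.
#' @return A [bold_dataset()].
#' @export
gen_bold_session <- function(spec, R, n_volumes = 200, tr = 1.13,
                             noise = default_phantom_noise(), seed = 1) {
  if (n_volumes < 50) stop_invalid("n_volumes must be >= 50")
  regions <- names(spec$region_masks)
  stopifnot(identical(colnames(R), regions))
  grid <- dim(spec$brain_mask)
  with_seed(seed, {
    L <- latent_signals(n_volumes, R, tr)
    if (is.null(L)) stop_invalid("target correlation matrix is not positive semidefinite")
    nvox <- prod(grid)
    flat <- matrix(stats::rnorm(nvox * n_volumes, 0,
                                noise$background_sd), n_volumes, nvox)
    flat[, !as.vector(spec$brain_mask)] <- 0
    for (r in seq_along(regions)) {
      idx <- which(as.vector(spec$region_masks[[r]]))
      if (!length(idx)) next
      flat[, idx] <- noise$loading * L[, r] +
        matrix(stats::rnorm(length(idx) * n_volumes, 0, noise$voxel_sd),
               n_volumes, length(idx))
    }
    for (tm in c("wm_mask", "csf_mask")) {
      idx <- which(as.vector(spec[[tm]]))
      if (!length(idx)) next
      lat <- bandpass_matrix(matrix(stats::rnorm(n_volumes), ncol = 1),
                             c(0.01, 0.1), 1 / tr)
      lat <- lat / stats::sd(lat)
      flat[, idx] <- as.vector(lat) +
        matrix(stats::rnorm(length(idx) * n_volumes, 0, noise$tissue_sd),
               n_volumes, length(idx))
    }
    motion <- matrix(cumsum(stats::rnorm(n_volumes * 6, 0, noise$motion_amp)),
                     n_volumes, 6)
    motion[, 4:6] <- motion[, 4:6] / 50  # rotations in rad, ~mm at 50 mm
    if (noise$drift_amp > 0) {
      tt <- seq(-0.5, 0.5, length.out = n_volumes)
      drift <- outer(tt, stats::rnorm(nvox, 0, noise$drift_amp))
      inb <- as.vector(spec$brain_mask | spec$wm_mask | spec$csf_mask)
      flat[, inb] <- flat[, inb] + drift[, inb]
    }
    if (noise$motion_coupling > 0) {
      cm <- c(0, sqrt(rowSums(diff(motion)^2)))
      inb <- which(as.vector(spec$brain_mask))
      flat[, inb] <- flat[, inb] + noise$motion_coupling * cm
    }
    bold_dataset(array(t(flat), c(grid, n_volumes)), tr = tr,
                 voxel_size = 1.2, brain_mask = spec$brain_mask,
                 wm_mask = spec$wm_mask, csf_mask = spec$csf_mask,
                 motion = motion)
  })
}

#' Default phantom noise specification
#'
#' @param voxel_sd White-noise SD on region voxels (latent signals have
#'   unit SD, so the default gives region voxels a 2:1 signal-to-noise
#'   ratio).
#' @param loading Latent-signal loading of region voxels.
#' @param background_sd Noise SD of non-region brain voxels.
#' @param tissue_sd Noise SD of WM/CSF voxels around their shared
#'   structured signal.
#' @param drift_amp Linear drift amplitude (0 disables).
#' @param motion_amp Motion random-walk step in mm (parameters are always
#'   recorded; coupling into the data is off by default).
#' @param motion_coupling Amplitude of the motion-correlated signal
#'   component (0 disables).
#' @return Named list.
#' @export
default_phantom_noise <- function(voxel_sd = 0.5, loading = 1,
                                  background_sd = 1, tissue_sd = 1,
                                  drift_amp = 0, motion_amp = 0.02,
                                  motion_coupling = 0) {
  list(voxel_sd = voxel_sd, loading = loading, background_sd = background_sd,
       tissue_sd = tissue_sd, drift_amp = drift_amp, motion_amp = motion_amp,
       motion_coupling = motion_coupling)
}

#' Generate a longitudinal two-group BOLD phantom cohort
#'
#' Simulates per subject-session 4D BOLD datasets with region-structured
#' connectivity whose inter-region correlation follows a per-(group, day)
#' target matrix; by default the learning group's effect-region-to-hub
#' correlation ramps down across training days (see
#' [default_effect_spec()]), planting a group-by-time eigenvector
#' centrality change in exactly one region of one group.
#'
#' @param grid_shape Grid size (default 24^3).
#' @param n_per_group Subjects per group.
#' @param days Scan days (default the scanned sessions d0, d1, d2, d5, d17).
#' @param n_volumes Volumes per session (default 200).
#' @param tr Repetition time in seconds (default 1.13).
#' @param region_spec See [default_region_spec()].
#' @param effect_spec See [default_effect_spec()].
#' @param noise_spec See [default_phantom_noise()].
#' @param seed Integer seed.
#' @return A list of class `bold_cohort`: `datasets` (nested list
#'   `[[subject]][[day]]` of [bold_dataset()]s), `groups` (named character
#'   vector), `days`, and `ground_truth` (region masks, per-(group, day)
#'   target correlation matrices, and the effect region label).
#' @export
gen_bold_cohort <- function(grid_shape = c(24, 24, 24), n_per_group = 10,
                            days = c("d1", "d5"), n_volumes = 200,
                            tr = 1.13, region_spec = NULL,
                            effect_spec = NULL,
                            noise_spec = default_phantom_noise(), seed = 1) {
  spec <- region_spec %||% default_region_spec(grid_shape)
  if (length(spec$region_masks) < 3) {
    stop_invalid("region_spec must define at least 3 regions")
  }
  eff <- effect_spec %||% default_effect_spec(days)
  if (!all(days %in% names(eff$ramp))) {
    stop_invalid("effect_spec ramp missing days: %s",
                 paste(setdiff(days, names(eff$ramp)), collapse = ", "))
  }
  regions <- names(spec$region_masks)
  subjects <- sprintf("sub%02d", seq_len(2 * n_per_group))
  groups <- stats::setNames(rep(c("LRN", "SMP"), each = n_per_group), subjects)

  corrs <- list()
  for (grp in c("LRN", "SMP")) {
    corrs[[grp]] <- list()
    for (day in days) {
      R <- session_corr_matrix(regions, eff, grp, day)
      ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
      if (min(ev) < -1e-10) {
        stop_invalid("target correlation matrix for (%s, %s) is not positive semidefinite",
                     grp, day)
      }
      corrs[[grp]][[day]] <- R
    }
  }

  datasets <- list()
  for (s in seq_along(subjects)) {
    subj <- subjects[s]
    datasets[[subj]] <- list()
    for (d in seq_along(days)) {
      datasets[[subj]][[days[d]]] <- gen_bold_session(
        spec, corrs[[groups[subj]]][[days[d]]], n_volumes = n_volumes,
        tr = tr, noise = noise_spec,
        seed = child_seed(seed, s * 101 + d))
    }
  }
  structure(
    list(datasets = datasets, groups = groups, days = days,
         ground_truth = list(region_masks = spec$region_masks,
                             brain_mask = spec$brain_mask,
                             session_correlation = corrs,
                             effect_region = eff$region,
                             effect_spec = eff)),
    class = "bold_cohort"
  )
}

#' @export
print.bold_cohort <- function(x, ...) {
  cat(sprintf("<bold_cohort> %d subjects x %d days, effect region '%s'\n",
              length(x$datasets), length(x$days),
              x$ground_truth$effect_region))
  invisible(x)
}
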