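#' Remove initial volumes for signal stabilization
#'
#' @param bold A [bold_dataset()].
#' @param n Number of leading volumes to drop (default 5). Motion
#'   parameters are trimmed to match.
#' @return A [bold_dataset()] with `n` fewer volumes.
#' @export
drop_initial_volumes <- function(bold, n = 5) {
  stopifnot(inherits(bold, "bold_dataset"))
  nt <- dim(bold$data)[4]
  if (n < 0 || n != round(n)) stop_invalid("n must be a non-negative integer")
  if (n >= nt) stop_invalid("cannot drop %d of %d volumes", n, nt)
  if (n == 0) return(bold)
  keep <- (n + 1L):nt
  bold_dataset(bold$data[, , , keep, drop = FALSE], tr = bold$tr,
               voxel_size = bold$voxel_size, brain_mask = bold$brain_mask,
               wm_mask = bold$wm_mask, csf_mask = bold$csf_mask,
               motion = if (!is.null(bold$motion)) bold$motion[keep, , drop = FALSE])
}

# Remove a linear trend (with intercept) from each column of Y.
detrend_linear <- function(Y) {
  t <- seq_len(nrow(Y))
  X <- cbind(1, t - mean(t))
  Y - X %*% qr.coef(qr(X), Y)
}

#' Physiological noise components from a tissue compartment
#'
#' Component-based confound extraction in the spirit of aCompCor: within
#' the given tissue mask (typically white matter or CSF), the most variable
#' voxels are selected, detrended and standardized, and the first left
#' singular vectors of their timecourse matrix are returned as nuisance
#' regressors.
#'
#' @param bold A [bold_dataset()].
#' @param tissue_mask 3D logical array (e.g. `bold$wm_mask`).
#' @param n_components Number of components to return (default 5).
#' @param variance_percentile Fraction (in percent) of most-variable voxels
#'   to retain (default 2).
#' @return A t x `n_components` matrix with orthonormal columns, named
#'   `physio_1`, `physio_2`, ...
#' @export
high_variance_confounds <- function(bold, tissue_mask, n_components = 5,
                                    variance_percentile = 2) {
  stopifnot(inherits(bold, "bold_dataset"))
  if (is.null(tissue_mask) || !any(tissue_mask)) {
    stop_invalid("tissue_mask is empty")
  }
  Y <- detrend_linear(mask_matrix(bold$data, tissue_mask))
  v <- apply(Y, 2, stats::var)
  n_keep <- max(n_components, ceiling(length(v) * variance_percentile / 100))
  keep <- order(v, decreasing = TRUE)[seq_len(min(n_keep, length(v)))]
  Y <- Y[, keep, drop = FALSE]
  sds <- sqrt(colMeans(Y^2))
  sds[sds == 0] <- 1
  Y <- sweep(Y, 2, sds, "/")
  k <- min(n_components, ncol(Y), nrow(Y) - 1L)
  if (k < n_components) {
    warning(sprintf("only %d component(s) available; reducing from %d",
                    k, n_components))
  }
  u <- svd(Y, nu = k, nv = 0)$u
  colnames(u) <- paste0("physio_", seq_len(k))
  u
}

#' Detect motion and global-signal spike volumes
#'
#' Flags volumes whose composite motion (Euclidean norm of frame-to-frame
#' parameter differences, with rotations converted to mm at a 50 mm head
#' radius) or whose average in-brain signal deviates by more than the given
#' z thresholds. Each flagged volume yields one one-hot regressor column.
#'
#' @param motion t x 6 motion-parameter matrix (translations mm, rotations
#'   rad), or `NULL`.
#' @param global_signal Length-t vector of mean in-brain signal, or `NULL`.
#' @param motion_z,signal_z z-score thresholds.
#' @param rotation_radius_mm Radius used to convert rotations to mm.
#' @return A t x k one-hot matrix (k flagged volumes; zero columns when
#'   none), with an attribute `flagged` giving volume indices.
#' @export
detect_spikes <- function(motion = NULL, global_signal = NULL,
                          motion_z = 3, signal_z = 3,
                          rotation_radius_mm = 50) {
  nt <- if (!is.null(motion)) nrow(motion) else length(global_signal)
  if (is.null(nt) || nt == 0) stop_invalid("no inputs to scan for spikes")
  if (!is.null(motion) && !is.null(global_signal) &&
      length(global_signal) != nrow(motion)) {
    stop_invalid("global_signal length (%d) does not match motion rows (%d)",
                 length(global_signal), nrow(motion))
  }
  flagged <- integer(0)
  zscore <- function(x) {
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) rep(0, length(x)) else (x - mean(x)) / s
  }
  if (!is.null(motion)) {
    m <- as.matrix(motion)
    m[, 4:6] <- m[, 4:6] * rotation_radius_mm
    composite <- c(0, sqrt(rowSums(diff(m)^2)))
    flagged <- union(flagged, which(zscore(composite) > motion_z))
  }
  if (!is.null(global_signal)) {
    flagged <- union(flagged, which(abs(zscore(global_signal)) > signal_z))
  }
  flagged <- sort(flagged)
  out <- matrix(0, nt, length(flagged))
  for (i in seq_along(flagged)) out[flagged[i], i] <- 1
  if (length(flagged)) colnames(out) <- paste0("spike_", flagged)
  attr(out, "flagged") <- flagged
  out
}

#' Assemble a confound matrix
#'
#' Combines the 12 motion regressors (6 parameters plus their first
#' derivatives), spike indicator columns and physiological components into
#' one named matrix aligned to the volumes.
#'
#' @param bold A [bold_dataset()] (motion parameters taken from it when
#'   present).
#' @param spikes Optional one-hot matrix from [detect_spikes()].
#' @param physio Optional matrix (or list of matrices) from
#'   [high_variance_confounds()].
#' @return A t x k numeric matrix (possibly zero columns).
#' @export
build_confounds <- function(bold, spikes = NULL, physio = NULL) {
  nt <- dim(bold$data)[4]
  parts <- list()
  if (!is.null(bold$motion)) {
    m <- as.matrix(bold$motion)
    dm <- rbind(0, diff(m))
    colnames(m) <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
    colnames(dm) <- paste0("d_", colnames(m))
    parts <- c(parts, list(m, dm))
  }
  if (!is.null(spikes) && ncol(spikes)) parts <- c(parts, list(spikes))
  if (!is.null(physio)) {
    if (is.list(physio)) parts <- c(parts, physio) else parts <- c(parts, list(physio))
  }
  if (!length(parts)) return(matrix(0, nt, 0))
  out <- do.call(cbind, parts)
  stopifnot(nrow(out) == nt)
  out
}

# Zero-phase Butterworth band-pass of each column of Y (t x V), with
# full-length odd reflection padding to suppress edge transients.
bandpass_matrix <- function(Y, band, fs, order = 4) {
  ny <- fs / 2
  if (band[1] <= 0 || band[2] >= ny || band[1] >= band[2]) {
    stop_invalid("band edges must satisfy 0 < lo < hi < Nyquist (%.4g Hz)", ny)
  }
  bf <- signal::butter(order, band / ny, type = "pass")
  n <- nrow(Y)
  pad <- n - 1L
  pre <- 2 * Y[rep(1L, pad), , drop = FALSE] - Y[(pad + 1L):2L, , drop = FALSE]
  post <- 2 * Y[rep(n, pad), , drop = FALSE] - Y[(n - 1L):(n - pad), , drop = FALSE]
  Yp <- rbind(pre, Y, post)
  out <- apply(Yp, 2, function(x) signal::filtfilt(bf, x))
  out[(pad + 1L):(pad + n), , drop = FALSE]
}

#' Clean BOLD time-series
#'
#' Per in-mask voxel, in order: regress out the confound columns (least
#' squares, keeping residuals), remove a linear trend, variance-normalize,
#' and band-pass filter with a zero-phase order-4 Butterworth filter whose
#' cutoffs (Hz) are interpreted relative to the sampling rate 1/TR. After
#' filtering, timecourses are re-standardized to zero mean and unit
#' variance so the output satisfies the variance-normalization contract.
#' Voxels whose residual after confound regression is numerically zero are
#' flagged as degenerate and dropped from the mask with a warning, as are
#' zero-variance voxels. Collinear confound columns are dropped with a
#' warning.
#'
#' @param bold A [bold_dataset()].
#' @param confounds Optional t x k confound matrix (see
#'   [build_confounds()]).
#' @param band Band-pass edges in Hz (default 0.01-0.1).
#' @param mask Mask to clean within (defaults to the brain mask).
#' @return An object of class `cleaned_bold`: 4D `data` (zeros outside the
#'   possibly reduced `mask`), `tr`, `voxel_size`, `mask`, and `provenance`
#'   (ordered list of applied steps with parameters).
#' @export
clean_timeseries <- function(bold, confounds = NULL, band = c(0.01, 0.1),
                             mask = NULL) {
  stopifnot(inherits(bold, "bold_dataset"))
  mask <- mask %||% bold$brain_mask
  grid <- dim(bold$data)[1:3]
  Y <- mask_matrix(bold$data, mask)
  nt <- nrow(Y)
  prov <- list()

  keep <- apply(Y, 2, stats::sd) > 0
  if (any(!keep)) {
    warning(sprintf("dropping %d zero-variance voxel(s) from the mask",
                    sum(!keep)))
    idx <- which(mask)
    mask[idx[!keep]] <- FALSE
    Y <- Y[, keep, drop = FALSE]
  }

  if (!is.null(confounds) && ncol(confounds)) {
    stopifnot(nrow(confounds) == nt)
    X <- cbind(intercept = 1, confounds)
    qx <- qr(X)
    if (qx$rank < ncol(X)) {
      dropped <- colnames(X)[qx$pivot[-seq_len(qx$rank)]]
      warning(sprintf("dropping %d collinear confound column(s): %s",
                      length(dropped), paste(dropped, collapse = ", ")))
    }
    Y <- qr.resid(qx, Y)
    prov[[length(prov) + 1L]] <- list(step = "confound_regression",
                                      n_confounds = ncol(confounds))
    resid_norm <- sqrt(colSums(Y^2))
    degen <- resid_norm < 1e-8
    if (any(degen)) {
      warning(sprintf("%d voxel(s) fully explained by confounds; flagged degenerate and dropped",
                      sum(degen)))
      idx <- which(mask)
      mask[idx[degen]] <- FALSE
      Y <- Y[, !degen, drop = FALSE]
    }
  }

  Y <- detrend_linear(Y)
  prov[[length(prov) + 1L]] <- list(step = "detrend", order = 1)

  sds <- sqrt(colMeans(Y^2))
  ok <- sds > 1e-12
  if (any(!ok)) {
    warning(sprintf("dropping %d voxel(s) with no variance after detrending",
                    sum(!ok)))
    idx <- which(mask)
    mask[idx[!ok]] <- FALSE
    Y <- Y[, ok, drop = FALSE]
    sds <- sds[ok]
  }
  Y <- sweep(Y, 2, sds, "/")
  prov[[length(prov) + 1L]] <- list(step = "variance_normalize")

  fs <- 1 / bold$tr
  Y <- bandpass_matrix(Y, band, fs)
  prov[[length(prov) + 1L]] <- list(step = "bandpass", lo = band[1],
                                    hi = band[2], order = 4,
                                    design = "butterworth zero-phase")

  # restandardize so the unit-variance contract holds on the output
  Y <- sweep(Y, 2, colMeans(Y), "-")
  Y <- sweep(Y, 2, sqrt(colMeans(Y^2)), "/")
  prov[[length(prov) + 1L]] <- list(step = "restandardize")

  structure(list(data = unmask_matrix(Y, mask, grid), tr = bold$tr,
                 voxel_size = bold$voxel_size, mask = mask,
                 provenance = prov),
            class = "cleaned_bold")
}

#' @export
print.cleaned_bold <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<cleaned_bold> %dx%dx%d grid, %d volumes, %d in-mask voxels, %d steps\n",
              d[1], d[2], d[3], d[4], sum(x$mask), length(x$provenance)))
  invisible(x)
}

# 1D Gaussian convolution matrix (n x n), kernel truncated at 3.5 sigma.
gauss_conv_matrix <- function(n, sigma_vox) {
  r <- max(1L, ceiling(3.5 * sigma_vox))
  w <- exp(-(seq(-r, r))^2 / (2 * sigma_vox^2))
  w <- w / sum(w)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- (i - r):(i + r)
    ok <- j >= 1 & j <= n
    K[i, j[ok]] <- w[ok]
  }
  K
}

smooth_volume <- function(vol, sigma_vox) {
  d <- dim(vol)
  x <- matrix(vol, d[1], d[2] * d[3])
  vol <- array(gauss_conv_matrix(d[1], sigma_vox) %*% x, d)
  vol <- aperm(vol, c(2, 1, 3))
  x <- matrix(vol, d[2], d[1] * d[3])
  vol <- aperm(array(gauss_conv_matrix(d[2], sigma_vox) %*% x, d[c(2, 1, 3)]),
               c(2, 1, 3))
  vol <- aperm(vol, c(3, 1, 2))
  x <- matrix(vol, d[3], d[1] * d[2])
  aperm(array(gauss_conv_matrix(d[3], sigma_vox) %*% x, d[c(3, 1, 2)]),
        c(2, 3, 1))
}

#' Mask-aware Gaussian spatial smoothing
#'
#' Applies a separable 3D Gaussian filter of the given full width at half
#' maximum to every volume. Smoothing is mask-aware: the data (zeroed
#' outside the mask) and the mask itself are smoothed with the same kernel
#' and their ratio is taken, which avoids edge dimming near the mask
#' boundary. `fwhm_mm = 0` returns the input unchanged.
#'
#' @param x A [bold_dataset()], `cleaned_bold`, or 3D/4D array.
#' @param fwhm_mm Kernel FWHM in millimetres (default 2.4).
#' @param voxel_size Voxel size in mm (taken from `x` when available).
#' @param mask Mask for mask-aware normalization (defaults to `x`'s mask;
#'   for bare arrays, all voxels).
#' @return Same type as the input, smoothed.
#' @export
smooth_gaussian <- function(x, fwhm_mm = 2.4, voxel_size = NULL, mask = NULL) {
  if (fwhm_mm < 0) stop_invalid("fwhm_mm must be >= 0")
  if (fwhm_mm == 0) return(x)
  is_obj <- inherits(x, "bold_dataset") || inherits(x, "cleaned_bold")
  data <- if (is_obj) x$data else x
  voxel_size <- voxel_size %||% (if (is_obj) x$voxel_size else 1)
  mask <- mask %||%
    (if (inherits(x, "cleaned_bold")) x$mask
     else if (inherits(x, "bold_dataset")) x$brain_mask
     else array(TRUE, dim(data)[seq_len(min(3, length(dim(data))))]))
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_size

  m <- array(as.numeric(mask), dim(mask))
  sm_mask <- smooth_volume(m, sigma)
  sm_mask[sm_mask < 1e-12] <- 1
  do_vol <- function(v) {
    out <- smooth_volume(v * m, sigma) / sm_mask
    out * m
  }
  if (length(dim(data)) == 3L) {
    res <- do_vol(data)
  } else {
    res <- data
    for (k in seq_len(dim(data)[4])) res[, , , k] <- do_vol(data[, , , k])
  }
  if (is_obj) {
    x$data <- res
    if (inherits(x, "cleaned_bold")) {
      x$provenance[[length(x$provenance) + 1L]] <-
        list(step = "smooth_gaussian", fwhm_mm = fwhm_mm)
    }
    x
  } else {
    res
  }
}
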