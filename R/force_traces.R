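#' Force trace objects
#'
#' A force trace is one trial's uniformly sampled pinch-force curve, expressed
#' in percent of the participant's maximum voluntary force. Traces are used
#' both for the on-screen reference bar (REF) and the participant-controlled
#' force bar (FOR).
#'
#' @param samples Numeric vector of force values (% max force).
#' @param fs Sampling rate in Hz.
#' @param range Optional length-2 numeric, the displayable force range
#'   (minimum and maximum bar level, % max force).
#' @return An object of class `force_trace` with fields `samples`, `fs`,
#'   `duration` (seconds) and `range`.
#' @export
force_trace <- function(samples, fs, range = NULL) {
  assert_scalar_pos(fs, "fs")
  samples <- as.numeric(samples)
  if (length(samples) < 2L) stop_invalid("a force trace needs at least 2 samples")
  if (!is.null(range)) {
    stopifnot(length(range) == 2L, range[1] < range[2])
  }
  structure(
    list(samples = samples, fs = fs, duration = length(samples) / fs,
         range = range),
    class = "force_trace"
  )
}

#' @export
print.force_trace <- function(x, ...) {
  cat(sprintf("<force_trace> %d samples @ %g Hz (%.3f s), range [%.3g, %.3g]\n",
              length(x$samples), x$fs, x$duration,
              min(x$samples), max(x$samples)))
  invisible(x)
}

#' @export
length.force_trace <- function(x) length(x$samples)

#' Dominant frequency of a force trace
#'
#' Frequency of maximum spectral power, excluding the zero-frequency bin.
#' The peak location is refined by parabolic interpolation of log-power
#' around the maximal bin, so frequencies that fall between FFT bins (a
#' non-integer number of cycles per trial) are still recovered accurately.
#'
#' @param trace A [force_trace()].
#' @return Frequency in Hz.
#' @export
dominant_frequency <- function(trace) {
  stopifnot(inherits(trace, "force_trace"))
  x <- trace$samples - mean(trace$samples)
  n <- length(x)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))  # Hann window
  p <- Mod(stats::fft(x * w))^2
  kmax <- floor(n / 2)
  p <- p[seq_len(kmax + 1L)]        # bins 0..n/2 (1-based index = bin + 1)
  k <- which.max(p[-1L])            # exclude DC
  delta <- 0
  if (k < kmax) {                   # parabola may use the DC bin on the left
    lp <- log(pmax(p[k:(k + 2L)], .Machine$double.xmin))
    den <- lp[1] - 2 * lp[2] + lp[3]
    if (is.finite(den) && abs(den) > 0) delta <- 0.5 * (lp[1] - lp[3]) / den
    delta <- max(min(delta, 0.5), -0.5)
  }
  (k + delta) * trace$fs / n
}

#' Generate a pseudo-random complex reference sequence (LRN)
#'
#' Emulates the properties of the complex learning sequence of the sequential
#' pinch force task: a smooth, difficult-to-predict curve through
#' pseudo-random target heights spanning the calibrated force range
#' (by default 5--30% of maximum voluntary force, 18 s at 80 Hz).
#'
#' @param duration_s Trial duration in seconds.
#' @param fs Sampling rate in Hz.
#' @param force_range Length-2 numeric `(lo, hi)`, the displayed force range.
#' @param n_segments Number of random target heights the curve passes through.
#' @param seed Integer seed; the generator is a pure function of its
#'   arguments including the seed.
#' @return A [force_trace()] spanning exactly `force_range`.
#' @export
gen_ref_lrn <- function(duration_s = 18, fs = 80, force_range = c(5, 30),
                        n_segments = 12, seed = 1) {
  assert_scalar_pos(duration_s, "duration_s")
  assert_scalar_pos(fs, "fs")
  stopifnot(length(force_range) == 2L)
  if (!(force_range[1] < force_range[2])) {
    stop_invalid("force_range must satisfy lo < hi")
  }
  if (n_segments < 4) stop_invalid("n_segments must be >= 4")

  n <- round(fs * duration_s)
  with_seed(seed, {
    knots_t <- seq(0, duration_s, length.out = n_segments)
    # alternate targets between the upper and lower half of the range so the
    # trace oscillates (like a real tracking sequence) with unpredictable
    # heights; dominant frequency ~ n_segments / (2 * duration)
    mid <- mean(force_range)
    highs <- stats::runif(ceiling(n_segments / 2), mid, force_range[2])
    lows <- stats::runif(ceiling(n_segments / 2), force_range[1], mid)
    knots_y <- as.vector(rbind(highs, lows))[seq_len(n_segments)]
    if (stats::runif(1) < 0.5) knots_y <- rev(knots_y)
    t <- (seq_len(n) - 1L) / fs
    y <- stats::spline(knots_t, knots_y, xout = t, method = "natural")$y
    force_trace(rescale_balanced(y, force_range), fs, range = force_range)
  })
}

#' Generate the matched simple control sequence (SMP)
#'
#' Constructs the simple sinusoidal control sequence matched to a given
#' reference sequence on four properties: frequency of maximum spectral
#' power, duration, force range, and total magnitude of force. The sinusoid
#' `a*sin(2*pi*f*t + phi) + c` takes `f` from the dominant frequency of
#' `matched_to`, `a` and `c` from its min/max, and `phi` minimizing the
#' absolute difference in summed force.
#'
#' @param matched_to A [force_trace()] (the complex LRN sequence).
#' @param tolerance Maximum allowed relative deviation for each matched
#'   property; exceeding it is an error, never a silent mismatch.
#' @return A list of class `sequence_pair` with fields `lrn_ref`, `smp_ref`
#'   and `match_report` (named relative deviations).
#' @export
gen_ref_smp <- function(matched_to, tolerance = 0.02) {
  stopifnot(inherits(matched_to, "force_trace"))
  x <- matched_to$samples
  n <- length(x)
  fs <- matched_to$fs
  t <- (seq_len(n) - 1L) / fs

  f <- dominant_frequency(matched_to)
  a <- (max(x) - min(x)) / 2
  mid <- (max(x) + min(x)) / 2
  rng <- max(x) - min(x)
  target_sum <- sum(x)

  # Joint choice of phase and offset: for each candidate phase, the offset
  # minimizing the worse of the range deviation (|c - mid| / range) and the
  # total-force deviation lies where the two are equal; scan phases and keep
  # the best pair.
  best <- list(dev = Inf, phi = 0, c = mid)
  A <- 1 / rng
  B <- n / abs(target_sum)
  for (phi in seq(0, 2 * pi, length.out = 721L)[-721L]) {
    s_sin <- sum(sin(2 * pi * f * t + phi))
    c_star <- (target_sum - a * s_sin) / n   # offset matching the sum exactly
    cc <- (A * mid + B * c_star) / (A + B)
    dev <- max(A * abs(cc - mid), B * abs(cc - c_star))
    if (dev < best$dev) best <- list(dev = dev, phi = phi, c = cc)
  }
  smp <- force_trace(a * sin(2 * pi * f * t + best$phi) + best$c, fs,
                     range = matched_to$range)

  rng <- max(x) - min(x)
  report <- c(
    dominant_frequency = abs(dominant_frequency(smp) - f) / f,
    duration = abs(smp$duration - matched_to$duration) / matched_to$duration,
    range = max(abs(min(smp$samples) - min(x)), abs(max(smp$samples) - max(x))) / rng,
    total_magnitude = abs(sum(smp$samples) - target_sum) / abs(target_sum)
  )
  if (any(report > tolerance)) {
    bad <- report[report > tolerance]
    stop_invalid(
      "SMP sequence could not be matched within tolerance %g: %s",
      tolerance,
      paste(sprintf("%s = %.4g", names(bad), bad), collapse = ", ")
    )
  }
  structure(list(lrn_ref = matched_to, smp_ref = smp, match_report = report),
            class = "sequence_pair")
}

#' Simulate a participant's force response to a reference sequence
#'
#' Forward model used by the synthetic behavioural cohort: the response is
#' the reference delayed by `lag_ms` (edges held at the first/last reference
#' value, avoiding wrap-around), scaled by `gain`, plus Gaussian noise, then
#' clipped to the displayable force range.
#'
#' @param ref Reference [force_trace()].
#' @param lag_ms Planted lag in milliseconds (positive = response lags the
#'   reference). Must be smaller than half the trial in magnitude.
#' @param noise_sd Gaussian noise standard deviation (% max force).
#' @param gain Multiplicative gain (> 0).
#' @param seed Integer seed.
#' @return A [force_trace()] with the same sampling rate and duration.
#' @export
gen_for_response <- function(ref, lag_ms = 0, noise_sd = 0, gain = 1,
                             seed = NULL) {
  stopifnot(inherits(ref, "force_trace"))
  if (abs(lag_ms) >= ref$duration * 1000 / 2) {
    stop_invalid("|lag_ms| must be smaller than half the trial duration")
  }
  if (noise_sd < 0) stop_invalid("noise_sd must be >= 0")
  assert_scalar_pos(gain, "gain")

  n <- length(ref$samples)
  k <- round(lag_ms / 1000 * ref$fs)
  shifted <- shift_hold(ref$samples, k)

  with_seed(seed, {
    y <- gain * shifted
    if (noise_sd > 0) y <- y + stats::rnorm(n, 0, noise_sd)
    if (!is.null(ref$range)) y <- pmin(pmax(y, ref$range[1]), ref$range[2])
    force_trace(y, ref$fs, range = ref$range)
  })
}

# Monotone two-piece rescaling mapping min -> lo, max -> hi and the mean to
# the middle of the range. Pinning the mean keeps the trace matchable by a
# sinusoid (whose mean is its mid-range) on total force.
rescale_balanced <- function(y, range) {
  lo <- range[1]; hi <- range[2]; mid <- (lo + hi) / 2
  ymin <- min(y); ymax <- max(y)
  if (ymax == ymin) return(rep(mid, length(y)))
  g <- function(anchor) {
    out <- ifelse(y <= anchor,
                  lo + (mid - lo) * (y - ymin) / (anchor - ymin),
                  mid + (hi - mid) * (y - anchor) / (ymax - anchor))
    out
  }
  eps <- (ymax - ymin) * 1e-6
  anchor <- stats::uniroot(function(a) mean(g(a)) - mid,
                           c(ymin + eps, ymax - eps), tol = 1e-12)$root
  g(anchor)
}

# Shift a vector by k samples (positive = delay), holding edge values.
shift_hold <- function(x, k) {
  n <- length(x)
  if (k == 0) return(x)
  if (abs(k) >= n) stop_invalid("shift exceeds trace length")
  if (k > 0) c(rep(x[1], k), x[seq_len(n - k)])
  else c(x[(-k + 1):n], rep(x[n], -k))
}
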