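make_bold <- function(grid = c(6, 6, 6), nt = 200, tr = 1.13, seed = 1,
                      noise = 0.1) {
  set.seed(seed)
  dat <- array(rnorm(prod(grid) * nt, 0, noise), c(grid, nt))
  bold_dataset(dat, tr = tr, brain_mask = array(TRUE, grid))
}

test_that("initial volume removal trims data and motion together", {
  b <- make_bold(nt = 200)
  b$motion <- matrix(rnorm(200 * 6, 0, 0.01), 200, 6)
  out <- drop_initial_volumes(b, 5)
  expect_equal(dim(out$data)[4], 195)
  expect_identical(out$data[, , , 1], b$data[, , , 6])
  expect_equal(nrow(out$motion), 195)
  expect_identical(drop_initial_volumes(b, 0), b)
  expect_error(drop_initial_volumes(b, 200), "cannot drop")
})

test_that("tissue confound extraction recovers a planted physiological signal", {
  grid <- c(6, 6, 6); nt <- 200; tr <- 1.13
  t <- (0:(nt - 1)) * tr
  phys <- sin(2 * pi * 0.07 * t)
  set.seed(2)
  dat <- array(rnorm(prod(grid) * nt), c(grid, nt))
  wm <- array(FALSE, grid); wm[, , 1] <- TRUE
  for (i in 1:6) for (j in 1:6) dat[i, j, 1, ] <- 0.3 * dat[i, j, 1, ] + phys
  brain <- array(TRUE, grid); brain[, , 1] <- FALSE
  b <- bold_dataset(dat, tr = tr, brain_mask = brain, wm_mask = wm)

  hv <- high_variance_confounds(b, wm)
  expect_equal(ncol(hv), 5)
  expect_gt(abs(cor(hv[, 1], phys)), 0.95)
  expect_lt(max(abs(crossprod(hv) - diag(5))), 1e-10)
  expect_warning(high_variance_confounds(b, wm, n_components = 50),
                 "reducing")
})

test_that("spike detection flags exactly the planted excursions", {
  nt <- 100
  motion <- matrix(0, nt, 6)
  expect_equal(ncol(detect_spikes(motion, rep(1, nt))), 0)

  motion[50, 1] <- 1  # 1 mm jump into and out of volume 50
  sp <- detect_spikes(motion, rep(1, nt))
  expect_setequal(attr(sp, "flagged"), c(50, 51))
  expect_equal(colSums(sp), rep(1, ncol(sp)), ignore_attr = TRUE)

  gs <- rep(100, nt); gs[30] <- 200
  sp2 <- detect_spikes(NULL, gs)
  expect_equal(attr(sp2, "flagged"), 30)

  expect_equal(ncol(detect_spikes(motion, gs, motion_z = Inf,
                                  signal_z = Inf)), 0)
})

test_that("cleaning regresses, normalizes and band-passes as specified", {
  grid <- c(5, 5, 5); nt <- 200; tr <- 1.13
  t <- (0:(nt - 1)) * tr
  set.seed(3)
  dat <- array(rnorm(prod(grid) * nt, 0, 0.1), c(grid, nt))
  dat[1, 1, 1, ] <- dat[1, 1, 1, ] + 5 * sin(2 * pi * 0.05 * t)
  dat[2, 1, 1, ] <- dat[2, 1, 1, ] + 5 * sin(2 * pi * 0.2 * t)
  b <- bold_dataset(dat, tr = tr, brain_mask = array(TRUE, grid))
  cl <- clean_timeseries(b)

  # unit-variance contract pre-smoothing
  Y <- motorecm:::mask_matrix(cl$data, cl$mask)
  expect_lt(max(abs(colMeans(Y^2) - 1)), 1e-6)
  expect_lt(max(abs(colMeans(Y))), 1e-9)

  amp <- function(y, f) {
    X <- cbind(sin(2 * pi * f * t), cos(2 * pi * f * t))
    sqrt(sum(qr.coef(qr(X), y)^2))
  }
  norm_raw <- function(v) { v <- v - mean(v); v / sqrt(mean(v^2)) }
  retained <- amp(cl$data[1, 1, 1, ], 0.05) /
    amp(norm_raw(b$data[1, 1, 1, ]), 0.05)
  expect_gte(retained, 0.9)
  att_db <- 20 * log10(amp(norm_raw(b$data[2, 1, 1, ]), 0.2) /
                         amp(cl$data[2, 1, 1, ], 0.2))
  expect_gte(att_db, 20)

  # determinism
  cl2 <- clean_timeseries(b)
  expect_identical(cl$data, cl2$data)
})

test_that("a confound-equal voxel is flagged degenerate and removed", {
  b <- make_bold(grid = c(4, 4, 4), nt = 120)
  conf <- matrix(rnorm(120), ncol = 1)
  b$data[1, 1, 1, ] <- 3 * conf[, 1]
  expect_warning(cl <- clean_timeseries(b, confounds = conf),
                 "degenerate")
  expect_false(cl$mask[1, 1, 1])
  expect_equal(sum(cl$mask), 63)
})

test_that("collinear confound columns are dropped with a warning", {
  b <- make_bold(grid = c(4, 4, 4), nt = 120)
  conf <- cbind(a = rnorm(120), b = 0)
  conf <- cbind(conf, c = conf[, "a"] * 2)
  expect_warning(clean_timeseries(b, confounds = conf), "collinear")
})

test_that("cleaning preserves in-band planted correlation structure", {
  co <- mini_phantom(grid = c(16, 16, 16), n_per_group = 1, days = "d1",
                     n_volumes = 200, seed = 21)
  b <- co$datasets$sub01$d1
  region_cor <- function(arr) {
    rm <- sapply(co$ground_truth$region_masks, function(m) {
      rowMeans(motorecm:::mask_matrix(arr, m))
    })
    cor(rm)
  }
  before <- region_cor(b$data)
  cl <- clean_timeseries(b, confounds = matrix(rnorm(200 * 3), 200, 3))
  after <- region_cor(cl$data)
  expect_lt(max(abs(before - after)), 0.05)
})

test_that("Gaussian smoothing has the analytic kernel profile", {
  g <- c(11, 11, 11)
  dat <- array(0, c(g, 2))
  dat[6, 6, 6, ] <- 1
  b <- bold_dataset(dat, tr = 1, voxel_size = 1.2,
                    brain_mask = array(TRUE, g))
  sm <- smooth_gaussian(b, fwhm_mm = 2.4)
  sigma <- 2.4 / (2 * sqrt(2 * log(2))) / 1.2
  v <- sm$data[, , , 1]
  expect_equal(v[7, 6, 6] / v[6, 6, 6], exp(-1 / (2 * sigma^2)),
               tolerance = 0.01)
  expect_equal(v[7, 7, 6] / v[6, 6, 6], exp(-2 / (2 * sigma^2)),
               tolerance = 0.01)
  expect_equal(sum(v), 1, tolerance = 1e-3)       # interior impulse mass
  expect_identical(smooth_gaussian(b, 0), b)      # fwhm 0 is the identity
  expect_error(smooth_gaussian(b, -1), "fwhm")
})

test_that("mask-aware smoothing does not dim voxels at the mask edge", {
  g <- c(9, 9, 9)
  mask <- array(FALSE, g); mask[1:5, , ] <- TRUE
  dat <- array(1, c(g, 2))
  b <- bold_dataset(dat, tr = 1, voxel_size = 1, brain_mask = mask)
  sm <- smooth_gaussian(b, fwhm_mm = 3)
  # constant input stays constant inside the mask despite the boundary
  expect_lt(max(abs(sm$data[, , , 1][mask] - 1)), 1e-6)
})
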