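# builds a dsc_series from a function curve(x, y, z) -> numeric(nt)
series_from_curves <- function(dims, nt, fn, te = 0.029, dt = 1.8,
                               baseline = 1:3, s0 = 100) {
  sig <- array(0, dim = c(dims, nt))
  for (x in seq_len(dims[1])) for (y in seq_len(dims[2]))
    for (z in seq_len(dims[3]))
      sig[x, y, z, ] <- s0 * exp(-te * fn(x, y, z))
  dsc_series(sig, te_s = te, dt_s = dt, baseline_window = baseline)
}

all_brain <- function(dims) mk_mask_grid(array(1, dim = dims))

test_that("concentration conversion inverts the exponential signal model", {
  dims <- c(4, 4, 2); nt <- 10
  set.seed(3)
  ctrue <- array(rnorm(prod(dims) * nt, 5, 2), dim = c(dims, nt))
  ctrue[, , , 1:3] <- 0  # baseline window carries S0 exactly
  sig <- 250 * exp(-0.029 * ctrue)
  ser <- dsc_series(sig, te_s = 0.029, dt_s = 1.8, baseline_window = 1:3)
  conc <- signal_to_concentration(ser, all_brain(dims))
  expect_equal(as.vector(conc), as.vector(ctrue), tolerance = 1e-10)
  expect_identical(attr(conc, "excluded_voxels"), 0L)

  # S(t) identical to S0 gives zero concentration
  ser0 <- dsc_series(array(120, dim = c(dims, nt)), baseline_window = 1:3)
  conc0 <- signal_to_concentration(ser0, all_brain(dims))
  expect_true(all(conc0 == 0))

  # closed form: S/S0 = 0.5 at TE = 29 ms
  cfix <- array(0, dim = c(dims, nt))
  cfix[, , , 5] <- log(2) / 0.029
  sig2 <- 100 * exp(-0.029 * cfix)
  conc2 <- signal_to_concentration(
    dsc_series(sig2, te_s = 0.029, baseline_window = 1:3), all_brain(dims))
  expect_equal(conc2[1, 1, 1, 5], log(2) / 0.029, tolerance = 1e-12)
  expect_equal(conc2[1, 1, 1, 5], 23.9016, tolerance = 1e-4)
})

test_that("non-positive in-mask signal is excluded with a report", {
  dims <- c(4, 4, 1); nt <- 6
  sig <- array(100, dim = c(dims, nt))
  sig[2, 3, 1, 5] <- 0
  ser <- dsc_series(sig, baseline_window = 1:2)
  expect_warning(conc <- signal_to_concentration(ser, all_brain(dims)),
                 "excluded")
  expect_identical(attr(conc, "excluded_voxels"), 1L)
  expect_true(all(conc[2, 3, 1, ] == 0))

  bad <- array(100, dim = c(dims, nt))
  bad[1, 1, 1, 1:2] <- 0  # baseline mean 0
  expect_error(signal_to_concentration(dsc_series(bad, baseline_window = 1:2),
                                       all_brain(dims)),
               "S0")
})

test_that("AIF of identical curves is the Gaussian-smoothed curve", {
  nt <- 20
  b <- dnorm(seq_len(nt), mean = 10, sd = 2.5) * 50
  conc_slice <- array(rep(b, each = 25), dim = c(5, 5, nt))
  aif <- estimate_slice_aif(conc_slice, matrix(1, 5, 5))
  # independent smoothing oracle: explicit reflect-padded convolution
  radius <- 4
  k <- dnorm(-radius:radius, sd = 1); k <- k / sum(k)
  xp <- c(b[radius:1], b, b[nt:(nt - radius + 1)])
  ref <- vapply(seq_len(nt), function(i)
    sum(xp[i:(i + 2 * radius)] * rev(k)), numeric(1))
  expect_equal(aif$concentration, ref, tolerance = 1e-12)
  expect_equal(aif$candidate_count, 25)
})

test_that("a minimum of ten candidate voxels is enforced", {
  nt <- 12
  b <- c(0, 0, 1, 4, 9, 7, 4, 2, 1, 0.5, 0.2, 0.1)
  conc_slice <- array(rep(b, each = 36), dim = c(6, 6, nt))
  set.seed(21)
  high <- sample.int(36, 6)
  for (i in high) {
    xy <- arrayInd(i, c(6, 6))
    conc_slice[xy[1], xy[2], ] <- 8 * b
  }
  aif <- estimate_slice_aif(conc_slice, matrix(1, 6, 6),
                            min_candidates = 10)
  expect_equal(aif$candidate_count, 10)
  # too few in-mask voxels: slice unusable
  m <- matrix(0, 6, 6); m[1:2, 1] <- 1
  expect_null(estimate_slice_aif(conc_slice, m, min_candidates = 10))
})

test_that("high-amplitude vascular voxels above the peak percentile form the candidate set", {
  # 24 x 24 slice: 20 voxels carry 10 * b(t), the rest carry b(t) with tiny
  # distinct perturbations; 20/576 = 3.5% of voxels exceed the 98th
  # percentile of peaks, so the candidate set is exactly those 20
  nt <- 15
  b <- dnorm(seq_len(nt), 8, 2) * 30
  conc_slice <- array(0, dim = c(24, 24, nt))
  jit <- seq(0, 0.01, length.out = 576)
  for (i in seq_len(576)) {
    xy <- arrayInd(i, c(24, 24))
    conc_slice[xy[1], xy[2], ] <- (1 + jit[i]) * b
  }
  high <- seq(13, by = 29, length.out = 20)
  for (i in high) {
    xy <- arrayInd(i, c(24, 24))
    conc_slice[xy[1], xy[2], ] <- 10 * b
  }
  aif <- estimate_slice_aif(conc_slice, matrix(1, 24, 24))
  expect_equal(aif$candidate_count, 20)
  # exhaustive percentile check: P_top must exceed every non-vascular peak
  peaks <- apply(conc_slice, c(1, 2), max)
  expect_true(aif$p_top_value > max(peaks[-high]))
  expect_true(all(peaks[high] >= aif$p_top_value))
  # the AIF is the smoothed vascular curve
  expect_equal(aif$concentration, gaussian_smooth1d(10 * b, 1),
               tolerance = 1e-12)
})

test_that("rCBV is 1 for AIF-identical curves and scales linearly", {
  dims <- c(6, 6, 2); nt <- 20
  # a pulse supported well away from both curve ends: Gaussian smoothing
  # then preserves the trapezoidal integral exactly, so identical curves
  # give rCBV exactly 1
  pulse <- numeric(nt); pulse[9:12] <- c(2, 6, 5, 1)
  ser <- series_from_curves(dims, nt, function(x, y, z) pulse)
  rc <- compute_rcbv_map(ser, all_brain(dims))
  expect_equal(as.vector(rc$grid$data), rep(1, prod(dims)),
               tolerance = 1e-9)
  # one voxel at 3x the AIF amplitude: linearity of the integral
  ser3 <- series_from_curves(dims, nt, function(x, y, z)
    if (x == 2 && y == 2 && z == 1) 3 * pulse else pulse)
  rc3 <- compute_rcbv_map(ser3, all_brain(dims))
  expect_equal(rc3$grid$data[2, 2, 1], 3, tolerance = 1e-9)
  expect_equal(rc3$grid$data[4, 4, 1], 1, tolerance = 1e-9)
})

test_that("rCBV is invariant under global signal scaling", {
  dims <- c(8, 8, 2); nt <- 16
  set.seed(9)
  sig <- array(500 + 200 * runif(prod(dims) * nt), dim = c(dims, nt))
  ser1 <- dsc_series(sig, baseline_window = 1:3)
  ser2 <- dsc_series(3.7 * sig, baseline_window = 1:3)
  m1 <- compute_rcbv_map(ser1, all_brain(dims))
  m2 <- compute_rcbv_map(ser2, all_brain(dims))
  expect_equal(m1$grid$data, m2$grid$data, tolerance = 1e-10)
})

test_that("trapezoidal integration is exact for piecewise-linear curves", {
  w <- pezmap:::trapezoid_weights(11, 1.8)
  t <- (0:10) * 1.8
  # triangular pulse peaking at t = 9 with height 6: area = 0.5*18*6
  f <- pmax(0, 6 * (1 - abs(t - 9) / 9))
  expect_equal(sum(f * w), 0.5 * 18 * 6, tolerance = 1e-12)
})

test_that("raising one voxel's curve never lowers its rCBV", {
  dims <- c(6, 6, 1); nt <- 12
  base <- dnorm(seq_len(nt), 7, 2) * 20
  ser <- series_from_curves(dims, nt, function(x, y, z)
    if (x == 1 && y == 1) 0.4 * base else base)
  rc1 <- compute_rcbv_map(ser, all_brain(dims))
  ser_up <- series_from_curves(dims, nt, function(x, y, z)
    if (x == 1 && y == 1) 0.4 * base + 0.5 else base)
  rc2 <- compute_rcbv_map(ser_up, all_brain(dims))
  expect_gte(rc2$grid$data[1, 1, 1], rc1$grid$data[1, 1, 1] - 1e-12)
})

test_that("slices without a valid AIF borrow the nearest valid slice", {
  dims <- c(6, 6, 3); nt <- 12
  ser <- series_from_curves(dims, nt, function(x, y, z)
    dnorm(seq_len(nt), 7, 2) * 20 * z)
  brain <- array(1, dim = dims)
  brain[, 3:6, 2] <- 0  # slice 2 has 12 in-mask voxels
  brain[, 2:6, 3] <- 0  # slice 3 has only 6 -> must borrow
  bm <- mk_mask_grid(brain)
  expect_message(rc <- compute_rcbv_map(ser, bm), "borrowed")
  expect_equal(rc$aif_source_slice[3], 2L)
  expect_true(all(is.finite(rc$grid$data[brain != 0])))
  # whole volume AIF-less
  tiny <- array(0, dim = dims); tiny[1:2, 1, ] <- 1
  expect_error(compute_rcbv_map(ser, mk_mask_grid(tiny)), "AIF")
})
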