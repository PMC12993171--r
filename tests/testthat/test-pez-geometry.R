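test_that("rim around a single voxel matches lattice-ball enumeration", {
  n <- 15
  core <- array(0, dim = c(n, n, n)); core[8, 8, 8] <- 1
  brain <- array(1, dim = c(n, n, n))
  rim <- build_pez(mk_mask_grid(core), mk_mask_grid(brain),
                   width_voxels = 5)
  count <- 0
  for (x in -5:5) for (y in -5:5) for (z in -5:5) {
    d2 <- x^2 + y^2 + z^2
    if (d2 > 0 && d2 <= 25) count <- count + 1
  }
  expect_equal(sum(rim$data), count)
})

test_that("distance transform agrees with brute force on random masks", {
  for (seed in 1:3) {
    set.seed(seed)
    dims <- c(14, 12, 10)
    mask <- array(rbinom(prod(dims), 1, 0.03), dim = dims)
    if (!any(mask == 1)) mask[3, 3, 3] <- 1
    expect_equal(distance_squared_to_mask(mk_mask_grid(mask)),
                 brute_edt_squared(mask),
                 ignore_attr = TRUE)
  }
})

test_that("rim oracle equivalence holds on a 32^3 sphere", {
  n <- 32
  core <- sphere_mask(n, c(16, 16, 16), 6)
  brain <- sphere_mask(n, c(16, 16, 16), 15)
  rim <- build_pez(mk_mask_grid(core), mk_mask_grid(brain), 5)
  d2 <- brute_edt_squared(core)
  ref <- (d2 > 0 & d2 <= 25 & brain != 0) * 1
  expect_identical(as.vector(rim$data), as.vector(ref))
  # rim width bounds from the brute-force distances
  expect_true(all(d2[rim$data != 0] > 0))
  expect_true(all(d2[rim$data != 0] <= 25))
})

test_that("rim respects grid bounds, excludes the core, stays in the brain", {
  n <- 12
  core <- array(0, dim = c(n, n, n)); core[1:3, 1:3, 1:3] <- 1
  brain <- array(1, dim = c(n, n, n))
  rim <- build_pez(mk_mask_grid(core), mk_mask_grid(brain), 5)
  expect_true(all(rim$data + core <= 1))       # disjoint from core
  expect_identical(dim(rim$data), dim(core))   # no out-of-bounds growth
  small_brain <- array(0, dim = c(n, n, n)); small_brain[1:6, 1:6, 1:6] <- 1
  rim2 <- build_pez(mk_mask_grid(core), mk_mask_grid(small_brain), 5)
  expect_true(all(rim2$data <= small_brain))
})

test_that("rim construction validates its inputs", {
  n <- 8
  empty <- mk_mask_grid(array(0, dim = c(n, n, n)))
  brain <- mk_mask_grid(array(1, dim = c(n, n, n)))
  expect_error(build_pez(empty, brain), "empty")
  core <- array(0, dim = c(n, n, n)); core[4, 4, 4] <- 1
  expect_error(build_pez(mk_mask_grid(core), brain, width_voxels = 0),
               ">= 1")
})

test_that("enlarging the core never shrinks core plus rim", {
  n <- 24
  brain <- mk_mask_grid(array(1, dim = c(n, n, n)))
  core1 <- sphere_mask(n, c(12, 12, 12), 4)
  core2 <- sphere_mask(n, c(12, 12, 12), 6)
  r1 <- build_pez(mk_mask_grid(core1), brain, 5)
  r2 <- build_pez(mk_mask_grid(core2), brain, 5)
  covered1 <- pmin(core1 + r1$data, 1)
  covered2 <- pmin(core2 + r2$data, 1)
  expect_true(all(covered2 >= covered1))
})

test_that("fluid exclusion splits the rim exactly at the threshold", {
  n <- 10
  pez <- array(rbinom(n^3, 1, 0.5), dim = c(n, n, n))
  set.seed(5)
  adc <- array(runif(n^3, 500, 3500), dim = c(n, n, n))
  out <- exclude_fluid(mk_mask_grid(pez), mk_map_grid(adc), 2000)
  expect_true(all(out$cleaned$data + out$excluded$data == pez))
  expect_true(all(adc[out$excluded$data != 0] >= 2000))
  expect_true(all(adc[out$cleaned$data != 0] < 2000))
  # all values below threshold: identity
  low <- mk_map_grid(array(900, dim = c(n, n, n)))
  id <- exclude_fluid(mk_mask_grid(pez), low, 2000)
  expect_identical(id$cleaned$data, pez * 1)
  expect_equal(sum(id$excluded$data), 0)
  # effectively infinite threshold: identity
  id2 <- exclude_fluid(mk_mask_grid(pez), mk_map_grid(adc), 1e12)
  expect_identical(id2$cleaned$data, pez * 1)
  expect_error(exclude_fluid(mk_mask_grid(pez), mk_map_grid(adc), -5),
               "positive")
})

test_that("phantom ventricle voxels in the rim are excluded by the ADC threshold", {
  sp <- phantom_spec(grid_shape = c(48, 48, 48), adc_noise_sd = 0,
                     signal_noise_sd = 0, between_subject_scale = 0,
                     with_dsc = FALSE)
  pc <- generate_case(sp, seed = 2)
  rim <- build_pez(pc$volumes$core_mask, pc$volumes$brain_mask, 5)
  out <- exclude_fluid(rim, pc$volumes$adc, 2000)
  fluid_idx <- which(pc$truth$class_names == "fluid")
  truth_fluid <- (pc$truth$labels == fluid_idx & rim$data != 0)
  expect_gt(sum(truth_fluid), 0)  # the ventricle really abuts the rim
  expect_identical(as.vector(out$excluded$data != 0), as.vector(truth_fluid))
})

test_that("suggested fluid threshold separates a bimodal ADC histogram", {
  set.seed(42)
  n_par <- 40000; n_fl <- 10000
  vals <- c(rnorm(n_par, 1000, 150), rnorm(n_fl, 3000, 200))
  labs <- rep(c(FALSE, TRUE), c(n_par, n_fl))
  dims <- c(50, 50, 20)
  adc <- array(vals, dim = dims)
  pez <- mk_mask_grid(array(1, dim = dims))
  th <- suggest_fluid_threshold(mk_map_grid(adc), pez)
  expect_gte(th, 1500); expect_lte(th, 2600)
  acc <- mean((vals >= th) == labs)
  expect_gte(acc, 0.95)
})

test_that("unimodal histograms fall back to the default threshold", {
  dims <- c(20, 20, 10)
  set.seed(7)
  adc <- array(rnorm(prod(dims), 1100, 140), dim = dims)
  pez <- mk_mask_grid(array(1, dim = dims))
  expect_equal(suggest_fluid_threshold(mk_map_grid(adc), pez), 2000)
})

test_that("partition is exact: disjoint compartments whose union is the rim", {
  for (seed in 1:3) {
    set.seed(seed)
    dims <- c(12, 12, 8)
    pez <- array(rbinom(prod(dims), 1, 0.4), dim = dims)
    flair <- array(rbinom(prod(dims), 1, 0.5), dim = dims)
    rec <- array(rbinom(prod(dims), 1, 0.3), dim = dims)
    part <- partition_pez(mk_mask_grid(pez), mk_mask_grid(flair),
                          mk_mask_grid(rec))
    total <- part$t1pos_flairpos$data + part$t1neg_flairpos$data +
      part$t1pos_flairneg$data + part$t1neg_flairneg$data
    expect_identical(total, pez * 1)        # union AND pairwise disjoint
  }
  # degenerate memberships
  dims <- c(8, 8, 4)
  pez <- array(1, dim = dims)
  none <- array(0, dim = dims)
  all1 <- array(1, dim = dims)
  p1 <- partition_pez(mk_mask_grid(pez), mk_mask_grid(all1),
                      mk_mask_grid(none))
  expect_equal(sum(p1$t1pos_flairpos$data) + sum(p1$t1pos_flairneg$data), 0)
  expect_equal(sum(p1$t1neg_flairpos$data), prod(dims))
  p2 <- partition_pez(mk_mask_grid(pez), mk_mask_grid(none),
                      mk_mask_grid(none))
  expect_equal(sum(p2$t1neg_flairneg$data), prod(dims))
})

test_that("partition rejects mismatched grids", {
  a <- mk_mask_grid(array(1, dim = c(6, 6, 6)))
  b <- mk_mask_grid(array(1, dim = c(6, 6, 5)))
  expect_error(partition_pez(a, b, a), "shape")
})
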