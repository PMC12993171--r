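test_that("voxel_grid enforces binarity and positive spacing", {
  arr <- array(0, dim = c(4, 4, 4))
  arr[2, 2, 2] <- 0.5
  expect_error(voxel_grid(arr, kind = "binary_mask"), "0 and 1")
  expect_error(voxel_grid(array(1, c(4, 4, 4)), spacing_mm = c(1, 0, 1)),
               "positive")
  g <- voxel_grid(array(1, c(4, 4, 4)), kind = "binary_mask")
  expect_identical(g$shape, c(4L, 4L, 4L))
})

test_that("NIfTI round-trip preserves masks bit-exactly and maps to float precision", {
  set.seed(1)
  mask <- mk_mask_grid(array(rbinom(6 * 5 * 4, 1, 0.4), dim = c(6, 5, 4)))
  map <- mk_map_grid(array(rnorm(6 * 5 * 4, 1000, 200), dim = c(6, 5, 4)),
                     units = "1e-6 mm^2/s")
  fm <- tempfile(fileext = ".nii.gz")
  fp <- tempfile(fileext = ".nii.gz")
  write_volume(mask, fm)
  write_volume(map, fp)
  mask2 <- read_volume(fm, kind = "binary_mask")
  map2 <- read_volume(fp)
  expect_identical(as.vector(mask2$data), as.vector(mask$data))
  expect_equal(as.vector(map2$data), as.vector(map$data), tolerance = 1e-6)
  expect_equal(mask2$spacing_mm, mask$spacing_mm)
})

test_that("resampling is the identity on the target grid and preserves constants", {
  g <- mk_map_grid(array(rnorm(8^3), dim = c(8, 8, 8)))
  expect_identical(resample_isotropic(g, 1, c(8, 8, 8))$data, g$data)
  const <- mk_map_grid(array(7.25, dim = c(8, 8, 8)))
  out <- resample_isotropic(const, 0.5, c(15, 15, 15))
  expect_true(all(abs(out$data - 7.25) < 1e-12))
})

test_that("mask resampling stays binary and round-trips convex shapes", {
  sph <- voxel_grid(sphere_mask(20, c(10.5, 10.5, 10.5), 7),
                    spacing_mm = c(2, 2, 2), kind = "binary_mask")
  up <- resample_isotropic(sph, 1, c(40, 40, 40))
  expect_true(all(up$data %in% c(0, 1)))
  expect_equal(up$spacing_mm, c(1, 1, 1))
  back <- resample_isotropic(up, 2, c(20, 20, 20))
  agree <- mean(back$data == sph$data)
  expect_gte(agree, 0.95)
})

test_that("resampling rejects invalid arguments", {
  g <- mk_map_grid(array(1, dim = c(4, 4, 4)))
  expect_error(resample_isotropic(g, -1), "positive")
  expect_error(resample_isotropic(g, 1, c(0, 4, 4)), "positive")
})

test_that("mask volume is voxel count times voxel volume", {
  empty <- mk_mask_grid(array(0, dim = c(10, 10, 10)))
  expect_equal(mask_volume_mm3(empty), 0)
  arr <- array(0, dim = c(10, 10, 10))
  arr[seq_len(1000)] <- 1
  expect_equal(mask_volume_mm3(mk_mask_grid(arr)), 1000)
  expect_error(mask_volume_mm3(mk_map_grid(arr)), "binary")
})

test_that("digital sphere volume matches exhaustive lattice enumeration", {
  # semi-axes (10,10,10): all lattice points with x^2+y^2+z^2 <= 100
  n <- 25
  ctr <- c(13, 13, 13)
  sph <- mk_mask_grid(sphere_mask(n, ctr, 10))
  count <- 0
  for (x in -10:10) for (y in -10:10) for (z in -10:10)
    if (x^2 + y^2 + z^2 <= 100) count <- count + 1
  expect_equal(mask_volume_mm3(sph), count)
})

test_that("mask volume is additive over disjoint masks", {
  set.seed(2)
  a <- array(rbinom(8^3, 1, 0.3), dim = c(8, 8, 8))
  b <- array(rbinom(8^3, 1, 0.3), dim = c(8, 8, 8))
  b[a == 1] <- 0
  expect_equal(mask_volume_mm3(mk_mask_grid(a)) +
                 mask_volume_mm3(mk_mask_grid(b)),
               mask_volume_mm3(mk_mask_grid(pmin(a + b, 1))))
})

test_that("case manifests round-trip through disk", {
  sp <- phantom_spec(grid_shape = c(24, 24, 24),
                     dsc_params = list(n_timepoints = 12),
                     with_dsc = TRUE)
  pc <- generate_case(sp, seed = 7)
  dir <- tempfile("case")
  man <- write_case(pc$volumes, dir)
  expect_true(file.exists(man))
  cs <- read_case_manifest(man)
  expect_equal(cs$adc$data, pc$volumes$adc$data, tolerance = 1e-6)
  expect_identical(as.vector(cs$core_mask$data),
                   as.vector(pc$volumes$core_mask$data))
  expect_equal(dim(cs$dsc$signal), dim(pc$volumes$dsc$signal))
  expect_equal(cs$dsc$te_s, pc$volumes$dsc$te_s)
})

test_that("manifest reading names the missing role", {
  dir <- tempfile("badcase")
  dir.create(dir)
  jsonlite::write_json(list(adc = "adc.nii.gz"),
                       file.path(dir, "manifest.json"), auto_unbox = TRUE)
  expect_error(read_case_manifest(file.path(dir, "manifest.json")),
               "core_mask")
})

test_that("case_volumes enforces shared geometry and core inside brain", {
  arr <- array(0, dim = c(6, 6, 6))
  brain <- arr; brain[2:5, 2:5, 2:5] <- 1
  core <- arr; core[3:4, 3:4, 3:4] <- 1
  adc <- mk_map_grid(array(1000, dim = c(6, 6, 6)))
  ok <- case_volumes(adc = adc, core_mask = mk_mask_grid(core),
                     flair_mask = mk_mask_grid(arr),
                     recurrence_mask = mk_mask_grid(arr),
                     brain_mask = mk_mask_grid(brain))
  expect_s3_class(ok, "case_volumes")
  bad_core <- arr; bad_core[1, 1, 1] <- 1
  expect_error(
    case_volumes(adc = adc, core_mask = mk_mask_grid(bad_core),
                 flair_mask = mk_mask_grid(arr),
                 recurrence_mask = mk_mask_grid(arr),
                 brain_mask = mk_mask_grid(brain)),
    "inside brain_mask")
})
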