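# Volumetry with cavity inclusion, time series, histograms and uptake.

test_that("sample volume is count times voxel volume, cavities included", {
  v <- attenuation_volume(array(0, c(12, 12, 12)), 2)
  expect_identical(sample_volume(v, 0.1), 0)
  v$data[2:11, 2:11, 2:11] <- 1
  expect_identical(sample_volume(v, 0.5), 10^3 * 2^3)
  # hollow shell: the enclosed cavity counts toward the sample volume
  sh <- attenuation_volume(array(0, c(16, 16, 16)), 1)
  sh$data[3:14, 3:14, 3:14] <- 1
  sh$data[6:11, 6:11, 6:11] <- 0
  expect_identical(sample_volume(sh, 0.5), 12^3 * 1)
  # an open notch to the border is background, not a cavity
  notch <- sh
  notch$data[8, 8, 3:16] <- 0   # channel from cavity to border
  # cavity (216) now drains to the border and the channel bores 6 voxels
  # through the shell walls: 1728 - 216 - 6
  expect_identical(sample_volume(notch, 0.5), 1506)
  expect_error(sample_volume(v, 0.5, voxel_size_um = -1), "positive")
  expect_error(sample_volume(v, NaN), "finite")
})

test_that("container voxels are removed before thresholding", {
  v <- attenuation_volume(array(0, c(10, 10, 10)), 2)
  v$data[3:8, 3:8, 3:8] <- 1
  cont <- array(FALSE, c(10, 10, 10))
  cont[3, , ] <- TRUE
  with_cont <- sample_volume(v, 0.5, container_mask = cont)
  expect_identical(with_cont, (6^3 - 6 * 6) * 8)
})

test_that("sample volume is invariant under lattice rotations", {
  cs <- iodine_cs()
  ph <- make_organ_phantom(unit_sum_spec(), cs, 0)
  thr <- 0.05
  v0 <- sample_volume(ph$le, thr)
  rot <- attenuation_volume(aperm(ph$le$data, c(2, 3, 1)),
                            ph$le$voxel_size_um)
  expect_identical(sample_volume(rot, thr), v0)
  flip <- attenuation_volume(ph$le$data[dim(ph$le$data)[1]:1, , ],
                             ph$le$voxel_size_um)
  expect_identical(sample_volume(flip, thr), v0)
})

test_that("relative volume series normalises to baseline and is scale-free", {
  m <- data.frame(time_min = c(0, 30), volume_um3 = c(5e6, 4e6))
  s <- relative_volume_series(m)
  expect_equal(s$relative_volume, c(1.0, 0.8))
  const <- relative_volume_series(
    data.frame(time_min = c(0, 60, 120), volume_um3 = rep(2e6, 3)))
  expect_true(all(const$relative_volume == 1))
  scaled <- relative_volume_series(
    data.frame(time_min = m$time_min, volume_um3 = 7 * m$volume_um3))
  expect_equal(scaled$relative_volume, s$relative_volume)
  expect_error(relative_volume_series(
    data.frame(time_min = c(0, 30), volume_um3 = c(0, 1))), "baseline")
  expect_error(relative_volume_series(
    data.frame(time_min = c(30, 0), volume_um3 = c(1, 1))), "increasing")
})

test_that("programmed shrinkage is recovered from the measured volumes", {
  cs <- iodine_cs()
  spec <- organ_phantom_spec(shape = c(48, 48, 48),
                             organ_semiaxes = c(18, 15, 12))
  thr <- (cs$air[1] + cs$pmma[1]) / 2
  specs <- list(spec, apply_shrinkage(spec, 0.8),
                apply_shrinkage(spec, 0.8))  # s = 1 afterwards: unchanged
  vols <- vapply(seq_along(specs), function(k) {
    ph <- make_organ_phantom(specs[[k]], cs, c(0, 30, 60)[k])
    sample_volume(ph$le, thr)
  }, numeric(1))
  s <- relative_volume_series(
    data.frame(time_min = c(0, 30, 60), volume_um3 = vols))
  expect_equal(s$relative_volume[2], 0.80, tolerance = 0.02)
  expect_equal(s$relative_volume[3], 0.80, tolerance = 0.02)
})

test_that("mean attenuation: exact cases and monotone staining series", {
  v <- attenuation_volume(array(0.4, c(8, 8, 8)), 5)
  m <- array(TRUE, c(8, 8, 8))
  expect_identical(mean_attenuation(v, m), 0.4)
  v$data[1:4, , ] <- 0.2
  expect_equal(mean_attenuation(v, m), 0.3)
  expect_error(mean_attenuation(v, array(FALSE, c(8, 8, 8))), "empty")
  cs <- iodine_cs()
  spec <- unit_sum_spec()
  means <- vapply(c(0, 30, 60), function(t) {
    ph <- make_organ_phantom(spec, cs, t)
    mean_attenuation(ph$le, ph$truth$organ_mask)
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("correlation histogram conserves counts and localises phases", {
  cs <- iodine_cs()
  d <- c(16, 16, 16)
  const_le <- attenuation_volume(array(0.2, d), 5)
  const_he <- attenuation_volume(array(0.1, d), 5)
  h <- correlation_histogram2d(const_le, const_he, n_bins = 32)
  expect_equal(sum(h$counts), prod(d))
  expect_identical(sum(h$counts > 0), 1L)
  # conservation on arbitrary data and masks
  ph <- make_calibration_phantom(
    calibration_phantom_geometry(shape = c(32, 32, 16)), cs,
    noise_spec(sigma = 0.004, seed = 3))
  mask <- array(c(TRUE, FALSE), dim(ph$labels))
  h2 <- correlation_histogram2d(ph$le, ph$he, mask = mask)
  expect_identical(sum(h2$counts), sum(mask))
  # air + PMMA two-phase phantom: two clusters near the basis pairs
  two <- ph
  keep <- ph$labels != 2L
  h3 <- correlation_histogram2d(two$le, two$he, mask = keep, n_bins = 64)
  df <- tidy_histogram(h3)
  near <- function(pt) {
    w <- df$count * (abs(df$mu_le - pt[1]) < 0.02)
    c(sum(w * df$mu_le) / sum(w), sum(w * df$mu_he) / sum(w))
  }
  sd_bound <- 3 * 0.004 / sqrt(min(sum(ph$labels == 0), sum(ph$labels == 1)))
  bin_w <- max(diff(h3$edges_le)[1], diff(h3$edges_he)[1])
  expect_lt(max(abs(near(cs$air) - cs$air)), sd_bound + bin_w)
  expect_lt(max(abs(near(cs$pmma) - cs$pmma)), sd_bound + bin_w)
  expect_error(correlation_histogram2d(const_le, const_he,
                                       edges_le = c(0, 0, 1)), "increasing")
})

test_that("uptake summary reports per-tissue statistics and empty labels", {
  cs <- iodine_cs()
  ph <- make_organ_phantom(unit_sum_spec(), cs, 60)
  fm <- decompose_volume(ph$le, ph$he, cs, mask = ph$truth$organ_mask)
  masks <- list(heart = ph$truth$heart_mask, lung = ph$truth$lung_mask)
  up <- uptake_summary(fm, masks, 60)
  expect_identical(up$tissue, c("heart", "lung"))
  expect_true(all(up$mean_f_stain <= up$max_f_stain))
  expect_identical(sum(up$n_voxels), sum(ph$truth$organ_mask))
  # constant-fraction region: mean equals max
  constm <- list(flat = ph$truth$depth == 1 & ph$truth$heart_mask)
  upc <- uptake_summary(fm, constm, 60)
  expect_equal(upc$mean_f_stain, upc$max_f_stain, tolerance = 1e-6)
  # an empty label is reported with zero count, not dropped
  withm <- c(masks, list(ghost = array(FALSE, dim(ph$truth$f_stain))))
  upg <- uptake_summary(fm, withm, 60)
  expect_identical(upg$n_voxels[upg$tissue == "ghost"], 0L)
  over <- list(a = masks$heart, b = masks$heart)
  expect_error(uptake_summary(fm, over, 60), "overlap")
})
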