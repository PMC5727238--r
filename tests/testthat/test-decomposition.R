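# The constrained voxel-wise decomposition: exactness on the basis span,
# agreement with a brute-force grid oracle, mode contracts and noise
# behaviour.

test_that("basis vertices and exact mixtures are recovered in all modes", {
  cs <- iodine_cs()
  for (mode in c("two_material", "three_material_soft",
                 "three_material_hard")) {
    res <- solve_voxel(cs$stain[1], cs$stain[2], cs, mode)
    expect_equal(unname(res$fractions), c(1, 0, 0), tolerance = 1e-9)
    expect_lt(res$residual, 1e-12)
    mix <- 0.3 * cs$stain + 0.7 * cs$pmma
    res2 <- solve_voxel(mix[1], mix[2], cs, mode)
    expect_equal(unname(res2$fractions), c(0.3, 0.7, 0), tolerance = 1e-9)
  }
})

test_that("solutions match the exhaustive grid-search oracle", {
  cs <- iodine_cs()
  B <- random_mu_pairs(60, cs, seed = 17)
  for (mode in c("three_material_soft", "three_material_hard")) {
    worst <- 0
    for (i in seq_len(nrow(B))) {
      f <- solve_voxel(B[i, 1], B[i, 2], cs, mode)$fractions
      g <- grid_oracle(B[i, ], cs, mode)
      worst <- max(worst, max(abs(unname(f) - g)))
    }
    expect_lt(worst, 2e-3)
  }
})

test_that("a voxel pushed off the constraint boundary stays non-negative", {
  cs <- iodine_cs()
  # perturbation that drives the unconstrained air fraction negative
  mix <- 0.9 * cs$stain + 0.3 * cs$pmma
  f <- solve_voxel(mix[1], mix[2], cs, "three_material_soft")$fractions
  expect_true(all(f >= 0))
  g <- grid_oracle(mix, cs, "three_material_soft")
  expect_lt(max(abs(unname(f) - g)), 2e-3)
})

test_that("noise-free span mixtures are recovered to 1e-6", {
  cs <- iodine_cs()
  A <- basis_matrix(cs)
  # tissue-like truths: stain + PMMA fill at most the voxel, air is the
  # complement (the near-zero air signature makes a free-floating air
  # fraction unidentifiable from attenuation alone, so sum-to-one truths
  # are the recoverable family)
  Fm <- withr::with_seed(3, {
    sp <- matrix(runif(2 * 200), 2)
    sp <- sweep(sp, 2, pmax(colSums(sp), 1), "/") *
      rep(runif(200, 0.6, 1), each = 2)
    rbind(sp, 1 - colSums(sp))
  })
  B <- A %*% Fm
  for (mode in c("three_material_soft", "three_material_hard")) {
    rec <- vapply(seq_len(ncol(B)), function(i) {
      solve_voxel(B[1, i], B[2, i], cs, mode)$fractions
    }, numeric(3))
    expect_lt(max(abs(rec - Fm)), 1e-6)
  }
})

test_that("soft mode reports fractions above unity where demanded", {
  cs <- iodine_cs()
  b <- 1.3 * cs$stain  # local accumulation at 1.3x the calibration solution
  f <- solve_voxel(b[1], b[2], cs, "three_material_soft")$fractions
  expect_gt(f[["stain"]], 1.2)
  # hard mode cannot: the simplex constraint caps the sum at one
  fh <- solve_voxel(b[1], b[2], cs, "three_material_hard")$fractions
  expect_lte(sum(fh), 1 + 1e-9)
})

test_that("soft-mode attenuation residual obeys the provable bound", {
  # J_soft(f_soft) <= J_soft(f_two) gives
  # soft_att^2 <= two_att^2 + s^2 (sum(f_two) - 1)^2
  cs <- iodine_cs()
  s <- mean(abs(basis_matrix(cs)))
  B <- random_mu_pairs(200, cs, seed = 23)
  for (i in seq_len(nrow(B))) {
    soft <- solve_voxel(B[i, 1], B[i, 2], cs, "three_material_soft")
    two <- solve_voxel(B[i, 1], B[i, 2], cs, "two_material")
    bound <- two$residual^2 + s^2 * (sum(two$fractions) - 1)^2
    expect_lte(soft$residual^2, bound + 1e-9)
  }
})

test_that("hard mode sums to one at every computed voxel", {
  cs <- iodine_cs()
  ph <- make_organ_phantom(unit_sum_spec(), cs, 60,
                           noise_spec(sigma = 0.01, seed = 31))
  fm <- decompose_volume(ph$le, ph$he, cs, mode = "three_material_hard")
  s <- fm$f_stain + fm$f_pmma + fm$f_air
  expect_lt(max(abs(s[fm$computed] - 1)), 1e-9)
  expect_true(all(fm$f_stain[fm$computed] >= 0))
})

test_that("volume decomposition matches per-voxel solves and masks out", {
  cs <- iodine_cs()
  ph <- make_organ_phantom(unit_sum_spec(), cs, 45,
                           noise_spec(sigma = 0.02, seed = 41))
  mask <- ph$truth$organ_mask
  fm <- decompose_volume(ph$le, ph$he, cs, mask = mask)
  expect_identical(sum(!is.nan(fm$f_stain)), sum(mask))
  expect_true(all(is.nan(fm$f_stain[!mask])))
  idx <- withr::with_seed(5, sample(which(mask), 25))
  for (i in idx) {
    sv <- solve_voxel(ph$le$data[i], ph$he$data[i], cs)
    expect_equal(fm$f_stain[i], sv$fractions[["stain"]], tolerance = 1e-12)
    expect_equal(fm$residual[i], sv$residual, tolerance = 1e-12)
  }
  expect_error(decompose_volume(ph$le, attenuation_volume(
    array(0, c(8, 8, 8)), 20), cs), "identical dimensions")
})

test_that("noise-free organ decomposition is exact; error grows with noise", {
  cs <- iodine_cs()
  spec <- unit_sum_spec()
  ph0 <- make_organ_phantom(spec, cs, 60)
  fm0 <- decompose_volume(ph0$le, ph0$he, cs, mode = "three_material_soft")
  expect_lt(max(abs(fm0$f_stain - ph0$truth$f_stain)), 1e-6)
  rmse <- vapply(c(0.01, 0.02, 0.05, 0.10), function(fr) {
    ph <- make_organ_phantom(spec, cs, 60,
                             noise_spec(sigma = fr * cs$stain[1], seed = 19))
    fm <- decompose_volume(ph$le, ph$he, cs, mode = "three_material_soft")
    m <- ph$truth$organ_mask
    sqrt(mean((fm$f_stain[m] - ph$truth$f_stain[m])^2))
  }, numeric(1))
  expect_true(all(diff(rmse) > 0))
})

test_that("negative attenuation inputs are accepted, fractions stay >= 0", {
  cs <- iodine_cs()
  f <- solve_voxel(-0.02, -0.01, cs, "three_material_soft")$fractions
  expect_true(all(f >= 0))
})
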