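# Generator properties: the diffusion profile, exact basis mixtures,
# determinism, shrinkage volumetrics, cupping and misalignment plumbing.

test_that("diffusion profile follows the half-space erfc solution", {
  expect_identical(diffusion_profile(5, D = 3, t = 0, f_surface = 1), 0)
  expect_identical(diffusion_profile(0, D = 1, t = 10, f_surface = 1), 1)
  # depth = 2*sqrt(D*t) puts the argument at 1: erfc(1)
  expect_equal(diffusion_profile(2, D = 1, t = 1, f_surface = 1), 0.1572992,
               tolerance = 1e-6)
  expect_equal(diffusion_profile(2, D = 1, t = 1, f_surface = 1),
               pracma::erfc(1), tolerance = 1e-12)
  # cap applies, including at the surface
  expect_equal(diffusion_profile(0, D = 1, t = 5, f_surface = 1.5,
                                 f_max = 1.3), 1.3)
  expect_error(diffusion_profile(-1, 1, 1, 1), "non-negative")
  expect_error(diffusion_profile(1, 1, -1, 1), "non-negative")
})

test_that("diffusion profile is monotone in time and depth", {
  depths <- c(1, 3, 7, 12)
  times <- c(0, 10, 30, 60, 120, 360)
  for (d in depths) {
    f <- vapply(times, function(t) diffusion_profile(d, 1.5, t, 1), numeric(1))
    expect_true(all(diff(f) >= 0))
  }
  prof <- diffusion_profile(0:15, 1.5, 60, 1)
  expect_true(all(diff(prof) <= 0))
})

test_that("calibration phantom voxels carry exact basis values", {
  cs <- iodine_cs()
  geom <- calibration_phantom_geometry(shape = c(32, 32, 12))
  ph <- make_calibration_phantom(geom, cs)
  expect_true(all(ph$le$data[ph$labels == 1L] == cs$pmma[1]))
  expect_true(all(ph$he$data[ph$labels == 2L] == cs$stain[2]))
  expect_true(all(ph$le$data[ph$labels == 0L] == cs$air[1]))
  # determinism: same seed, bit-identical
  n1 <- make_calibration_phantom(geom, cs, noise_spec(sigma = 0.01, seed = 5))
  n2 <- make_calibration_phantom(geom, cs, noise_spec(sigma = 0.01, seed = 5))
  expect_identical(n1$le$data, n2$le$data)
  expect_identical(n1$he$data, n2$he$data)
  # CLT bound on the stain-region mean
  nvox <- sum(ph$labels == 2L)
  expect_lt(abs(mean(n1$le$data[ph$labels == 2L]) - cs$stain[1]),
            4 * 0.01 / sqrt(nvox))
})

test_that("calibration phantom geometry is validated", {
  cs <- iodine_cs()
  geom <- calibration_phantom_geometry(shape = c(32, 32, 12),
                                       rod_center = c(10, 16),
                                       tube_center = c(14, 16),
                                       rod_radius = 5, tube_radius = 4)
  expect_error(make_calibration_phantom(geom, cs), "overlap")
  geom2 <- calibration_phantom_geometry(shape = c(32, 32, 12),
                                        rod_center = c(3, 16), rod_radius = 6)
  expect_error(make_calibration_phantom(geom2, cs), "fit inside")
})

test_that("organ phantom is an exact basis mixture with consistent truth", {
  cs <- iodine_cs()
  ph <- make_organ_phantom(unit_sum_spec(), cs, t_min = 60)
  A <- basis_matrix(cs)
  le <- A[1, 1] * ph$truth$f_stain + A[1, 2] * ph$truth$f_pmma +
    A[1, 3] * ph$truth$f_air
  he <- A[2, 1] * ph$truth$f_stain + A[2, 2] * ph$truth$f_pmma +
    A[2, 3] * ph$truth$f_air
  scale <- max(abs(ph$le$data))
  expect_lt(max(abs(le - ph$le$data)) / scale, 1e-12)
  expect_lt(max(abs(he - ph$he$data)) / scale, 1e-12)
  # fraction bounds and compartment bookkeeping
  expect_true(all(ph$truth$f_pmma >= 0 & ph$truth$f_pmma <= 1))
  expect_true(all(ph$truth$f_air %in% c(0, 1)))
  expect_true(all(ph$truth$f_stain >= 0))
  expect_false(any(ph$truth$heart_mask & ph$truth$lung_mask))
  expect_true(all((ph$truth$heart_mask | ph$truth$lung_mask) ==
                    ph$truth$organ_mask))
  # conservation: PMMA + air + capped stain never exceeds unity
  capped <- pmin(ph$truth$f_stain, 1)
  expect_true(all(ph$truth$f_pmma + ph$truth$f_air + capped <= 1 + 1e-12))
})

test_that("no staining at t = 0 and saturation at long times", {
  cs <- iodine_cs()
  ph0 <- make_organ_phantom(unit_sum_spec(), cs, t_min = 0)
  expect_true(all(ph0$truth$f_stain == 0))
  expect_true(all(ph0$le$data[ph0$truth$organ_mask] == cs$pmma[1]))
  # t large: interior approaches the saturation value
  ph_inf <- make_organ_phantom(unit_sum_spec(), cs, t_min = 1e6)
  interior <- ph_inf$truth$heart_mask & ph_inf$truth$depth > 3
  expect_gt(min(ph_inf$truth$f_stain[interior]), 0.99)
})

test_that("stain uptake is monotone in staining time", {
  cs <- iodine_cs()
  spec <- unit_sum_spec()
  maps <- lapply(c(0, 30, 60, 120), function(t) {
    make_organ_phantom(spec, cs, t)$truth$f_stain
  })
  for (k in 2:length(maps)) {
    expect_true(all(maps[[k]] - maps[[k - 1]] >= -1e-12))
  }
})

test_that("faster diffusion gives higher compartment uptake", {
  cs <- iodine_cs()
  spec <- organ_phantom_spec(shape = c(32, 32, 32),
                             organ_semiaxes = c(12, 10, 8),
                             D = c(heart = 4, lung = 0.25),
                             f_surface = c(heart = 1, lung = 1),
                             f_max = c(heart = 1, lung = 1))
  for (t in c(30, 60, 120)) {
    tr <- make_organ_phantom(spec, cs, t)$truth
    expect_gt(mean(tr$f_stain[tr$heart_mask]), mean(tr$f_stain[tr$lung_mask]))
  }
})

test_that("shrinkage scales rasterized volume by the programmed ratio", {
  spec <- organ_phantom_spec()
  expect_equal(apply_shrinkage(spec, 1)$organ_semiaxes, spec$organ_semiaxes)
  count <- function(sp) sum(dectmix:::rasterize_organ(sp)$organ)
  v0 <- count(spec)
  expect_equal(count(apply_shrinkage(spec, 0.8)) / v0, 0.80, tolerance = 0.02)
  twice <- apply_shrinkage(apply_shrinkage(spec, 0.9), 0.9)
  expect_equal(count(twice) / v0, 0.81, tolerance = 0.02)
  expect_identical(twice$shrinkage_history, c(0.9, 0.9))
  expect_error(apply_shrinkage(spec, 0), "ratio")
  expect_error(apply_shrinkage(spec, 1.5), "ratio")
})

test_that("organ phantom generation is deterministic given a seed", {
  cs <- iodine_cs()
  spec <- unit_sum_spec()
  a <- make_organ_phantom(spec, cs, 60, noise_spec(sigma = 0.01, seed = 3))
  b <- make_organ_phantom(spec, cs, 60, noise_spec(sigma = 0.01, seed = 3))
  expect_identical(a$le$data, b$le$data)
  expect_identical(a$he$data, b$he$data)
  c <- make_organ_phantom(spec, cs, 60, noise_spec(sigma = 0.01, seed = 4))
  expect_false(identical(a$le$data, c$le$data))
})

test_that("rigid resampling: identity, lattice shifts, round trips", {
  cs <- iodine_cs()
  ph <- make_organ_phantom(unit_sum_spec(), cs, 60)
  v <- ph$le
  expect_identical(apply_rigid_transform(v, rigid_transform())$data, v$data)
  # integer translation equals an index shift on the overlap
  sh <- apply_rigid_transform(v, rigid_transform(c(3, 0, 0)), fill = -99)
  expect_equal(sh$data[4:32, , ], v$data[1:29, , ])
  expect_true(all(sh$data[1:3, , ] == -99))
  # tf then its inverse recovers a smooth field away from the borders
  # (trilinear interpolation error scales with curvature, so the bound is
  # checked on a smooth blob rather than a discontinuous phantom)
  g <- dectmix:::voxel_grid(c(32, 32, 32))
  blob <- array(0.5 * exp(-rowSums(sweep(g, 2, c(16.5, 16.5, 16.5))^2) / 72),
                c(32, 32, 32))
  vb <- attenuation_volume(blob, 20)
  tf <- rigid_transform(c(1.5, -2.25, 0.75), c(3, -2, 1.5))
  M <- solve(dectmix:::transform_matrix(tf, dim(vb$data)))
  inv <- rigid_transform(M[1:3, 4] + M[1:3, 1:3] %*% ((dim(vb$data) + 1) / 2) -
                           (dim(vb$data) + 1) / 2,
                         dectmix:::euler_from_rotation(M[1:3, 1:3]))
  back <- apply_rigid_transform(
    apply_rigid_transform(vb, tf, fill = NA), inv, fill = NA)
  core <- array(FALSE, dim(vb$data)); core[8:25, 8:25, 8:25] <- TRUE
  ok <- core & !is.na(back$data)
  dyn <- diff(range(vb$data))
  expect_lt(max(abs(back$data[ok] - vb$data[ok])), 0.05 * dyn)
})

test_that("cupping bias has the programmed radial form", {
  v <- attenuation_volume(array(1, c(21, 21, 21)), 10)
  expect_identical(add_cupping_bias(v, 0)$data, v$data)
  b <- add_cupping_bias(v, 0.1)
  expect_equal(b$data[11, 11, 11], 1 - 0.1, tolerance = 1e-12)
  # radial mean profile increases outward on a constant volume
  g <- dectmix:::voxel_grid(dim(v$data))
  r <- round(sqrt(rowSums(sweep(g, 2, c(11, 11, 11))^2)))
  prof <- tapply(as.vector(b$data), r, mean)[1:10]
  expect_true(all(diff(prof) > 0))
  expect_error(add_cupping_bias(v, 1.2), "beta")
})
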