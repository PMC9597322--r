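# Synthetic phantom generator: geometry, truth bookkeeping, determinism.

test_that("rendered sphere volume matches the lattice-count oracle exactly", {
  sp <- phantom_spec(voi_shape = c(24L, 24L, 24L), nodule_radii = c(5, 5, 5),
                     background_noise_sd = 0, edge_softness = 0)
  ph <- render_phantom(sp)
  oracle <- oracle_ellipsoid_voxels(c(24, 24, 24), c(1, 1, 1),
                                    sp$nodule_center, c(5, 5, 5))
  expect_identical(ph$truth$n_voxels, oracle)
  expect_equal(ph$truth$volume_mm3, oracle * 1)
  # and is within 5% of the analytic ellipsoid volume at this resolution
  expect_lt(abs(ph$truth$volume_mm3 - 4 / 3 * pi * 125) / (4 / 3 * pi * 125),
            0.06)
})

test_that("air-density nodule has zero mass; truth mass identity always holds", {
  sp <- phantom_spec(voi_shape = c(20L, 20L, 20L), nodule_radii = c(4, 4, 4),
                     background_hu = -1000.0001, nodule_mean_hu = -1000,
                     background_noise_sd = 0, edge_softness = 0)
  ph <- render_phantom(sp)
  expect_equal(ph$truth$mass_mg, 0)
  for (seed in 1:5) {
    sp2 <- phantom_spec(nodule_radii = runif(3, 3, 8), seed = seed,
                        nodule_mean_hu = runif(1, -700, -500),
                        edge_softness = runif(1, 0, 1.5))
    ph2 <- render_phantom(sp2)
    expect_equal(ph2$truth$mass_mg,
                 ph2$truth$volume_mm3 * (ph2$truth$mean_hu + 1000) / 1000,
                 tolerance = 1e-14)
  }
})

test_that("rendering is deterministic in the seed", {
  sp <- phantom_spec(seed = 77L)
  a <- render_phantom(sp)
  b <- render_phantom(sp)
  expect_identical(a$grid$values, b$grid$values)
  sp2 <- phantom_spec(seed = 78L)
  expect_false(identical(render_phantom(sp2)$grid$values, a$grid$values))
})

test_that("nodules that stick out of the VOI raise an axis-named error", {
  expect_error(render_phantom(
    phantom_spec(voi_shape = c(10L, 48L, 48L), nodule_radii = c(8, 8, 8),
                 edge_softness = 0)), "z axis")
  expect_error(phantom_spec(nodule_radii = c(1, 1, 1)), "\\[5, 30\\]")
  expect_error(phantom_spec(nodule_radii = c(16, 8, 8)), "\\[5, 30\\]")
  expect_error(phantom_spec(nodule_mean_hu = -900), "exceed")
})

test_that("trajectories follow the stated kinetics", {
  sp <- phantom_spec(voi_shape = c(40L, 40L, 40L), nodule_radii = c(5, 5, 5),
                     background_noise_sd = 0, edge_softness = 0)
  # no growth: identical truth at all time points
  tr0 <- simulate_trajectory(sp, growth_kinetics(1, 0, c(365, 365)))
  expect_equal(tr0[[1]]$truth$mass_mg, tr0[[2]]$truth$mass_mg)
  expect_equal(tr0[[2]]$truth$mass_mg, tr0[[3]]$truth$mass_mg)
  expect_equal(tr0[[3]]$truth$annualized_mass_rate, 0)
  # radius scale 2^(1/3) per year, one year: volume and mass double
  # (up to voxelisation of the truth masks; density is unchanged, so the
  # mass ratio equals the volume ratio exactly)
  tr2 <- simulate_trajectory(sp, growth_kinetics(2^(1 / 3), 0, 365))
  vol_ratio <- tr2[[2]]$truth$volume_mm3 / tr2[[1]]$truth$volume_mm3
  expect_equal(vol_ratio, 2, tolerance = 0.05)
  expect_equal(tr2[[2]]$truth$mass_mg / tr2[[1]]$truth$mass_mg, vol_ratio,
               tolerance = 1e-12)
  # mixed size + attenuation growth: closed-form mass ratio
  sp2 <- phantom_spec(voi_shape = c(40L, 40L, 40L), nodule_radii = c(6, 6, 6),
                      nodule_mean_hu = -650, background_noise_sd = 0,
                      edge_softness = 0)
  tr3 <- simulate_trajectory(sp2, growth_kinetics(1.05, 40, 365))
  expected <- 1.05^3 * (-650 + 40 + 1000) / (-650 + 1000)
  expect_equal(tr3[[2]]$truth$mass_mg / tr3[[1]]$truth$mass_mg, expected,
               tolerance = 0.02)
})

test_that("trajectory offsets are recorded and growth beyond the VOI errors", {
  sp <- phantom_spec(voi_shape = c(40L, 40L, 40L), nodule_radii = c(5, 5, 5),
                     edge_softness = 0)
  tr <- simulate_trajectory(sp, growth_kinetics(1, 0, 365, jitter_mm = 2))
  expect_identical(tr[[1]]$offset_mm, c(0, 0, 0))
  expect_true(all(abs(tr[[2]]$offset_mm) <= 2))
  expect_true(any(tr[[2]]$offset_mm != 0))
  sp_small <- phantom_spec(voi_shape = c(24L, 24L, 24L),
                           nodule_radii = c(10, 10, 10), edge_softness = 0)
  expect_error(simulate_trajectory(sp_small, growth_kinetics(1.5, 0, 730)),
               "beyond the VOI")
})

test_that("generate_cohort is stratified, consistent and seed-deterministic", {
  coh <- generate_cohort(20, growth_fraction = 0.5, seed = 5L, noise_sd = 0)
  expect_identical(sum(coh$manifest$growth_label), 10L)
  # growth labels hold exactly by construction (truth masses, 0.25 rule)
  expect_identical(coh$manifest$growth_label, coh$manifest$y >= 0.25)
  coh2 <- generate_cohort(20, growth_fraction = 0.5, seed = 5L, noise_sd = 0)
  expect_identical(coh$manifest, coh2$manifest)
  expect_identical(coh$examples[[3]]$current_voi$values,
                   coh2$examples[[3]]$current_voi$values)
  expect_error(generate_cohort(0), "n must be")
})

test_that("cohort files round-trip through NIfTI with manifest intact", {
  dir <- withr::local_tempdir()
  coh <- generate_cohort(4, growth_fraction = 0.5, seed = 9L, out_dir = dir)
  man <- utils::read.csv(file.path(dir, "manifest.csv"))
  expect_identical(nrow(man), 4L)
  g <- read_nifti(man$current_path[1])
  expect_equal(g$values, coh$examples[[1]]$current_voi$values,
               tolerance = 1e-6)   # float32 storage
  mk <- read_nifti_mask(man$mask_path[1])
  expect_identical(mk$mask, coh$examples[[1]]$current_mask$mask)
})
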