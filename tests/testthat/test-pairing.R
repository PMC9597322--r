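# Registration, nodule pairing and VOI extraction.

test_that("registering a volume onto itself gives the identity", {
  ph <- fixture_phantom(noise = 20, seed = 3L)
  tr <- register_rigid(ph$grid, ph$grid)
  expect_lt(sqrt(sum(tr$translation_mm^2)), 0.1)
  expect_identical(tr$rotation, diag(3))
})

test_that("known integer and sub-voxel shifts are recovered within 0.5 voxel", {
  set.seed(12)
  for (k in 1:8) {
    # fixed and moving scans carry independent noise fields
    sp_f <- phantom_spec(voi_shape = c(40L, 40L, 40L),
                         nodule_radii = c(5, 5, 5),
                         background_noise_sd = 10, seed = 12L + 2L * k)
    sp_m <- phantom_spec(voi_shape = c(40L, 40L, 40L),
                         nodule_radii = c(5, 5, 5),
                         background_noise_sd = 10, seed = 13L + 2L * k)
    off <- sample(-4:4, 3, replace = TRUE)
    fixed <- render_phantom(sp_f)
    moving <- render_phantom(sp_m, center = sp_m$nodule_center - off)
    tr <- register_rigid(moving$grid, fixed$grid)
    expect_lt(max(abs(tr$translation_mm - off)), 0.5)
  }
})

test_that("degenerate registration inputs error instead of guessing", {
  set.seed(5)
  a <- voxel_grid(array(rnorm(27e3, -850, 30), c(30, 30, 30)))
  b <- voxel_grid(array(rnorm(27e3, -850, 30), c(30, 30, 30)))
  expect_error(register_rigid(a, b), "registration failed|degenerate")
  flat <- voxel_grid(array(-850, c(30, 30, 30)))
  expect_error(register_rigid(flat, flat), "degenerate")
  small <- voxel_grid(array(-850, c(10, 10, 10)))
  expect_error(register_rigid(small, a), "share shape")
})

test_that("mutual-nearest-neighbour pairing follows its contract", {
  # one lesion each side, 2 mm apart: matched
  r <- pair_nodules(matrix(c(10, 10, 10), 1), matrix(c(10, 10, 12), 1))
  expect_identical(nrow(r$matches), 1L)
  expect_equal(r$matches$dist_mm, 2)
  # two priors near one current: only the mutual nearest pair matches
  r2 <- pair_nodules(rbind(c(10, 10, 10), c(10, 10, 14)),
                     matrix(c(10, 10, 11), 1))
  expect_identical(r2$matches$prior, 1L)
  expect_identical(r2$unmatched_prior, 2L)
  # beyond the gate: no match
  r3 <- pair_nodules(matrix(c(0, 0, 0), 1), matrix(c(0, 0, 20), 1))
  expect_identical(nrow(r3$matches), 0L)
  # empty inputs allowed
  r4 <- pair_nodules(NULL, matrix(c(1, 2, 3), 1))
  expect_identical(nrow(r4$matches), 0L)
  expect_identical(r4$unmatched_current, 1L)
})

test_that("pairing is symmetric and matches the exhaustive assignment oracle", {
  set.seed(21)
  for (k in 1:30) {
    # 5 well-separated lesions; current = permuted priors + small offsets
    pm <- matrix(runif(15, 0, 100), 5, 3)
    while (min(stats::dist(pm)) < 25) pm <- matrix(runif(15, 0, 100), 5, 3)
    perm <- sample(5)
    cm <- pm[perm, ] + matrix(runif(15, -2, 2), 5, 3)
    res <- pair_nodules(pm, cm, gate_mm = 10)
    oracle <- oracle_assignment(pm, cm, gate = 10)
    got <- as.matrix(res$matches[order(res$matches$prior), c("prior", "current")])
    expect_equal(unname(got), unname(oracle))
    # symmetry: swapping the lists transposes the matching
    swapped <- pair_nodules(cm, pm, gate_mm = 10)
    expect_equal(unname(as.matrix(swapped$matches[order(swapped$matches$current),
                                                  c("current", "prior")])),
                 unname(got))
  }
})

test_that("extract_voi pads with -1000 and preserves contained nodules", {
  ph <- fixture_phantom(radii = c(5, 5, 5), shape = c(40L, 40L, 40L),
                        softness = 0)
  ctr <- ssngrowth:::mask_centroid(ph$mask)
  voi <- extract_voi(ph$grid, ctr, 24L)
  expect_identical(dim(voi$values), rep(24L, 3))
  expect_gt(voi$values[12, 12, 12], -700)       # centre voxel is lesion
  # near-edge extraction keeps exact size, padding -1000
  voi_edge <- extract_voi(ph$grid, c(2, 2, 2), 24L)
  expect_identical(dim(voi_edge$values), rep(24L, 3))
  expect_equal(voi_edge$values[1, 1, 1], -1000)
  expect_error(extract_voi(ph$grid, c(-30, 0, 0), 24L), "outside")
  # volume-preserving: VOI-measured volume within 5% of full-grid volume
  mvoi <- extract_voi_mask(ph$mask, ctr, 24L)
  m_full <- measure(ph$grid, ph$mask)
  m_voi <- measure(voi, mvoi)
  expect_lt(abs(m_voi$volume_mm3 - m_full$volume_mm3) / m_full$volume_mm3,
            0.05)
  expect_lt(abs(m_voi$mass_mg - m_full$mass_mg) / m_full$mass_mg, 0.05)
})

test_that("the fixture segmenter recovers a phantom mask well", {
  ph <- fixture_phantom(radii = c(6, 6, 6), shape = c(40L, 40L, 40L),
                        noise = 25, softness = 0.8, seed = 8L)
  seg <- segment_phantom(ph$grid)
  inter <- sum(seg$mask & ph$mask$mask)
  dice <- 2 * inter / (sum(seg$mask) + sum(ph$mask$mask))
  expect_gt(dice, 0.85)
})
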