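# Mask-based measurement: diameter / volume / mass, rates, doubling times.

test_that("axis-aligned cuboid measures exactly by the direct formulas", {
  g <- voxel_grid(array(-600, c(4, 6, 10)))          # z=4, y=6, x=10
  mk <- nodule_mask(array(TRUE, c(4, 6, 10)), grid = g)
  m <- measure(g, mk)
  expect_equal(m$volume_mm3, 240)
  expect_equal(m$mean_hu, -600)
  expect_equal(m$mass_mg, 96)
  expect_equal(m$diameter_mm, 10)
})

test_that("single voxel follows the one-voxel-side convention", {
  g <- voxel_grid(array(-500, c(3, 3, 3)))
  a <- array(FALSE, c(3, 3, 3)); a[2, 2, 2] <- TRUE
  m <- measure(g, nodule_mask(a, grid = g))
  expect_equal(m$volume_mm3, 1)
  expect_equal(m$diameter_mm, 1)
  # anisotropic in-plane spacing: longest rectangle side is the larger pitch
  g2 <- voxel_grid(array(-500, c(3, 3, 3)), spacing = c(1, 0.5, 0.7))
  m2 <- measure(g2, nodule_mask(a, spacing = c(1, 0.5, 0.7)))
  expect_equal(m2$diameter_mm, 0.7)
  expect_equal(m2$volume_mm3, 0.35)
})

test_that("empty masks and misaligned shapes are rejected", {
  g <- voxel_grid(array(-500, c(3, 3, 3)))
  expect_error(measure(g, nodule_mask(array(FALSE, c(3, 3, 3)), grid = g)),
               "empty")
  expect_error(measure(g, nodule_mask(array(TRUE, c(3, 3, 4)))), "match")
})

test_that("rotated-slab diameters match the rotating-calipers oracle", {
  set.seed(42)
  for (k in 1:25) {
    # a rotated rectangular slab rasterised into one slice
    ang <- runif(1, 0, pi / 2)
    L <- runif(1, 6, 14); W <- runif(1, 2, 5)
    n <- 40L
    sl <- matrix(FALSE, n, n)
    cy <- runif(1, 16, 24); cx <- runif(1, 16, 24)
    for (j in 1:n) for (i in 1:n) {
      u <- (i - cx) * cos(ang) + (j - cy) * sin(ang)
      v <- -(i - cx) * sin(ang) + (j - cy) * cos(ang)
      sl[j, i] <- abs(u) <= L / 2 && abs(v) <= W / 2
    }
    if (sum(sl) < 4) next
    a <- array(FALSE, c(3, n, n)); a[2, , ] <- sl
    g <- voxel_grid(array(-600, c(3, n, n)))
    m <- measure(g, nodule_mask(a, grid = g))
    pts <- ssngrowth:::pixel_corners_mm(sl, c(1, 1))
    expect_equal(m$diameter_mm, oracle_min_rect_long_side(pts),
                 tolerance = 1e-9)
  }
})

test_that("mass identity and 90-degree rotation invariance hold on phantoms", {
  ph <- fixture_phantom(radii = c(5, 6, 4), softness = 0.8)
  m <- measure(ph$grid, ph$mask)
  expect_equal(m$mass_mg, m$volume_mm3 * (m$mean_hu + 1000) / 1000,
               tolerance = 1e-14)
  # rotate the grid 90 degrees in-plane (y <-> x): volume and diameter stable
  rot_vals <- aperm(ph$grid$values, c(1, 3, 2))
  rot_mask <- aperm(ph$mask$mask, c(1, 3, 2))
  g2 <- voxel_grid(rot_vals)
  m2 <- measure(g2, nodule_mask(rot_mask, grid = g2))
  expect_equal(m2$volume_mm3, m$volume_mm3)
  expect_equal(m2$diameter_mm, m$diameter_mm, tolerance = 1e-9)
  expect_equal(m2$mass_mg, m$mass_mg, tolerance = 1e-10)
})

test_that("measured mass equals phantom truth exactly on noiseless phantoms", {
  for (seed in 1:6) {
    set.seed(seed)
    ph <- fixture_phantom(radii = runif(3, 3.5, 7), hu = runif(1, -700, -500),
                          softness = runif(1, 0, 1.2), seed = seed)
    m <- measure(ph$grid, ph$mask)
    expect_identical(m$volume_mm3, ph$truth$volume_mm3)
    expect_equal(m$mass_mg, ph$truth$mass_mg, tolerance = 1e-13)
  }
})

test_that("increase_rate follows (curr - prev)/prev including shrinkage", {
  expect_equal(increase_rate(100, 174), 0.74)
  expect_equal(increase_rate(55, 55), 0)
  expect_equal(increase_rate(200, 150), -0.25)
  expect_error(increase_rate(0, 10), "> 0")
  ph <- fixture_phantom()
  m <- measure(ph$grid, ph$mask)
  expect_equal(increase_rate(m, m, "volume"), 0)
})

test_that("doubling_time matches the closed form and flags non-growth", {
  expect_equal(doubling_time(100, 200, 365), 365)
  expect_equal(doubling_time(100, 130, 300), 300 * log(2) / log(1.3))
  expect_true(is.na(doubling_time(100, 90, 365)))
  expect_true(is.na(doubling_time(100, 100, 365)))
  expect_error(doubling_time(100, 110, 0), "dt_days")
  expect_error(doubling_time(-1, 110, 10), "> 0")
  # scale invariance: DT(kX1, kX2) = DT(X1, X2)
  set.seed(1)
  for (i in 1:20) {
    x1 <- runif(1, 10, 100); x2 <- x1 * runif(1, 1.01, 3)
    dt <- runif(1, 30, 900); k <- runif(1, 0.1, 50)
    expect_equal(doubling_time(k * x1, k * x2, dt), doubling_time(x1, x2, dt),
                 tolerance = 1e-10)
  }
})

test_that("summarize_cohort clips doubling times and compares groups", {
  mk_rec <- function(m1, m2, dt) {
    a <- structure(list(diameter_mm = m1^(1 / 3), volume_mm3 = m1,
                        mean_hu = -500, mass_mg = m1),
                   class = "nodule_measurement")
    b <- structure(list(diameter_mm = m2^(1 / 3), volume_mm3 = m2,
                        mean_hu = -500, mass_mg = m2),
                   class = "nodule_measurement")
    growth_record(a, b, dt)
  }
  # identical groups: all P-values 1
  recs <- rbind(mk_rec(100, 130, 365), mk_rec(100, 150, 365),
                mk_rec(100, 130, 365), mk_rec(100, 150, 365))
  s <- summarize_cohort(recs, c("a", "a", "b", "b"))
  expect_true(all(s$p_rate[!is.na(s$p_rate)] == 1))
  # a DT = 1500 d record is excluded from quartiles but kept in rates
  slow <- mk_rec(100, 100 * 2^(365 / 1500), 365)   # DT exactly 1500 d
  expect_equal(slow$dt_mass, 1500, tolerance = 1e-9)
  recs2 <- rbind(mk_rec(100, 200, 365), mk_rec(100, 180, 365), slow)
  s2 <- summarize_cohort(recs2, rep("g", 3))
  expect_identical(s2$dt_n[s2$metric == "mass"], 2L)
  expect_identical(s2$n[s2$metric == "mass"], 3L)
  expect_error(summarize_cohort(recs2, c("g", "g", "h")), "fewer than 2")
})

test_that("cohort summary medians recover generating doubling times", {
  # two groups with mass doubling times near 490 d and 620 d
  set.seed(7)
  n <- 120
  mk <- function(dt_med) {
    dts <- exp(rnorm(n, log(dt_med), 0.15))
    m2 <- 100 * 2^(365 / dts)
    data.frame(rate_diameter = 0, rate_volume = 0, rate_mass = m2 / 100 - 1,
               dt_diameter = NA_real_, dt_volume = NA_real_, dt_mass = dts,
               dt_days = 365, y = m2 / 100 - 1, growth_label = TRUE)
  }
  recs <- rbind(mk(490), mk(620))
  s <- summarize_cohort(recs, rep(c("cancer", "noncancer"), each = n))
  med_c <- s$dt_median[s$metric == "mass" & s$group == "cancer"]
  med_n <- s$dt_median[s$metric == "mass" & s$group == "noncancer"]
  expect_lt(abs(med_c - 490) / 490, 0.1)
  expect_lt(abs(med_n - 620) / 620, 0.1)
  expect_lt(s$p_dt[s$metric == "mass"][1], 0.001)
})
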