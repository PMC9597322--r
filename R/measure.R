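# Mask-based nodule quantification.
#
# Three measurements are supported, following standard CT volumetry:
#   diameter — longest side (mm) of the minimum-area rotated rectangle
#              circumscribing the mask foreground on the axial slice with
#              maximal foreground area (ties: lowest slice index);
#   volume   — foreground voxel count times the single-voxel volume (mm^3);
#   mass     — M = V * (A + 1000) / 1000 (mg), A the mean HU under the mask.
# The rectangle is computed on the convex hull of the foreground voxels'
# outer corners (not centres), so a single voxel has diameter equal to one
# in-plane spacing and an axis-aligned cuboid measures exactly its edge.

#' Measure diameter, volume, mean attenuation and mass of a nodule
#'
#' @param voi a [voxel_grid] of HU values.
#' @param mask a [nodule_mask] aligned to `voi` (same shape and spacing).
#' @return A `nodule_measurement`: list with `diameter_mm`, `volume_mm3`,
#'   `mean_hu`, `mass_mg`, `n_voxels` and `slice_index` (the axial slice the
#'   diameter was measured on).
#' @examples
#' g <- voxel_grid(array(-600, c(4, 6, 10)))
#' m <- nodule_mask(array(TRUE, c(4, 6, 10)), grid = g)
#' measure(g, m)$mass_mg   # 240 * ((-600 + 1000)/1000) = 96
#' @export
measure <- function(voi, mask) {
  stopifnot(inherits(voi, "voxel_grid"), inherits(mask, "nodule_mask"))
  check_aligned(voi, mask)
  fg <- mask$mask
  n_fg <- sum(fg)
  if (n_fg == 0L) stop("cannot measure an empty mask", call. = FALSE)
  vol <- n_fg * prod(voi$spacing)
  a <- mean(voi$values[fg])
  mass <- vol * (a + 1000) / 1000
  # axial slice (z) of maximal foreground area; which.max takes lowest tie
  per_slice <- apply(fg, 1, sum)
  zi <- which.max(per_slice)
  sl <- fg[zi, , , drop = TRUE]                 # (y, x)
  pts <- pixel_corners_mm(sl, voi$spacing[2:3])
  rect <- min_area_rect(pts)
  structure(list(diameter_mm = rect$long_side, volume_mm3 = vol,
                 mean_hu = a, mass_mg = mass, n_voxels = n_fg,
                 slice_index = zi),
            class = "nodule_measurement")
}

#' @export
print.nodule_measurement <- function(x, ...) {
  cat(sprintf("<nodule_measurement> d = %.2f mm, V = %.1f mm3, A = %.1f HU, M = %.2f mg\n",
              x$diameter_mm, x$volume_mm3, x$mean_hu, x$mass_mg))
  invisible(x)
}

# outer-corner points (mm) of foreground pixels of a 2D logical slice;
# columns (y, x); spacing = c(sy, sx)
pixel_corners_mm <- function(sl, spacing) {
  idx <- which(sl, arr.ind = TRUE)
  if (is.null(dim(idx))) idx <- matrix(idx, ncol = 2)
  cy <- (idx[, 1] - 1) * spacing[1]
  cx <- (idx[, 2] - 1) * spacing[2]
  hy <- spacing[1] / 2; hx <- spacing[2] / 2
  cbind(y = c(cy - hy, cy - hy, cy + hy, cy + hy),
        x = c(cx - hx, cx + hx, cx - hx, cx + hx))
}

#' Minimum-area circumscribed rectangle of a 2D point set
#'
#' Rotating-calipers search over convex-hull edges: the minimum-area
#' enclosing rectangle of a convex polygon has one side collinear with a
#' hull edge, so scanning edges is exact. Ties are broken by the first
#' (lowest-index) hull edge attaining the minimum.
#'
#' @param pts two-column matrix of points (mm).
#' @return list with `area`, `long_side`, `short_side`, `angle` (radians of
#'   the long side) and `corners` (4 x 2 matrix).
#' @export
min_area_rect <- function(pts) {
  pts <- unique(as.matrix(pts))
  if (nrow(pts) == 1L)
    return(list(area = 0, long_side = 0, short_side = 0, angle = 0,
                corners = pts[c(1, 1, 1, 1), , drop = FALSE]))
  h <- grDevices::chull(pts)
  hp <- pts[h, , drop = FALSE]
  nh <- nrow(hp)
  best <- NULL
  for (i in seq_len(nh)) {
    p1 <- hp[i, ]; p2 <- hp[if (i == nh) 1L else i + 1L, ]
    e <- p2 - p1
    len <- sqrt(sum(e^2))
    if (len < 1e-12) next
    u <- e / len
    v <- c(-u[2], u[1])
    pu <- hp %*% u
    pv <- hp %*% v
    du <- max(pu) - min(pu)
    dv <- max(pv) - min(pv)
    area <- du * dv
    if (is.null(best) || area < best$area - 1e-12) {
      c00 <- min(pu) * u + min(pv) * v
      best <- list(area = area, long_side = max(du, dv),
                   short_side = min(du, dv),
                   angle = if (du >= dv) atan2(u[2], u[1]) else atan2(v[2], v[1]),
                   corners = rbind(c00, c00 + du * u, c00 + du * u + dv * v,
                                   c00 + dv * v))
    }
  }
  best
}

# Welch t-test P that stays defined for (near-)constant samples: identical
# constant groups compare equal (P = 1), different constants unequal (P ~ 0).
welch_p <- function(a, b) {
  if (stats::sd(a) == 0 && stats::sd(b) == 0)
    return(if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0)
  stats::t.test(a, b)$p.value
}

metric_value <- function(x, metric) {
  if (inherits(x, "nodule_measurement"))
    x <- switch(metric, diameter = x$diameter_mm, volume = x$volume_mm3,
                mass = x$mass_mg,
                stop("unknown metric '", metric, "'", call. = FALSE))
  as.numeric(x)
}

#' Relative increase rate between two exams
#'
#' @param prev,curr `nodule_measurement`s or plain positive numbers.
#' @param metric one of "mass", "volume", "diameter" (ignored for numbers).
#' @return Dimensionless relative increase `(curr - prev) / prev`.
#' @export
increase_rate <- function(prev, curr, metric = "mass") {
  p <- metric_value(prev, metric); q <- metric_value(curr, metric)
  if (!is.finite(p) || p <= 0)
    stop("previous ", metric, " must be > 0", call. = FALSE)
  (q - p) / p
}

#' Doubling time of a growing measurement
#'
#' Assumes exponential growth: `DT = dt_days * log(2) / log(curr / prev)`.
#' When the metric did not strictly increase the doubling time is undefined
#' and `NA` is returned (an explicit flag, never infinity); cohort summaries
#' use only defined values within `[1, 1000]` days.
#'
#' @inheritParams increase_rate
#' @param dt_days inter-exam interval in days (> 0).
#' @return Days, or `NA` when `curr <= prev`.
#' @export
doubling_time <- function(prev, curr, dt_days, metric = "mass") {
  p <- metric_value(prev, metric); q <- metric_value(curr, metric)
  if (!is.finite(dt_days) || dt_days <= 0)
    stop("dt_days must be > 0", call. = FALSE)
  if (!is.finite(p) || !is.finite(q) || p <= 0 || q <= 0)
    stop("both measurements must be > 0", call. = FALSE)
  if (q <= p) return(NA_real_)
  dt_days * log(2) / log(q / p)
}

#' Build one growth record from two consecutive measurements
#'
#' @param prev,curr `nodule_measurement`s at T_{t-1} and T_t.
#' @param dt_days interval in days.
#' @return One-row data.frame with per-metric increase rates and doubling
#'   times, the annualised mass rate `y`, and the binary growth label.
#' @export
growth_record <- function(prev, curr, dt_days) {
  y <- annualized_mass_rate(prev$mass_mg, curr$mass_mg, dt_days)
  data.frame(
    rate_diameter = increase_rate(prev, curr, "diameter"),
    rate_volume = increase_rate(prev, curr, "volume"),
    rate_mass = increase_rate(prev, curr, "mass"),
    dt_diameter = doubling_time(prev, curr, dt_days, "diameter"),
    dt_volume = doubling_time(prev, curr, dt_days, "volume"),
    dt_mass = doubling_time(prev, curr, dt_days, "mass"),
    dt_days = dt_days,
    y = y,
    growth_label = growth_label(y))
}

#' Summarise growth records by group
#'
#' Mirrors the standard cohort table: per metric and group, mean +/- SD of
#' the relative increase rates and median (Q1, Q3) of the doubling times
#' restricted to `dt_clip` days (undefined doubling times are excluded from
#' the quartiles but their records still contribute to the rate rows).
#' With exactly two groups, two-sided Welch t-test P-values compare the
#' rates and the clipped doubling times between groups.
#'
#' @param records data.frame as produced by rbinding [growth_record()] rows.
#' @param groups factor/character vector, one group label per record.
#' @param dt_clip doubling-time inclusion window in days.
#' @return data.frame with one row per (metric, statistic, group) cell plus
#'   a `p_value` column on the first group's rows when two groups are given.
#' @export
summarize_cohort <- function(records, groups, dt_clip = c(1, 1000)) {
  groups <- as.character(groups)
  stopifnot(nrow(records) == length(groups))
  lv <- unique(groups)
  for (g in lv) if (sum(groups == g) < 2L)
    stop("group '", g, "' has fewer than 2 records", call. = FALSE)
  two <- length(lv) == 2L
  rows <- list()
  for (metric in c("diameter", "volume", "mass")) {
    rates <- records[[paste0("rate_", metric)]]
    dts <- records[[paste0("dt_", metric)]]
    keep <- !is.na(dts) & dts >= dt_clip[1] & dts <= dt_clip[2]
    p_rate <- p_dt <- NA_real_
    if (two) {
      p_rate <- welch_p(rates[groups == lv[1]], rates[groups == lv[2]])
      d1 <- dts[keep & groups == lv[1]]; d2 <- dts[keep & groups == lv[2]]
      if (length(d1) >= 2 && length(d2) >= 2) p_dt <- welch_p(d1, d2)
    }
    for (g in lv) {
      sel <- groups == g
      q <- if (any(keep & sel))
        stats::quantile(dts[keep & sel], c(0.25, 0.5, 0.75), names = FALSE)
      else rep(NA_real_, 3)
      rows[[length(rows) + 1L]] <- data.frame(
        metric = metric, group = g, n = sum(sel),
        rate_mean = mean(rates[sel]), rate_sd = stats::sd(rates[sel]),
        dt_n = sum(keep & sel),
        dt_median = q[2], dt_q1 = q[1], dt_q3 = q[3],
        p_rate = if (g == lv[1]) p_rate else NA_real_,
        p_dt = if (g == lv[1]) p_dt else NA_real_)
    }
  }
  do.call(rbind, rows)
}

#' Write per-nodule measurements to CSV
#'
#' @param measurements named list of `nodule_measurement` (names = ids).
#' @param path output CSV path.
#' @export
write_measurements_csv <- function(measurements, path) {
  df <- do.call(rbind, lapply(names(measurements), function(id) {
    m <- measurements[[id]]
    data.frame(id = id, diameter_mm = m$diameter_mm, volume_mm3 = m$volume_mm3,
               mean_hu = m$mean_hu, mass_mg = m$mass_mg)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
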