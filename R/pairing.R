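# Scan alignment and nodule pairing across time points.
#
# Registration is deliberately simple: consecutive thorax scans of the same
# subject are related by an approximately rigid transform, and at VOI scale
# a translation recovered by FFT cross-correlation with sub-voxel quadratic
# refinement is sufficient. Lesion correspondence uses mutual-nearest-
# neighbour matching of transformed centroids within a gating radius.

#' Rigid registration of two volumes by FFT cross-correlation
#'
#' Maximises the intensity cross-correlation between `moving` and `fixed`
#' over integer translations via FFT, then refines each axis by a quadratic
#' fit through the correlation peak. The returned transform maps `moving`
#' into the frame of `fixed`: a point at world position `x` in the moving
#' volume corresponds to `x + translation_mm` in the fixed volume. Rotation
#' is not estimated (identity); at VOI scale and for phantom work the
#' translational component dominates.
#'
#' Degenerate inputs (uncorrelated noise, constant intensity) are detected
#' by the sharpness of the correlation peak and raise an error rather than
#' returning a silently wrong transform.
#'
#' @param moving,fixed [voxel_grid]s with identical shape and spacing.
#' @param min_peak_z minimal peak z-score `(max - mean)/sd` of the
#'   correlation field accepted as a reliable lock (default 6; pure noise
#'   peaks near `sqrt(2 log N)` ~ 4.5).
#' @return A `rigid_transform`: list with `translation_mm` (length 3, z,y,x),
#'   `rotation` (3x3, identity), `peak_z` and `shift_voxels`.
#' @export
register_rigid <- function(moving, fixed, min_peak_z = 6) {
  stopifnot(inherits(moving, "voxel_grid"), inherits(fixed, "voxel_grid"))
  if (!identical(dim(moving$values), dim(fixed$values)))
    stop("moving and fixed must share shape for FFT registration", call. = FALSE)
  if (max(abs(moving$spacing - fixed$spacing)) > 1e-8)
    stop("moving and fixed must share voxel spacing", call. = FALSE)
  d <- dim(fixed$values)
  f <- fixed$values - mean(fixed$values)
  m <- moving$values - mean(moving$values)
  if (stats::sd(f) == 0 || stats::sd(m) == 0)
    stop("degenerate (constant) intensity: registration impossible",
         call. = FALSE)
  cc <- Re(stats::fft(stats::fft(f) * Conj(stats::fft(m)), inverse = TRUE))
  pk <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  z <- (max(cc) - mean(cc)) / stats::sd(cc)
  if (z < min_peak_z)
    stop(sprintf(
      "registration failed: correlation peak z = %.2f below %.2f (no reliable overlap)",
      z, min_peak_z), call. = FALSE)
  shift <- pk - 1
  shift <- ifelse(shift > d / 2, shift - d, shift)
  # sub-voxel refinement: 1D quadratic through the wrapped peak neighbours
  sub <- vapply(1:3, function(a) {
    at <- function(delta) {
      idx <- pk
      idx[a] <- ((idx[a] - 1 + delta) %% d[a]) + 1
      cc[idx[1], idx[2], idx[3]]
    }
    c0 <- at(0); cm <- at(-1); cp <- at(1)
    den <- cm - 2 * c0 + cp
    if (abs(den) < 1e-12) 0 else 0.5 * (cm - cp) / den
  }, numeric(1))
  sub[abs(sub) > 0.5] <- 0
  shift <- shift + sub
  structure(list(translation_mm = shift * fixed$spacing,
                 rotation = diag(3), shift_voxels = shift, peak_z = z),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform> t = (%.2f, %.2f, %.2f) mm (z,y,x), peak z = %.1f\n",
              x$translation_mm[1], x$translation_mm[2], x$translation_mm[3],
              x$peak_z))
  invisible(x)
}

#' Apply a rigid transform to world-mm points
#'
#' @param transform a `rigid_transform`.
#' @param points n x 3 matrix of world coordinates (z, y, x mm).
#' @return Transformed n x 3 matrix.
#' @export
apply_transform <- function(transform, points) {
  points <- matrix(as.numeric(points), ncol = 3)
  t(transform$rotation %*% t(points)) +
    matrix(transform$translation_mm, nrow(points), 3, byrow = TRUE)
}

#' Match nodules across time points by mutual nearest neighbours
#'
#' Prior-scan centroids are mapped through `transform` (if given) into the
#' current frame; a prior lesion i and current lesion j are matched iff each
#' is the other's nearest neighbour and their distance is within `gate_mm`.
#' Swapping the two lists transposes the matching.
#'
#' @param lesions_prior,lesions_current n x 3 matrices of centroids
#'   (world mm, z,y,x); either may be empty (0 rows or NULL).
#' @param transform optional `rigid_transform` mapping prior to current.
#' @param gate_mm gating radius, default 10 mm.
#' @return list with `matches` (data.frame: prior, current, dist_mm) and
#'   index vectors `unmatched_prior`, `unmatched_current`.
#' @export
pair_nodules <- function(lesions_prior, lesions_current, transform = NULL,
                         gate_mm = 10) {
  pm <- if (is.null(lesions_prior)) matrix(numeric(0), 0, 3) else
    matrix(as.numeric(lesions_prior), ncol = 3)
  cm <- if (is.null(lesions_current)) matrix(numeric(0), 0, 3) else
    matrix(as.numeric(lesions_current), ncol = 3)
  if (!is.null(transform) && nrow(pm) > 0) pm <- apply_transform(transform, pm)
  empty <- data.frame(prior = integer(0), current = integer(0),
                      dist_mm = numeric(0))
  if (nrow(pm) == 0 || nrow(cm) == 0)
    return(list(matches = empty,
                unmatched_prior = seq_len(nrow(pm)),
                unmatched_current = seq_len(nrow(cm))))
  d2 <- outer(rowSums(pm^2), rep(1, nrow(cm))) +
    outer(rep(1, nrow(pm)), rowSums(cm^2)) - 2 * pm %*% t(cm)
  d <- sqrt(pmax(d2, 0))
  nn_c <- apply(d, 1, which.min)       # nearest current for each prior
  nn_p <- apply(d, 2, which.min)       # nearest prior for each current
  keep <- which(nn_p[nn_c] == seq_len(nrow(pm)) &
                  d[cbind(seq_len(nrow(pm)), nn_c)] <= gate_mm)
  matches <- if (length(keep)) data.frame(
    prior = keep, current = nn_c[keep],
    dist_mm = d[cbind(keep, nn_c[keep])]) else empty
  list(matches = matches,
       unmatched_prior = setdiff(seq_len(nrow(pm)), matches$prior),
       unmatched_current = setdiff(seq_len(nrow(cm)), matches$current))
}

# world-mm sample positions of a cubic VOI of `size` voxels at 1 mm
voi_sample_axes <- function(center, size) {
  lapply(1:3, function(a) center[a] + (seq_len(size) - 1) - (size - 1) / 2)
}

#' Extract a nodule-centred cubic VOI at 1 mm isotropic spacing
#'
#' Resamples `grid` (trilinear) onto a `size`^3 cube of 1 mm voxels centred
#' on `center`; sample points outside the scan are padded with -1000 HU.
#' The companion `extract_voi_mask()` resamples a mask with nearest-
#' neighbour interpolation (padding FALSE).
#'
#' @param grid a [voxel_grid].
#' @param center world mm (z, y, x); must lie inside the scan.
#' @param size cube edge in voxels.
#' @return A [voxel_grid] of shape `c(size, size, size)`, spacing 1 mm, with
#'   origin such that world coordinates are preserved.
#' @export
extract_voi <- function(grid, center, size) {
  stopifnot(inherits(grid, "voxel_grid"))
  size <- as.integer(size)
  d <- dim(grid$values)
  idx_c <- (center - grid$origin) / grid$spacing + 1
  if (any(idx_c < 0.5) || any(idx_c > d + 0.5))
    stop("VOI center lies outside the scan", call. = FALSE)
  ax <- voi_sample_axes(center, size)
  idx <- lapply(1:3, function(a) (ax[[a]] - grid$origin[a]) / grid$spacing[a] + 1)
  vals <- trilinear_sample(grid$values, idx[[1]], idx[[2]], idx[[3]],
                           pad = -1000)
  voxel_grid(array(vals, rep(size, 3)), spacing = c(1, 1, 1),
             origin = vapply(ax, `[`, numeric(1), 1L))
}

#' @rdname extract_voi
#' @param mask a [nodule_mask].
#' @export
extract_voi_mask <- function(mask, center, size) {
  stopifnot(inherits(mask, "nodule_mask"))
  size <- as.integer(size)
  ax <- voi_sample_axes(center, size)
  d <- dim(mask$mask)
  idx <- lapply(1:3, function(a)
    round((ax[[a]] - mask$origin[a]) / mask$spacing[a] + 1))
  gz <- expand.grid(z = idx[[1]], y = idx[[2]], x = idx[[3]])
  ok <- gz$z >= 1 & gz$z <= d[1] & gz$y >= 1 & gz$y <= d[2] &
    gz$x >= 1 & gz$x <= d[3]
  out <- rep(FALSE, nrow(gz))
  out[ok] <- mask$mask[cbind(gz$z[ok], gz$y[ok], gz$x[ok])]
  nodule_mask(array(out, rep(size, 3)), spacing = c(1, 1, 1),
              origin = vapply(ax, `[`, numeric(1), 1L))
}

# vectorised trilinear interpolation on a 3D array at fractional 1-based
# indices given per axis (tensor grid); out-of-volume corners read `pad`
trilinear_sample <- function(arr, iz, iy, ix, pad = -1000) {
  d <- dim(arr)
  nz <- length(iz); ny <- length(iy); nx <- length(ix)
  g <- expand.grid(z = iz, y = iy, x = ix)
  z0 <- floor(g$z); y0 <- floor(g$y); x0 <- floor(g$x)
  fz <- g$z - z0; fy <- g$y - y0; fx <- g$x - x0
  gather <- function(z, y, x) {
    ok <- z >= 1 & z <= d[1] & y >= 1 & y <= d[2] & x >= 1 & x <= d[3]
    v <- rep(pad, length(z))
    v[ok] <- arr[cbind(z[ok], y[ok], x[ok])]
    v
  }
  v000 <- gather(z0, y0, x0);     v001 <- gather(z0, y0, x0 + 1)
  v010 <- gather(z0, y0 + 1, x0); v011 <- gather(z0, y0 + 1, x0 + 1)
  v100 <- gather(z0 + 1, y0, x0); v101 <- gather(z0 + 1, y0, x0 + 1)
  v110 <- gather(z0 + 1, y0 + 1, x0); v111 <- gather(z0 + 1, y0 + 1, x0 + 1)
  w <- v000 * (1 - fz) * (1 - fy) * (1 - fx) +
    v001 * (1 - fz) * (1 - fy) * fx +
    v010 * (1 - fz) * fy * (1 - fx) +
    v011 * (1 - fz) * fy * fx +
    v100 * fz * (1 - fy) * (1 - fx) +
    v101 * fz * (1 - fy) * fx +
    v110 * fz * fy * (1 - fx) +
    v111 * fz * fy * fx
  array(w, c(nz, ny, nx))
}

# --- fixture segmenter (phantom pipelines only) -----------------------------

shift_arr <- function(a, axis, by, fill = FALSE) {
  d <- dim(a)
  out <- array(fill, d)
  src <- dst <- lapply(d, seq_len)
  if (by > 0) { dst[[axis]] <- (1 + by):d[axis]; src[[axis]] <- 1:(d[axis] - by) }
  else if (by < 0) { dst[[axis]] <- 1:(d[axis] + by); src[[axis]] <- (1 - by):d[axis] }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

dilate6 <- function(a) {
  out <- a
  for (ax in 1:3) for (s in c(-1, 1)) out <- out | shift_arr(a, ax, s)
  out
}
erode6 <- function(a) {
  out <- a
  for (ax in 1:3) for (s in c(-1, 1)) out <- out & shift_arr(a, ax, s, fill = TRUE)
  out
}

# largest 6-connected component of a logical array (vectorised BFS)
largest_component <- function(fg) {
  d <- dim(fg)
  remaining <- fg
  best <- NULL; best_n <- 0L
  while (any(remaining)) {
    seed <- which(remaining)[1]
    comp <- array(FALSE, d)
    comp[seed] <- TRUE
    frontier <- comp
    remaining[seed] <- FALSE
    repeat {
      grown <- dilate6(frontier) & remaining
      if (!any(grown)) break
      comp <- comp | grown
      remaining[grown] <- FALSE
      frontier <- grown
    }
    n <- sum(comp)
    if (n > best_n) { best <- comp; best_n <- n }
  }
  if (is.null(best)) array(FALSE, d) else best
}

#' Threshold-based phantom segmenter (fixture)
#'
#' A deliberately simple segmenter for synthetic phantoms only: thresholds
#' at the estimated parenchyma level plus `k` noise SDs (both estimated from
#' the volume border), applies one morphological closing, and keeps the
#' largest 6-connected component. It stands in for a trained lesion
#' segmenter in phantom pipelines and is not intended for clinical images.
#'
#' @param grid a [voxel_grid].
#' @param k threshold in border-noise SDs above the border median (default 3).
#' @return A [nodule_mask].
#' @export
segment_phantom <- function(grid, k = 3) {
  stopifnot(inherits(grid, "voxel_grid"))
  v <- grid$values
  d <- dim(v)
  border <- array(FALSE, d)
  border[c(1, d[1]), , ] <- TRUE
  border[, c(1, d[2]), ] <- TRUE
  border[, , c(1, d[3])] <- TRUE
  bg <- stats::median(v[border])
  sdv <- stats::mad(v[border])
  if (sdv == 0) sdv <- max(stats::sd(v[border]), 1)
  fg <- v > bg + k * sdv
  if (!any(fg)) stop("segmentation found no foreground", call. = FALSE)
  fg <- erode6(dilate6(fg))            # morphological closing
  nodule_mask(largest_component(fg), grid = grid)
}
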