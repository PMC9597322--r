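# Independent oracle implementations used to check the package's operations.
# These deliberately re-derive each quantity from first principles (brute
# force, closed form, exhaustive enumeration) and share no code with the
# implementation paths they verify.

# minimum-area enclosing rectangle by exhaustive rotation to every hull-edge
# angle: rotate the point cloud, take the axis-aligned bounding box
oracle_min_rect_long_side <- function(pts) {
  pts <- unique(as.matrix(pts))
  h <- grDevices::chull(pts)
  hp <- pts[h, , drop = FALSE]
  nh <- nrow(hp)
  angles <- vapply(seq_len(nh), function(i) {
    e <- hp[if (i == nh) 1L else i + 1L, ] - hp[i, ]
    atan2(e[2], e[1])
  }, numeric(1))
  best_area <- Inf; best_long <- NA_real_
  for (th in angles) {
    pu <- pts[, 1] * cos(th) + pts[, 2] * sin(th)   # along the edge
    pv <- -pts[, 1] * sin(th) + pts[, 2] * cos(th)  # perpendicular
    w <- max(pu) - min(pu)
    hgt <- max(pv) - min(pv)
    if (w * hgt < best_area) {
      best_area <- w * hgt
      best_long <- max(w, hgt)
    }
  }
  best_long
}

# O(n^2) pairwise-comparison AUC with half credit for ties
oracle_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# chi-squared statistic by direct sum((O - E)^2 / E)
oracle_chisq <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

# exhaustive minimum-total-distance assignment of <=5 prior to <=5 current
# centroids, pairs beyond the gate forbidden
oracle_assignment <- function(pm, cm, gate) {
  np <- nrow(pm); nc <- nrow(cm)
  d <- as.matrix(stats::dist(rbind(pm, cm)))[seq_len(np), np + seq_len(nc),
                                             drop = FALSE]
  best <- NULL; best_cost <- Inf; best_n <- -1L
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    out
  }
  for (pm_ord in perms(seq_len(nc))) {
    k <- min(np, nc)
    assign_cur <- pm_ord[seq_len(k)]
    keep <- which(d[cbind(seq_len(k), assign_cur)] <= gate)
    n_m <- length(keep)
    cost <- sum(d[cbind(keep, assign_cur[keep])])
    if (n_m > best_n || (n_m == best_n && cost < best_cost)) {
      best_n <- n_m; best_cost <- cost
      best <- cbind(prior = keep, current = assign_cur[keep])
    }
  }
  best[order(best[, 1]), , drop = FALSE]
}

# lattice-count volume of an ellipsoid: voxel centres inside
oracle_ellipsoid_voxels <- function(shape, spacing, center, radii) {
  ax <- lapply(1:3, function(a) (seq_len(shape[a]) - 1) * spacing[a])
  z <- ((ax[[1]] - center[1]) / radii[1])^2
  y <- ((ax[[2]] - center[2]) / radii[2])^2
  x <- ((ax[[3]] - center[3]) / radii[3])^2
  sum(outer(outer(z, y, `+`), x, `+`) <= 1)
}

# a small noiseless phantom fixture used across tests
fixture_phantom <- function(radii = c(5, 5, 5), hu = -650, noise = 0,
                            softness = 0, shape = c(24L, 24L, 24L),
                            seed = 1L) {
  render_phantom(phantom_spec(voi_shape = shape, nodule_radii = radii,
                              nodule_mean_hu = hu, background_noise_sd = noise,
                              edge_softness = softness, seed = seed))
}
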