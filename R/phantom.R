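# Synthetic longitudinal nodule phantoms.
#
# Ground-glass nodules are modelled as soft-edged ellipsoids embedded in
# noisy lung parenchyma. The lesion membership is a Gaussian-smoothed
# indicator of the ellipsoid (scale `edge_softness`, mm); the ground-truth
# mask is membership >= 0.5, i.e. voxel centres inside the ellipsoid.
# All analytic truth (volume, mean HU, mass) is defined on the voxelised
# mask and the pre-noise image, so downstream measurement can be checked
# exactly rather than to a tolerance.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Specify a synthetic sub-solid nodule phantom
#'
#' Describes one ellipsoidal ground-glass lesion inside a block of lung
#' parenchyma. Defaults place a 10 mm nodule of mean attenuation -650 HU in
#' -850 HU parenchyma with 25 HU Gaussian noise, matching typical
#' screening-cohort attenuation for sub-solid nodules; the initial maximal
#' diameter must lie in the 5-30 mm inclusion window used for such cohorts.
#'
#' @param voi_shape integer length-3, voxels per axis (z, y, x).
#' @param spacing mm per voxel (z, y, x).
#' @param background_hu mean parenchyma attenuation (HU).
#' @param background_noise_sd Gaussian noise SD (HU) added outside the lesion.
#' @param nodule_center world mm (z, y, x); default is the VOI centre.
#' @param nodule_radii ellipsoid semi-axes, mm (z, y, x).
#' @param nodule_mean_hu lesion attenuation (HU); must exceed `background_hu`.
#' @param edge_softness Gaussian smoothing scale of the lesion boundary (mm);
#'   0 gives a hard edge.
#' @param seed integer RNG seed for the noise field.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(voi_shape = c(48L, 48L, 48L), spacing = c(1, 1, 1),
                         background_hu = -850, background_noise_sd = 25,
                         nodule_center = NULL, nodule_radii = c(5, 5, 5),
                         nodule_mean_hu = -650, edge_softness = 0.8,
                         seed = 1L) {
  voi_shape <- as.integer(voi_shape)
  spacing <- as.numeric(spacing)
  stopifnot(length(voi_shape) == 3L, all(voi_shape >= 1L),
            length(spacing) == 3L, all(spacing > 0))
  if (is.null(nodule_center)) nodule_center <- (voi_shape - 1) / 2 * spacing
  nodule_radii <- as.numeric(nodule_radii)
  if (length(nodule_radii) != 3L || any(nodule_radii <= 0))
    stop("all nodule radii must be > 0", call. = FALSE)
  dmax <- 2 * max(nodule_radii)
  if (dmax < 5 - 1e-9 || dmax > 30 + 1e-9)
    stop("initial maximal diameter must lie within [5, 30] mm, got ",
         signif(dmax, 4), call. = FALSE)
  if (!(nodule_mean_hu > background_hu))
    stop("nodule_mean_hu must exceed background_hu", call. = FALSE)
  if (background_noise_sd < 0 || edge_softness < 0)
    stop("noise SD and edge_softness must be >= 0", call. = FALSE)
  structure(list(voi_shape = voi_shape, spacing = spacing,
                 background_hu = background_hu,
                 background_noise_sd = background_noise_sd,
                 nodule_center = as.numeric(nodule_center),
                 nodule_radii = nodule_radii,
                 nodule_mean_hu = nodule_mean_hu,
                 edge_softness = edge_softness, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Growth kinetics of a phantom trajectory
#'
#' @param radius_scale_per_year multiplicative factor applied to every
#'   semi-axis per 365 days (> 0; 1 = no size change).
#' @param hu_delta_per_year additive drift of the lesion mean attenuation,
#'   HU per 365 days.
#' @param interval_days inter-exam gaps in days; length 1 (two exams) or
#'   2 (three exams).
#' @param jitter_mm half-width of the uniform random rigid offset applied to
#'   follow-up time points (mm; 0 disables). The applied offset is recorded
#'   in the trajectory output.
#' @return A `growth_kinetics` object.
#' @export
growth_kinetics <- function(radius_scale_per_year = 1,
                            hu_delta_per_year = 0,
                            interval_days = 365,
                            jitter_mm = 0) {
  if (!(radius_scale_per_year > 0))
    stop("radius_scale_per_year must be > 0", call. = FALSE)
  interval_days <- as.numeric(interval_days)
  if (!(length(interval_days) %in% 1:2) || any(interval_days <= 0))
    stop("interval_days must be 1 or 2 positive gaps (2 or 3 exams)",
         call. = FALSE)
  if (jitter_mm < 0) stop("jitter_mm must be >= 0", call. = FALSE)
  structure(list(radius_scale_per_year = radius_scale_per_year,
                 hu_delta_per_year = hu_delta_per_year,
                 interval_days = interval_days, jitter_mm = jitter_mm),
            class = "growth_kinetics")
}

# smoothed ellipsoid membership on voxel centres; returns list(m, inside)
ellipsoid_membership <- function(spec, center, radii) {
  d <- spec$voi_shape
  ax <- lapply(1:3, function(a)
    spec$origin_mm[a] %||% 0 + (seq_len(d[a]) - 1) * spec$spacing[a])
  z <- (ax[[1]] - center[1]) / radii[1]
  y <- (ax[[2]] - center[2]) / radii[2]
  x <- (ax[[3]] - center[3]) / radii[3]
  # normalised radial coordinate rho and an exact-for-spheres signed distance
  rho2 <- outer(outer(z^2, y^2, `+`), x^2, `+`)
  rho <- sqrt(rho2)
  inside <- rho <= 1
  if (spec$edge_softness == 0) {
    m <- array(as.numeric(inside), d)
  } else {
    gz <- (ax[[1]] - center[1]) / radii[1]^2
    gy <- (ax[[2]] - center[2]) / radii[2]^2
    gx <- (ax[[3]] - center[3]) / radii[3]^2
    grad <- sqrt(outer(outer(gz^2, gy^2, `+`), gx^2, `+`))
    sd_mm <- ifelse(grad > 0, (rho2 - rho) / grad, -min(radii)) # rho*(rho-1)/grad
    m <- array(stats::pnorm(-sd_mm / spec$edge_softness), d)
    m[inside & grad == 0] <- 1
  }
  list(m = m, inside = inside)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Render a phantom volume, its mask and its analytic truth
#'
#' Voxels inside the smoothed lesion take the (blended) nodule attenuation;
#' voxels outside take parenchyma plus Gaussian noise. The ground-truth mask
#' marks voxels whose pre-noise lesion membership is >= 0.5. The returned
#' truth is computed on the voxelised mask and the pre-noise image, so
#' `measure()` on a noise-free phantom reproduces it exactly.
#'
#' @param spec a [phantom_spec].
#' @param center,radii optional overrides of the spec's nodule geometry
#'   (used internally by [simulate_trajectory()]).
#' @param mean_hu optional override of the lesion attenuation.
#' @return list with elements `grid` ([voxel_grid]), `mask` ([nodule_mask])
#'   and `truth` (list: `volume_mm3`, `mean_hu`, `mass_mg`, `n_voxels`).
#' @export
render_phantom <- function(spec, center = spec$nodule_center,
                           radii = spec$nodule_radii,
                           mean_hu = spec$nodule_mean_hu) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$voi_shape
  hi <- (d - 1) * spec$spacing + spec$spacing / 2
  lo <- -spec$spacing / 2
  pad <- 3 * spec$edge_softness
  for (a in 1:3) {
    if (center[a] - radii[a] - pad < lo[a] || center[a] + radii[a] + pad > hi[a])
      stop("nodule extends beyond the VOI along the ",
           c("z", "y", "x")[a], " axis", call. = FALSE)
  }
  mem <- ellipsoid_membership(spec, center, radii)
  hu0 <- spec$background_hu + (mean_hu - spec$background_hu) * mem$m
  mask <- mem$inside
  img <- hu0
  if (spec$background_noise_sd > 0) {
    noise <- with_seed(spec$seed,
      array(stats::rnorm(prod(d), 0, spec$background_noise_sd), d))
    img[!mask] <- img[!mask] + noise[!mask]
  }
  vol <- sum(mask) * prod(spec$spacing)
  mhu <- mean(hu0[mask])
  truth <- list(volume_mm3 = vol, mean_hu = mhu,
                mass_mg = vol * (mhu + 1000) / 1000, n_voxels = sum(mask))
  g <- voxel_grid(img, spacing = spec$spacing)
  list(grid = g, mask = nodule_mask(mask, grid = g), truth = truth)
}

#' Simulate a longitudinal phantom trajectory
#'
#' Time point k (elapsed time t_k years) scales every semi-axis by
#' `radius_scale_per_year^t_k` and shifts the lesion attenuation by
#' `hu_delta_per_year * t_k`; follow-up scans may additionally be displaced
#' by a small recorded rigid offset to emulate inter-scan misalignment.
#'
#' @param spec a [phantom_spec] describing the baseline exam.
#' @param kin a [growth_kinetics].
#' @return list of per-time-point lists (`grid`, `mask`, `truth`, `offset_mm`,
#'   `elapsed_days`), with attribute `"kinetics"`; the truth of time point k
#'   additionally carries the annualised mass rate and growth label of the
#'   interval ending at k.
#' @export
simulate_trajectory <- function(spec, kin) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(kin, "growth_kinetics"))
  elapsed <- c(0, cumsum(kin$interval_days))
  offsets <- matrix(0, length(elapsed), 3)
  if (kin$jitter_mm > 0 && length(elapsed) > 1) {
    offsets[-1, ] <- with_seed(spec$seed + 7L,
      matrix(stats::runif(3 * (length(elapsed) - 1), -kin$jitter_mm,
                          kin$jitter_mm), ncol = 3))
  }
  out <- vector("list", length(elapsed))
  for (k in seq_along(elapsed)) {
    t_yr <- elapsed[k] / 365
    sp_k <- spec
    sp_k$seed <- spec$seed + 31L * k
    rk <- spec$nodule_radii * kin$radius_scale_per_year^t_yr
    hk <- spec$nodule_mean_hu + kin$hu_delta_per_year * t_yr
    ph <- render_phantom(sp_k, center = spec$nodule_center + offsets[k, ],
                         radii = rk, mean_hu = hk)
    ph$offset_mm <- offsets[k, ]
    ph$elapsed_days <- elapsed[k]
    if (k > 1) {
      prev <- out[[k - 1]]$truth
      dt <- elapsed[k] - elapsed[k - 1]
      y <- annualized_mass_rate(prev$mass_mg, ph$truth$mass_mg, dt)
      ph$truth$annualized_mass_rate <- y
      ph$truth$growth_label <- growth_label(y)
    }
    out[[k]] <- ph
  }
  attr(out, "kinetics") <- kin
  out
}

# class-conditional sampling ranges for generate_cohort(); the growth class
# mirrors the larger, denser nodules reported for growing SSNs in screening
# cohorts, the non-growth class the smaller, more lucent majority.
cohort_effect_defaults <- function() {
  list(
    growth = list(diameter_meanlog = log(10), diameter_sdlog = 0.30,
                  diameter_range = c(5, 18),
                  hu_mean = -590, hu_sd = 55, hu_range = c(-750, -460),
                  y_mean = 0.5, y_sd = 0.10, y_range = c(0.30, 0.80),
                  hu_delta_range = c(10, 40)),
    non_growth = list(diameter_meanlog = log(6.5), diameter_sdlog = 0.25,
                      diameter_range = c(5, 14),
                      hu_mean = -640, hu_sd = 40, hu_range = c(-750, -460),
                      y_mean = 0.0, y_sd = 0.05, y_range = c(-0.12, 0.12),
                      hu_delta_range = c(-10, 10)))
}

rnorm_clip <- function(n, mean, sd, range)
  pmin(pmax(stats::rnorm(n, mean, sd), range[1]), range[2])
rlnorm_clip <- function(n, meanlog, sdlog, range)
  pmin(pmax(stats::rlnorm(n, meanlog, sdlog), range[1]), range[2])

#' Generate a labelled synthetic cohort of longitudinal exam pairs
#'
#' Draws `n` independent nodule trajectories (stratified so that exactly
#' `round(n * growth_fraction)` have growth-class kinetics), renders each at
#' 2 or 3 time points, extracts nodule-centred VOIs at 1 mm isotropic
#' spacing, and returns model-ready examples: the prior VOI (absent for
#' two-exam trajectories), the current VOI and mask, and the ground-truth
#' annualised mass rate `y` of the *following* interval — the quantity the
#' growth model regresses. The target rate is drawn per class and the radius
#' scaling solved from it, so truth labels are consistent by construction.
#'
#' @param n number of trajectories (> 0).
#' @param growth_fraction proportion with growth-class kinetics; the default
#'   0.07 mimics the ~7% growth prevalence of screening cohorts.
#' @param effect per-class sampling ranges; see `cohort_effect_defaults()`.
#' @param two_exam_fraction proportion of trajectories with only two exams
#'   (these have no prior VOI and exercise the learnable-substitute path).
#' @param interval_range days; each inter-exam gap is uniform in this range.
#' @param voi_size cubic VOI edge in voxels (1 mm isotropic).
#' @param noise_sd parenchyma noise SD in HU.
#' @param seed integer seed; the cohort is a pure function of (arguments, seed).
#' @param out_dir if non-NULL, VOIs/masks are written there as NIfTI
#'   (`.nii.gz`) and the manifest as `manifest.csv`.
#' @return list with `examples` (list of per-trajectory lists: `prior_voi`,
#'   `current_voi`, `current_mask`, `y`, `label`, `interval_days`, `id`) and
#'   `manifest` (data.frame, one row per trajectory).
#' @export
generate_cohort <- function(n, growth_fraction = 0.07,
                            effect = cohort_effect_defaults(),
                            two_exam_fraction = 0.15,
                            interval_range = c(300, 430),
                            voi_size = 32L, noise_sd = 25,
                            seed = 1L, out_dir = NULL) {
  if (n <= 0) stop("n must be > 0", call. = FALSE)
  if (growth_fraction < 0 || growth_fraction > 1)
    stop("growth_fraction must be in [0, 1]", call. = FALSE)
  n <- as.integer(n)
  n_grow <- round(n * growth_fraction)
  params <- with_seed(seed, {
    is_growth <- rep(c(TRUE, FALSE), c(n_grow, n - n_grow))
    cls <- ifelse(is_growth, "growth", "non_growth")
    df <- data.frame(id = sprintf("S%04d", seq_len(n)), class = cls,
                     stringsAsFactors = FALSE)
    for (cl in c("growth", "non_growth")) {
      e <- effect[[cl]]; m <- cls == cl; k <- sum(m)
      if (k == 0) next
      df$diameter[m] <- rlnorm_clip(k, e$diameter_meanlog, e$diameter_sdlog,
                                    e$diameter_range)
      df$mean_hu[m] <- rnorm_clip(k, e$hu_mean, e$hu_sd, e$hu_range)
      df$y_target[m] <- rnorm_clip(k, e$y_mean, e$y_sd, e$y_range)
      df$hu_delta[m] <- stats::runif(k, e$hu_delta_range[1], e$hu_delta_range[2])
    }
    df$ax1 <- stats::runif(n, 0.8, 1); df$ax2 <- stats::runif(n, 0.8, 1)
    df$two_exam <- stats::runif(n) < two_exam_fraction
    df$gap1 <- stats::runif(n, interval_range[1], interval_range[2])
    df$gap2 <- stats::runif(n, interval_range[1], interval_range[2])
    df$jz <- stats::runif(n, -1.5, 1.5); df$jy <- stats::runif(n, -1.5, 1.5)
    df$jx <- stats::runif(n, -1.5, 1.5)
    df$sub_seed <- sample.int(2^31 - 2, n)
    df
  })

  examples <- vector("list", n)
  man <- vector("list", n)
  grid_shape <- rep(max(48L, voi_size + 16L), 3)
  for (i in seq_len(n)) {
    p <- params[i, ]
    gaps <- if (p$two_exam) p$gap1 else c(p$gap1, p$gap2)
    dt_last <- gaps[length(gaps)]
    # solve per-year radius scaling so the final interval hits y_target
    mass_ratio <- 1 + p$y_target * dt_last / 365
    dens_ratio <- (p$mean_hu + p$hu_delta * dt_last / 365 + 1000) /
      (p$mean_hu + 1000)
    s_total <- (mass_ratio / dens_ratio)^(1 / 3)
    s_per_year <- s_total^(365 / dt_last)
    semi <- p$diameter / 2 * c(1, p$ax1, p$ax2)
    ctr <- (grid_shape - 1) / 2 + c(p$jz, p$jy, p$jx)
    spec <- phantom_spec(voi_shape = grid_shape, spacing = c(1, 1, 1),
                         background_noise_sd = noise_sd,
                         nodule_center = ctr, nodule_radii = semi,
                         nodule_mean_hu = p$mean_hu, seed = p$sub_seed)
    kin <- growth_kinetics(radius_scale_per_year = s_per_year,
                           hu_delta_per_year = p$hu_delta,
                           interval_days = gaps)
    traj <- simulate_trajectory(spec, kin)
    n_tp <- length(traj)
    # model input: (T_{t-1}, T_t) = the two exams before the last;
    # target: annualised mass rate over the final interval.
    t_cur <- n_tp - 1L
    cur <- traj[[t_cur]]
    ctr_cur <- mask_centroid(cur$mask)
    cur_voi <- extract_voi(cur$grid, ctr_cur, voi_size)
    cur_mask <- extract_voi_mask(cur$mask, ctr_cur, voi_size)
    prior_voi <- NULL
    if (t_cur > 1L) {
      pri <- traj[[t_cur - 1L]]
      prior_voi <- extract_voi(pri$grid, mask_centroid(pri$mask), voi_size)
    }
    fin <- traj[[n_tp]]$truth
    examples[[i]] <- list(id = p$id, prior_voi = prior_voi,
                          current_voi = cur_voi, current_mask = cur_mask,
                          y = fin$annualized_mass_rate,
                          label = fin$growth_label,
                          interval_days = dt_last,
                          class = p$class)
    man[[i]] <- data.frame(
      id = p$id, class = p$class, n_exams = n_tp,
      interval_days = round(dt_last, 3),
      has_prior = t_cur > 1L,
      init_diameter_mm = round(p$diameter, 4),
      init_mean_hu = round(p$mean_hu, 4),
      true_volume_mm3 = round(fin$volume_mm3, 6),
      true_mean_hu = round(fin$mean_hu, 6),
      true_mass_mg = round(fin$mass_mg, 6),
      y = round(fin$annualized_mass_rate, 8),
      growth_label = fin$growth_label,
      stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, man)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(n)) {
      ex <- examples[[i]]
      vp <- file.path(out_dir, paste0(ex$id, "_current.nii.gz"))
      mp <- file.path(out_dir, paste0(ex$id, "_current_mask.nii.gz"))
      write_nifti(ex$current_voi, vp)
      write_nifti(ex$current_mask, mp)
      manifest$current_path[i] <- vp
      manifest$mask_path[i] <- mp
      if (!is.null(ex$prior_voi)) {
        pp <- file.path(out_dir, paste0(ex$id, "_prior.nii.gz"))
        write_nifti(ex$prior_voi, pp)
        manifest$prior_path[i] <- pp
      } else manifest$prior_path[i] <- ""
    }
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)
  }
  list(examples = examples, manifest = manifest)
}
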