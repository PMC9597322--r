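# Hand-crafted radiomics baseline.
#
# A documented, reproducible feature set over the masked VOI: 18 first-order
# intensity features, 14 shape features, 24 grey-level co-occurrence (GLCM)
# and 16 grey-level run-length (GLRLM) features (72 base features;
# optionally tripled by Gaussian-smoothed and gradient-magnitude filter
# banks applied to the intensity families). Intensities are discretised
# with a fixed 25 HU bin width. Texture matrices aggregate the 13 unique
# 3D directions at distance 1, which makes them invariant to 90-degree
# grid rotations; the LASSO-logistic pipeline on top mirrors the standard
# radiomics modelling recipe.

fo_features <- function(v, bin_width) {
  q <- stats::quantile(v, c(0.1, 0.25, 0.5, 0.75, 0.9), names = FALSE)
  n <- length(v)
  ctr <- v - mean(v)
  s2 <- mean(ctr^2)
  hist_p <- tabulate(discretize_hu(v, bin_width))
  hist_p <- hist_p[hist_p > 0] / n
  inner <- v[v >= q[1] & v <= q[5]]
  c(fo_mean = mean(v), fo_median = q[3], fo_min = min(v), fo_max = max(v),
    fo_p10 = q[1], fo_p90 = q[5], fo_iqr = q[4] - q[2],
    fo_range = max(v) - min(v), fo_variance = s2, fo_sd = sqrt(s2),
    fo_skewness = if (s2 > 0) mean(ctr^3) / s2^1.5 else 0,
    fo_kurtosis = if (s2 > 0) mean(ctr^4) / s2^2 else 0,
    fo_energy = sum(v^2), fo_rms = sqrt(mean(v^2)),
    fo_mad = mean(abs(ctr)),
    fo_rmad = if (length(inner)) mean(abs(inner - mean(inner))) else 0,
    fo_entropy = -sum(hist_p * log2(hist_p)),
    fo_uniformity = sum(hist_p^2))
}

discretize_hu <- function(v, bin_width) {
  as.integer(floor((v - min(v)) / bin_width)) + 1L
}

# separable Gaussian smoothing of a 3D array, sigma in voxels, zero-padded
gauss_smooth3 <- function(a, sigma = 1) {
  n <- max(dim(a))
  r <- ceiling(3 * sigma)
  smooth_axis <- function(x, axis) {
    d <- dim(x)
    perm <- c(axis, setdiff(1:3, axis))
    xp <- aperm(x, perm)
    m <- matrix(xp, d[axis])
    k <- stats::dnorm(-r:r, sd = sigma)
    k <- k / sum(k)
    km <- matrix(0, d[axis], d[axis])
    for (off in -r:r) {
      rows <- seq_len(d[axis])
      cols <- rows + off
      ok <- cols >= 1 & cols <= d[axis]
      km[cbind(rows[ok], cols[ok])] <- k[off + r + 1]
    }
    out <- km %*% m
    aperm(array(out, d[perm]), order(perm))
  }
  for (ax in 1:3) a <- smooth_axis(a, ax)
  a
}

shape_features <- function(mask, spacing) {
  idx <- which(mask, arr.ind = TRUE)
  nv <- nrow(idx)
  vol <- nv * prod(spacing)
  # surface area: coarea formula on a Gaussian-smoothed indicator; central
  # differences in mm. More faithful to the smooth lesion boundary than
  # counting voxel faces (which overestimates a sphere's area by ~50%).
  m <- array(0, dim(mask)); m[mask] <- 1
  ms <- gauss_smooth3(m, sigma = 1)
  gz <- (shift_arr(ms, 1, -1) - shift_arr(ms, 1, 1)) / (2 * spacing[1])
  gy <- (shift_arr(ms, 2, -1) - shift_arr(ms, 2, 1)) / (2 * spacing[2])
  gx <- (shift_arr(ms, 3, -1) - shift_arr(ms, 3, 1)) / (2 * spacing[3])
  surf <- sum(sqrt(gz^2 + gy^2 + gx^2)) * prod(spacing)
  surf <- max(surf, 1e-6)
  # principal axis lengths from the voxel-centre covariance
  pts <- sweep(idx - 1, 2, spacing, `*`)
  ev <- if (nv >= 2) {
    sort(pmax(eigen(stats::cov(pts), symmetric = TRUE,
                    only.values = TRUE)$values, 0), decreasing = TRUE)
  } else c(0, 0, 0)
  axes <- 4 * sqrt(ev)
  # max 3D diameter over boundary voxels (deterministically subsampled)
  inner <- mask
  for (ax in 1:3) for (s in c(-1, 1))
    inner <- inner & shift_arr(mask, ax, s, fill = FALSE)
  bpts <- sweep(which(mask & !inner, arr.ind = TRUE) - 1, 2, spacing, `*`)
  if (nrow(bpts) == 0) bpts <- pts
  if (nrow(bpts) > 3000)
    bpts <- bpts[seq(1, nrow(bpts), length.out = 3000), , drop = FALSE]
  dmax <- if (nrow(bpts) >= 2) sqrt(max(stats::dist(bpts)^2)) else
    max(spacing)
  r_eq <- (3 * vol / (4 * pi))^(1 / 3)
  c(sh_volume = vol, sh_surface = surf, sh_surface_to_volume = surf / vol,
    sh_sphericity = pi^(1 / 3) * (6 * vol)^(2 / 3) / surf,
    sh_compactness1 = vol / (sqrt(pi) * surf^1.5),
    sh_compactness2 = 36 * pi * vol^2 / surf^3,
    sh_spherical_disproportion = surf / (4 * pi * r_eq^2),
    sh_max_diameter3d = dmax,
    sh_major_axis = axes[1], sh_minor_axis = axes[2], sh_least_axis = axes[3],
    sh_elongation = if (axes[1] > 0) sqrt(ev[2] / ev[1]) else 0,
    sh_flatness = if (axes[1] > 0) sqrt(ev[3] / ev[1]) else 0,
    sh_equiv_sphere_diameter = 2 * r_eq)
}

# the 13 unique 3D directions at distance 1
DIRECTIONS_3D <- rbind(
  c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
  c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1),
  c(0, 1, 1), c(0, 1, -1),
  c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1))

shift_dir <- function(a, d, fill = 0) {
  for (ax in 1:3) if (d[ax] != 0) a <- shift_arr(a, ax, -d[ax], fill = fill)
  a
}

glcm_matrix <- function(lev, L) {
  pmat <- matrix(0, L, L)
  for (k in seq_len(nrow(DIRECTIONS_3D))) {
    d <- DIRECTIONS_3D[k, ]
    nb <- shift_dir(lev, d)            # nb[x] = lev[x + d], 0 outside
    ok <- lev > 0 & nb > 0
    if (!any(ok)) next
    counts <- tabulate(lev[ok] + (nb[ok] - 1L) * L, nbins = L * L)
    pmat <- pmat + matrix(counts, L, L)
  }
  pmat <- pmat + t(pmat)               # symmetric
  if (sum(pmat) == 0) pmat[1, 1] <- 1
  pmat / sum(pmat)
}

glcm_features <- function(p) {
  L <- nrow(p)
  i <- matrix(seq_len(L), L, L)
  j <- t(i)
  px <- rowSums(p)
  mu_x <- sum(seq_len(L) * px)
  sd_x <- sqrt(sum((seq_len(L) - mu_x)^2 * px))
  ks <- 2:(2 * L)
  p_sum <- vapply(ks, function(k) sum(p[i + j == k]), numeric(1))
  kd <- 0:(L - 1)
  p_diff <- vapply(kd, function(k) sum(p[abs(i - j) == k]), numeric(1))
  ent <- function(q) { q <- q[q > 0]; -sum(q * log2(q)) }
  hxy <- ent(p)
  pxpy <- outer(px, px)
  hxy1 <- -sum(p[pxpy > 0] * log2(pxpy[pxpy > 0]))
  hxy2 <- ent(pxpy)
  hx <- ent(px)
  da <- sum(kd * p_diff)
  c(glcm_autocorrelation = sum(i * j * p),
    glcm_joint_average = mu_x,
    glcm_cluster_prominence = sum((i + j - 2 * mu_x)^4 * p),
    glcm_cluster_shade = sum((i + j - 2 * mu_x)^3 * p),
    glcm_cluster_tendency = sum((i + j - 2 * mu_x)^2 * p),
    glcm_contrast = sum((i - j)^2 * p),
    glcm_correlation = if (sd_x > 0)
      (sum(i * j * p) - mu_x^2) / sd_x^2 else 1,
    glcm_difference_average = da,
    glcm_difference_entropy = ent(p_diff),
    glcm_difference_variance = sum((kd - da)^2 * p_diff),
    glcm_joint_energy = sum(p^2),
    glcm_joint_entropy = hxy,
    glcm_imc1 = if (hx > 0) (hxy - hxy1) / hx else 0,
    glcm_imc2 = sqrt(pmax(1 - exp(-2 * (hxy2 - hxy)), 0)),
    glcm_idm = sum(p / (1 + (i - j)^2)),
    glcm_id = sum(p / (1 + abs(i - j))),
    glcm_idmn = sum(p / (1 + (i - j)^2 / L^2)),
    glcm_idn = sum(p / (1 + abs(i - j) / L)),
    glcm_inverse_variance = sum(p[i != j] / (i - j)[i != j]^2),
    glcm_max_probability = max(p),
    glcm_sum_average = sum(ks * p_sum),
    glcm_sum_entropy = ent(p_sum),
    glcm_sum_squares = sum((i - mu_x)^2 * p),
    glcm_dissimilarity = sum(abs(i - j) * p))
}

glrlm_matrix <- function(lev, L, dims) {
  max_run <- max(dims)
  R <- matrix(0, L, max_run)
  n_dir <- nrow(DIRECTIONS_3D)
  for (k in seq_len(n_dir)) {
    d <- DIRECTIONS_3D[k, ]
    prev <- shift_dir(lev, -d)         # value at coord - d
    is_start <- lev > 0 & prev != lev
    coords <- which(is_start, arr.ind = TRUE)
    if (nrow(coords) == 0) next
    vals <- lev[is_start]
    len <- rep(1L, nrow(coords))
    alive <- rep(TRUE, nrow(coords))
    cur <- coords
    while (any(alive)) {
      cur[alive, ] <- cur[alive, , drop = FALSE] +
        matrix(d, sum(alive), 3, byrow = TRUE)
      ai <- which(alive)
      inb <- cur[ai, 1] >= 1 & cur[ai, 1] <= dims[1] &
        cur[ai, 2] >= 1 & cur[ai, 2] <= dims[2] &
        cur[ai, 3] >= 1 & cur[ai, 3] <= dims[3]
      same <- rep(FALSE, length(ai))
      if (any(inb))
        same[inb] <- lev[cur[ai[inb], , drop = FALSE]] == vals[ai[inb]]
      len[ai[same]] <- len[ai[same]] + 1L
      alive[ai[!same]] <- FALSE
    }
    idx <- cbind(vals, pmin(len, max_run))
    for (r in seq_len(nrow(idx))) R[idx[r, 1], idx[r, 2]] <-
        R[idx[r, 1], idx[r, 2]] + 1
  }
  R
}

glrlm_features <- function(R, n_voxels) {
  nr <- sum(R)
  if (nr == 0) { R[1, 1] <- 1; nr <- 1 }
  L <- nrow(R); J <- ncol(R)
  i <- matrix(seq_len(L), L, J)
  j <- matrix(seq_len(J), L, J, byrow = TRUE)
  p <- R / nr
  ri <- rowSums(R); rj <- colSums(R)
  mu_i <- sum(i * p); mu_j <- sum(j * p)
  pe <- p[p > 0]
  c(glrlm_sre = sum(R / j^2) / nr,
    glrlm_lre = sum(R * j^2) / nr,
    glrlm_gln = sum(ri^2) / nr,
    glrlm_glnn = sum(ri^2) / nr^2,
    glrlm_rln = sum(rj^2) / nr,
    glrlm_rlnn = sum(rj^2) / nr^2,
    glrlm_rp = nr / (nrow(DIRECTIONS_3D) * n_voxels),
    glrlm_glv = sum((i - mu_i)^2 * p),
    glrlm_rv = sum((j - mu_j)^2 * p),
    glrlm_re = -sum(pe * log2(pe)),
    glrlm_lglre = sum(R / i^2) / nr,
    glrlm_hglre = sum(R * i^2) / nr,
    glrlm_srlgle = sum(R / (i^2 * j^2)) / nr,
    glrlm_srhgle = sum(R * i^2 / j^2) / nr,
    glrlm_lrlgle = sum(R * j^2 / i^2) / nr,
    glrlm_lrhgle = sum(R * i^2 * j^2) / nr)
}

intensity_family <- function(values, mask, bin_width, prefix = "") {
  v <- values[mask]
  lev <- array(0L, dim(mask))
  lev[mask] <- discretize_hu(v, bin_width)
  L <- max(lev)
  out <- c(fo_features(v, bin_width),
           glcm_features(glcm_matrix(lev, L)),
           glrlm_features(glrlm_matrix(lev, L, dim(mask)), sum(mask)))
  if (nzchar(prefix)) names(out) <- paste0(prefix, names(out))
  out
}

#' Extract radiomics features from a masked VOI
#'
#' @param voi a [voxel_grid]. @param mask an aligned [nodule_mask].
#' @param bin_width HU bin width for texture discretisation (default 25).
#' @param filters if TRUE, additionally extract the intensity families from
#'   a Gaussian-smoothed (sigma 1 voxel) and a gradient-magnitude filtered
#'   image (tripling the intensity feature count).
#' @return named numeric feature vector (72 base features).
#' @export
extract_features <- function(voi, mask, bin_width = 25, filters = FALSE) {
  stopifnot(inherits(voi, "voxel_grid"), inherits(mask, "nodule_mask"))
  check_aligned(voi, mask)
  if (!any(mask$mask)) stop("cannot extract features from an empty mask",
                            call. = FALSE)
  out <- c(intensity_family(voi$values, mask$mask, bin_width),
           shape_features(mask$mask, voi$spacing))
  if (filters) {
    sm <- gauss_smooth3(voi$values, sigma = 1)
    gz <- (shift_arr(sm, 1, -1) - shift_arr(sm, 1, 1)) / (2 * voi$spacing[1])
    gy <- (shift_arr(sm, 2, -1) - shift_arr(sm, 2, 1)) / (2 * voi$spacing[2])
    gx <- (shift_arr(sm, 3, -1) - shift_arr(sm, 3, 1)) / (2 * voi$spacing[3])
    grad <- sqrt(gz^2 + gy^2 + gx^2)
    out <- c(out,
             intensity_family(sm, mask$mask, bin_width, "gauss_"),
             intensity_family(grad, mask$mask, bin_width / 5, "grad_"))
  }
  if (any(!is.finite(out))) out[!is.finite(out)] <- 0
  out
}

#' LASSO feature selection for a binary outcome
#'
#' Columns are z-scored, constant columns dropped with a warning, and an
#' L1-penalised logistic regression fitted along a lambda path; the penalty
#' is chosen by `nfolds`-fold cross-validated deviance (seed-controlled
#' folds) and the features with nonzero coefficients at that penalty are
#' returned.
#'
#' @param X numeric feature matrix (rows = nodules, named columns).
#' @param y binary labels (logical or 0/1); both classes required.
#' @param nfolds CV folds (default 5). @param seed fold seed.
#' @param s which penalty to read coefficients at (`"lambda.min"` or
#'   `"lambda.1se"`).
#' @return list: `selected` (names), `coef` (named nonzero coefficients),
#'   `lambda` (chosen), `lambda_path`, `center`, `scale`, `dropped`.
#' @export
lasso_select <- function(X, y, nfolds = 5, seed = 1L, s = "lambda.min") {
  X <- as.matrix(X)
  y <- as.numeric(as.logical(y))
  if (length(unique(y)) < 2) stop("need both classes", call. = FALSE)
  sds <- apply(X, 2, stats::sd)
  dropped <- colnames(X)[sds == 0]
  if (length(dropped))
    warning("dropping constant features: ", paste(dropped, collapse = ", "))
  X <- X[, sds > 0, drop = FALSE]
  ctr <- colMeans(X); scl <- apply(X, 2, stats::sd)
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, `/`)
  foldid <- with_seed(seed, sample(rep_len(seq_len(nfolds), nrow(Xs))))
  cvfit <- glmnet::cv.glmnet(Xs, y, family = "binomial", alpha = 1,
                             foldid = foldid, standardize = FALSE)
  lam <- cvfit[[s]]
  cf <- as.matrix(stats::coef(cvfit, s = lam))
  nz <- cf[-1, 1]
  nz <- nz[nz != 0]
  list(selected = names(nz), coef = nz, lambda = lam,
       lambda_path = cvfit$lambda, cvm = cvfit$cvm,
       center = ctr, scale = scl, dropped = dropped)
}

#' Regularised logistic regression scores on selected features
#'
#' Ridge-regularised logistic fit (small fixed penalty), so complete
#' separation cannot crash the fit; features are standardised with the
#' training statistics before fitting and scoring.
#'
#' @param X_train,X_test feature matrices with matching named columns.
#' @param y_train binary training labels.
#' @param lambda ridge penalty (default 1e-2).
#' @return list: `scores` (test probabilities in (0,1)), `coef` (named,
#'   on the standardised scale), `intercept`.
#' @export
fit_predict_logistic <- function(X_train, y_train, X_test, lambda = 1e-2) {
  X_train <- as.matrix(X_train); X_test <- as.matrix(X_test)
  if (ncol(X_train) == 0) stop("no selected features", call. = FALSE)
  y <- as.numeric(as.logical(y_train))
  ctr <- colMeans(X_train)
  scl <- apply(X_train, 2, stats::sd)
  if (all(scl == 0)) {                 # no informative features at all:
    p0 <- mean(y)                      # intercept-only model, equal scores
    return(list(scores = rep(p0, nrow(X_test)),
                coef = stats::setNames(rep(0, ncol(X_train)),
                                       colnames(X_train)),
                intercept = stats::qlogis(min(max(p0, 1e-6), 1 - 1e-6))))
  }
  scl[scl == 0] <- 1
  zs <- function(M) sweep(sweep(M, 2, ctr), 2, scl, `/`)
  Xs <- zs(X_train); Xt <- zs(X_test)
  if (ncol(Xs) == 1) {                 # glmnet needs >= 2 columns
    Xs <- cbind(Xs, .pad = 0); Xt <- cbind(Xt, .pad = 0)
  }
  fit <- glmnet::glmnet(Xs, y, family = "binomial", alpha = 0,
                        lambda = lambda, standardize = FALSE)
  scores <- as.vector(stats::predict(fit, Xt, type = "response"))
  cf <- as.matrix(stats::coef(fit))[, 1]
  list(scores = scores, coef = cf[-1][colnames(X_train)],
       intercept = cf[1])
}

#' End-to-end radiomics baseline on cohort examples
#'
#' Extracts features from each example's current VOI and mask, selects
#' features by LASSO on the training split, and scores the test split with
#' the regularised logistic model — the "radiomics (once)" comparator.
#'
#' @param train_examples,test_examples example lists (see
#'   [generate_cohort()]); each needs `current_voi`, `current_mask`, `label`.
#' @param bin_width,filters passed to [extract_features()].
#' @param seed fold seed for the LASSO CV.
#' @return list: `scores`, `selection`, `n_features`.
#' @export
radiomics_baseline <- function(train_examples, test_examples,
                               bin_width = 25, filters = FALSE, seed = 1L) {
  featurise <- function(exs) do.call(rbind, lapply(exs, function(e)
    extract_features(e$current_voi, e$current_mask, bin_width, filters)))
  Xtr <- featurise(train_examples)
  Xte <- featurise(test_examples)
  ytr <- vapply(train_examples, function(e) e$label, logical(1))
  sel <- suppressWarnings(lasso_select(Xtr, ytr, seed = seed))
  feats <- if (length(sel$selected)) sel$selected else colnames(Xtr)[
    apply(Xtr, 2, stats::sd) > 0][1:5]
  fit <- fit_predict_logistic(Xtr[, feats, drop = FALSE], ytr,
                              Xte[, feats, drop = FALSE])
  list(scores = fit$scores, selection = sel, n_features = ncol(Xtr))
}
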