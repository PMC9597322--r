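# Siamese growth-prediction model.
#
# Paired nodule VOIs (prior T_{t-1}, current T_t) pass through one
# shared-weight 3D vision-transformer encoder. Three embeddings are fused:
#   FG_t    — global summary (class token) of the current VOI only;
#   FL_t    — local summary (mean of patch tokens whose centres fall in a
#             fixed central cube) of the current VOI;
#   FL_prev — the same local summary of the prior VOI, or a learnable
#             substitute vector when no prior scan exists.
# A spatial-temporal mixer (one token-mixing MLP across the three
# embeddings plus one channel MLP, both with residuals and layer norm)
# feeds a single fully connected head that regresses the annualised
# relative mass growth rate p. Classification is derived afterwards by the
# sharpening map and a validation-chosen threshold, never trained directly.

#' Configuration of the Siamese growth model
#'
#' Defaults follow the published training recipe: imbalance coefficient
#' `alpha = 3`, loss indicator threshold `r = 0.1`, AdamW with weight decay
#' 0.05 and first-moment decay 0.9, batch size 16, 100 epochs with 5 warmup
#' epochs, base learning rate 5e-4 scaled by `batch_size / 64`, cosine
#' annealing. The `"tiny"` encoder variant (4 layers, 128 channels, 4 heads,
#' 8-voxel patches on 32-voxel VOIs) is sized for CPU-scale experiments;
#' `"vit-b"` selects the full-scale backbone geometry.
#'
#' @param variant `"tiny"` or `"vit-b"`.
#' @param voi_size,patch_size cube edges in voxels; `patch_size` must divide
#'   `voi_size`.
#' @param embed_dim,depth,heads,mlp_ratio encoder geometry (defaults depend
#'   on `variant`).
#' @param alpha imbalance coefficient of the weighted smooth-L1 loss (>= 1).
#' @param r loss indicator threshold on the true rate (> 0).
#' @param beta smooth-L1 transition width.
#' @param lr,weight_decay,momentum_beta1,batch_size,epochs,warmup_epochs
#'   optimiser and schedule settings.
#' @param tau sharpening coefficient of the probability map.
#' @param local_extent fraction of the VOI edge defining the central cube
#'   of the local embedding.
#' @param min_lr cosine annealing floor.
#' @param seed integer seed for initialisation and batch order.
#' @return A `model_config` list.
#' @export
model_config <- function(variant = c("tiny", "vit-b"), voi_size = 32L,
                         patch_size = 8L, embed_dim = NULL, depth = NULL,
                         heads = NULL, mlp_ratio = 2, alpha = 3.0, r = 0.1,
                         beta = 1.0, lr = 5e-4, weight_decay = 0.05,
                         momentum_beta1 = 0.9, batch_size = 16L,
                         epochs = 100L, warmup_epochs = 5L, tau = 0.1,
                         local_extent = 0.5, min_lr = 0, seed = 1L) {
  variant <- match.arg(variant)
  if (is.null(embed_dim)) embed_dim <- if (variant == "tiny") 128L else 768L
  if (is.null(depth)) depth <- if (variant == "tiny") 4L else 12L
  if (is.null(heads)) heads <- if (variant == "tiny") 4L else 12L
  if (voi_size %% patch_size != 0)
    stop("patch_size must divide voi_size", call. = FALSE)
  if (embed_dim %% heads != 0)
    stop("heads must divide embed_dim", call. = FALSE)
  if (alpha < 1) stop("alpha must be >= 1", call. = FALSE)
  if (r <= 0) stop("r must be > 0", call. = FALSE)
  if (beta <= 0) stop("beta must be > 0", call. = FALSE)
  if (tau <= 0) stop("tau must be > 0", call. = FALSE)
  structure(list(variant = variant, voi_size = as.integer(voi_size),
                 patch_size = as.integer(patch_size),
                 embed_dim = as.integer(embed_dim), depth = as.integer(depth),
                 heads = as.integer(heads), mlp_ratio = mlp_ratio,
                 alpha = alpha, r = r, beta = beta, lr = lr,
                 weight_decay = weight_decay,
                 momentum_beta1 = momentum_beta1,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 warmup_epochs = as.integer(warmup_epochs), tau = tau,
                 local_extent = local_extent, min_lr = min_lr,
                 seed = as.integer(seed)),
            class = "model_config")
}

# HU intensity normalisation: clip to [-1000, 400], scale to [0, 1]
normalize_hu <- function(values) {
  v <- pmin(pmax(values, -1000), 400)
  (v + 1000) / 1400
}

# P x V matrix of linear array indices turning a (s,s,s) volume into
# non-overlapping patch rows; cached per geometry in the session
patch_perm_cache <- new.env(parent = emptyenv())
patch_perm <- function(voi_size, patch_size) {
  key <- paste(voi_size, patch_size)
  if (!is.null(patch_perm_cache[[key]])) return(patch_perm_cache[[key]])
  g <- voi_size %/% patch_size
  pg <- expand.grid(pz = 0:(g - 1), py = 0:(g - 1), px = 0:(g - 1))
  og <- expand.grid(oz = 1:patch_size, oy = 1:patch_size, ox = 1:patch_size)
  Z <- outer(pg$pz * patch_size, og$oz, `+`)
  Y <- outer(pg$py * patch_size, og$oy, `+`)
  X <- outer(pg$px * patch_size, og$ox, `+`)
  pp <- Z + (Y - 1) * voi_size + (X - 1) * voi_size^2
  res <- list(pp = pp, grid = g,
              centers = (as.matrix(pg) + 0.5) * patch_size)
  patch_perm_cache[[key]] <- res
  res
}

# indices (1-based, patch order) of patches whose centres fall in the
# central cube of extent `local_extent` * voi_size
local_patch_set <- function(cfg) {
  pp <- patch_perm(cfg$voi_size, cfg$patch_size)
  half <- cfg$voi_size * cfg$local_extent / 2
  ok <- apply(abs(pp$centers - cfg$voi_size / 2) <= half + 1e-9, 1, all)
  which(ok)
}

voi_to_patches <- function(voi, cfg) {
  vals <- if (inherits(voi, "voxel_grid")) voi$values else voi
  stopifnot(all(dim(vals) == cfg$voi_size))
  pp <- patch_perm(cfg$voi_size, cfg$patch_size)$pp
  matrix(normalize_hu(vals)[pp], nrow(pp), ncol(pp))
}

trunc_normal <- function(n, sd = 0.02) {
  x <- stats::rnorm(n, 0, sd)
  pmin(pmax(x, -2 * sd), 2 * sd)
}

#' Initialise a Siamese growth model
#'
#' @param cfg a [model_config].
#' @return A `siam_model`: list with `params`, `cfg` and empty `history`.
#' @export
siam_init <- function(cfg) {
  stopifnot(inherits(cfg, "model_config"))
  D <- cfg$embed_dim
  P <- (cfg$voi_size %/% cfg$patch_size)^3
  Dp <- cfg$patch_size^3
  H <- as.integer(round(D * cfg$mlp_ratio))
  with_seed(cfg$seed, {
    pr <- list(
      embed_W = matrix(trunc_normal(Dp * D), Dp, D),
      embed_b = numeric(D),
      cls = trunc_normal(D),
      pos = matrix(trunc_normal((P + 1) * D), P + 1, D),
      missing = trunc_normal(D))
    for (i in seq_len(cfg$depth)) {
      pre <- paste0("L", i, "_")
      pr[[paste0(pre, "ln1_g")]] <- rep(1, D)
      pr[[paste0(pre, "ln1_b")]] <- numeric(D)
      for (w in c("Wq", "Wk", "Wv", "Wo"))
        pr[[paste0(pre, w)]] <- matrix(trunc_normal(D * D), D, D)
      for (b in c("bq", "bk", "bv", "bo"))
        pr[[paste0(pre, b)]] <- numeric(D)
      pr[[paste0(pre, "ln2_g")]] <- rep(1, D)
      pr[[paste0(pre, "ln2_b")]] <- numeric(D)
      pr[[paste0(pre, "W1")]] <- matrix(trunc_normal(D * H), D, H)
      pr[[paste0(pre, "b1")]] <- numeric(H)
      pr[[paste0(pre, "W2")]] <- matrix(trunc_normal(H * D), H, D)
      pr[[paste0(pre, "b2")]] <- numeric(D)
    }
    pr$lnf_g <- rep(1, D); pr$lnf_b <- numeric(D)
    ht <- 8L
    pr$lnT_g <- rep(1, D); pr$lnT_b <- numeric(D)
    pr$Wt1 <- matrix(trunc_normal(3 * ht), 3, ht); pr$bt1 <- numeric(ht)
    pr$Wt2 <- matrix(trunc_normal(ht * 3), ht, 3); pr$bt2 <- numeric(3)
    pr$lnC_g <- rep(1, D); pr$lnC_b <- numeric(D)
    pr$Wc1 <- matrix(trunc_normal(D * H), D, H); pr$bc1 <- numeric(H)
    pr$Wc2 <- matrix(trunc_normal(H * D), H, D); pr$bc2 <- numeric(D)
    pr$head_W <- matrix(trunc_normal(3 * D), 3 * D, 1)
    pr$head_b <- 0
    structure(list(params = pr, cfg = cfg, history = NULL),
              class = "siam_model")
  })
}

#' @export
print.siam_model <- function(x, ...) {
  n_par <- sum(vapply(x$params, length, numeric(1)))
  cat(sprintf("<siam_model> %s encoder: depth %d, dim %d, %d heads; %s parameters\n",
              x$cfg$variant, x$cfg$depth, x$cfg$embed_dim, x$cfg$heads,
              format(n_par, big.mark = ",")))
  if (!is.null(x$history))
    cat(sprintf("  trained %d epochs, final mean loss %.4f\n",
                nrow(x$history), x$history$loss[nrow(x$history)]))
  invisible(x)
}

# ---- encoder ---------------------------------------------------------------

encoder_forward <- function(pr, Xp, cfg, want_cache = TRUE) {
  D <- cfg$embed_dim
  P <- (cfg$voi_size %/% cfg$patch_size)^3
  Tn <- P + 1L
  N <- nrow(Xp) / P
  tok <- linear_fwd(Xp, pr$embed_W, pr$embed_b)
  cls_rows <- (seq_len(N) - 1L) * Tn + 1L
  patch_rows <- setdiff(seq_len(N * Tn), cls_rows)
  x <- matrix(0, N * Tn, D)
  x[cls_rows, ] <- rowmat(pr$cls, N)
  x[patch_rows, ] <- tok
  x <- x + pr$pos[rep(seq_len(Tn), N), ]
  caches <- if (want_cache) vector("list", cfg$depth) else NULL
  for (i in seq_len(cfg$depth)) {
    pre <- paste0("L", i, "_")
    ln1 <- layernorm_fwd(x, pr[[paste0(pre, "ln1_g")]], pr[[paste0(pre, "ln1_b")]])
    at <- attention_fwd(ln1$y, pr[[paste0(pre, "Wq")]], pr[[paste0(pre, "bq")]],
                        pr[[paste0(pre, "Wk")]], pr[[paste0(pre, "bk")]],
                        pr[[paste0(pre, "Wv")]], pr[[paste0(pre, "bv")]],
                        pr[[paste0(pre, "Wo")]], pr[[paste0(pre, "bo")]],
                        Tn, cfg$heads)
    x1 <- x + at$out
    ln2 <- layernorm_fwd(x1, pr[[paste0(pre, "ln2_g")]], pr[[paste0(pre, "ln2_b")]])
    hpre <- linear_fwd(ln2$y, pr[[paste0(pre, "W1")]], pr[[paste0(pre, "b1")]])
    h <- gelu(hpre)
    x2 <- x1 + linear_fwd(h, pr[[paste0(pre, "W2")]], pr[[paste0(pre, "b2")]])
    if (want_cache) {
      at$y <- ln1$y   # keep LN output for weight grads
      caches[[i]] <- list(ln1 = ln1, at = at, x = x, x1 = x1, ln2 = ln2,
                          hpre = hpre, h = h)
    }
    x <- x2
  }
  lnf <- layernorm_fwd(x, pr$lnf_g, pr$lnf_b)
  list(out = lnf$y,
       cache = if (want_cache) list(layers = caches, lnf = lnf, xf = x,
                                    Xp = Xp, N = N, Tn = Tn,
                                    cls_rows = cls_rows,
                                    patch_rows = patch_rows) else NULL,
       N = N, Tn = Tn, cls_rows = cls_rows)
}

encoder_backward <- function(pr, dout, cache, cfg) {
  g <- list()
  lb <- layernorm_bwd(dout, cache$lnf)
  g$lnf_g <- lb$dg; g$lnf_b <- lb$db
  dx <- lb$dx
  for (i in rev(seq_len(cfg$depth))) {
    pre <- paste0("L", i, "_")
    cc <- cache$layers[[i]]
    # MLP branch
    dmlp <- dx
    dh <- dmlp %*% t(pr[[paste0(pre, "W2")]])
    g[[paste0(pre, "W2")]] <- crossprod(cc$h, dmlp)
    g[[paste0(pre, "b2")]] <- colSums(dmlp)
    dhpre <- dh * gelu_grad(cc$hpre)
    dy2 <- dhpre %*% t(pr[[paste0(pre, "W1")]])
    g[[paste0(pre, "W1")]] <- crossprod(cc$ln2$y, dhpre)
    g[[paste0(pre, "b1")]] <- colSums(dhpre)
    lb2 <- layernorm_bwd(dy2, cc$ln2)
    g[[paste0(pre, "ln2_g")]] <- lb2$dg
    g[[paste0(pre, "ln2_b")]] <- lb2$db
    dx1 <- dx + lb2$dx
    # attention branch
    ab <- attention_bwd(dx1, cc$at, pr[[paste0(pre, "Wq")]],
                        pr[[paste0(pre, "Wk")]], pr[[paste0(pre, "Wv")]],
                        pr[[paste0(pre, "Wo")]])
    g[[paste0(pre, "Wq")]] <- ab$dWq; g[[paste0(pre, "bq")]] <- ab$dbq
    g[[paste0(pre, "Wk")]] <- ab$dWk; g[[paste0(pre, "bk")]] <- ab$dbk
    g[[paste0(pre, "Wv")]] <- ab$dWv; g[[paste0(pre, "bv")]] <- ab$dbv
    g[[paste0(pre, "Wo")]] <- ab$dWo; g[[paste0(pre, "bo")]] <- ab$dbo
    lb1 <- layernorm_bwd(ab$dy, cc$ln1)
    g[[paste0(pre, "ln1_g")]] <- lb1$dg
    g[[paste0(pre, "ln1_b")]] <- lb1$db
    dx <- dx1 + lb1$dx
  }
  N <- cache$N; Tn <- cache$Tn
  g$pos <- rowsum(dx, rep(seq_len(Tn), N), reorder = TRUE)
  g$cls <- colSums(dx[cache$cls_rows, , drop = FALSE])
  dtok <- dx[cache$patch_rows, , drop = FALSE]
  g$embed_W <- crossprod(cache$Xp, dtok)
  g$embed_b <- colSums(dtok)
  g
}

# pooled embeddings from encoder output: FG (cls) and FL (central patches)
encoder_pool <- function(out, N, Tn, local_rel, cls_rows) {
  FG <- out[cls_rows, , drop = FALSE]
  loc_rows <- as.vector(outer(local_rel, (seq_len(N) - 1L) * Tn, `+`))
  grp <- rep(seq_len(N), each = length(local_rel))
  FL <- rowsum(out[loc_rows, , drop = FALSE], grp, reorder = TRUE) /
    length(local_rel)
  list(FG = FG, FL = FL, loc_rows = loc_rows, grp = grp)
}

# ---- fusion (spatial-temporal mixer) + head --------------------------------

fusion_forward <- function(pr, FG, FLt, FLp, want_cache = TRUE) {
  B <- nrow(FG); D <- ncol(FG)
  ZT <- rbind(FG, FLt, FLp)                     # 3B x D, token blocks
  lnT <- layernorm_fwd(ZT, pr$lnT_g, pr$lnT_b)
  U <- lnT$y
  V <- cbind(as.vector(U[1:B, ]), as.vector(U[B + 1:B, ]),
             as.vector(U[2 * B + 1:B, ]))       # (B*D) x 3
  h1pre <- linear_fwd(V, pr$Wt1, pr$bt1)
  h1 <- gelu(h1pre)
  V2 <- linear_fwd(h1, pr$Wt2, pr$bt2)
  tokout <- rbind(matrix(V2[, 1], B, D), matrix(V2[, 2], B, D),
                  matrix(V2[, 3], B, D))
  Z1 <- ZT + tokout
  lnC <- layernorm_fwd(Z1, pr$lnC_g, pr$lnC_b)
  h2pre <- linear_fwd(lnC$y, pr$Wc1, pr$bc1)
  h2 <- gelu(h2pre)
  Z2 <- Z1 + linear_fwd(h2, pr$Wc2, pr$bc2)
  feat <- cbind(Z2[1:B, , drop = FALSE], Z2[B + 1:B, , drop = FALSE],
                Z2[2 * B + 1:B, , drop = FALSE])
  p <- as.vector(feat %*% pr$head_W + pr$head_b)
  cache <- if (want_cache) list(B = B, D = D, lnT = lnT, U = U, V = V,
                                h1pre = h1pre, h1 = h1, lnC = lnC,
                                h2pre = h2pre, h2 = h2, feat = feat) else NULL
  list(p = p, cache = cache)
}

fusion_backward <- function(pr, dp, cache) {
  B <- cache$B; D <- cache$D
  g <- list()
  dp <- matrix(dp, B, 1)
  g$head_W <- crossprod(cache$feat, dp)
  g$head_b <- sum(dp)
  dfeat <- dp %*% t(pr$head_W)                   # B x 3D
  dZ2 <- rbind(dfeat[, 1:D, drop = FALSE], dfeat[, D + 1:D, drop = FALSE],
               dfeat[, 2 * D + 1:D, drop = FALSE])
  # channel MLP
  dh2 <- dZ2 %*% t(pr$Wc2)
  g$Wc2 <- crossprod(cache$h2, dZ2)
  g$bc2 <- colSums(dZ2)
  dh2pre <- dh2 * gelu_grad(cache$h2pre)
  dCn <- dh2pre %*% t(pr$Wc1)
  g$Wc1 <- crossprod(cache$lnC$y, dh2pre)
  g$bc1 <- colSums(dh2pre)
  lbC <- layernorm_bwd(dCn, cache$lnC)
  g$lnC_g <- lbC$dg; g$lnC_b <- lbC$db
  dZ1 <- dZ2 + lbC$dx
  # token MLP
  dV2 <- cbind(as.vector(dZ1[1:B, ]), as.vector(dZ1[B + 1:B, ]),
               as.vector(dZ1[2 * B + 1:B, ]))
  dh1 <- dV2 %*% t(pr$Wt2)
  g$Wt2 <- crossprod(cache$h1, dV2)
  g$bt2 <- colSums(dV2)
  dh1pre <- dh1 * gelu_grad(cache$h1pre)
  dV <- dh1pre %*% t(pr$Wt1)
  g$Wt1 <- crossprod(cache$V, dh1pre)
  g$bt1 <- colSums(dh1pre)
  dU <- rbind(matrix(dV[, 1], B, D), matrix(dV[, 2], B, D),
              matrix(dV[, 3], B, D))
  lbT <- layernorm_bwd(dU, cache$lnT)
  g$lnT_g <- lbT$dg; g$lnT_b <- lbT$db
  dZT <- dZ1 + lbT$dx
  list(grads = g, dFG = dZT[1:B, , drop = FALSE],
       dFLt = dZT[B + 1:B, , drop = FALSE],
       dFLp = dZT[2 * B + 1:B, , drop = FALSE])
}

# ---- spec-level operations -------------------------------------------------

#' Encode an exam pair into its feature bundle
#'
#' Both VOIs pass through the same shared-weight encoder. `FG_t` is the
#' whole-VOI class-token summary of the current VOI only, `FL_t` and
#' `FL_prev` are nodule-centred local summaries; when the prior VOI is
#' absent, `FL_prev` is the model's learnable substitute vector.
#'
#' @param pair list with `current_voi` ([voxel_grid] or array) and optional
#'   `prior_voi` (NULL when the prior scan is unavailable).
#' @param model a `siam_model`.
#' @return list `FG_t`, `FL_t`, `FL_prev` (numeric vectors of `embed_dim`).
#' @export
encode_pair <- function(pair, model) {
  cfg <- model$cfg
  cur <- voi_to_patches(pair$current_voi, cfg)
  has_prior <- !is.null(pair$prior_voi)
  Xp <- if (has_prior) rbind(cur, voi_to_patches(pair$prior_voi, cfg)) else cur
  fw <- encoder_forward(model$params, Xp, cfg, want_cache = FALSE)
  local_rel <- local_patch_set(cfg) + 1L
  pool <- encoder_pool(fw$out, fw$N, fw$Tn, local_rel, fw$cls_rows)
  list(FG_t = pool$FG[1, ], FL_t = pool$FL[1, ],
       FL_prev = if (has_prior) pool$FL[2, ] else model$params$missing)
}

#' Fuse a feature bundle and predict the growth rate
#'
#' @param bundle output of [encode_pair()].
#' @param model a `siam_model`.
#' @return scalar predicted relative growth rate `p`.
#' @export
fuse_and_predict <- function(bundle, model) {
  fusion_forward(model$params, matrix(bundle$FG_t, 1), matrix(bundle$FL_t, 1),
                 matrix(bundle$FL_prev, 1), want_cache = FALSE)$p
}

#' Weighted smooth-L1 regression loss
#'
#' `loss = alpha * SmoothL1(p - y)` when `y >= r`, else `SmoothL1(p - y)`,
#' with `SmoothL1(d) = d^2 / (2 beta)` for `|d| < beta` and
#' `|d| - beta / 2` otherwise. Weighting the scarce high-rate (growing)
#' examples by `alpha` counteracts the class imbalance of screening
#' cohorts. Reduces to plain smooth-L1 at `alpha = 1`.
#'
#' @param p predicted rates. @param y true rates.
#' @param alpha imbalance coefficient (default 3).
#' @param r indicator threshold on `y` (default 0.1).
#' @param beta transition width (default 1).
#' @return elementwise loss values (same length as `p`).
#' @export
weighted_smooth_l1 <- function(p, y, alpha = 3.0, r = 0.1, beta = 1.0) {
  stopifnot(alpha > 0, beta > 0)
  d <- p - y
  base <- ifelse(abs(d) < beta, d^2 / (2 * beta), abs(d) - beta / 2)
  ifelse(y >= r, alpha * base, base)
}

weighted_smooth_l1_grad <- function(p, y, alpha, r, beta) {
  d <- p - y
  g <- ifelse(abs(d) < beta, d / beta, sign(d))
  ifelse(y >= r, alpha * g, g)
}

#' Map a predicted rate to a growth probability (sharpening)
#'
#' `prob = 1 / (1 + exp(-(p - th) / tau))`: a logistic map centred on the
#' operating threshold with sharpening coefficient `tau` (default 0.1).
#' `prob >= 0.5` (equivalently `p >= th`) indicates predicted growth.
#'
#' @param p predicted rate(s). @param th operating threshold.
#' @param tau sharpening coefficient (> 0).
#' @return list with `prob` and logical `decision`.
#' @export
sharpen <- function(p, th, tau = 0.1) {
  stopifnot(tau > 0)
  prob <- 1 / (1 + exp(-(p - th) / tau))
  list(prob = prob, decision = prob >= 0.5)
}

#' Choose the operating threshold by Youden's J on a validation set
#'
#' Scans the midpoints between consecutive distinct validation scores and
#' returns the threshold maximising J = sensitivity + specificity - 1
#' under the inclusive decision rule `score >= th`; ties take the smallest
#' candidate.
#'
#' @param val_outputs validation scores. @param val_labels logical labels.
#' @return threshold.
#' @export
select_threshold <- function(val_outputs, val_labels) {
  val_labels <- as.logical(val_labels)
  if (!any(val_labels) || all(val_labels))
    stop("validation labels must contain both classes", call. = FALSE)
  u <- sort(unique(val_outputs))
  cands <- if (length(u) > 1) (u[-1] + u[-length(u)]) / 2 else u
  j <- vapply(cands, function(th) {
    m <- operating_metrics(val_outputs, val_labels, th)
    m$sensitivity + m$specificity - 1
  }, numeric(1))
  cands[which.max(j)]
}

# ---- training --------------------------------------------------------------

# assemble pooled-gradient matrix for the encoder: dFG/dFLt into current
# volumes, dFLp into present-prior volumes
assemble_dout <- function(dFG, dFLt, dFLp_enc, N, Tn, B, local_rel, prior_vol_idx) {
  D <- ncol(dFG)
  dout <- matrix(0, N * Tn, D)
  cls_rows <- (seq_len(B) - 1L) * Tn + 1L
  dout[cls_rows, ] <- dFG
  nl <- length(local_rel)
  for (b in seq_len(B)) {
    rows <- (b - 1L) * Tn + local_rel
    dout[rows, ] <- dout[rows, ] + rowmat(dFLt[b, ] / nl, nl)
  }
  if (length(prior_vol_idx))
    for (j in seq_along(prior_vol_idx)) {
      rows <- (prior_vol_idx[j] - 1L) * Tn + local_rel
      dout[rows, ] <- dout[rows, ] + rowmat(dFLp_enc[j, ] / nl, nl)
    }
  dout
}

#' Train the Siamese growth model
#'
#' AdamW with decoupled weight decay, linear warmup from 1e-5 to
#' `lr * batch_size / 64` over the warmup epochs, then cosine annealing.
#' The loss is the weighted smooth-L1 on the predicted vs. true annualised
#' mass rate. Training is deterministic given `cfg$seed`.
#'
#' @param examples list of examples, each with `current_voi`, optional
#'   `prior_voi` (NULL = use the learnable substitute) and target rate `y`
#'   (e.g. `generate_cohort()$examples`).
#' @param cfg a [model_config].
#' @param use_prior if FALSE, all priors are treated as absent (the
#'   single-timepoint "once" mode).
#' @param verbose print per-epoch loss.
#' @return A trained `siam_model` with `history` (epoch, lr, loss).
#' @export
train_siam <- function(examples, cfg, use_prior = TRUE, verbose = FALSE) {
  if (length(examples) == 0) stop("empty training set", call. = FALSE)
  y_all <- vapply(examples, function(e) e$y, numeric(1))
  stopifnot(all(is.finite(y_all)))
  cur_p <- lapply(examples, function(e) voi_to_patches(e$current_voi, cfg))
  pri_p <- lapply(examples, function(e)
    if (use_prior && !is.null(e$prior_voi)) voi_to_patches(e$prior_voi, cfg)
    else NULL)
  has_prior <- !vapply(pri_p, is.null, logical(1))
  n <- length(examples)
  model <- siam_init(cfg)
  # deep-copy so the in-place AdamW kernel owns these buffers exclusively
  pr <- lapply(model$params, function(x) x + 0)
  state <- adamw_init(pr)
  decay_mask <- adamw_decay_set(pr)
  local_rel <- local_patch_set(cfg) + 1L
  n_batches <- ceiling(n / cfg$batch_size)
  total_steps <- cfg$epochs * n_batches
  warmup_steps <- cfg$warmup_epochs * n_batches
  base_lr <- cfg$lr * cfg$batch_size / 64
  hist <- data.frame(epoch = integer(0), lr = numeric(0), loss = numeric(0))
  step <- 0L
  for (ep in seq_len(cfg$epochs)) {
    ord <- with_seed(cfg$seed + 1000L + ep, sample.int(n))
    ep_loss <- 0; ep_n <- 0L; lr_now <- NA_real_
    for (bi in seq_len(n_batches)) {
      idx <- ord[((bi - 1L) * cfg$batch_size + 1L):min(bi * cfg$batch_size, n)]
      B <- length(idx)
      pv_idx <- idx[has_prior[idx]]
      Xp <- do.call(rbind, c(cur_p[idx], pri_p[pv_idx]))
      fw <- encoder_forward(pr, Xp, cfg, want_cache = TRUE)
      pool <- encoder_pool(fw$out, fw$N, fw$Tn, local_rel, fw$cls_rows)
      FG <- pool$FG[seq_len(B), , drop = FALSE]
      FLt <- pool$FL[seq_len(B), , drop = FALSE]
      FLp <- matrix(0, B, cfg$embed_dim)
      miss <- !has_prior[idx]
      if (any(!miss))
        FLp[!miss, ] <- pool$FL[B + seq_len(sum(!miss)), , drop = FALSE]
      if (any(miss)) FLp[miss, ] <- rowmat(pr$missing, sum(miss))
      fu <- fusion_forward(pr, FG, FLt, FLp, want_cache = TRUE)
      yb <- y_all[idx]
      loss_b <- mean(weighted_smooth_l1(fu$p, yb, cfg$alpha, cfg$r, cfg$beta))
      dp <- weighted_smooth_l1_grad(fu$p, yb, cfg$alpha, cfg$r, cfg$beta) / B
      fb <- fusion_backward(pr, dp, fu$cache)
      grads <- fb$grads
      if (any(miss))
        grads$missing <- colSums(fb$dFLp[miss, , drop = FALSE])
      dFLp_enc <- fb$dFLp[!miss, , drop = FALSE]
      dout <- assemble_dout(fb$dFG, fb$dFLt, dFLp_enc, fw$N, fw$Tn, B,
                            local_rel, B + seq_len(sum(!miss)))
      genc <- encoder_backward(pr, dout, fw$cache, cfg)
      grads[names(genc)] <- genc
      lr_now <- lr_schedule(step, total_steps, warmup_steps, base_lr,
                            min_lr = cfg$min_lr)
      upd <- adamw_step(pr, grads, state, lr = lr_now, wd = cfg$weight_decay,
                        beta1 = cfg$momentum_beta1, decay_mask = decay_mask)
      pr <- upd$params; state <- upd$state
      step <- step + 1L
      ep_loss <- ep_loss + loss_b * B; ep_n <- ep_n + B
    }
    hist <- rbind(hist, data.frame(epoch = ep, lr = lr_now,
                                   loss = ep_loss / ep_n))
    if (verbose)
      message(sprintf("epoch %3d  lr %.3e  loss %.5f", ep, lr_now,
                      ep_loss / ep_n))
  }
  model$params <- pr
  model$history <- hist
  model
}

#' Predict growth rates for a set of examples
#'
#' @param model a trained `siam_model`.
#' @param examples list of examples (`current_voi`, optional `prior_voi`).
#' @param use_prior if FALSE, ignore all priors (single-timepoint mode).
#' @return numeric vector of predicted rates `p`.
#' @export
predict_siam <- function(model, examples, use_prior = TRUE) {
  cfg <- model$cfg
  pr <- model$params
  local_rel <- local_patch_set(cfg) + 1L
  n <- length(examples)
  out <- numeric(n)
  bs <- cfg$batch_size
  for (start in seq(1, n, by = bs)) {
    idx <- start:min(start + bs - 1L, n)
    B <- length(idx)
    cur <- lapply(examples[idx], function(e) voi_to_patches(e$current_voi, cfg))
    pri <- lapply(examples[idx], function(e)
      if (use_prior && !is.null(e$prior_voi)) voi_to_patches(e$prior_voi, cfg)
      else NULL)
    hasp <- !vapply(pri, is.null, logical(1))
    Xp <- do.call(rbind, c(cur, pri[hasp]))
    fw <- encoder_forward(pr, Xp, cfg, want_cache = FALSE)
    pool <- encoder_pool(fw$out, fw$N, fw$Tn, local_rel, fw$cls_rows)
    FG <- pool$FG[seq_len(B), , drop = FALSE]
    FLt <- pool$FL[seq_len(B), , drop = FALSE]
    FLp <- matrix(0, B, cfg$embed_dim)
    if (any(hasp)) FLp[hasp, ] <- pool$FL[B + seq_len(sum(hasp)), , drop = FALSE]
    if (any(!hasp)) FLp[!hasp, ] <- rowmat(pr$missing, sum(!hasp))
    out[idx] <- fusion_forward(pr, FG, FLt, FLp, want_cache = FALSE)$p
  }
  out
}

#' Save / load a trained model with a JSON metadata sidecar
#'
#' The binary checkpoint holds the parameters; the `.json` sidecar records
#' the configuration, seed and training history for provenance.
#'
#' @param model a `siam_model`. @param path checkpoint path (`.rds`).
#' @export
save_siam <- function(model, path) {
  saveRDS(model, path)
  meta <- list(config = unclass(model$cfg),
               history = model$history,
               n_parameters = sum(vapply(model$params, length, numeric(1))))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname save_siam
#' @export
load_siam <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "siam_model"))
  model
}
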