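# Siamese growth model: loss, sharpening, thresholding, schedule,
# architecture contracts and hand-derived gradients.

tiny_cfg <- function(...) model_config(voi_size = 8L, patch_size = 4L,
                                       embed_dim = 16L, depth = 2L,
                                       heads = 2L, seed = 3L, ...)

rand_voi <- function(seed, s = 8L) {
  set.seed(seed)
  array(rnorm(s^3, -700, 100), rep(s, 3))
}

test_that("weighted smooth-L1 matches its definition branch by branch", {
  expect_equal(weighted_smooth_l1(0.3, 0.3), 0)
  expect_equal(weighted_smooth_l1(0.85, 0.05), 0.5 * 0.8^2)    # quadratic branch
  expect_equal(weighted_smooth_l1(2.05, 0.05, beta = 1), 2 - 0.5)  # linear branch
  # the y >= r branch is exactly alpha times the y < r branch
  for (res in c(0.05, 0.5, 2, 7)) {
    lo <- weighted_smooth_l1(0.05 + res, 0.05, alpha = 3, r = 0.1)
    hi <- weighted_smooth_l1(0.2 + res, 0.2, alpha = 3, r = 0.1)
    expect_equal(hi / lo, 3)
  }
  # alpha = 1 reduces to plain smooth-L1 everywhere
  set.seed(1)
  p <- rnorm(50); y <- rnorm(50)
  d <- abs(p - y)
  plain <- ifelse(d < 1, d^2 / 2, d - 0.5)
  expect_equal(weighted_smooth_l1(p, y, alpha = 1), plain)
  # continuity across the beta transition
  beta <- 0.7
  eps <- 1e-8
  below <- weighted_smooth_l1(beta - eps, 0, alpha = 1, beta = beta)
  above <- weighted_smooth_l1(beta + eps, 0, alpha = 1, beta = beta)
  expect_lt(abs(above - below), 1e-6)
})

test_that("sharpen is the logistic map with the inclusive 0.5 boundary", {
  s <- sharpen(0.4, th = 0.4)
  expect_equal(s$prob, 0.5)
  expect_true(s$decision)
  expect_equal(sharpen(0.5, th = 0.4, tau = 0.1)$prob, 1 / (1 + exp(-1)))
  expect_gt(sharpen(50, 0)$prob, 1 - 1e-10)
  expect_lt(sharpen(-50, 0)$prob, 1e-10)
  # strict monotonicity and decision = sign(p - th)
  p <- seq(-1, 1, by = 0.05)
  pr <- sharpen(p, th = 0.2)$prob
  expect_true(all(diff(pr) > 0))
  expect_identical(sharpen(p, th = 0.2)$decision, p >= 0.2)
})

test_that("select_threshold maximises Youden's J with smallest-tie rule", {
  th <- select_threshold(c(0, 0.1, 0.8, 0.9), c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(th, 0.45)            # smallest midpoint attaining J = 1
  expect_error(select_threshold(1:4, rep(TRUE, 4)), "both classes")
  # degenerate: all scores equal -> J = 0 at the single candidate
  expect_equal(select_threshold(rep(0.3, 6), rep(c(TRUE, FALSE), 3)), 0.3)
  # brute-force sweep agreement on mixed sets
  set.seed(6)
  for (k in 1:10) {
    sc <- round(runif(20), 2)
    lb <- runif(20) < 0.5
    if (!any(lb) || all(lb)) next
    th <- select_threshold(sc, lb)
    j_at <- function(t) {
      m <- operating_metrics(sc, lb, t)
      m$sensitivity + m$specificity - 1
    }
    u <- sort(unique(sc))
    cands <- if (length(u) > 1) (u[-1] + u[-length(u)]) / 2 else u
    expect_equal(j_at(th), max(vapply(cands, j_at, numeric(1))),
                 tolerance = 1e-12)
  }
})

test_that("the learning-rate schedule hits its anchors", {
  # warmup start 1e-5; end of warmup = lr * batch / 64 = 1.25e-4
  base <- 5e-4 * 16 / 64
  expect_equal(lr_schedule(0, 1000, 50, base), 1e-5)
  expect_equal(lr_schedule(50, 1000, 50, base), base)
  expect_lt(lr_schedule(999, 1000, 50, base), base * 1e-4 + 1e-9)
  expect_equal(lr_schedule(1000, 1000, 50, base), 0)
  # monotone increase through warmup, monotone decrease after
  lrs <- vapply(0:1000, lr_schedule, numeric(1), total_steps = 1000,
                warmup_steps = 50, base_lr = base)
  expect_true(all(diff(lrs[1:51]) > 0))
  expect_true(all(diff(lrs[52:1001]) <= 1e-12))
})

test_that("Siamese weight sharing and the learnable substitute hold exactly", {
  cfg <- tiny_cfg()
  model <- siam_init(cfg)
  v <- rand_voi(1)
  # identical prior and current: identical local embeddings
  b <- encode_pair(list(current_voi = v, prior_voi = v), model)
  expect_equal(b$FL_t, b$FL_prev, tolerance = 1e-12)
  # absent prior: FL_prev is the stored substitute, whatever the current VOI
  b1 <- encode_pair(list(current_voi = v), model)
  b2 <- encode_pair(list(current_voi = rand_voi(2)), model)
  expect_identical(b1$FL_prev, model$params$missing)
  expect_identical(b2$FL_prev, model$params$missing)
  # batch order does not change per-item predictions (eval determinism)
  exs <- lapply(1:5, function(i) list(current_voi = rand_voi(i),
                                      prior_voi = rand_voi(i + 10)))
  p <- predict_siam(model, exs)
  p_rev <- rev(predict_siam(model, rev(exs)))
  expect_equal(p, p_rev, tolerance = 1e-10)
})

test_that("fusion head is linear in its final layer and uses every embedding", {
  cfg <- tiny_cfg()
  model <- siam_init(cfg)
  D <- cfg$embed_dim
  zero_b <- list(FG_t = numeric(D), FL_t = numeric(D), FL_prev = numeric(D))
  m0 <- model
  m0$params$head_W[] <- 0
  m0$params$head_b <- 0.37
  expect_equal(fuse_and_predict(zero_b, m0), 0.37, tolerance = 1e-12)
  # doubling head weights and bias doubles p
  b <- encode_pair(list(current_voi = rand_voi(3), prior_voi = rand_voi(4)),
                   model)
  p1 <- fuse_and_predict(b, model)
  m2 <- model
  m2$params$head_W <- 2 * m2$params$head_W
  m2$params$head_b <- 2 * m2$params$head_b
  expect_equal(fuse_and_predict(b, m2), 2 * p1, tolerance = 1e-10)
  # finite-difference sensitivity: p responds to each of the three embeddings
  for (nm in c("FG_t", "FL_t", "FL_prev")) {
    bp <- b; bp[[nm]] <- bp[[nm]] + 1e-4
    expect_gt(abs(fuse_and_predict(bp, model) - p1), 0)
  }
})

test_that("hand-derived gradients match finite differences everywhere", {
  cfg <- tiny_cfg()
  pr <- siam_init(cfg)$params
  exs <- lapply(1:3, function(i)
    list(current_voi = rand_voi(i),
         prior_voi = if (i %% 2 == 0) rand_voi(i + 20) else NULL,
         y = c(0.5, -0.1, 0.3)[i]))
  cur_p <- lapply(exs, function(e) ssngrowth:::voi_to_patches(e$current_voi, cfg))
  pri_p <- lapply(exs, function(e)
    if (!is.null(e$prior_voi)) ssngrowth:::voi_to_patches(e$prior_voi, cfg)
    else NULL)
  hasp <- !vapply(pri_p, is.null, logical(1))
  yb <- vapply(exs, function(e) e$y, numeric(1))
  local_rel <- ssngrowth:::local_patch_set(cfg) + 1L
  B <- 3L
  loss_fn <- function(pr) {
    Xp <- do.call(rbind, c(cur_p, pri_p[hasp]))
    fw <- ssngrowth:::encoder_forward(pr, Xp, cfg, want_cache = TRUE)
    pool <- ssngrowth:::encoder_pool(fw$out, fw$N, fw$Tn, local_rel,
                                     fw$cls_rows)
    FG <- pool$FG[1:B, , drop = FALSE]
    FLt <- pool$FL[1:B, , drop = FALSE]
    FLp <- matrix(0, B, cfg$embed_dim)
    FLp[hasp, ] <- pool$FL[B + seq_len(sum(hasp)), , drop = FALSE]
    FLp[!hasp, ] <- ssngrowth:::rowmat(pr$missing, sum(!hasp))
    fu <- ssngrowth:::fusion_forward(pr, FG, FLt, FLp, want_cache = TRUE)
    list(loss = mean(weighted_smooth_l1(fu$p, yb, 3, 0.1, 1)),
         fw = fw, fu = fu)
  }
  res <- loss_fn(pr)
  dp <- ssngrowth:::weighted_smooth_l1_grad(res$fu$p, yb, 3, 0.1, 1) / B
  fb <- ssngrowth:::fusion_backward(pr, dp, res$fu$cache)
  grads <- fb$grads
  grads$missing <- colSums(fb$dFLp[!hasp, , drop = FALSE])
  dout <- ssngrowth:::assemble_dout(fb$dFG, fb$dFLt,
                                    fb$dFLp[hasp, , drop = FALSE],
                                    res$fw$N, res$fw$Tn, B, local_rel,
                                    B + seq_len(sum(hasp)))
  genc <- ssngrowth:::encoder_backward(pr, dout, res$fw$cache, cfg)
  grads[names(genc)] <- genc
  eps <- 1e-5
  worst <- 0
  for (nm in names(pr)) {
    set.seed(nchar(nm))
    for (i in sample(length(pr[[nm]]), min(3, length(pr[[nm]])))) {
      pr2 <- pr
      pr2[[nm]][i] <- pr2[[nm]][i] + eps
      lp <- loss_fn(pr2)$loss
      pr2[[nm]][i] <- pr2[[nm]][i] - 2 * eps
      lm <- loss_fn(pr2)$loss
      fd <- (lp - lm) / (2 * eps)
      an <- grads[[nm]][i]
      # denominator floored: tiny gradients are dominated by FD round-off
      worst <- max(worst, abs(fd - an) / max(1e-5, abs(fd) + abs(an)))
    }
  }
  expect_lt(worst, 1e-3)
})

test_that("a short training run reduces the loss and is seed-reproducible", {
  set.seed(50)
  exs <- lapply(1:40, function(i) {
    grow <- i %% 2 == 0
    base <- rand_voi(i)
    list(current_voi = base + if (grow) 120 else 0,
         prior_voi = if (i %% 5 == 0) NULL else rand_voi(i + 100),
         y = if (grow) 0.5 else 0)
  })
  cfg <- tiny_cfg(epochs = 8L, warmup_epochs = 1L, batch_size = 8L)
  m1 <- train_siam(exs, cfg)
  expect_lt(m1$history$loss[8], m1$history$loss[1])
  m2 <- train_siam(exs, cfg)
  expect_identical(m1$history, m2$history)
  expect_equal(m1$params$head_W, m2$params$head_W, tolerance = 1e-12)
  expect_error(train_siam(list(), cfg), "empty")
})

test_that("model checkpoints round-trip with their JSON sidecar", {
  cfg <- tiny_cfg()
  model <- siam_init(cfg)
  path <- tempfile(fileext = ".rds")
  save_siam(model, path)
  re <- load_siam(path)
  expect_equal(re$params, model$params)
  meta <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(meta$config$embed_dim, 16)
  unlink(c(path, paste0(path, ".json")))
})
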