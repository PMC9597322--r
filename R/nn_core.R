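# Minimal dense neural-network core with hand-derived backpropagation.
#
# No deep-learning runtime is available in the installed R stack, so the
# transformer pieces the growth model needs are implemented directly:
# BLAS-backed linear maps, layer normalisation, GELU (sigmoid
# approximation), multi-head softmax attention (compiled kernels in
# src/attention.cpp), AdamW, and the linear-warmup + cosine-annealing
# learning-rate schedule. Activations are (rows = tokens across the batch)
# x (columns = channels) matrices throughout; every forward returns the
# cache its backward needs.

# GELU, sigmoid approximation: x * sigmoid(1.702 x). Within 1e-2 of the
# exact erf form and one exponential per element instead of two special
# functions; the approximation is standard in transformer practice.
gelu <- function(x) gelu_cpp(x)
gelu_grad <- function(x) gelu_grad_cpp(x)

rowmat <- function(v, n) matrix(v, n, length(v), byrow = TRUE)

linear_fwd <- function(x, W, b) add_rowvec_cpp(x %*% W, b)

layernorm_fwd <- function(x, g, b, eps = 1e-5) {
  out <- layernorm_fwd_cpp(x, g, b, eps)
  out$g <- g
  out
}

layernorm_bwd <- function(dy, cache) {
  layernorm_bwd_cpp(dy, cache$xhat, cache$inv, cache$g)
}

# multi-head self-attention over N independent token blocks of T rows each
attention_fwd <- function(y, Wq, bq, Wk, bk, Wv, bv, Wo, bo, n_tok, heads) {
  q <- linear_fwd(y, Wq, bq)
  k <- linear_fwd(y, Wk, bk)
  v <- linear_fwd(y, Wv, bv)
  a <- attn_fwd_cpp(q, k, v, n_tok, heads)
  out <- linear_fwd(a$o, Wo, bo)
  list(out = out, q = q, k = k, v = v, o = a$o, attn = a$attn, y = y,
       n_tok = n_tok, heads = heads)
}

attention_bwd <- function(dout, cache, Wq, Wk, Wv, Wo) {
  y <- cache$y
  dWo <- crossprod(cache$o, dout)
  dbo <- colSums(dout)
  do_ <- tcrossprod(dout, Wo)          # dout %*% t(Wo)
  b <- attn_bwd_cpp(do_, cache$q, cache$k, cache$v, cache$attn,
                    cache$n_tok, cache$heads)
  dy <- tcrossprod(b$dq, Wq) + tcrossprod(b$dk, Wk) + tcrossprod(b$dv, Wv)
  list(dy = dy,
       dWq = crossprod(y, b$dq), dbq = colSums(b$dq),
       dWk = crossprod(y, b$dk), dbk = colSums(b$dk),
       dWv = crossprod(y, b$dv), dbv = colSums(b$dv),
       dWo = dWo, dbo = dbo)
}

# ---- AdamW -----------------------------------------------------------------

adamw_init <- function(params)
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), step = 0L)

# decoupled weight decay on 2D weight matrices only (embeddings, attention,
# MLP, head); biases, gains, positional and token parameters are not decayed
adamw_decay_set <- function(params) {
  vapply(names(params), function(nm)
    is.matrix(params[[nm]]) && !nm %in% c("pos"), logical(1))
}

# The fused C++ kernel updates params and moments in place; callers must
# own the passed objects exclusively (train_siam deep-copies once upfront).
adamw_step <- function(params, grads, state, lr, wd, beta1 = 0.9,
                       beta2 = 0.999, eps = 1e-8, decay_mask = NULL) {
  state$step <- state$step + 1L
  t <- state$step
  if (is.null(decay_mask)) decay_mask <- adamw_decay_set(params)
  bc1 <- 1 - beta1^t; bc2 <- 1 - beta2^t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    adamw_update_cpp(params[[nm]], g, state$m[[nm]], state$v[[nm]],
                     lr, if (decay_mask[[nm]]) wd else 0,
                     beta1, beta2, eps, bc1, bc2)
  }
  list(params = params, state = state)
}

#' Warmup + cosine-annealing learning-rate schedule
#'
#' Linear warmup from `start_lr` (1e-5) to the scaled base rate
#' `lr * batch_size / 64` over the warmup steps, then cosine annealing to
#' `min_lr` over the remaining steps.
#'
#' @param step 0-based optimisation step.
#' @param total_steps total steps of the run.
#' @param warmup_steps steps in the warmup phase.
#' @param base_lr the already-scaled peak rate (`lr * batch_size / 64`).
#' @param start_lr warmup starting rate.
#' @param min_lr cosine floor.
#' @return learning rate at `step`.
#' @export
lr_schedule <- function(step, total_steps, warmup_steps, base_lr,
                        start_lr = 1e-5, min_lr = 0) {
  if (warmup_steps > 0 && step < warmup_steps)
    return(start_lr + (base_lr - start_lr) * step / warmup_steps)
  if (total_steps <= warmup_steps) return(base_lr)
  frac <- (step - warmup_steps) / (total_steps - warmup_steps)
  frac <- min(max(frac, 0), 1)
  min_lr + 0.5 * (base_lr - min_lr) * (1 + cos(pi * frac))
}
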