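#' Transformer model configuration
#'
#' Hyperparameters of the encoder. The hidden width `h` must be divisible by
#' the head count `k`; the per-head width is `d = h / k`. The sequence length
#' is `F + T` (phenotype slots then gene slots) and the position-embedding
#' table has one row per slot. Attention logits are scaled by `1/sqrt(d)` by
#' default; `attn_scale = "d"` switches to `1/d`.
#'
#' @param L number of transformer blocks.
#' @param h hidden width.
#' @param k number of attention heads.
#' @param B number of expression bins.
#' @param T number of gene slots.
#' @param F number of phenotype slots.
#' @param vocab_size vocabulary size.
#' @param ffn_mult feed-forward expansion factor (default 4).
#' @param dropout dropout rate on attention and feed-forward outputs
#'   (default 0.1; applied only during training).
#' @param attn_scale `"sqrt_d"` (default) or `"d"`.
#' @param pad_attend when FALSE (default), PAD keys are masked out of
#'   attention, so only expressed genes are attended to; which genes are
#'   absent still informs every output implicitly, because the softmax
#'   renormalizes over the present keys. TRUE keeps PAD slots visible as a
#'   dedicated "not expressed" embedding; in our planted-signal experiments
#'   this slowed learning (PAD keys swamp attention in sparse cells) without
#'   an accuracy benefit. PAD slots are excluded from the loss and from
#'   embedding extraction either way.
#' @return a `model_config` list with the above plus `d` and `S = F + T`.
#' @export
model_config <- function(L = 4L, h = 128L, k = 4L, B = 10L, T, F,
                         vocab_size, ffn_mult = 4L, dropout = 0.1,
                         attn_scale = c("sqrt_d", "d"), pad_attend = FALSE) {
  attn_scale <- match.arg(attn_scale)
  if (h %% k != 0L) stop("h must be divisible by k")
  if (any(c(L, h, k, B, T, F, vocab_size, ffn_mult) <= 0) && L != 0L)
    stop("config values must be positive")
  structure(list(L = as.integer(L), h = as.integer(h), k = as.integer(k),
                 d = as.integer(h / k), B = as.integer(B),
                 T = as.integer(T), F = as.integer(F),
                 S = as.integer(F + T),
                 vocab_size = as.integer(vocab_size),
                 ffn_mult = as.integer(ffn_mult), dropout = dropout,
                 attn_scale = attn_scale, pad_attend = isTRUE(pad_attend)),
            class = "model_config")
}

#' Initialize model parameters
#'
#' Gaussian init (sd 0.02) for embeddings and projection weights, unit gains
#' and zero biases for the layer norms. The token embedding `We` is tied to
#' the output head.
#'
#' @param cfg a `model_config`.
#' @param seed RNG seed.
#' @return a named list of parameter matrices/vectors (`We`, `Wp`, per-layer
#'   `L<l>.{ln1_g,ln1_b,Wq,Wk,Wv,Wo,ln2_g,ln2_b,W1,b1,W2,b2}`, `lnf_g`,
#'   `lnf_b`).
#' @export
init_params <- function(cfg, seed = 1L) {
  set.seed(seed)
  h <- cfg$h; ffn <- cfg$ffn_mult * h
  rn <- function(nr, nc) matrix(stats::rnorm(nr * nc, sd = 0.02), nr, nc)
  p <- list(We = rn(cfg$vocab_size, h), Wp = rn(cfg$S, h))
  for (l in seq_len(cfg$L)) {
    pre <- paste0("L", l, ".")
    p[[paste0(pre, "ln1_g")]] <- rep(1, h)
    p[[paste0(pre, "ln1_b")]] <- rep(0, h)
    p[[paste0(pre, "Wq")]] <- rn(h, h)
    p[[paste0(pre, "Wk")]] <- rn(h, h)
    p[[paste0(pre, "Wv")]] <- rn(h, h)
    p[[paste0(pre, "Wo")]] <- rn(h, h)
    p[[paste0(pre, "ln2_g")]] <- rep(1, h)
    p[[paste0(pre, "ln2_b")]] <- rep(0, h)
    p[[paste0(pre, "W1")]] <- rn(h, ffn)
    p[[paste0(pre, "b1")]] <- rep(0, ffn)
    p[[paste0(pre, "W2")]] <- rn(ffn, h)
    p[[paste0(pre, "b2")]] <- rep(0, h)
  }
  p$lnf_g <- rep(1, h)
  p$lnf_b <- rep(0, h)
  p
}

# ---- primitives -----------------------------------------------------------

#' Gaussian error linear unit
#' @param x numeric vector or matrix.
#' @return `x * pnorm(x)` (exact GELU).
#' @export
gelu <- function(x) x * stats::pnorm(x)

gelu_grad <- function(x) stats::pnorm(x) + x * stats::dnorm(x)

# multiply / add a per-column vector without sweep's aperm copies
scale_cols <- function(x, g) x * rep(g, each = nrow(x))
add_cols <- function(x, b) x + rep(b, each = nrow(x))

# Row-wise layer norm; returns y plus the cache needed for the backward pass.
layer_norm_fwd <- function(x, g, b, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  inv <- 1 / sqrt(rowMeans(xc * xc) + eps)
  xhat <- xc * inv
  y <- add_cols(scale_cols(xhat, g), b)
  list(y = y, xhat = xhat, inv = inv)
}

layer_norm_bwd <- function(dy, cache, g) {
  dxhat <- scale_cols(dy, g)
  dg <- colSums(dy * cache$xhat)
  db <- colSums(dy)
  dx <- cache$inv *
    (dxhat - rowMeans(dxhat) - cache$xhat * rowMeans(dxhat * cache$xhat))
  list(dx = dx, dg = dg, db = db)
}

#' Layer normalization
#'
#' Row-wise layer norm with learnable gain and bias (epsilon 1e-5).
#'
#' @param x rows x h matrix (one token state per row).
#' @param g gain vector of length h.
#' @param b bias vector of length h.
#' @return normalized matrix of the same shape.
#' @export
layer_norm <- function(x, g = rep(1, ncol(x)), b = rep(0, ncol(x))) {
  layer_norm_fwd(x, g, b)$y
}

#' Scaled softmax attention for one head
#'
#' Computes row-softmax attention `D^-1 A V` with `A = exp(Q K' / sqrt(d))`
#' (or `/ d` when `scale = "d"`), restricting the softmax to unmasked keys.
#' A query whose keys are all masked yields a zero output row.
#'
#' @param Q,K,V S x d matrices.
#' @param pad_mask logical length-S vector, TRUE where the position is PAD
#'   and must be excluded as a key.
#' @param scale `"sqrt_d"` (default) or `"d"`.
#' @return S x d output matrix with attribute `"weights"` (the S x S row-
#'   stochastic attention matrix; all-masked rows are zero).
#' @export
attention <- function(Q, K, V, pad_mask = NULL,
                      scale = c("sqrt_d", "d")) {
  scale <- match.arg(scale)
  d <- ncol(Q)
  sc <- if (scale == "d") d else sqrt(d)
  logits <- tcrossprod(Q, K) / sc
  if (!is.null(pad_mask) && any(pad_mask)) {
    if (all(pad_mask)) {
      A <- matrix(0, nrow(Q), nrow(K))
      out <- matrix(0, nrow(Q), ncol(V))
      attr(out, "weights") <- A
      return(out)
    }
    logits[, pad_mask] <- -Inf
  }
  A <- row_softmax(logits)
  out <- A %*% V
  attr(out, "weights") <- A
  out
}

# numerically stable row softmax; rows that are entirely -Inf become zero
row_softmax <- function(logits) {
  mx <- logits[cbind(seq_len(nrow(logits)), max.col(logits, "first"))]
  bad <- !is.finite(mx)
  mx[bad] <- 0
  e <- exp(logits - mx)
  e[!is.finite(e)] <- 0
  s <- rowSums(e)
  s[s == 0] <- 1
  e / s
}

#' One pre-norm transformer block
#'
#' Pre-norm residual composition: `Xb = LN(X)`, `M = MultiHead(Xb) + X`,
#' `Mb = LN(M)`, `out = FFN(Mb) + M`, with multi-head attention the
#' concatenation of `k` scaled-softmax heads times an output projection and
#' the FFN a GELU two-layer perceptron.
#'
#' @param X S x h input matrix.
#' @param lp layer parameter list with `ln1_g, ln1_b, Wq, Wk, Wv, Wo, ln2_g,
#'   ln2_b, W1, b1, W2, b2`.
#' @param k number of heads.
#' @param pad_mask logical length-S key mask (TRUE = excluded).
#' @param scale attention logit scaling (see [attention()]).
#' @return S x h output matrix.
#' @export
transformer_block <- function(X, lp, k, pad_mask = NULL,
                              scale = c("sqrt_d", "d")) {
  scale <- match.arg(scale)
  if (anyNA(X) || any(!is.finite(X))) stop("numeric error: NaN in block input")
  h <- ncol(X); d <- h / k
  Xb <- layer_norm_fwd(X, lp$ln1_g, lp$ln1_b)$y
  Q <- Xb %*% lp$Wq; K <- Xb %*% lp$Wk; V <- Xb %*% lp$Wv
  Z <- matrix(0, nrow(X), h)
  for (i in seq_len(k)) {
    cols <- ((i - 1L) * d + 1L):(i * d)
    Z[, cols] <- attention(Q[, cols, drop = FALSE], K[, cols, drop = FALSE],
                           V[, cols, drop = FALSE], pad_mask, scale)
  }
  M <- Z %*% lp$Wo + X
  Mb <- layer_norm_fwd(M, lp$ln2_g, lp$ln2_b)$y
  Hff <- add_cols(Mb %*% lp$W1, lp$b1)
  out <- add_cols(gelu(Hff) %*% lp$W2, lp$b2) + M
  if (any(!is.finite(out))) stop("numeric error: NaN in block output")
  out
}

# extract the parameter sub-list of layer l
layer_params <- function(params, l) {
  pre <- paste0("L", l, ".")
  nm <- c("ln1_g", "ln1_b", "Wq", "Wk", "Wv", "Wo", "ln2_g", "ln2_b",
          "W1", "b1", "W2", "b2")
  out <- lapply(nm, function(s) params[[paste0(pre, s)]])
  names(out) <- nm
  out
}
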