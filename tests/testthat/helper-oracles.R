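# Independent brute-force oracles used to cross-check the fast paths.

# attention by explicit per-row softmax loops
oracle_attention <- function(Q, K, V, pad_mask = NULL, scale = "sqrt_d") {
  d <- ncol(Q)
  sc <- if (scale == "d") d else sqrt(d)
  S <- nrow(Q)
  out <- matrix(0, S, ncol(V))
  for (i in seq_len(S)) {
    w <- numeric(nrow(K))
    for (j in seq_len(nrow(K))) w[j] <- sum(Q[i, ] * K[j, ]) / sc
    if (!is.null(pad_mask)) w[pad_mask] <- -Inf
    if (all(!is.finite(w))) next
    e <- exp(w - max(w[is.finite(w)]))
    e[!is.finite(e)] <- 0
    p <- e / sum(e)
    for (j in seq_len(nrow(K))) out[i, ] <- out[i, ] + p[j] * V[j, ]
  }
  out
}

# hand-coded pre-norm block composition, written independently of the package
oracle_block <- function(X, lp, k) {
  ln <- function(x, g, b) {
    t(apply(x, 1L, function(r) {
      mu <- mean(r); v <- mean((r - mu)^2)
      g * (r - mu) / sqrt(v + 1e-5) + b
    }))
  }
  h <- ncol(X); d <- h / k
  Xb <- ln(X, lp$ln1_g, lp$ln1_b)
  Z <- matrix(0, nrow(X), h)
  for (i in seq_len(k)) {
    cols <- ((i - 1) * d + 1):(i * d)
    Z[, cols] <- oracle_attention(Xb %*% lp$Wq[, cols, drop = FALSE],
                                  Xb %*% lp$Wk[, cols, drop = FALSE],
                                  Xb %*% lp$Wv[, cols, drop = FALSE])
  }
  M <- Z %*% lp$Wo + X
  Mb <- ln(M, lp$ln2_g, lp$ln2_b)
  Hff <- sweep(Mb %*% lp$W1, 2, lp$b1, "+")
  act <- Hff * pnorm(Hff)
  sweep(act %*% lp$W2, 2, lp$b2, "+") + M
}

# naive O(n^3) average-linkage agglomeration; returns sorted merge heights
oracle_average_linkage_heights <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- c(NA, NA); best_h <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        hh <- mean(d[clusters[[i]], clusters[[j]]])
        if (hh < best_h) { best_h <- hh; best <- c(i, j) }
      }
    }
    heights <- c(heights, best_h)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  sort(heights)
}

# per-slot additive embedding computed position by position
embed_flat_oracle <- function(cells, params) {
  n <- nrow(cells$tokens); S <- ncol(cells$tokens)
  out <- matrix(0, n * S, ncol(params$We))
  for (c_i in seq_len(n)) for (s in seq_len(S))
    out[(s - 1) * n + c_i, ] <-
      params$We[cells$tokens[c_i, s], ] + params$Wp[s, ]
  out
}

# random layer parameters for block-level tests
random_layer_params <- function(h, ffn_mult = 4, sd = 0.2, zero = FALSE) {
  rn <- function(nr, nc) {
    if (zero) matrix(0, nr, nc) else matrix(rnorm(nr * nc, sd = sd), nr, nc)
  }
  list(ln1_g = rep(1, h), ln1_b = rep(0, h),
       Wq = rn(h, h), Wk = rn(h, h), Wv = rn(h, h), Wo = rn(h, h),
       ln2_g = rep(1, h), ln2_b = rep(0, h),
       W1 = rn(h, ffn_mult * h), b1 = rep(0, ffn_mult * h),
       W2 = rn(ffn_mult * h, h), b2 = rep(0, h))
}
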