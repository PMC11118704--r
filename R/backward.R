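# Analytic backward pass through the tied head and the pre-norm encoder.

# Full forward + backward on one corrupted batch.
# Returns list(loss, grads) where grads has the same names/shapes as params.
loss_and_grads <- function(params, cfg, corrupted, r_smooth = 0.1,
                           train = TRUE) {
  tokens <- corrupted$tokens; pad <- corrupted$pad
  n <- nrow(tokens); S <- ncol(tokens)
  h <- cfg$h; k <- cfg$k; d <- cfg$d
  fw <- encoder_forward(tokens, pad, params, cfg, train = train,
                        keep_cache = TRUE)
  scores <- tied_scores(fw$H, params, corrupted, cfg)
  ce <- masked_ce_core(scores, corrupted, r_smooth, want_grad = TRUE)
  g <- init_zero_grads(params)
  if (ce$n_masked == 0L) return(list(loss = 0, grads = g))

  # everything below runs on the compacted (non-PAD) rows
  m <- length(fw$act_idx)
  inv <- integer(n * S)
  inv[fw$act_idx] <- seq_len(m)
  dS <- ce$dscores
  rows <- which(rowSums(dS != 0) > 0)       # masked rows, all non-PAD
  dH <- matrix(0, m, h)
  dH[inv[rows], ] <- dS[rows, , drop = FALSE] %*% params$We
  g$We <- g$We + crossprod(dS[rows, , drop = FALSE],
                           fw$Hc[inv[rows], , drop = FALSE])

  lb <- layer_norm_bwd(dH, fw$lnf, params$lnf_g)
  g$lnf_g <- g$lnf_g + lb$dg
  g$lnf_b <- g$lnf_b + lb$db
  dX <- lb$dx

  scale <- if (cfg$attn_scale == "d") d else sqrt(d)
  for (l in rev(seq_len(cfg$L))) {
    lp <- layer_params(params, l)
    cc <- fw$layers[[l]]
    pre <- paste0("L", l, ".")
    # FFN branch
    dFF <- if (!is.null(cc$D2)) dX * cc$D2 else dX
    g[[paste0(pre, "b2")]] <- g[[paste0(pre, "b2")]] + colSums(dFF)
    g[[paste0(pre, "W2")]] <- g[[paste0(pre, "W2")]] + crossprod(cc$Gact, dFF)
    dG <- tcrossprod(dFF, lp$W2)
    dHff <- dG * (cc$Phi + cc$Hff * stats::dnorm(cc$Hff))
    g[[paste0(pre, "b1")]] <- g[[paste0(pre, "b1")]] + colSums(dHff)
    g[[paste0(pre, "W1")]] <- g[[paste0(pre, "W1")]] + crossprod(cc$Mb, dHff)
    dMb <- tcrossprod(dHff, lp$W1)
    lb2 <- layer_norm_bwd(dMb, cc$ln2, lp$ln2_g)
    g[[paste0(pre, "ln2_g")]] <- g[[paste0(pre, "ln2_g")]] + lb2$dg
    g[[paste0(pre, "ln2_b")]] <- g[[paste0(pre, "ln2_b")]] + lb2$db
    dM <- dX + lb2$dx                            # residual + LN2 path
    # attention branch
    dAO <- if (!is.null(cc$D1)) dM * cc$D1 else dM
    g[[paste0(pre, "Wo")]] <- g[[paste0(pre, "Wo")]] + crossprod(cc$Z, dAO)
    dZ <- tcrossprod(dAO, lp$Wo)
    dQ <- matrix(0, m, h); dK <- matrix(0, m, h)
    dV <- matrix(0, m, h)
    for (c_i in seq_len(n)) {
      idx <- fw$cell_rows[[c_i]]
      for (hd in seq_len(k)) {
        cols <- ((hd - 1L) * d + 1L):(hd * d)
        A <- cc$A[[c_i]][[hd]]
        dZc <- dZ[idx, cols, drop = FALSE]
        Vc <- cc$V[idx, cols, drop = FALSE]
        dA <- tcrossprod(dZc, Vc)
        dV[idx, cols] <- crossprod(A, dZc)
        dlog <- A * (dA - rowSums(dA * A))
        dQ[idx, cols] <- dlog %*% cc$K[idx, cols, drop = FALSE] / scale
        dK[idx, cols] <- crossprod(dlog, cc$Q[idx, cols, drop = FALSE]) / scale
      }
    }
    g[[paste0(pre, "Wq")]] <- g[[paste0(pre, "Wq")]] + crossprod(cc$Xb, dQ)
    g[[paste0(pre, "Wk")]] <- g[[paste0(pre, "Wk")]] + crossprod(cc$Xb, dK)
    g[[paste0(pre, "Wv")]] <- g[[paste0(pre, "Wv")]] + crossprod(cc$Xb, dV)
    dXb <- tcrossprod(dQ, lp$Wq) + tcrossprod(dK, lp$Wk) + tcrossprod(dV, lp$Wv)
    lb1 <- layer_norm_bwd(dXb, cc$ln1, lp$ln1_g)
    g[[paste0(pre, "ln1_g")]] <- g[[paste0(pre, "ln1_g")]] + lb1$dg
    g[[paste0(pre, "ln1_b")]] <- g[[paste0(pre, "ln1_b")]] + lb1$db
    dX <- dM + lb1$dx                            # residual + LN1 path
  }
  # embeddings: dX0 -> token table (by id) and position table (by slot)
  agg <- rowsum(dX, fw$tok_act)
  ids <- as.integer(rownames(agg))
  g$We[ids, ] <- g$We[ids, , drop = FALSE] + agg
  aggp <- rowsum(dX, fw$slot_act)
  g$Wp[as.integer(rownames(aggp)), ] <-
    g$Wp[as.integer(rownames(aggp)), , drop = FALSE] + aggp
  list(loss = ce$loss, grads = g)
}

init_zero_grads <- function(params) {
  lapply(params, function(p) {
    if (is.matrix(p)) matrix(0, nrow(p), ncol(p)) else numeric(length(p))
  })
}

# finite-difference gradient of the batch loss wrt selected parameter
# entries; used by the gradient-check tests as an independent oracle
numeric_grad <- function(params, cfg, corrupted, r_smooth, name, index,
                         eps = 1e-5) {
  f <- function(p) {
    fw <- encoder_forward(corrupted$tokens, corrupted$pad, p, cfg)
    sc <- tied_scores(fw$H, p, corrupted, cfg)
    masked_ce_core(sc, corrupted, r_smooth)$loss
  }
  pp <- params; pp[[name]][index] <- pp[[name]][index] + eps
  pm <- params; pm[[name]][index] <- pm[[name]][index] - eps
  (f(pp) - f(pm)) / (2 * eps)
}
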