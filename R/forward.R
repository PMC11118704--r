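# Batched encoder forward/backward.
#
# A batch of n cells with S = F + T slots is processed as one (n*S) x h
# matrix in column-major slot order: flat row r holds cell ((r-1) %% n) + 1,
# slot ((r-1) %/% n) + 1. Position-wise ops (layer norm, FFN, embeddings,
# output head) are single BLAS calls on the flat matrix; attention loops
# over cells and heads.

flat_cell_rows <- function(cell, n, S) seq.int(cell, n * S, by = n)

# slot class of each slot: field name for phenotype slots, "gene" after
slot_classes <- function(Fn, Tn, vocab) {
  c(names(vocab$phenotype_tokens), rep("gene", Tn))
}

# S x vocab_size logical matrix of tokens allowed at each slot
legal_matrix <- function(Fn, Tn, vocab) {
  cls <- slot_classes(Fn, Tn, vocab)
  allowed <- matrix(FALSE, Fn + Tn, vocab$size)
  for (s in seq_along(cls)) allowed[s, vocab$legal_sets[[cls[s]]]] <- TRUE
  allowed
}

#' Embed a batch of token sequences
#'
#' Additive token + position embedding: `output[b, t, ] = We[token] + Wp[t]`.
#' PAD carries a dedicated embedding row; it is excluded later through the
#' attention key mask, not here.
#'
#' @param tokens integer matrix (cells x slots) of token ids, or a
#'   `corrupted_cells` / `tokenized_cells` object.
#' @param params parameter list (uses `We`, `Wp`).
#' @return cells x slots x h numeric array.
#' @export
embed_input <- function(tokens, params) {
  if (inherits(tokens, c("corrupted_cells", "tokenized_cells")))
    tokens <- tokens$tokens
  if (any(tokens > nrow(params$We)) || any(tokens < 1L))
    stop("indexing error: token id out of vocabulary range")
  n <- nrow(tokens); S <- ncol(tokens); h <- ncol(params$We)
  flat <- embed_flat(tokens, params)
  array(flat, dim = c(n, S, h))
}

embed_flat <- function(tokens, params) {
  n <- nrow(tokens); S <- ncol(tokens)
  params$We[as.vector(tokens), , drop = FALSE] +
    params$Wp[rep(seq_len(S), each = n), , drop = FALSE]
}

# full encoder forward; returns final hidden states (flat, full layout) and,
# optionally, every intermediate needed by the backward pass.
#
# When PAD keys are masked (the default), PAD slots receive exactly zero
# gradient and contribute nothing to any non-PAD state: their keys are
# excluded from every softmax, their values never mix in, and their own
# output rows feed neither the loss nor the embeddings. The computation is
# therefore run on the COMPACTED sequence of non-PAD slots — identical
# results at a fraction of the cost, since attention is quadratic in the
# active length. With `pad_attend = TRUE` every slot is active.
encoder_forward <- function(tokens, pad, params, cfg, train = FALSE,
                            keep_cache = FALSE) {
  n <- nrow(tokens); S <- ncol(tokens)
  h <- cfg$h; k <- cfg$k; d <- cfg$d
  drop_p <- if (train) cfg$dropout else 0
  tok_flat <- as.vector(tokens)
  slot_flat <- rep(seq_len(S), each = n)
  active <- if (isTRUE(cfg$pad_attend)) rep(TRUE, n * S)
            else !as.vector(pad)
  act_idx <- which(active)
  m <- length(act_idx)
  # per-cell row positions within the compacted matrix
  cell_flat <- rep(seq_len(n), times = S)[act_idx]
  cell_rows <- split(seq_len(m), cell_flat)
  X <- params$We[tok_flat[act_idx], , drop = FALSE] +
    params$Wp[slot_flat[act_idx], , drop = FALSE]
  layers <- vector("list", cfg$L)
  for (l in seq_len(cfg$L)) {
    lp <- layer_params(params, l)
    ln1 <- layer_norm_fwd(X, lp$ln1_g, lp$ln1_b)
    Xb <- ln1$y
    Q <- Xb %*% lp$Wq; K <- Xb %*% lp$Wk; V <- Xb %*% lp$Wv
    Z <- matrix(0, m, h)
    A_cache <- if (keep_cache) vector("list", n) else NULL
    for (c_i in seq_len(n)) {
      idx <- cell_rows[[c_i]]
      heads <- if (keep_cache) vector("list", k) else NULL
      for (hd in seq_len(k)) {
        cols <- ((hd - 1L) * d + 1L):(hd * d)
        o <- attention(Q[idx, cols, drop = FALSE],
                       K[idx, cols, drop = FALSE],
                       V[idx, cols, drop = FALSE], NULL, cfg$attn_scale)
        Z[idx, cols] <- o
        if (keep_cache) heads[[hd]] <- attr(o, "weights")
      }
      if (keep_cache) A_cache[[c_i]] <- heads
    }
    AO <- Z %*% lp$Wo
    D1 <- if (drop_p > 0)
      matrix((stats::runif(m * h) >= drop_p) / (1 - drop_p), m, h)
    else NULL
    if (!is.null(D1)) AO <- AO * D1
    M <- AO + X
    ln2 <- layer_norm_fwd(M, lp$ln2_g, lp$ln2_b)
    Mb <- ln2$y
    Hff <- add_cols(Mb %*% lp$W1, lp$b1)
    Phi <- stats::pnorm(Hff)   # cached for the GELU derivative
    Gact <- Hff * Phi
    FF <- add_cols(Gact %*% lp$W2, lp$b2)
    D2 <- if (drop_p > 0)
      matrix((stats::runif(m * h) >= drop_p) / (1 - drop_p), m, h)
    else NULL
    if (!is.null(D2)) FF <- FF * D2
    Xnew <- FF + M
    if (any(!is.finite(Xnew)))
      stop("numeric error: non-finite activations in layer ", l)
    if (keep_cache)
      layers[[l]] <- list(ln1 = ln1, Xb = Xb, Q = Q, K = K, V = V,
                          A = A_cache, Z = Z, D1 = D1, ln2 = ln2,
                          Mb = Mb, Hff = Hff, Phi = Phi, Gact = Gact,
                          D2 = D2)
    X <- Xnew
  }
  lnf <- layer_norm_fwd(X, params$lnf_g, params$lnf_b)
  H <- matrix(0, n * S, h)
  H[act_idx, ] <- lnf$y
  list(H = H, Hc = lnf$y, lnf = lnf, layers = layers, n = n, S = S,
       act_idx = act_idx, cell_rows = cell_rows,
       tok_act = tok_flat[act_idx], slot_act = slot_flat[act_idx])
}

#' Forward pass to output scores
#'
#' Runs the `L`-block encoder on a batch, applies the final layer norm and
#' the tied output head (`scores = H %*% t(We)`), then masks the score of
#' every token outside the slot's legal set to `-Inf`, so a softmax at a
#' gene slot is supported on bin tokens only and a phenotype slot on its
#' field's categories only.
#'
#' @param batch a `corrupted_cells` or `tokenized_cells` object.
#' @param params parameter list from [init_params()] / [pretrain()].
#' @param cfg the matching `model_config`.
#' @return a `model_scores` object: list with `scores` ((n*S) x vocab flat
#'   matrix, column-major slot layout), `n`, `S`, `F`, `T`, `vocab`.
#' @export
forward_logits <- function(batch, params, cfg) {
  if (ncol(params$We) != cfg$h || nrow(params$We) != cfg$vocab_size)
    stop("shape error: params do not match config")
  fw <- encoder_forward(batch$tokens, batch$pad, params, cfg)
  scores <- tied_scores(fw$H, params, batch, cfg)
  structure(list(scores = scores, n = fw$n, S = fw$S, F = batch$F,
                 T = batch$T, vocab = batch$vocab),
            class = "model_scores")
}

tied_scores <- function(H, params, batch, cfg) {
  scores <- tcrossprod(H, params$We)
  allowed <- legal_matrix(batch$F, batch$T, batch$vocab)
  n <- nrow(batch$tokens)
  # expand slot-level mask to flat rows (column-major slot layout)
  scores[!allowed[rep(seq_len(batch$F + batch$T), each = n), ]] <- -Inf
  scores
}

#' Softmax probabilities at given slots
#'
#' @param ms a `model_scores` object.
#' @param cell cell index.
#' @param slot slot index.
#' @return named probability vector over the slot's legal set.
#' @export
slot_probs <- function(ms, cell, slot) {
  r <- (slot - 1L) * ms$n + cell
  cls <- slot_classes(ms$F, ms$T, ms$vocab)[slot]
  legal <- ms$vocab$legal_sets[[cls]]
  z <- ms$scores[r, legal]
  p <- exp(z - max(z)); p <- p / sum(p)
  names(p) <- ms$vocab$labels[legal]
  p
}

# cross-entropy over masked slots plus gradient wrt scores.
# Returns list(loss, n_masked, dscores or NULL).
masked_ce_core <- function(scores, corrupted, r_smooth, want_grad = FALSE) {
  n <- nrow(corrupted$tokens); S <- ncol(corrupted$tokens)
  vocab <- corrupted$vocab
  cls <- slot_classes(corrupted$F, corrupted$T, vocab)
  flat_slot <- rep(seq_len(S), each = n)
  masked_flat <- as.vector(corrupted$masked)
  labels_flat <- as.vector(corrupted$labels)
  n_masked <- sum(masked_flat)
  dsc <- if (want_grad) matrix(0, n * S, vocab$size) else NULL
  if (n_masked == 0L) {
    warning("no masked tokens in batch; loss defined as 0")
    return(list(loss = 0, n_masked = 0L, dscores = dsc))
  }
  total <- 0
  for (cl in unique(cls)) {
    rows <- which(masked_flat & cls[flat_slot] == cl)
    if (length(rows) == 0L) next
    legal <- vocab$legal_sets[[cl]]
    kk <- length(legal)
    z <- scores[rows, legal, drop = FALSE]
    mx <- apply(z, 1L, max)
    zc <- z - mx
    lse <- log(rowSums(exp(zc)))
    logp <- zc - lse
    true_pos <- match(labels_flat[rows], legal)
    if (anyNA(true_pos))
      stop("masked label outside the slot's legal set")
    ij <- cbind(seq_along(rows), true_pos)
    if (kk == 1L) next  # degenerate singleton legal set: zero loss
    off <- r_smooth / (kk - 1L)
    ce <- -(off * rowSums(logp) + (1 - r_smooth - off) * logp[ij])
    total <- total + sum(ce)
    if (want_grad) {
      p <- exp(logp)
      q <- matrix(off, length(rows), kk)
      q[ij] <- 1 - r_smooth
      dsc[rows, legal] <- dsc[rows, legal] + (p - q) / n_masked
    }
  }
  list(loss = total / n_masked, n_masked = n_masked, dscores = dsc)
}

#' Masked soft-label cross-entropy loss
#'
#' Mean, over masked positions, of the cross-entropy between the soft-label
#' distribution of the true token (see [soft_label()]) and the model's
#' softmax over the slot's legal set. Unmasked and PAD positions contribute
#' nothing. The loss is bounded below by the soft-label entropy
#' ([soft_label_entropy()]); with `r_smooth = 0` and a perfect prediction it
#' is 0.
#'
#' @param scores a `model_scores` object from [forward_logits()], or a flat
#'   `(n*S) x vocab` score matrix in the same layout.
#' @param corrupted the `corrupted_cells` batch the scores were computed on.
#' @param r_smooth soft-label smoothing mass (default 0.1).
#' @return scalar loss (nats per masked token).
#' @export
masked_ce_loss <- function(scores, corrupted, r_smooth = 0.1) {
  if (inherits(scores, "model_scores")) scores <- scores$scores
  masked_ce_core(scores, corrupted, r_smooth)$loss
}
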