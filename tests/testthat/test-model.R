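test_that("input embedding is additive in token and position tables", {
  cells <- toy_cells()
  vocab <- cells$vocab
  cfg <- model_config(L = 1L, h = 8L, k = 2L, B = 8L, T = cells$T, F = 2L,
                      vocab_size = vocab$size, dropout = 0)
  params <- init_params(cfg, seed = 2)
  # zero token table: rows reduce to the position table
  p0 <- params
  p0$We[] <- 0
  X <- embed_input(cells, p0)
  for (s in seq_len(cfg$S))
    expect_equal(X[2, s, ], unname(p0$Wp[s, ]), tolerance = 1e-12)
  # locality: changing one slot's token changes only that slot (pre-attention)
  cells2 <- cells
  free <- which(!cells$pad[1, ])
  s0 <- max(free)
  cells2$tokens[1, s0] <- vocab$mask
  X1 <- embed_input(cells, params)
  X2 <- embed_input(cells2, params)
  diff_slots <- which(apply(abs(X1[1, , ] - X2[1, , ]), 1, max) > 0)
  expect_equal(diff_slots, s0)
  # out-of-range ids error
  cells3 <- cells
  cells3$tokens[1, 1] <- vocab$size + 5L
  expect_error(embed_input(cells3, params), "indexing error")
})

test_that("attention matches a brute-force softmax oracle", {
  set.seed(8)
  Q <- matrix(rnorm(20), 5, 4); K <- matrix(rnorm(20), 5, 4)
  V <- matrix(rnorm(20), 5, 4)
  expect_equal(attention(Q, K, V), oracle_attention(Q, K, V),
               tolerance = 1e-10, ignore_attr = TRUE)
  # with masked keys
  pm <- c(FALSE, TRUE, FALSE, TRUE, FALSE)
  expect_equal(attention(Q, K, V, pm), oracle_attention(Q, K, V, pm),
               tolerance = 1e-10, ignore_attr = TRUE)
  # row weights are a distribution over unmasked keys
  W <- attr(attention(Q, K, V, pm), "weights")
  expect_equal(rowSums(W), rep(1, 5), tolerance = 1e-12)
  expect_true(all(W[, pm] == 0) && all(W >= 0))
  # alternative 1/d scaling agrees with the oracle too
  expect_equal(attention(Q, K, V, scale = "d"),
               oracle_attention(Q, K, V, scale = "d"),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("attention degenerate cases", {
  # single position: output is the single value row
  Q <- matrix(rnorm(4), 1, 4)
  out <- attention(Q, Q, Q)
  expect_equal(out, Q, tolerance = 1e-12, ignore_attr = TRUE)
  # identical queries/keys at two positions: output is the mean value row
  Q2 <- matrix(rep(1, 8), 2, 4)
  V2 <- matrix(rnorm(8), 2, 4)
  out2 <- attention(Q2, Q2, V2)
  expect_equal(out2[1, ], colMeans(V2), tolerance = 1e-12)
  # all keys masked: zero rows
  out3 <- attention(Q2, Q2, V2, pad_mask = c(TRUE, TRUE))
  expect_true(all(out3 == 0))
})

test_that("transformer block matches an independent composition oracle", {
  set.seed(13)
  X <- matrix(rnorm(24), 3, 8)
  lp <- random_layer_params(8)
  expect_equal(transformer_block(X, lp, k = 2),
               oracle_block(X, lp, k = 2), tolerance = 1e-8)
  # zeroed weights: residuals only, block is the identity
  lpz <- random_layer_params(8, zero = TRUE)
  expect_equal(transformer_block(X, lpz, k = 2), X, tolerance = 1e-12)
  # shape contract for any sequence length
  X2 <- matrix(rnorm(9 * 8), 9, 8)
  expect_equal(dim(transformer_block(X2, lp, k = 4)), c(9L, 8L))
})

test_that("forward scores respect legal sets and normalize", {
  cells <- toy_cells()
  vocab <- cells$vocab
  cfg <- model_config(L = 2L, h = 16L, k = 2L, B = 8L, T = cells$T, F = 2L,
                      vocab_size = vocab$size, dropout = 0)
  params <- init_params(cfg, seed = 4)
  ms <- forward_logits(cells, params, cfg)
  # softmax over a slot's legal set sums to one
  p <- slot_probs(ms, cell = 1, slot = 1)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  expect_length(p, 2)  # sex categories only
  # a gene slot puts zero probability on phenotype-category tokens
  r <- (3L - 1L) * ms$n + 1L  # cell 1, first gene slot
  expect_true(all(ms$scores[r, unlist(vocab$phenotype_tokens)] == -Inf))
  expect_true(all(is.finite(ms$scores[r, vocab$bin_tokens])))
})

test_that("L = 0 degenerate config reduces to normed embeddings x tied head", {
  cells <- toy_cells()
  vocab <- cells$vocab
  cfg <- model_config(L = 0L, h = 8L, k = 2L, B = 8L, T = cells$T, F = 2L,
                      vocab_size = vocab$size, dropout = 0)
  params <- init_params(cfg, seed = 6)
  ms <- forward_logits(cells, params, cfg)
  X0 <- embed_flat_oracle(cells, params)
  Hn <- t(apply(X0, 1, function(r) {
    mu <- mean(r); v <- mean((r - mu)^2)
    (r - mu) / sqrt(v + 1e-5)
  }))
  # PAD slots carry no state; compare the defined (non-PAD) rows only
  live <- !as.vector(cells$pad) & ms$scores > -Inf
  expect_equal(ms$scores[live], (Hn %*% t(params$We))[live],
               tolerance = 1e-10)
})

test_that("masked CE loss closed forms", {
  cells <- toy_cells(n = 4L)
  vocab <- cells$vocab
  set.seed(3)
  corr <- corrupt(cells, masking_policy(0.5, 0.5))
  n <- nrow(cells$tokens); S <- ncol(cells$tokens)

  # uniform scores over every legal set, r_smooth = 0: loss is the mean of
  # log|legal| over masked slots; with only gene slots masked it is ln B
  sc <- matrix(0, n * S, vocab$size)
  corr_genes <- corr
  corr_genes$masked[, 1:2] <- FALSE  # keep only gene-slot masks
  if (!any(corr_genes$masked)) skip("no gene slots masked under this seed")
  expect_equal(masked_ce_loss(sc, corr_genes, r_smooth = 0), log(8),
               tolerance = 1e-12)

  # model equals the soft-label distribution: loss equals its entropy
  r <- 0.1
  sc2 <- matrix(-Inf, n * S, vocab$size)
  for (s in seq_len(S)) for (c_i in seq_len(n)) {
    row <- (s - 1) * n + c_i
    cl <- if (s <= 2) names(vocab$phenotype_tokens)[s] else "gene"
    legal <- vocab$legal_sets[[cl]]
    if (corr$masked[c_i, s]) {
      sc2[row, legal] <- log(soft_label(corr$labels[c_i, s], legal, r))
    } else sc2[row, legal] <- 0
  }
  cls <- c(names(vocab$phenotype_tokens), rep("gene", cells$T))
  masked_cls <- cls[rep(seq_len(S), each = n)][as.vector(corr$masked)]
  # expected: mean soft-label entropy over the masked slots
  expected <- mean(vapply(masked_cls, function(cl)
    soft_label_entropy(length(vocab$legal_sets[[cl]]), r), numeric(1)))
  expect_equal(masked_ce_loss(sc2, corr, r_smooth = r), expected,
               tolerance = 1e-10)

  # probability one on the truth with r_smooth = 0: zero loss
  expect_equal(masked_ce_loss(sc2, corr, r_smooth = 0) >= 0, TRUE)
  sc3 <- matrix(-Inf, n * S, vocab$size)
  flat_lab <- as.vector(corr$labels)
  for (row in seq_len(n * S)) sc3[row, flat_lab[row]] <- 0
  sc3[sc3 == -Inf] <- -1e9
  expect_equal(masked_ce_loss(sc3, corr, r_smooth = 0), 0, tolerance = 1e-6)

  # no masked tokens: defined 0 with a warning
  c0 <- corr
  c0$masked[] <- FALSE
  expect_warning(l0 <- masked_ce_loss(sc, c0), "no masked tokens")
  expect_equal(l0, 0)
})

test_that("analytic gradients match finite differences on a tiny config", {
  cells <- toy_cells(n = 3L, T = 5L, seed = 2L)
  vocab <- cells$vocab
  cfg <- model_config(L = 1L, h = 8L, k = 2L, B = 8L, T = 5L, F = 2L,
                      vocab_size = vocab$size, dropout = 0)
  params <- init_params(cfg, seed = 3)
  set.seed(5)
  batch <- corrupt(cells, masking_policy(0.3, 0.5))
  lg <- genophen:::loss_and_grads(params, cfg, batch, r_smooth = 0.1,
                                  train = FALSE)
  set.seed(17)
  for (nm in names(params)) {
    len <- length(params[[nm]])
    for (ix in unique(c(1L, sample(len, min(3L, len))))) {
      ng <- genophen:::numeric_grad(params, cfg, batch, 0.1, nm, ix)
      ag <- lg$grads[[nm]][ix]
      expect_lt(abs(ng - ag) / max(1e-6, abs(ng) + abs(ag)), 1e-4)
    }
  }
})

test_that("batch forward is permutation-consistent over cells", {
  cells <- toy_cells(n = 5L)
  cfg <- model_config(L = 1L, h = 8L, k = 2L, B = 8L, T = cells$T, F = 2L,
                      vocab_size = cells$vocab$size, dropout = 0)
  params <- init_params(cfg, seed = 9)
  ms <- forward_logits(cells, params, cfg)
  perm <- c(3L, 1L, 5L, 2L, 4L)
  msP <- forward_logits(subset_tokenized(cells, perm), params, cfg)
  for (s in seq_len(cfg$S)) {
    rows <- (s - 1L) * 5L + seq_len(5L)
    expect_equal(msP$scores[rows, ], ms$scores[rows, ][perm, ],
                 tolerance = 1e-12)
  }
})

test_that("checkpoints round-trip parameters and config", {
  cells <- toy_cells()
  cfg <- model_config(L = 1L, h = 8L, k = 2L, B = 8L, T = cells$T, F = 2L,
                      vocab_size = cells$vocab$size, dropout = 0)
  params <- init_params(cfg, seed = 1)
  path <- withr::local_tempfile(fileext = ".json")
  save_checkpoint(params, cfg, cells$vocab, path)
  back <- load_checkpoint(path)
  expect_equal(back$params, params, tolerance = 1e-12)
  expect_equal(back$cfg, cfg)
  expect_identical(back$vocab$labels, cells$vocab$labels)
})
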