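# Shared fixtures, built once per test run and memoised.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, builder(), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

# a small raw atlas with planted structure
small_atlas <- function() {
  memo("small_atlas", function() {
    generate_atlas(synthetic_config(n_cells = 300L, n_genes = 120L,
                                    program_size = 10L,
                                    celltype_program_size = 5L, seed = 7L))
  })
}

# the small atlas preprocessed and tokenized (T = 32 genes, B = 8 bins)
small_prep <- function() {
  memo("small_prep", function() prepare_corpus(small_atlas()$matrix,
                                               T = 32L, B = 8L))
}

# hand-built two-phenotype schema vocabulary for unit tests
toy_vocab <- function(B = 8L) {
  build_vocabulary(list(sex = c("F", "M"),
                        tissue = c("heart", "lung", "blood")), B)
}

# a tiny deterministic tokenized corpus over the toy vocabulary
toy_cells <- function(n = 6L, T = 5L, seed = 1L) {
  vocab <- toy_vocab()
  set.seed(seed)
  tokens <- cbind(
    sample(vocab$phenotype_tokens$sex, n, replace = TRUE),
    sample(vocab$phenotype_tokens$tissue, n, replace = TRUE),
    matrix(sample(c(vocab$pad, vocab$bin_tokens), n * T, replace = TRUE),
           n, T))
  pad <- tokens == vocab$pad
  structure(list(tokens = tokens, pad = pad, F = 2L, T = as.integer(T),
                 slot_entities = c("sex", "tissue", paste0("g", seq_len(T))),
                 cell_ids = paste0("c", seq_len(n)),
                 phenotypes = data.frame(
                   sex = names(vocab$phenotype_tokens$sex)[
                     match(tokens[, 1], vocab$phenotype_tokens$sex)],
                   tissue = names(vocab$phenotype_tokens$tissue)[
                     match(tokens[, 2], vocab$phenotype_tokens$tissue)],
                   stringsAsFactors = FALSE),
                 vocab = vocab),
            class = "tokenized_cells")
}

# reference-scale fixture shared by the end-to-end acceptance checks:
# default 2,000-cell atlas, T = 128 genes, B = 16 bins, the 4-layer/128-wide
# encoder trained for 6 epochs, plus embeddings on 600 training cells
reference_fit <- function() {
  memo("reference_fit", function() {
    atl <- generate_atlas(synthetic_config(seed = 42L))
    prep <- prepare_corpus(atl$matrix, T = 128L, B = 16L)
    sp <- split_corpus(prep$cells, val_frac = 0.1, seed = 1L)
    cfg <- model_config(L = 4L, h = 128L, k = 4L, B = 16L, T = 128L,
                        F = 4L, vocab_size = prep$vocab$size, dropout = 0)
    tc <- train_config(learning_rate = 1e-3, epochs = 6L, seed = 5L)
    fit <- pretrain(sp$train, cfg, tc)
    emb <- extract_embeddings(fit$params, cfg,
                              subset_tokenized(sp$train, 1:600))
    list(atl = atl, prep = prep, sp = sp, cfg = cfg, fit = fit, emb = emb)
  })
}

# planted-structure recovery on the reference fixture for one procedure seed
trained_recovery <- function(s) {
  rf <- reference_fit()
  emb <- rf$emb
  ct <- names(which.max(table(emb$phenotypes$cell_type)))
  pf <- polyfunctionality(emb, rf$atl$truth$poly_gene, ct, seed = s)
  pm <- polyfunctionality(emb, rf$atl$truth$mono_gene, ct, seed = s)
  pg <- phenotype_gene_similarity(emb, "tissue")
  markers <- unlist(rf$atl$truth$markers[grep("tissue",
                                              names(rf$atl$truth$markers))])
  list(poly_k = pf$n_clusters, mono_k = pm$n_clusters,
       top5_markers = sum(head(pg$universal$gene, 5L) %in% markers))
}

# greedily pick cells whose token sequences are pairwise far apart (Hamming
# distance over all slots), so that a masked-slot truth is always identified
# by the visible remainder of the cell during memorization checks
pick_distinct_cells <- function(cells, n = 8L, min_dist = 12L) {
  tok <- cells$tokens
  chosen <- 1L
  for (i in 2:nrow(tok)) {
    if (length(chosen) >= n) break
    d <- vapply(chosen, function(j) sum(tok[i, ] != tok[j, ]), integer(1))
    if (all(d >= min_dist)) chosen <- c(chosen, i)
  }
  chosen
}

# small trained model over the small atlas, reused by training-dependent
# analysis tests; short schedule, desk-scale config
small_trained <- function() {
  memo("small_trained", function() {
    prep <- small_prep()
    cfg <- model_config(L = 2L, h = 64L, k = 4L, B = 8L, T = 32L, F = 4L,
                        vocab_size = prep$vocab$size)
    tc <- train_config(learning_rate = 1e-3, epochs = 3L, seed = 11L)
    fit <- pretrain(prep$cells, cfg, tc)
    list(prep = prep, cfg = cfg, fit = fit)
  })
}
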