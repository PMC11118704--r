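# build an embedding_table by hand: `vectors` rows described by entity/role
# and per-cell phenotype metadata; bypasses the model entirely
fake_table <- function(vectors, entity, role, cell, phenotypes) {
  info <- data.frame(cell = cell, cell_id = paste0("c", cell),
                     slot = seq_along(entity), role = role, entity = entity,
                     stringsAsFactors = FALSE)
  info <- cbind(info, phenotypes[cell, , drop = FALSE])
  rownames(info) <- NULL
  n <- nrow(phenotypes)
  cells <- rowsum(vectors, factor(cell, levels = seq_len(n))) /
    as.vector(table(factor(cell, levels = seq_len(n))))
  structure(list(vectors = vectors, info = info, cells = cells,
                 phenotypes = phenotypes, h = ncol(vectors)),
            class = "embedding_table")
}

test_that("cosine similarity and Euclidean distance basics", {
  a <- c(1, 2, 3); b <- c(-1, -2, -3)
  expect_equal(cosine_similarity(a, a), 1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_similarity(a, b), -1)
  expect_error(cosine_similarity(a, c(0, 0, 0)), "zero vector")

  ctx <- structure(list(vectors = rbind(x = c(1, 2), y = c(4, -2)),
                        context = data.frame(v = c("x", "y")),
                        n_cells = c(5, 5), flagged = c(FALSE, FALSE),
                        entity = "g"), class = "context_embeddings")
  expect_equal(embedding_distance(ctx, "x", "x"), 0)
  expect_equal(embedding_distance(ctx, "x", "y"), sqrt(9 + 16))
  expect_error(embedding_distance(ctx, "x", "z"), "lookup error")

  # triangle inequality and brute-force agreement on random triples
  set.seed(12)
  for (i in 1:10) {
    V <- matrix(rnorm(15), 3, 5)
    rownames(V) <- c("a", "b", "c")
    ctx <- structure(list(vectors = V), class = "context_embeddings")
    dab <- embedding_distance(ctx, "a", "b")
    dbc <- embedding_distance(ctx, "b", "c")
    dac <- embedding_distance(ctx, "a", "c")
    expect_lte(dac, dab + dbc + 1e-12)
    expect_equal(dab, sqrt(sum((V[1, ] - V[2, ])^2)), tolerance = 1e-10)
  }
})

test_that("context aggregation averages and supports are consistent", {
  set.seed(3)
  pheno <- data.frame(tissue = rep(c("t1", "t2"), each = 10),
                      stringsAsFactors = FALSE)
  cell <- rep(1:20, each = 1)
  V <- matrix(rnorm(20 * 4), 20, 4)
  tab <- fake_table(V, entity = rep("g1", 20), role = rep("gene", 20),
                    cell = cell, phenotypes = pheno)
  ctx <- aggregate_by_context(tab, "g1", "tissue", min_support = 5)
  expect_equal(nrow(ctx$vectors), 2)
  expect_equal(sum(ctx$n_cells), 20)
  expect_equal(ctx$vectors["t1", ], colMeans(V[1:10, ]), tolerance = 1e-12)
  # linearity: weighted mean of split halves recovers the full mean
  m1 <- colMeans(V[1:5, ]); m2 <- colMeans(V[6:10, ])
  expect_equal((5 * m1 + 5 * m2) / 10, ctx$vectors["t1", ],
               tolerance = 1e-12)
  # single-row context equals that row; support flagging
  tab1 <- fake_table(V[1, , drop = FALSE], "g1", "gene", 1L,
                     pheno[1, , drop = FALSE])
  ctx1 <- aggregate_by_context(tab1, "g1", "tissue", min_support = 20)
  expect_equal(ctx1$vectors[1, ], V[1, ], tolerance = 1e-15)
  expect_true(ctx1$flagged[1])
  expect_error(aggregate_by_context(tab, "nope", "tissue"), "lookup error")
})

test_that("differential embedding score measures context dispersion", {
  V <- rbind(c(1, 0, 0), c(1, 0, 0), c(1, 0, 0))
  expect_equal(differential_embedding_score(V), 0, tolerance = 1e-12)
  V2 <- rbind(c(1, 0), c(-1, 0))
  expect_equal(differential_embedding_score(V2), 2, tolerance = 1e-12)
  expect_error(differential_embedding_score(V2[1, , drop = FALSE]),
               "undefined")
})

test_that("tissue similarity matrix is a unit-diagonal Pearson matrix", {
  set.seed(8)
  pheno <- data.frame(tissue = rep(c("t1", "t2", "t3"), each = 8),
                      stringsAsFactors = FALSE)
  V <- matrix(rnorm(24 * 6), 24, 6) +
    outer(as.integer(factor(pheno$tissue)), rep(1, 6))
  tab <- fake_table(V, entity = rep("cell_type", 24),
                    role = rep("phenotype", 24), cell = 1:24,
                    phenotypes = pheno)
  ts <- tissue_similarity_matrix(tab)
  expect_equal(ts$correlation, t(ts$correlation))
  expect_equal(unname(diag(ts$correlation)), rep(1, 3))
  # duplicated tissue (same cells under two labels) correlates at 1
  pheno2 <- data.frame(tissue = rep(c("a", "b"), each = 8))
  V2 <- rbind(V[1:8, ], V[1:8, ])
  tab2 <- fake_table(V2, rep("cell_type", 16), rep("phenotype", 16),
                     1:16, pheno2)
  ts2 <- tissue_similarity_matrix(tab2)
  expect_equal(ts2$correlation["a", "b"], 1, tolerance = 1e-12)
})

test_that("gene network edges are exactly the pairs above threshold", {
  set.seed(10)
  emb <- matrix(rnorm(50 * 8), 50, 8)
  rownames(emb) <- sprintf("g%02d", 1:50)
  net <- build_gene_network(emb, tau_quantile = 0.9)
  # brute-force O(n^2) pair scan
  cnt <- 0L
  deg <- setNames(integer(50), rownames(emb))
  for (i in 1:49) for (j in (i + 1):50) {
    s <- cosine_similarity(emb[i, ], emb[j, ])
    if (s > net$tau) {
      cnt <- cnt + 1L
      deg[i] <- deg[i] + 1L
      deg[j] <- deg[j] + 1L
    }
  }
  expect_equal(igraph::ecount(net$graph), cnt)
  expect_equal(net$degree[names(deg)], deg)

  # tau = -1 gives the complete graph; tau = 1 an empty one
  net_full <- build_gene_network(emb, tau = -1)
  expect_true(all(net_full$degree == 49))
  net_empty <- build_gene_network(emb, tau = 1)
  expect_equal(igraph::ecount(net_empty$graph), 0)
  expect_error(build_gene_network(emb, tau_quantile = 1.2),
               "parameter error")
})

test_that("discrete power-law MLE recovers the generating exponent", {
  set.seed(1234)
  x <- rpowerlaw(10000, alpha = 2.5, xmin = 1)
  fit <- fit_power_law(x)
  expect_gt(fit$alpha, 2.35)
  expect_lt(fit$alpha, 2.65)
  # exchangeability: degree order does not matter
  fit2 <- fit_power_law(rev(x))
  expect_equal(fit$alpha, fit2$alpha)
  # degraded inputs
  expect_warning(f3 <- fit_power_law(c(1, 1, 1, 2)), "fewer than 50")
  expect_true(f3$alpha > 1)
  expect_error(suppressWarnings(fit_power_law(rep(3, 10))), "degenerate")
})

test_that("gene dendrogram matches a brute-force average-linkage oracle", {
  set.seed(14)
  emb <- matrix(rnorm(8 * 5), 8, 5)
  rownames(emb) <- paste0("g", 1:8)
  den <- gene_dendrogram(emb)
  d <- 1 - genophen:::cosine_matrix(emb)
  expect_equal(sort(den$hclust$height),
               oracle_average_linkage_heights(stats::as.dist(d)),
               tolerance = 1e-10)
  expect_setequal(den$phylo$tip.label, rownames(emb))
  expect_match(den$newick, "^\\(")

  # two genes: a single merge at their cosine distance
  den2 <- gene_dendrogram(emb[1:2, ])
  expect_length(den2$hclust$height, 1)
  expect_equal(den2$hclust$height,
               1 - cosine_similarity(emb[1, ], emb[2, ]), tolerance = 1e-12)
})

test_that("network comparison ranks degree changes", {
  set.seed(16)
  emb <- matrix(rnorm(30 * 6), 30, 6)
  rownames(emb) <- sprintf("g%02d", 1:30)
  netA <- build_gene_network(emb, tau_quantile = 0.8)
  cmp_same <- compare_networks(netA, netA, fit_powerlaw = FALSE)
  expect_true(all(cmp_same$degree_delta$delta == 0))

  # add 5 edges incident to one node: it tops the delta ranking
  netB <- netA
  g <- netA$graph
  nb <- setdiff(which(!igraph::are_adjacent(g, 1, 1:30) & 1:30 != 1), 1)[1:5]
  netB$graph <- igraph::add_edges(g, as.vector(rbind(1, nb)))
  netB$degree <- igraph::degree(netB$graph)
  cmp <- compare_networks(netA, netB, fit_powerlaw = FALSE)
  expect_equal(cmp$degree_delta$gene[1], "g01")
  expect_equal(cmp$degree_delta$delta[1], 5L)
})

test_that("polyfunctionality separates planted blobs and rejects one blob", {
  set.seed(20)
  pheno <- data.frame(cell_type = rep("ec", 120), tissue = rep("t", 120),
                      stringsAsFactors = FALSE)
  # two well-separated blobs
  V <- rbind(matrix(rnorm(60 * 6, mean = 0, sd = 0.2), 60, 6) +
               matrix(rep(c(4, 0, 0, 0, 0, 0), each = 60), 60, 6),
             matrix(rnorm(60 * 6, mean = 0, sd = 0.2), 60, 6) +
               matrix(rep(c(0, 4, 0, 0, 0, 0), each = 60), 60, 6))
  tab <- fake_table(V, entity = rep("gx", 120), role = rep("gene", 120),
                    cell = 1:120, phenotypes = pheno)
  pf <- polyfunctionality(tab, "gx", "ec", min_cells = 50)
  expect_equal(pf$n_clusters, 2L)
  expect_true(pf$polyfunctional)
  expect_gt(pf$silhouette, 0.1)
  # the recovered split matches the planted one (up to label swap)
  expect_true(all(pf$labels[1:60] == pf$labels[1]) &&
                all(pf$labels[61:120] == pf$labels[61]) &&
                pf$labels[1] != pf$labels[61])

  # identical embeddings: a single cluster, not polyfunctional
  V1 <- matrix(rep(c(1, 2, 3, 4, 5, 6), each = 120), 120, 6)
  tab1 <- fake_table(V1, rep("gy", 120), rep("gene", 120), 1:120, pheno)
  pf1 <- polyfunctionality(tab1, "gy", "ec", min_cells = 50)
  expect_equal(pf1$n_clusters, 1L)
  expect_false(pf1$polyfunctional)

  # one diffuse blob: not polyfunctional
  V2 <- matrix(rnorm(120 * 6, sd = 0.3), 120, 6) +
    matrix(rep(c(3, 3, 0, 0, 0, 0), each = 120), 120, 6)
  tab2 <- fake_table(V2, rep("gz", 120), rep("gene", 120), 1:120, pheno)
  pf2 <- polyfunctionality(tab2, "gz", "ec", min_cells = 50)
  expect_equal(pf2$n_clusters, 1L)

  expect_error(polyfunctionality(tab, "gx", "missing_ct"), "support error")
})

test_that("extract_embeddings satisfies its row and mean contracts", {
  cells <- toy_cells(n = 6L, T = 5L, seed = 3L)
  cfg <- model_config(L = 1L, h = 8L, k = 2L, B = 8L, T = 5L, F = 2L,
                      vocab_size = cells$vocab$size, dropout = 0)
  params <- init_params(cfg, seed = 8)
  emb <- extract_embeddings(params, cfg, cells)
  expect_equal(nrow(emb$vectors), sum(!cells$pad))
  # identical cells embed identically
  cells2 <- cells
  cells2$tokens[2, ] <- cells$tokens[1, ]
  cells2$pad[2, ] <- cells$pad[1, ]
  emb2 <- extract_embeddings(params, cfg, cells2)
  r1 <- emb2$vectors[emb2$info$cell == 1, ]
  r2 <- emb2$vectors[emb2$info$cell == 2, ]
  expect_equal(r1, r2, tolerance = 1e-12)
  # per-cell vector equals the brute-force mean over its slot rows
  for (c_i in 1:3) {
    rows <- emb$info$cell == c_i
    expect_equal(emb$cells[c_i, ], colMeans(emb$vectors[rows, , drop = FALSE]),
                 tolerance = 1e-10)
  }
})
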