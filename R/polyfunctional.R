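# Polyfunctionality: does one gene's per-cell contextual embedding split
# into well-separated clusters within a single cell type?

# mean silhouette width on a precomputed distance matrix
mean_silhouette <- function(d, labels) {
  labels <- as.integer(factor(labels))
  k <- max(labels)
  if (k < 2L) return(0)
  n <- length(labels)
  sizes <- tabulate(labels, k)
  # mean distance from each point to each cluster
  md <- rowsum(t(d), labels)                 # k x n sums
  md <- md / sizes
  s <- numeric(n)
  for (i in seq_len(n)) {
    ci <- labels[i]
    a <- if (sizes[ci] > 1L) md[ci, i] * sizes[ci] / (sizes[ci] - 1L) else 0
    b <- min(md[-ci, i])
    s[i] <- if (sizes[ci] > 1L && max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  mean(s)
}

# symmetric kNN graph (cosine similarity) as an igraph object
knn_graph <- function(vectors, k = 15L) {
  sims <- cosine_matrix(vectors)
  diag(sims) <- -Inf
  n <- nrow(sims)
  k <- min(k, n - 1L)
  edges <- vector("list", n)
  for (i in seq_len(n)) {
    nb <- order(sims[i, ], decreasing = TRUE)[seq_len(k)]
    edges[[i]] <- cbind(i, nb, (1 + sims[i, nb]) / 2)
  }
  e <- do.call(rbind, edges)
  g <- igraph::graph_from_edgelist(e[, 1:2, drop = FALSE], directed = FALSE)
  igraph::E(g)$weight <- e[, 3]
  igraph::simplify(g, edge.attr.comb = "max")
}

# one clustering pass: kNN-Louvain communities, small clusters merged, then
# the partition maximizing mean silhouette along a greedy centroid-merge path
cluster_embeddings <- function(E, k_neighbors, resolution, min_frac) {
  n <- nrow(E)
  g <- knn_graph(E, k_neighbors)
  comm <- igraph::cluster_louvain(g, resolution = resolution)
  labels <- merge_small_clusters(E, igraph::membership(comm), min_frac)
  d <- 1 - cosine_matrix(E)
  best_labels <- rep(1L, n); best_sil <- -Inf
  cur <- relabel(labels)
  while (TRUE) {
    k <- max(cur)
    if (k >= 2L) {
      sil <- mean_silhouette(d, cur)
      if (sil > best_sil) {
        best_sil <- sil
        best_labels <- cur
      }
    }
    if (k <= 2L) break
    cen <- rowsum(E, cur) / tabulate(cur, k)
    cs <- cosine_matrix(cen)
    diag(cs) <- -Inf
    pair <- which(cs == max(cs), arr.ind = TRUE)[1L, ]
    cur[cur == pair[2L]] <- pair[1L]
    cur <- relabel(cur)
  }
  list(labels = best_labels,
       silhouette = if (is.finite(best_sil)) best_sil else 0)
}

# does a 1-D projection look two-component rather than one-component?
# BIC model selection between a 1- and 2-component Gaussian mixture
projection_bimodal <- function(x, bic_margin = 20) {
  if (length(x) < 8L || stats::sd(x) < 1e-10) return(FALSE)
  bic <- tryCatch(
    suppressWarnings(mclust::mclustBIC(x, G = 1:2, verbose = FALSE)),
    error = function(e) NULL)
  if (is.null(bic)) return(FALSE)
  b <- suppressWarnings(apply(unclass(bic), 1L, max, na.rm = TRUE))
  is.finite(b["2"]) && is.finite(b["1"]) && b["2"] - b["1"] >= bic_margin
}

# merge cluster pairs whose union, projected on the centroid-difference
# axis, is not decisively two-component (BIC margin on the Kass-Raftery
# "very strong" scale). kNN community detection splits any point cloud; an
# artificial split of one mode projects to a single Gaussian, while two
# real modes project to a bimodal mixture.
refine_partition <- function(E, labels, bic_margin = 20) {
  labels <- relabel(labels)
  repeat {
    k <- max(labels)
    if (k < 2L) return(labels)
    cen <- rowsum(E, labels) / tabulate(labels, k)
    cs <- cosine_matrix(cen)
    pairs <- which(upper.tri(cs), arr.ind = TRUE)
    pairs <- pairs[order(-cs[upper.tri(cs)]), , drop = FALSE]
    merged <- FALSE
    for (p in seq_len(nrow(pairs))) {
      i <- pairs[p, 1L]; j <- pairs[p, 2L]
      members <- labels == i | labels == j
      axis <- cen[i, ] - cen[j, ]
      proj <- as.vector(E[members, , drop = FALSE] %*% axis)
      if (!projection_bimodal(proj, bic_margin)) {
        labels[labels == j] <- i
        labels <- relabel(labels)
        merged <- TRUE
        break
      }
    }
    if (!merged) return(labels)
  }
}

#' Polyfunctionality clustering of a gene's per-cell embeddings
#'
#' Restricts the embedding table to the gene's non-PAD contextualized
#' embeddings within one cell type and asks whether they form multiple
#' well-separated clusters. Initial communities come from Louvain detection
#' on a cosine k-nearest-neighbor graph; clusters below a minimum size
#' fraction are merged into their nearest (centroid-cosine) cluster; the
#' final cluster count is then chosen along a greedy centroid-merging path
#' as the partition maximizing the mean silhouette width (cosine distance).
#'
#' Before clustering, the embeddings are residualized against the cell's
#' detected-gene count (the number of expressed genes is the dominant
#' technical covariate of per-cell embeddings — with key-masked attention it
#' sets the size of the attended set) and against the known phenotype
#' fields: polyfunctional modes are functional states a gene occupies
#' *within* a phenotype context, so clusters that merely restate the cell's
#' tissue or age are not evidence of polyfunctionality — the modes of
#' interest are the ones that persist across phenotype strata. Set
#' `residualize_density` / `residualize_phenotypes` to FALSE to disable.
#'
#' Because kNN community detection finds "clusters" in any point cloud, the
#' partition is then refined: every cluster pair is projected onto its
#' centroid-difference axis, and pairs whose projected union a 2-component
#' Gaussian mixture does not beat a 1-component fit (BIC) are merged — an
#' artificial split through one mode projects to a single Gaussian, two
#' genuine modes to a bimodal mixture. A gene is polyfunctional when at
#' least two clusters survive the refinement and the partition's mean
#' silhouette reaches `sil_min`; otherwise it is reported as one cluster.
#'
#' @param table an `embedding_table`.
#' @param gene gene id.
#' @param cell_type cell-type label to restrict to.
#' @param k_neighbors kNN graph degree (default 15).
#' @param resolution Louvain resolution (default 1).
#' @param min_cells minimum member cells required (default 50).
#' @param min_frac clusters below this fraction of cells are merged
#'   (default 0.05).
#' @param sil_min silhouette floor for calling >= 2 clusters (default 0.1).
#' @param refine merge cluster pairs that fail the projected two-component
#'   test (default TRUE).
#' @param bic_margin evidence margin the two-component fit must hold over
#'   the one-component fit (default 20, decisive on the usual BIC scale).
#' @param cell_type_field phenotype field holding the cell-type label.
#' @param residualize_density regress the per-cell detected-gene count out
#'   of the embeddings before clustering (default TRUE; requires the
#'   `n_expressed` column [extract_embeddings()] provides).
#' @param residualize_phenotypes regress the phenotype fields (factor main
#'   effects) out of the embeddings before clustering (default TRUE).
#' @param n_top_genes number of co-similar genes reported per cluster.
#' @param seed RNG seed for the community detection and the null draws.
#' @return a `polyfunctionality_result`: list with `gene`, `cell_type`,
#'   `labels` (per member cell), `cell` (cell indices), `n_clusters`,
#'   `silhouette`, `polyfunctional` (logical), `top_genes` (per cluster, the
#'   genes whose within-cell-type context embeddings are most cosine-similar
#'   to the cluster centroid).
#' @export
polyfunctionality <- function(table, gene, cell_type, k_neighbors = 15L,
                              resolution = 1, min_cells = 50L,
                              min_frac = 0.05, sil_min = 0.1,
                              refine = TRUE, bic_margin = 20,
                              cell_type_field = "cell_type",
                              residualize_density = TRUE,
                              residualize_phenotypes = TRUE,
                              n_top_genes = 10L, seed = 1L) {
  stopifnot(inherits(table, "embedding_table"))
  sel <- table$info$entity == gene &
    table$info[[cell_type_field]] == cell_type
  if (sum(sel) < min_cells)
    stop("support error: gene '", gene, "' has ", sum(sel),
         " embeddings in cell type '", cell_type, "' (need ", min_cells, ")")
  E <- table$vectors[sel, , drop = FALSE]
  covars <- list()
  if (residualize_density && "n_expressed" %in% names(table$info))
    covars$n <- scale(table$info$n_expressed[sel])
  if (residualize_phenotypes) {
    for (f in names(table$phenotypes)) {
      if (f == cell_type_field) next  # constant within the restriction
      v <- factor(table$info[[f]][sel])
      if (nlevels(v) >= 2L)
        covars[[f]] <- stats::model.matrix(~ v)[, -1L, drop = FALSE]
    }
  }
  if (length(covars) > 0L) {
    X <- cbind(1, do.call(cbind, covars))
    E <- E - X %*% solve(crossprod(X), crossprod(X, E))
  }
  cells <- table$info$cell[sel]
  n <- nrow(E)
  set.seed(seed)
  obs <- cluster_embeddings(E, k_neighbors, resolution, min_frac)
  labels <- obs$labels
  if (refine && max(labels) >= 2L)
    labels <- refine_partition(E, labels, bic_margin)
  silhouette <- if (max(labels) >= 2L)
    mean_silhouette(1 - cosine_matrix(E), labels) else obs$silhouette
  ok <- max(labels) >= 2L && silhouette >= sil_min
  if (!ok) labels <- rep(1L, n)
  top <- cluster_top_genes(table, gene, cell_type, cell_type_field,
                           E, labels, n_top_genes)
  structure(list(gene = gene, cell_type = cell_type, labels = labels,
                 cell = cells, n_clusters = max(labels),
                 silhouette = silhouette,
                 polyfunctional = ok, top_genes = top),
            class = "polyfunctionality_result")
}

relabel <- function(labels) as.integer(factor(labels))

merge_small_clusters <- function(E, labels, min_frac) {
  labels <- relabel(labels)
  repeat {
    k <- max(labels)
    if (k <= 1L) return(labels)
    sizes <- tabulate(labels, k)
    small <- which(sizes < min_frac * length(labels))
    if (length(small) == 0L) return(labels)
    cen <- rowsum(E, labels) / sizes
    cs <- cosine_matrix(cen)
    diag(cs) <- -Inf
    s <- small[which.min(sizes[small])]
    target <- which.max(cs[s, ])
    labels[labels == s] <- target
    labels <- relabel(labels)
  }
}

# genes whose within-cell-type mean embeddings best match each centroid
cluster_top_genes <- function(table, gene, cell_type, cell_type_field,
                              E, labels, n_top) {
  in_ct <- table$info$role == "gene" &
    table$info[[cell_type_field]] == cell_type &
    table$info$entity != gene
  if (!any(in_ct)) return(list())
  ginfo <- table$info$entity[in_ct]
  gv <- rowsum(table$vectors[in_ct, , drop = FALSE], ginfo)
  gv <- gv / as.vector(table(factor(ginfo, levels = rownames(gv))))
  k <- max(labels)
  cen <- rowsum(E, labels) / tabulate(labels, k)
  sims <- cosine_matrix(gv, cen)
  out <- vector("list", k)
  for (cl in seq_len(k)) {
    ord <- order(-sims[, cl])[seq_len(min(n_top, nrow(sims)))]
    out[[cl]] <- data.frame(gene = rownames(sims)[ord],
                            similarity = sims[ord, cl],
                            stringsAsFactors = FALSE)
  }
  names(out) <- paste0("cluster_", seq_len(k))
  out
}

#' @export
print.polyfunctionality_result <- function(x, ...) {
  cat(sprintf(
    "polyfunctionality: gene %s in %s -> %d cluster(s), silhouette %.3f%s\n",
    x$gene, x$cell_type, x$n_clusters, x$silhouette,
    if (x$polyfunctional) " [polyfunctional]" else ""))
  invisible(x)
}
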