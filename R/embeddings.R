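#' Extract contextualized embeddings
#'
#' Runs the trained encoder on uncorrupted cells and collects the last-layer
#' hidden state (after the final layer norm) at every non-PAD slot: the
#' contextualized embedding of that gene or phenotype token in that cell.
#' Also emits a per-cell vector, the mean over the cell's non-PAD slots.
#'
#' @param params trained parameters.
#' @param cfg the `model_config`.
#' @param cells a `tokenized_cells` object (clean, not corrupted).
#' @param batch_size forward batch size.
#' @return an `embedding_table`: list with `vectors` (rows x h matrix, one
#'   row per non-PAD slot per cell), `info` (data.frame: `cell`, `cell_id`,
#'   `slot`, `role` = "phenotype"/"gene", `entity` = field name or gene id,
#'   plus the cell's phenotype columns), `cells` (n x h per-cell means),
#'   `phenotypes`, `h`.
#' @export
extract_embeddings <- function(params, cfg, cells, batch_size = 64L) {
  stopifnot(inherits(cells, "tokenized_cells"))
  n <- nrow(cells$tokens); S <- ncol(cells$tokens)
  H <- matrix(NA_real_, n * S, cfg$h)
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    sub <- subset_tokenized(cells, idx)
    fw <- encoder_forward(sub$tokens, sub$pad, params, cfg)
    m <- length(idx)
    for (s in seq_len(S))
      H[(s - 1L) * n + idx, ] <- fw$H[(s - 1L) * m + seq_len(m), ,
                                      drop = FALSE]
  }
  keep_flat <- !as.vector(cells$pad)
  cell_of <- rep(seq_len(n), times = S)
  slot_of <- rep(seq_len(S), each = n)
  role <- ifelse(slot_of <= cells$F, "phenotype", "gene")
  entity <- cells$slot_entities[slot_of]
  info <- data.frame(cell = cell_of[keep_flat],
                     cell_id = cells$cell_ids[cell_of[keep_flat]],
                     slot = slot_of[keep_flat],
                     role = role[keep_flat],
                     entity = entity[keep_flat],
                     stringsAsFactors = FALSE)
  info <- cbind(info, cells$phenotypes[info$cell, , drop = FALSE])
  # detected-gene count: the classic per-cell technical covariate; the
  # polyfunctionality clustering residualizes against it
  info$n_expressed <- rowSums(!cells$pad)[info$cell]
  rownames(info) <- NULL
  vectors <- H[keep_flat, , drop = FALSE]
  cell_means <- rowsum(vectors, info$cell) /
    as.vector(table(factor(info$cell, levels = seq_len(n))))
  structure(list(vectors = vectors, info = info, cells = cell_means,
                 phenotypes = cells$phenotypes, h = cfg$h),
            class = "embedding_table")
}

#' @export
print.embedding_table <- function(x, ...) {
  cat(sprintf("embedding_table: %d slot embeddings (h = %d) over %d cells\n",
              nrow(x$vectors), x$h, nrow(x$cells)))
  invisible(x)
}

#' Aggregate embeddings of one entity by phenotype context
#'
#' Averages the contextualized embeddings of a gene or phenotype slot over
#' all cells sharing a combination of the grouping fields, yielding one
#' context embedding per observed combination with its support count.
#'
#' @param table an `embedding_table`.
#' @param entity gene id or phenotype field name.
#' @param fields character vector of phenotype fields to group by.
#' @param min_support contexts with fewer member cells are flagged
#'   (default 20).
#' @return a `context_embeddings` object: list with `context` (data.frame of
#'   grouping values), `vectors` (contexts x h matrix of means), `n_cells`,
#'   `flagged` (logical, support below `min_support`), `entity`.
#' @export
aggregate_by_context <- function(table, entity, fields,
                                 min_support = 20L) {
  stopifnot(inherits(table, "embedding_table"))
  if (!all(fields %in% names(table$phenotypes)))
    stop("grouping fields must belong to the phenotype schema")
  sel <- table$info$entity == entity
  if (!any(sel)) stop("lookup error: entity '", entity, "' not in table")
  info <- table$info[sel, , drop = FALSE]
  vec <- table$vectors[sel, , drop = FALSE]
  key <- do.call(paste, c(info[fields], sep = "\r"))
  grp <- factor(key)
  sums <- rowsum(vec, grp)
  counts <- as.vector(table(grp))
  means <- sums / counts
  ctx <- unique(info[fields])
  ctx <- ctx[match(levels(grp), do.call(paste, c(ctx, sep = "\r"))), ,
             drop = FALSE]
  rownames(ctx) <- NULL
  rownames(means) <- do.call(paste, c(ctx, sep = "|"))
  structure(list(context = ctx, vectors = means, n_cells = counts,
                 flagged = counts < min_support, entity = entity),
            class = "context_embeddings")
}

#' Cosine similarity between two vectors
#'
#' @param a,b non-zero numeric vectors of equal length.
#' @return cosine similarity in `[-1, 1]`.
#' @export
cosine_similarity <- function(a, b) {
  na <- sqrt(sum(a * a)); nb <- sqrt(sum(b * b))
  if (na == 0 || nb == 0)
    stop("undefined similarity: zero vector")
  sum(a * b) / (na * nb)
}

# pairwise cosine similarity matrix between rows of A (and rows of B)
cosine_matrix <- function(A, B = NULL) {
  An <- A / sqrt(rowSums(A * A))
  if (is.null(B)) return(An %*% t(An))
  Bn <- B / sqrt(rowSums(B * B))
  An %*% t(Bn)
}

#' Euclidean distance between a gene's context embeddings
#'
#' @param ctx a `context_embeddings` object for the gene.
#' @param contextA,contextB row names (or indices) of the two contexts.
#' @return non-negative Euclidean distance.
#' @export
embedding_distance <- function(ctx, contextA, contextB) {
  stopifnot(inherits(ctx, "context_embeddings"))
  ia <- if (is.character(contextA)) match(contextA, rownames(ctx$vectors))
        else contextA
  ib <- if (is.character(contextB)) match(contextB, rownames(ctx$vectors))
        else contextB
  if (is.na(ia) || is.na(ib))
    stop("lookup error: context not found")
  sqrt(sum((ctx$vectors[ia, ] - ctx$vectors[ib, ])^2))
}

#' Phenotype-gene similarity matrix and universal ranking
#'
#' For every value of a phenotype field, computes the cosine similarity
#' between each gene's context embedding (mean over cells with that value)
#' and the phenotype slot's context embedding in the same cells. The
#' "universal" score of a gene is the mean similarity over the field's
#' values (contexts where the gene is unobserved are excluded); the minimum
#' over values is also reported. Genes are ranked by descending universal
#' score.
#'
#' @param table an `embedding_table`.
#' @param field phenotype field name.
#' @param min_support minimum member cells for a (gene, value) entry.
#' @return list with `similarity` (genes x values matrix, NA where missing),
#'   `universal` (data.frame: gene, universal, min_similarity, sorted
#'   descending), `field`.
#' @export
phenotype_gene_similarity <- function(table, field, min_support = 1L) {
  stopifnot(inherits(table, "embedding_table"))
  if (!field %in% names(table$phenotypes))
    stop("unknown field '", field, "'")
  values <- sort(unique(as.character(table$phenotypes[[field]])))
  genes <- sort(unique(table$info$entity[table$info$role == "gene"]))
  sim <- matrix(NA_real_, length(genes), length(values),
                dimnames = list(genes, values))
  for (v in values) {
    in_ctx <- table$info[[field]] == v
    ph <- table$info$role == "phenotype" & table$info$entity == field & in_ctx
    if (!any(ph)) next
    pvec <- colMeans(table$vectors[ph, , drop = FALSE])
    ge <- table$info$role == "gene" & in_ctx
    if (!any(ge)) next
    ginfo <- table$info$entity[ge]
    gv <- rowsum(table$vectors[ge, , drop = FALSE], ginfo)
    cnt <- as.vector(table(factor(ginfo, levels = rownames(gv))))
    gv <- gv / cnt
    ok <- cnt >= min_support
    s <- as.vector(cosine_matrix(gv, matrix(pvec, 1L)))
    sim[rownames(gv)[ok], v] <- s[ok]
  }
  universal <- rowMeans(sim, na.rm = TRUE)
  minsim <- suppressWarnings(apply(sim, 1L, min, na.rm = TRUE))
  minsim[!is.finite(minsim)] <- NA_real_
  ord <- order(-universal)
  rank_df <- data.frame(gene = genes[ord], universal = universal[ord],
                        min_similarity = minsim[ord],
                        stringsAsFactors = FALSE)
  rownames(rank_df) <- NULL
  list(similarity = sim, universal = rank_df, field = field)
}

#' Differential-embedding score of a gene across a field
#'
#' One minus the mean pairwise cosine similarity among the gene's context
#' embeddings across the values of a phenotype field: 0 when the embeddings
#' are identical in every context, up to 2 for antipodal contexts. Ranking
#' genes by descending score yields the differentially embedded genes
#' (DEGs) for that field.
#'
#' @param ctx a `context_embeddings` object with >= 2 contexts, or a
#'   contexts x h numeric matrix.
#' @return scalar score >= 0.
#' @export
differential_embedding_score <- function(ctx) {
  vec <- if (inherits(ctx, "context_embeddings")) ctx$vectors else ctx
  m <- nrow(vec)
  if (m < 2L) stop("undefined: need >= 2 context embeddings")
  cm <- cosine_matrix(vec)
  1 - mean(cm[upper.tri(cm)])
}

#' Rank differentially embedded genes over one field
#'
#' Applies [differential_embedding_score()] to every gene observed in at
#' least two values of the field.
#'
#' @param table an `embedding_table`.
#' @param field phenotype field name.
#' @param min_support minimum member cells per (gene, value) context.
#' @return data.frame (`gene`, `score`, `n_contexts`) sorted by descending
#'   score; genes with < 2 qualifying contexts are excluded.
#' @export
rank_deg <- function(table, field, min_support = 1L) {
  genes <- unique(table$info$entity[table$info$role == "gene"])
  res <- lapply(genes, function(g) {
    ctx <- tryCatch(aggregate_by_context(table, g, field,
                                         min_support = min_support),
                    error = function(e) NULL)
    if (is.null(ctx)) return(NULL)
    keep <- ctx$n_cells >= min_support
    if (sum(keep) < 2L) return(NULL)
    data.frame(gene = g,
               score = differential_embedding_score(
                 ctx$vectors[keep, , drop = FALSE]),
               n_contexts = sum(keep), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out <- out[order(-out$score), ]
  rownames(out) <- NULL
  out
}

#' Tissue similarity matrix and dendrogram
#'
#' Averages the per-cell embedding vectors within each tissue, computes the
#' Pearson correlation between tissue vectors, and clusters tissues by
#' average linkage on the distance `1 - r`.
#'
#' @param table an `embedding_table`.
#' @param field phenotype field holding the tissue label (default
#'   `"tissue"`).
#' @return list with `correlation` (symmetric matrix, unit diagonal),
#'   `hclust` (average-linkage tree on `1 - r`), `flagged` (tissues with
#'   < 2 cells).
#' @export
tissue_similarity_matrix <- function(table, field = "tissue") {
  stopifnot(inherits(table, "embedding_table"))
  lab <- as.character(table$phenotypes[[field]])
  if (length(unique(lab)) < 2L) stop("need >= 2 tissues")
  grp <- factor(lab)
  means <- rowsum(table$cells, grp) / as.vector(table(grp))
  r <- stats::cor(t(means))
  hc <- stats::hclust(stats::as.dist(1 - r), method = "average")
  flagged <- names(which(table(grp) < 2L))
  list(correlation = r, hclust = hc, flagged = flagged)
}
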