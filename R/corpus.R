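#' Build the unified token vocabulary
#'
#' Lays out one contiguous id space over special tokens, expression-bin
#' tokens and phenotype-category tokens, in a deterministic order:
#' `[PAD, MASK, bin_0..bin_{B-1}, field_1 categories..., field_2 ...]`
#' (fields in schema order, categories in declared order). Each position
#' class of a token sequence — a gene slot, or a slot of a given phenotype
#' field — has a legal set of token ids it may carry.
#'
#' @param phenotype_schema named list: field name -> character vector of
#'   categories.
#' @param B number of expression bins (>= 2).
#' @return a `vocabulary`: list with `size`, `pad`, `mask`, `bin_tokens`
#'   (ids of bins 0..B-1), `phenotype_tokens` (per field, named id vector),
#'   `legal_sets` (list: `gene` plus one entry per field), `B`, `schema`,
#'   and `labels` (id -> printable token name).
#' @export
build_vocabulary <- function(phenotype_schema, B) {
  if (length(phenotype_schema) == 0L) stop("schema error: empty schema")
  if (is.null(names(phenotype_schema)) || any(names(phenotype_schema) == ""))
    stop("schema error: fields must be named")
  if (B < 2L) stop("schema error: B must be >= 2")
  for (f in names(phenotype_schema)) {
    if (anyDuplicated(phenotype_schema[[f]]))
      stop("schema error: duplicate category within field '", f, "'")
  }
  B <- as.integer(B)
  labels <- c("<pad>", "<mask>", paste0("bin_", 0:(B - 1L)))
  pheno <- list()
  nxt <- length(labels) + 1L
  for (f in names(phenotype_schema)) {
    cats <- as.character(phenotype_schema[[f]])
    ids <- seq.int(nxt, length.out = length(cats))
    names(ids) <- cats
    pheno[[f]] <- ids
    labels <- c(labels, paste0(f, "=", cats))
    nxt <- nxt + length(cats)
  }
  legal <- c(list(gene = seq.int(3L, 2L + B)), lapply(pheno, unname))
  structure(list(size = length(labels), pad = 1L, mask = 2L,
                 bin_tokens = seq.int(3L, 2L + B),
                 phenotype_tokens = pheno, legal_sets = legal,
                 B = B, schema = phenotype_schema, labels = labels),
            class = "vocabulary")
}

#' @export
print.vocabulary <- function(x, ...) {
  cat(sprintf("vocabulary: %d ids (%d bins, %d phenotype fields)\n",
              x$size, x$B, length(x$phenotype_tokens)))
  invisible(x)
}

#' Tokenize cells into phenotype + gene sequences
#'
#' Turns every cell of a normalized expression matrix into a fixed-length
#' token sequence `[p_1..p_F, g_1..g_T]`: first one token per phenotype
#' field (schema order), then one slot per retained highly variable gene in
#' HVG-rank order, so slot `F + i` permanently identifies the rank-i gene
#' regardless of input column order. A gene below the expression threshold
#' is a PAD token and flagged in the pad mask; phenotype slots are never
#' PAD.
#'
#' @param matrix a normalized `expression_matrix`.
#' @param ranking a `gene_ranking` from [rank_hvg()].
#' @param spec a `binning_spec`.
#' @param vocab a `vocabulary` built on the same schema and `B`.
#' @return a `tokenized_cells` object: list with integer matrix `tokens`
#'   (cells x (F+T)), logical matrix `pad` (TRUE where gene non-expressed),
#'   `F`, `T`, `slot_entities` (field names then gene ids), `cell_ids`,
#'   `phenotypes`, `vocab`.
#' @export
tokenize_cells <- function(matrix, ranking, spec, vocab) {
  stopifnot(inherits(matrix, "expression_matrix"),
            inherits(ranking, "gene_ranking"),
            inherits(spec, "binning_spec"),
            inherits(vocab, "vocabulary"))
  fields <- names(vocab$phenotype_tokens)
  Fn <- length(fields)
  genes <- ranking$retained
  missing_genes <- setdiff(genes, matrix$gene_ids)
  if (length(missing_genes) > 0)
    stop("retained genes absent from matrix: ",
         paste(utils::head(missing_genes, 3L), collapse = ", "))
  Tn <- length(genes)
  n <- nrow(matrix$values)
  tokens <- matrix(vocab$pad, n, Fn + Tn)
  for (j in seq_along(fields)) {
    f <- fields[j]
    vals <- as.character(matrix$phenotypes[[f]])
    ids <- vocab$phenotype_tokens[[f]][vals]
    if (anyNA(ids)) {
      bad <- unique(vals[is.na(ids)])
      stop("vocabulary error: unknown category for field '", f, "': ",
           paste(bad, collapse = ", "))
    }
    tokens[, j] <- ids
  }
  vals <- as.matrix(matrix$values)[, match(genes, matrix$gene_ids),
                                   drop = FALSE]
  bins <- bin_expression(vals, spec)
  expressed <- bins != NON_EXPRESSED
  gene_tok <- matrix(vocab$pad, n, Tn)
  gene_tok[expressed] <- vocab$bin_tokens[bins[expressed] + 1L]
  tokens[, Fn + seq_len(Tn)] <- gene_tok
  pad <- tokens == vocab$pad
  structure(list(tokens = tokens, pad = pad, F = Fn, T = Tn,
                 slot_entities = c(fields, genes),
                 cell_ids = matrix$cell_ids,
                 phenotypes = matrix$phenotypes, vocab = vocab),
            class = "tokenized_cells")
}

#' @export
print.tokenized_cells <- function(x, ...) {
  cat(sprintf("tokenized_cells: %d cells, %d phenotype + %d gene slots\n",
              nrow(x$tokens), x$F, x$T))
  invisible(x)
}

#' Subset a tokenized corpus by cell index
#' @param x a `tokenized_cells` object.
#' @param cells integer or logical index over cells.
#' @return a `tokenized_cells` restricted to the selected cells.
#' @export
subset_tokenized <- function(x, cells) {
  out <- x
  out$tokens <- x$tokens[cells, , drop = FALSE]
  out$pad <- x$pad[cells, , drop = FALSE]
  out$cell_ids <- x$cell_ids[cells]
  out$phenotypes <- x$phenotypes[cells, , drop = FALSE]
  out
}

#' Masking policy for the multi-task corruption
#'
#' Genotype (gene-bin) slots and phenotype slots are masked at different
#' rates: phenotype slots with higher probability, because there are far
#' fewer of them per cell. PAD slots are never maskable.
#'
#' @param r_geno gene-slot mask rate (default 0.15).
#' @param r_pheno phenotype-slot mask rate (default 0.50).
#' @return a `masking_policy` list.
#' @export
masking_policy <- function(r_geno = 0.15, r_pheno = 0.50) {
  if (r_geno < 0 || r_geno > 1 || r_pheno < 0 || r_pheno > 1)
    stop("mask rates must lie in [0, 1]")
  structure(list(r_geno = r_geno, r_pheno = r_pheno),
            class = "masking_policy")
}

#' Corrupt tokenized cells by random masking
#'
#' Independently replaces each non-PAD slot's token by MASK — gene slots
#' with probability `policy$r_geno`, phenotype slots with `policy$r_pheno` —
#' and records the original tokens as labels. Reproducible from the current
#' RNG state (seed with [set.seed()] before the call).
#'
#' @param cells a `tokenized_cells` object.
#' @param policy a `masking_policy`.
#' @return a `corrupted_cells` object: `tokens` (corrupted), `masked`
#'   (logical matrix, the masked set), `labels` (original tokens), `pad`,
#'   plus the slot layout fields of the input.
#' @export
corrupt <- function(cells, policy = masking_policy()) {
  stopifnot(inherits(cells, "tokenized_cells"),
            inherits(policy, "masking_policy"))
  tok <- cells$tokens
  n <- nrow(tok); S <- ncol(tok)
  rate <- matrix(rep(c(rep(policy$r_pheno, cells$F),
                       rep(policy$r_geno, cells$T)), each = n), n, S)
  masked <- matrix(stats::runif(n * S) < rate, n, S) & !cells$pad
  out_tok <- tok
  out_tok[masked] <- cells$vocab$mask
  structure(list(tokens = out_tok, masked = masked, labels = tok,
                 pad = cells$pad, F = cells$F, T = cells$T,
                 slot_entities = cells$slot_entities,
                 cell_ids = cells$cell_ids, phenotypes = cells$phenotypes,
                 vocab = cells$vocab),
            class = "corrupted_cells")
}

#' Ordinal soft-label distribution
#'
#' Replaces the one-hot target by a smoothed distribution over the legal
#' token set of the slot: the true token keeps `1 - r_smooth` and the
#' remaining mass is dispersed evenly over the other legal tokens,
#' `r_smooth / (|legal| - 1)` each. A singleton legal set degenerates to
#' probability one on the true token.
#'
#' @param true_token id of the true token; must belong to `legal_set`.
#' @param legal_set integer vector of legal token ids (names of the result).
#' @param r_smooth smoothing mass in `[0, 1)` (default 0.1).
#' @return numeric probability vector over `legal_set`, summing to 1.
#' @export
soft_label <- function(true_token, legal_set, r_smooth = 0.1) {
  if (r_smooth < 0 || r_smooth >= 1) stop("r_smooth must lie in [0, 1)")
  k <- length(legal_set)
  pos <- match(true_token, legal_set)
  if (is.na(pos)) stop("true_token is not in the legal set")
  if (k == 1L) {
    p <- 1
  } else {
    p <- rep(r_smooth / (k - 1L), k)
    p[pos] <- 1 - r_smooth
  }
  names(p) <- legal_set
  p
}

#' Entropy of a soft-label distribution
#'
#' The cross-entropy between a soft-label target and a model that outputs
#' exactly that target equals this entropy: it is the attainable lower bound
#' of the masked training loss.
#'
#' @param n_legal size of the slot's legal token set.
#' @param r_smooth smoothing mass.
#' @return entropy in nats.
#' @export
soft_label_entropy <- function(n_legal, r_smooth = 0.1) {
  if (n_legal == 1L || r_smooth == 0) return(0)
  q <- c(1 - r_smooth, rep(r_smooth / (n_legal - 1L), n_legal - 1L))
  -sum(q * log(q))
}

#' Stratified train/validation split of a tokenized corpus
#'
#' @param cells a `tokenized_cells` object.
#' @param by phenotype field to stratify on (default `"cell_type"` when
#'   present, else the last schema field).
#' @param val_frac validation fraction (default 0.1).
#' @param seed RNG seed.
#' @return list with `train` and `val` `tokenized_cells`, and the index
#'   vectors `train_idx`, `val_idx`.
#' @export
split_corpus <- function(cells, by = NULL, val_frac = 0.1, seed = 1L) {
  stopifnot(inherits(cells, "tokenized_cells"))
  fields <- names(cells$vocab$phenotype_tokens)
  if (is.null(by))
    by <- if ("cell_type" %in% fields) "cell_type" else fields[length(fields)]
  labels <- as.character(cells$phenotypes[[by]])
  set.seed(seed)
  val_idx <- integer(0)
  for (lv in unique(labels)) {
    idx <- which(labels == lv)
    n_val <- max(1L, round(length(idx) * val_frac))
    val_idx <- c(val_idx, sample(idx, n_val))
  }
  val_idx <- sort(val_idx)
  train_idx <- setdiff(seq_along(labels), val_idx)
  list(train = subset_tokenized(cells, train_idx),
       val = subset_tokenized(cells, val_idx),
       train_idx = train_idx, val_idx = val_idx)
}
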