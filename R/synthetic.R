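#' Configuration for the synthetic single-cell atlas
#'
#' The generator emulates the structure of a multi-donor human cell atlas:
#' categorical phenotype fields (sex, age group, tissue, cell type), sparse
#' negative-binomial counts with log-normal library sizes, phenotype-linked
#' gene programs (each tissue and each cell type activates one program of
#' genes with a fixed log-fold loading), one planted polyfunctional gene
#' whose expression and co-variation partner switch with a context field,
#' and one planted single-mode control gene.
#'
#' @param n_cells number of cells (default 2000).
#' @param n_genes number of genes (default 300); must accommodate all
#'   programs plus the two planted genes.
#' @param schema named list of phenotype categories. Default: sex (2), age
#'   group (3), tissue (3), cell type (4).
#' @param program_size genes per tissue program (default 20).
#' @param celltype_program_size genes per cell-type program (default 10).
#' @param log_fold natural-log loading of a tissue program on its genes
#'   (default 1.5).
#' @param celltype_log_fold loading of cell-type programs (default 1.0).
#' @param switch_field what drives the polyfunctional gene's mode. The
#'   default `"latent"` draws a per-cell Bernoulli state independent of
#'   every phenotype field — polyfunctional modes are functional states
#'   *within* a phenotype context, not phenotype relabelings — matching how
#'   polyfunctionality is validated downstream (clusters that persist after
#'   known phenotypes are regressed out). Alternatively the name of a
#'   schema field, whose first half of categories selects mode A.
#' @param mode_frac probability of mode A under the latent switch
#'   (default 0.5).
#' @param partner_module_size genes per dedicated partner module of the
#'   polyfunctional gene (default 10). The two partner modules are their own
#'   gene sets, not reused tissue or cell-type programs, so the two modes
#'   are not entangled with any other phenotype's expression signature.
#' @param mode_loading extra log-mean of the mode's partner module in cells
#'   of that mode (default 1.5, the tissue-program loading): each mode is a
#'   context program as strong as a tissue signature — partner
#'   module A is mildly active wherever the polyfunctional gene is in mode
#'   A, module B in mode B — so the two modes differ in cellular context,
#'   not only in the gene's own expression bin.
#' @param poly_shift extra log-mean of the polyfunctional gene in mode A
#'   (default 2.5): large enough that the two modes occupy disjoint
#'   expression-bin ranges, i.e., the planted modes are well separated.
#' @param latent_sd sd of the shared log-normal latent coupling the
#'   polyfunctional gene to its partner module (default 0.5). The gene's
#'   HVG rank is carried by the between-mode shift; the within-mode latent
#'   is kept small so the two modes stay well separated in normalized bin
#'   space after the dispersion scaling (which compresses exactly the genes
#'   it makes most variable).
#' @param mono_latent_sd sd of the private, context-independent latent of
#'   the single-mode control gene (default 1.2): enough variability to rank
#'   among the HVGs, but unimodal in every context.
#' @param planted_base baseline log-mean of the two planted genes (default
#'   `log(1.5)`): expressed in most cells yet in the mid range of means,
#'   where their latent variability ranks them among the HVGs.
#' @param nb_dispersion negative-binomial dispersion phi (variance
#'   `mu + phi mu^2`; default 0.5).
#' @param lib_meanlog,lib_sdlog log-normal library-size factor parameters
#'   (defaults 0, 0.3).
#' @param base_meanlog,base_sdlog per-gene baseline log-mean distribution
#'   (defaults `log(0.8)`, 0.4).
#' @param n_donors donors recorded as metadata (default 8; not a token
#'   field).
#' @param seed mandatory RNG seed.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_cells = 2000L, n_genes = 300L,
                             schema = list(
                               sex = c("female", "male"),
                               age = c("young", "middle", "old"),
                               tissue = c("heart", "lung", "blood"),
                               cell_type = c("endothelial", "epithelial",
                                             "fibroblast", "macrophage")),
                             program_size = 20L,
                             celltype_program_size = 10L,
                             log_fold = 1.5, celltype_log_fold = 1.0,
                             switch_field = "latent", mode_frac = 0.5,
                             partner_module_size = 10L,
                             mode_loading = 1.5,
                             poly_shift = 2.5, latent_sd = 0.5,
                             mono_latent_sd = 1.2,
                             planted_base = log(1.5),
                             nb_dispersion = 0.5,
                             lib_meanlog = 0, lib_sdlog = 0.3,
                             base_meanlog = log(0.8), base_sdlog = 0.4,
                             n_donors = 8L, seed) {
  if (missing(seed)) stop("seed is mandatory")
  n_prog_genes <- length(schema$tissue) * program_size +
    length(schema$cell_type) * celltype_program_size +
    2L * partner_module_size
  if (n_prog_genes + 2L > n_genes)
    stop("config error: programs (", n_prog_genes,
         " genes) plus planted genes exceed n_genes = ", n_genes)
  structure(as.list(environment()), class = "synthetic_config")
}

#' Generate a synthetic atlas with planted structure
#'
#' Draws per-cell phenotypes uniformly, builds each cell's log-mean
#' expression as baseline + the loadings of the programs its tissue and cell
#' type activate, couples the planted polyfunctional gene to partner module
#' A (shared log-normal latent, plus an expression shift) in cells where the
#' switch field takes its first half of categories and to module B
#' otherwise, and draws negative-binomial counts scaled by a log-normal
#' library-size factor. Deterministic given `config$seed`.
#'
#' @param config a `synthetic_config`.
#' @return list with `matrix` (an `expression_matrix`) and `truth` (a
#'   `planted_truth`: `gene_program` map, `context_programs` map, `markers`
#'   per phenotype value, `poly_gene`, `mono_gene`, `poly_mode` per cell,
#'   and the `generator` internals reused by [generate_aged_variant()]).
#' @export
generate_atlas <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n <- config$n_cells; m <- config$n_genes
  gene_ids <- sprintf("G%04d", seq_len(m))
  poly_gene <- "GPOLY"; mono_gene <- "GMONO"
  gene_ids[m - 1L] <- poly_gene
  gene_ids[m] <- mono_gene
  cell_ids <- sprintf("C%05d", seq_len(n))
  pheno <- as.data.frame(lapply(config$schema, function(cats)
    sample(cats, n, replace = TRUE)), stringsAsFactors = FALSE)
  donor <- sample(sprintf("D%02d", seq_len(config$n_donors)), n,
                  replace = TRUE)

  # program memberships: tissue programs first, then cell-type programs
  nxt <- 1L
  programs <- list()
  gene_program <- setNames(rep(NA_character_, m), gene_ids)
  context_programs <- list()
  markers <- list()
  for (tv in config$schema$tissue) {
    idx <- nxt:(nxt + config$program_size - 1L)
    nxt <- nxt + config$program_size
    pname <- paste0("tissue:", tv)
    programs[[pname]] <- list(genes = idx, field = "tissue", value = tv,
                              loading = config$log_fold)
    gene_program[idx] <- pname
    context_programs[[pname]] <- tv
    markers[[paste0("tissue=", tv)]] <- gene_ids[idx]
  }
  for (cv in config$schema$cell_type) {
    idx <- nxt:(nxt + config$celltype_program_size - 1L)
    nxt <- nxt + config$celltype_program_size
    pname <- paste0("cell_type:", cv)
    programs[[pname]] <- list(genes = idx, field = "cell_type", value = cv,
                              loading = config$celltype_log_fold)
    gene_program[idx] <- pname
    markers[[paste0("cell_type=", cv)]] <- gene_ids[idx]
  }

  base_g <- stats::rnorm(m, config$base_meanlog, config$base_sdlog)
  base_g[m - 1L] <- config$planted_base  # poly gene: expressed everywhere
  base_g[m] <- config$planted_base       # single-mode control gene
  logmu <- matrix(rep(base_g, each = n), n, m)
  for (p in programs) {
    in_ctx <- pheno[[p$field]] == p$value
    logmu[in_ctx, p$genes] <- logmu[in_ctx, p$genes] + p$loading
  }

  # dedicated partner modules of the polyfunctional gene
  partnerA <- nxt:(nxt + config$partner_module_size - 1L)
  nxt <- nxt + config$partner_module_size
  partnerB <- nxt:(nxt + config$partner_module_size - 1L)
  nxt <- nxt + config$partner_module_size
  gene_program[partnerA] <- "mode:A"
  gene_program[partnerB] <- "mode:B"
  markers[["mode=A"]] <- gene_ids[partnerA]
  markers[["mode=B"]] <- gene_ids[partnerB]

  # polyfunctional gene: latent per-cell mode, or a phenotype field's first
  # half of categories
  sw <- config$switch_field
  if (identical(sw, "latent")) {
    modeA <- stats::runif(n) < config$mode_frac
  } else {
    cats <- config$schema[[sw]]
    modeA_vals <- cats[seq_len(floor(length(cats) / 2))]
    modeA <- pheno[[sw]] %in% modeA_vals
  }
  zA <- stats::rnorm(n, 0, config$latent_sd)
  zB <- stats::rnorm(n, 0, config$latent_sd)
  jp <- m - 1L
  logmu[modeA, jp] <- logmu[modeA, jp] + config$poly_shift + zA[modeA]
  logmu[modeA, partnerA] <- logmu[modeA, partnerA] + config$mode_loading +
    zA[modeA]
  logmu[!modeA, jp] <- logmu[!modeA, jp] + zB[!modeA]
  logmu[!modeA, partnerB] <- logmu[!modeA, partnerB] + config$mode_loading +
    zB[!modeA]

  # single-mode control: private unimodal variability, no context coupling
  zM <- stats::rnorm(n, 0, config$mono_latent_sd)
  logmu[, m] <- logmu[, m] + zM

  s_c <- stats::rlnorm(n, config$lib_meanlog, config$lib_sdlog)
  counts <- draw_counts(logmu, s_c, config$nb_dispersion)

  meta <- cbind(pheno, donor = donor, stringsAsFactors = FALSE)
  em <- expression_matrix(counts, gene_ids, cell_ids, meta,
                          schema = config$schema)
  truth <- structure(
    list(gene_program = gene_program, context_programs = context_programs,
         markers = markers, poly_gene = poly_gene, mono_gene = mono_gene,
         poly_mode = ifelse(modeA, "A", "B"),
         generator = list(config = config, base_g = base_g,
                          programs = programs,
                          partnerA = partnerA, partnerB = partnerB,
                          logmu = logmu, s_c = s_c,
                          zA = zA, zB = zB, modeA = modeA)),
    class = "planted_truth")
  list(matrix = em, truth = truth)
}

draw_counts <- function(logmu, s_c, phi) {
  n <- nrow(logmu); m <- ncol(logmu)
  mu <- exp(logmu) * s_c
  counts <- matrix(stats::rnbinom(n * m, mu = as.vector(mu), size = 1 / phi),
                   n, m)
  counts
}

#' Generate an "aged" variant with extra cross-module coupling
#'
#' Re-draws the atlas counts after adding, for cells in the oldest age
#' category, a shared log-normal latent of scale `edge_noise` across all
#' program genes. The shared factor induces cross-module gene-gene
#' correlations (absent in the source atlas, where latents are confined to
#' one module), which raises the connectivity of otherwise low-degree genes
#' in the embedding-similarity network. `edge_noise = 0` reproduces the
#' source distributional parameters exactly.
#'
#' @param atlas the `expression_matrix` from [generate_atlas()].
#' @param truth the matching `planted_truth`.
#' @param edge_noise coupling scale in `[0, 1]`.
#' @return list with `matrix` and `truth`, as in [generate_atlas()]; the
#'   truth records `aged_cells` and `edge_noise`.
#' @export
generate_aged_variant <- function(atlas, truth, edge_noise) {
  stopifnot(inherits(atlas, "expression_matrix"),
            inherits(truth, "planted_truth"))
  if (edge_noise < 0 || edge_noise > 1)
    stop("parameter error: edge_noise must lie in [0, 1]")
  gen <- truth$generator
  config <- gen$config
  set.seed(config$seed + 1L)
  old_cat <- config$schema$age[length(config$schema$age)]
  old <- atlas$phenotypes$age == old_cat
  logmu <- gen$logmu
  prog_genes <- sort(unique(c(unlist(lapply(gen$programs, `[[`, "genes")),
                              gen$partnerA, gen$partnerB)))
  g_c <- stats::rnorm(config$n_cells, 0, edge_noise)
  logmu[old, prog_genes] <- logmu[old, prog_genes] + g_c[old]
  counts <- draw_counts(logmu, gen$s_c, config$nb_dispersion)
  em <- expression_matrix(counts, atlas$gene_ids, atlas$cell_ids,
                          atlas$phenotypes, schema = config$schema)
  truth2 <- truth
  truth2$generator$logmu <- logmu
  truth2$aged_cells <- which(old)
  truth2$edge_noise <- edge_noise
  list(matrix = em, truth = truth2)
}

#' End-to-end corpus preparation
#'
#' Convenience pipeline: normalize, rank HVGs, resolve the
#' expressed/non-expressed threshold, build the binning spec and vocabulary,
#' and tokenize — the preprocessing a raw atlas needs before [pretrain()].
#'
#' @param em an `expression_matrix` of raw counts.
#' @param T number of HVGs to retain.
#' @param B number of expression bins (default 10).
#' @param threshold `"auto"` (histogram detection) or a numeric value
#'   (default 0.1).
#' @param target_total library-size target (default 10000).
#' @return list with `cells` (a `tokenized_cells`), `vocab`, `ranking`,
#'   `spec`, `normalized` (the normalized `expression_matrix`).
#' @export
prepare_corpus <- function(em, T, B = 10L, threshold = 0.1,
                           target_total = 1e4) {
  norm <- normalize_expression(em, target_total)
  ranking <- rank_hvg(norm, T)
  thr <- if (identical(threshold, "auto")) detect_threshold(norm)
         else threshold
  spec <- binning_spec(norm, B = B, threshold = thr)
  vocab <- build_vocabulary(norm$schema, B)
  cells <- tokenize_cells(norm, ranking, spec, vocab)
  list(cells = cells, vocab = vocab, ranking = ranking, spec = spec,
       normalized = norm)
}
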