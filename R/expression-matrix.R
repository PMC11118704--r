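#' Construct an annotated expression matrix
#'
#' Bundles a cells x genes matrix of non-negative expression values with
#' per-cell categorical phenotype metadata and the phenotype schema (the
#' declared category set of every field). This is the input container for
#' the whole pipeline; all downstream functions (normalization, tokenization,
#' the synthetic generator) produce or consume it.
#'
#' @param values cells x genes numeric matrix (dense or `Matrix` sparse),
#'   non-negative.
#' @param gene_ids character vector of unique gene symbols, one per column.
#' @param cell_ids character vector of unique cell barcodes, one per row.
#' @param phenotypes data.frame with one row per cell; categorical columns.
#' @param schema named list mapping each phenotype field to its declared
#'   category levels (character). Defaults to the observed levels of every
#'   column of `phenotypes`.
#' @return An object of class `expression_matrix` with elements `values`,
#'   `gene_ids`, `cell_ids`, `phenotypes`, `schema`.
#' @export
expression_matrix <- function(values, gene_ids, cell_ids, phenotypes,
                              schema = NULL) {
  if (is.null(dim(values))) stop("`values` must be a matrix")
  if (nrow(values) == 0L || ncol(values) == 0L)
    stop("invalid input: expression matrix must have at least one cell and one gene")
  if (length(gene_ids) != ncol(values))
    stop("length(gene_ids) must equal ncol(values)")
  if (length(cell_ids) != nrow(values))
    stop("length(cell_ids) must equal nrow(values)")
  if (anyDuplicated(gene_ids)) stop("gene_ids must be unique")
  phenotypes <- as.data.frame(phenotypes, stringsAsFactors = FALSE)
  if (nrow(phenotypes) != nrow(values))
    stop("phenotypes must have one row per cell")
  if (is.null(schema)) {
    schema <- lapply(phenotypes, function(col) sort(unique(as.character(col))))
  }
  obj <- structure(
    list(values = values, gene_ids = as.character(gene_ids),
         cell_ids = as.character(cell_ids), phenotypes = phenotypes,
         schema = schema),
    class = "expression_matrix")
  validate_expression_matrix(obj)
  obj
}

#' Validate an expression_matrix
#'
#' Checks the container invariants: non-negative finite values, unique gene
#' ids, one metadata row per cell, and every phenotype value belonging to its
#' field's declared category set. Offending indices are named in the error.
#'
#' @param x an `expression_matrix`.
#' @return `x`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_expression_matrix <- function(x) {
  v <- x$values
  bad <- if (inherits(v, "sparseMatrix")) {
    vv <- v@x
    which(is.na(vv) | vv < 0)
  } else {
    which(is.na(v) | v < 0)
  }
  if (length(bad) > 0)
    stop("validation error: NaN or negative expression values at indices ",
         paste(utils::head(bad, 5L), collapse = ", "))
  for (f in names(x$schema)) {
    if (!f %in% names(x$phenotypes))
      stop("schema field '", f, "' missing from phenotype table")
    vals <- as.character(x$phenotypes[[f]])
    unknown <- setdiff(unique(vals), x$schema[[f]])
    if (length(unknown) > 0)
      stop("phenotype field '", f, "' has values outside its declared ",
           "categories: ", paste(unknown, collapse = ", "))
  }
  invisible(x)
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d cells x %d genes\n",
              nrow(x$values), ncol(x$values)))
  cat("phenotype fields:",
      paste(sprintf("%s(%d)", names(x$schema), lengths(x$schema)),
            collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Subset cells of an expression matrix
#'
#' @param x an `expression_matrix`.
#' @param cells integer or logical index over cells.
#' @return an `expression_matrix` restricted to the selected cells.
#' @export
subset_cells <- function(x, cells) {
  expression_matrix(x$values[cells, , drop = FALSE], x$gene_ids,
                    x$cell_ids[cells],
                    x$phenotypes[cells, , drop = FALSE], x$schema)
}

#' Write an expression matrix as a Matrix Market bundle
#'
#' Writes `matrix.mtx` (cells x genes, MatrixMarket), `genes.tsv`,
#' `barcodes.tsv`, `metadata.tsv` (tab-separated, header row, one row per
#' cell) and `schema.json` into `dir`.
#'
#' @param x an `expression_matrix`.
#' @param dir output directory, created if missing.
#' @return `dir`, invisibly.
#' @export
write_mtx_bundle <- function(x, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  m <- methods::as(methods::as(Matrix::Matrix(x$values, sparse = TRUE),
                               "generalMatrix"), "CsparseMatrix")
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(x$gene_ids, file.path(dir, "genes.tsv"))
  writeLines(x$cell_ids, file.path(dir, "barcodes.tsv"))
  utils::write.table(x$phenotypes, file.path(dir, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(x$schema, file.path(dir, "schema.json"))
  invisible(dir)
}

#' Read an expression matrix from a Matrix Market bundle
#'
#' Expects the layout written by [write_mtx_bundle()]: `matrix.mtx` with
#' cells as rows, `genes.tsv`/`barcodes.tsv` (one id per line) and
#' `metadata.tsv` with a header row. `schema.json` is optional; when absent
#' the schema is inferred from the observed metadata levels.
#'
#' @param dir directory containing the bundle.
#' @return an `expression_matrix`.
#' @export
read_mtx_bundle <- function(dir) {
  m <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  genes <- readLines(file.path(dir, "genes.tsv"))
  cells <- readLines(file.path(dir, "barcodes.tsv"))
  meta <- utils::read.table(file.path(dir, "metadata.tsv"), sep = "\t",
                            header = TRUE, stringsAsFactors = FALSE,
                            check.names = FALSE)
  schema_path <- file.path(dir, "schema.json")
  schema <- if (file.exists(schema_path)) {
    lapply(jsonlite::read_json(schema_path), function(f)
      vapply(f, as.character, character(1)))
  } else NULL
  expression_matrix(methods::as(m, "CsparseMatrix"), genes, cells, meta,
                    schema)
}
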