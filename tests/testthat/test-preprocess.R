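make_em <- function(values, ids = NULL) {
  n <- nrow(values); m <- ncol(values)
  if (is.null(ids)) ids <- sprintf("g%02d", seq_len(m))
  expression_matrix(values, ids, paste0("c", seq_len(n)),
                    data.frame(grp = rep("a", n)),
                    schema = list(grp = "a"))
}

test_that("normalization chain: library scaling, log1p, dispersion division", {
  # single gene, two cells: both cells scale to the target total, so both
  # normalized values equal log1p(target); dispersion across cells is 0 and
  # the column is left unscaled
  em <- make_em(matrix(c(2, 8), 2, 1))
  out <- normalize_expression(em, target_total = 10)
  expect_equal(as.vector(out$values), rep(log(11), 2), tolerance = 1e-12)

  # an all-zero gene stays all-zero, zeros are preserved, shape kept
  set.seed(4)
  v <- matrix(rpois(50 * 20, 2), 50, 20)
  v[, 7] <- 0
  em <- make_em(v)
  out <- normalize_expression(em)
  expect_equal(dim(out$values), dim(v))
  expect_true(all(out$values[, 7] == 0))
  expect_identical(out$values == 0, v == 0)
  expect_true(all(is.finite(out$values)) && all(out$values >= 0))
})

test_that("normalization rejects invalid input", {
  expect_error(expression_matrix(matrix(numeric(0), 0, 0), character(0),
                                 character(0), data.frame()),
               "at least one cell")
  em <- make_em(matrix(1:4, 2, 2))
  em$values[2, 1] <- -3
  expect_error(validate_expression_matrix(em), "negative")
})

test_that("HVG ranking orders by variability with lexicographic ties", {
  # constant gene ranks after a varying gene
  v <- cbind(A = rep(5, 20), B = c(rep(0, 10), rep(9, 10)))
  em <- make_em(v, ids = c("A", "B"))
  rk <- rank_hvg(em, 2)
  expect_identical(rk$ordered_genes[1], "B")
  expect_identical(rk$retained, rk$ordered_genes)  # T = N keeps everything

  # bit-identical columns tie-break lexicographically, checked against a
  # brute-force sort oracle
  set.seed(2)
  col <- rpois(30, 3)
  v <- cbind(zz = col, aa = col, mm = rpois(30, 5))
  em <- make_em(v, ids = colnames(v))
  rk <- rank_hvg(em, 3)
  mu <- colMeans(v); sc <- apply(v, 2, var) / mu
  oracle <- colnames(v)[order(-sc, colnames(v))]
  expect_identical(rk$ordered_genes, oracle)
  pos <- match(c("aa", "zz"), rk$ordered_genes)
  expect_true(pos[1] < pos[2])

  # permutation property: retained + dropped = all genes, no duplicates
  prep <- small_prep()
  rk <- prep$ranking
  expect_setequal(rk$ordered_genes, small_atlas()$matrix$gene_ids)
  expect_false(anyDuplicated(rk$ordered_genes) > 0)
  expect_true(all(diff(rk$variability_score) <= 1e-12))

  expect_error(rank_hvg(em, 0), "parameter error")
  expect_error(rank_hvg(em, 4), "parameter error")
})

test_that("planted program markers rank at the top of the HVG list", {
  atl <- small_atlas()
  norm <- normalize_expression(atl$matrix)
  rk <- rank_hvg(norm, 32)
  planted <- c(unlist(atl$truth$markers), atl$truth$poly_gene,
               atl$truth$mono_gene)
  expect_gt(mean(rk$retained %in% planted), 0.7)
  expect_true(all(head(rk$ordered_genes, 5) %in% planted))
})

test_that("threshold detection finds the histogram dip, else defaults", {
  set.seed(9)
  vals <- c(runif(5000, 0.01, 0.09), runif(5000, 0.25, 0.60))
  v <- matrix(vals, 100, 100)
  em <- make_em(v)
  thr <- detect_threshold(em)
  expect_gt(thr, 0.09)
  expect_lt(thr, 0.25)

  # no dip: uniform positive values
  em2 <- make_em(matrix(runif(1000, 0.01, 1), 50, 20))
  expect_equal(detect_threshold(em2), 0.1)

  # degenerate: all-zero matrix falls back with a warning
  em3 <- make_em(matrix(0, 5, 4))
  expect_warning(thr3 <- detect_threshold(em3), "default")
  expect_equal(thr3, 0.1)
})

test_that("binning respects the threshold demarcation and edges", {
  spec <- binning_spec(B = 10L, threshold = 0.1, global_max = 1.1)
  expect_equal(bin_expression(0.09, spec)[1], NON_EXPRESSED)
  expect_gte(bin_expression(0.11, spec)[1], 0L)
  expect_equal(bin_expression(0.1, spec)[1], 0L)
  expect_equal(bin_expression(1.1, spec)[1], 9L)  # top edge inclusive
  # out-of-range values clamp into the top bin and are counted
  out <- bin_expression(c(0.5, 2.0), spec)
  expect_equal(out[2], 9L)
  expect_equal(attr(out, "clamped"), 1L)
  # equal widths
  expect_equal(diff(spec$bin_edges), rep(0.1, 10), tolerance = 1e-9)
})

test_that("binning is monotone in the value", {
  spec <- binning_spec(B = 8L, threshold = 0.1, global_max = 3)
  set.seed(11)
  v <- sort(runif(1000, 0, 3.2))
  b <- bin_expression(v, spec)
  b[b == NON_EXPRESSED] <- -1L  # below bin 0
  expect_true(all(diff(b) >= 0))
  # agreement with a brute-force edge search
  brute <- vapply(v, function(x) {
    if (x < spec$threshold) return(-1L)
    if (x > spec$bin_edges[9]) return(7L)
    max(0L, min(7L, sum(x >= spec$bin_edges[-1]) -
                  as.integer(x == spec$bin_edges[9]) * 0L))
  }, integer(1))
  # oracle: index of the last edge not exceeding the value
  brute2 <- vapply(v, function(x) {
    if (x < spec$threshold) return(-1L)
    i <- findInterval(x, spec$bin_edges, rightmost.closed = TRUE) - 1L
    min(i, 7L)
  }, integer(1))
  expect_equal(b, brute2, ignore_attr = TRUE)
})

test_that("mtx bundle round-trips an expression matrix", {
  atl <- small_atlas()
  dir <- withr::local_tempdir()
  write_mtx_bundle(atl$matrix, dir)
  back <- read_mtx_bundle(dir)
  expect_equal(as.matrix(back$values), as.matrix(atl$matrix$values),
               ignore_attr = TRUE)
  expect_identical(back$gene_ids, atl$matrix$gene_ids)
  expect_identical(back$phenotypes$tissue, atl$matrix$phenotypes$tissue)
  expect_identical(back$schema, atl$matrix$schema)
})
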