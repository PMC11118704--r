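#' Normalize expression values for binning
#'
#' Per-cell library-size scaling to a fixed total, log1p transform, then a
#' per-gene dispersion scaling: each gene column is divided by its dispersion
#' (variance / mean across cells, computed on the log1p values) so that
#' expression magnitudes are comparable across genes before thresholding and
#' binning. Genes with zero dispersion (constant or all-zero columns) are
#' left unscaled; zeros are fixed points of the whole chain.
#'
#' @param raw an `expression_matrix` of non-negative counts or intensities.
#' @param target_total library-size target per cell (default 10000).
#' @return an `expression_matrix` of normalized values (dense), same shape,
#'   all finite and non-negative.
#' @export
normalize_expression <- function(raw, target_total = 1e4) {
  stopifnot(inherits(raw, "expression_matrix"))
  validate_expression_matrix(raw)
  v <- as.matrix(raw$values)
  lib <- rowSums(v)
  scale <- ifelse(lib > 0, target_total / lib, 0)
  v <- log1p(v * scale)
  mu <- colMeans(v)
  vv <- colVars(v)
  disp <- ifelse(mu > 0, vv / mu, 0)
  keep <- disp > 0
  if (any(keep)) v[, keep] <- sweep(v[, keep, drop = FALSE], 2L,
                                    disp[keep], "/")
  out <- raw
  out$values <- v
  # dispersion of the log-scaled values, before the per-gene scaling: the
  # scaling equalizes variance/mean across genes by construction, so this
  # pre-scaling dispersion is the gene-variability signal HVG ranking needs
  attr(out, "gene_dispersion") <- stats::setNames(disp, raw$gene_ids)
  attr(out, "gene_log_mean") <- stats::setNames(mu, raw$gene_ids)
  out
}

# z-score of dispersion within quantile bins of mean expression; degenerate
# bins (single gene, zero spread) fall back to a centered score
binned_dispersion_z <- function(disp, mu, n_bins) {
  n_bins <- max(1L, min(n_bins, max(1L, floor(length(mu) / 5))))
  br <- unique(stats::quantile(mu, probs = seq(0, 1, length.out = n_bins + 1L)))
  bin <- if (length(br) > 2L)
    cut(mu, breaks = br, include.lowest = TRUE, labels = FALSE)
  else rep(1L, length(mu))
  z <- numeric(length(disp))
  for (b in unique(bin)) {
    i <- bin == b
    m <- mean(disp[i]); s <- stats::sd(disp[i])
    z[i] <- if (is.na(s) || s == 0) disp[i] - m else (disp[i] - m) / s
  }
  z
}

# column variances with the usual n-1 denominator, without forming copies
colVars <- function(m) {
  n <- nrow(m)
  if (n < 2L) return(numeric(ncol(m)))
  mu <- colMeans(m)
  (colSums(m * m) - n * mu^2) / (n - 1)
}

#' Rank genes by normalized dispersion
#'
#' Scores every gene by its normalized dispersion (variance / mean across
#' cells of the library-scaled log1p values; genes with zero mean score 0)
#' and orders genes by decreasing score, breaking ties lexicographically by
#' gene id. The first `T` genes are flagged as the retained highly variable
#' genes (HVGs) that fix the gene-slot layout of the token sequence.
#'
#' The normalization step is undone before scoring: the dispersion scaling
#' equalizes variance/mean across genes by construction (dividing a gene by
#' `c` divides its variance/mean by `c`, and `c` *is* its variance/mean), so
#' the ratio must be taken on the pre-scaling log values, which
#' [normalize_expression()] records. The raw dispersion is then normalized
#' within quantile bins of mean expression (z-score of dispersion among
#' genes of similar mean), the usual correction for the strong
#' mean-dispersion relationship of log-transformed sparse counts; without it
#' the ranking is dominated by lowly expressed, mostly-zero genes.
#'
#' @param matrix a normalized `expression_matrix` (see
#'   [normalize_expression()]).
#' @param T number of genes to retain, `1 <= T <=` number of genes.
#' @param n_mean_bins number of mean-expression quantile bins for dispersion
#'   normalization (default 20).
#' @return a `gene_ranking`: list with `ordered_genes`, `variability_score`
#'   (aligned with `ordered_genes`, non-increasing), `T`, and `retained`
#'   (the first `T` ordered gene ids).
#' @export
rank_hvg <- function(matrix, T, n_mean_bins = 20L) {
  stopifnot(inherits(matrix, "expression_matrix"))
  n_genes <- ncol(matrix$values)
  if (length(T) != 1L || is.na(T) || T <= 0 || T > n_genes)
    stop("parameter error: T must satisfy 1 <= T <= ", n_genes)
  disp <- attr(matrix, "gene_dispersion")
  mu <- attr(matrix, "gene_log_mean")
  if (is.null(disp) || is.null(mu)) {
    v <- as.matrix(matrix$values)
    mu <- colMeans(v)
    disp <- ifelse(mu > 0, colVars(v) / mu, 0)
  } else {
    disp <- unname(disp[matrix$gene_ids])
    mu <- unname(mu[matrix$gene_ids])
  }
  score <- binned_dispersion_z(disp, mu, n_mean_bins)
  ord <- order(-score, matrix$gene_ids, method = "radix")
  structure(
    list(ordered_genes = matrix$gene_ids[ord],
         variability_score = score[ord],
         T = as.integer(T),
         retained = matrix$gene_ids[ord][seq_len(T)]),
    class = "gene_ranking")
}

#' @export
print.gene_ranking <- function(x, ...) {
  cat(sprintf("gene_ranking: %d genes scored, top %d retained\n",
              length(x$ordered_genes), x$T))
  invisible(x)
}

#' Detect the expressed/non-expressed threshold from the value distribution
#'
#' Estimates the density of the positive normalized expression values and
#' returns the location of the first interior local minimum that is a real
#' valley — flanked on both sides by density at least `min_rise` times the
#' valley density — the dip that separates the low-value mass of effectively
#' unexpressed genes from the bump of expressed ones. When no such valley
#' exists (unimodal or flat distributions) the conventional default of 0.1
#' is returned.
#'
#' @param matrix a normalized `expression_matrix`.
#' @param n_hist_bins density grid resolution (default 256).
#' @param default fallback threshold (default 0.1).
#' @param min_rise required ratio of the flanking density peaks to the
#'   valley density (default 1.2); guards against noise dips.
#' @return a single numeric threshold in normalized-expression units.
#' @export
detect_threshold <- function(matrix, n_hist_bins = 256L, default = 0.1,
                             min_rise = 1.2) {
  stopifnot(inherits(matrix, "expression_matrix"))
  v <- as.matrix(matrix$values)
  pos <- v[v > 0]
  if (length(pos) == 0L) {
    warning("no positive expression values; returning default threshold ",
            default)
    return(default)
  }
  den <- stats::density(pos, n = n_hist_bins, from = 0, to = max(pos))
  y <- den$y
  n <- length(y)
  if (n >= 3L) {
    for (i in 2:(n - 1L)) {
      if (y[i] < y[i - 1L] && y[i] <= y[i + 1L]) {
        left_peak <- max(y[1:(i - 1L)])
        right_peak <- max(y[(i + 1L):n])
        if (left_peak >= min_rise * y[i] && right_peak >= min_rise * y[i])
          return(den$x[i])
      }
    }
  }
  default
}

#' Build an equal-width binning specification
#'
#' Splits the normalized expression range above `threshold` into `B`
#' equal-width bins spanning `[threshold, global_max]`. Values below the
#' threshold are treated as non-expressed. The global range (rather than a
#' per-gene range) makes bin tokens comparable across genes, which a tied
#' input/output embedding requires. When the upper edge is derived from a
#' matrix it is taken as the `cap_quantile` quantile of the above-threshold
#' values rather than the absolute maximum: equal-width bins over a
#' long-tailed distribution otherwise collapse almost all values into the
#' lowest bin, and the few values beyond the edge are clamped into the top
#' bin anyway.
#'
#' @param matrix a normalized `expression_matrix` (the training split), used
#'   to fix `global_max`. Alternatively pass `global_max` directly.
#' @param B number of bins (default 10).
#' @param threshold expressed/non-expressed demarcation (default 0.1).
#' @param global_max optional explicit upper edge (absolute; disables the
#'   quantile cap).
#' @param cap_quantile quantile of above-threshold values used as the upper
#'   edge when derived from `matrix` (default 0.999).
#' @return a `binning_spec`: list with `threshold`, `B`, `bin_edges`
#'   (length `B + 1`, first edge equal to `threshold`).
#' @export
binning_spec <- function(matrix = NULL, B = 10L, threshold = 0.1,
                         global_max = NULL, cap_quantile = 0.999) {
  if (B < 1L) stop("parameter error: B must be >= 1")
  if (is.null(global_max)) {
    stopifnot(inherits(matrix, "expression_matrix"))
    v <- as.matrix(matrix$values)
    expressed <- v[v >= threshold]
    global_max <- if (length(expressed) == 0L) threshold + 1
      else as.numeric(stats::quantile(expressed, cap_quantile))
  }
  if (global_max <= threshold) global_max <- threshold + 1
  edges <- seq(threshold, global_max, length.out = B + 1L)
  structure(list(threshold = threshold, B = as.integer(B),
                 bin_edges = edges),
            class = "binning_spec")
}

#' Marker for non-expressed values
#'
#' Bin index returned by [bin_expression()] for values below the
#' expressed/non-expressed threshold; downstream tokenization maps it to the
#' PAD token so the position is excluded from attention and loss.
#' @export
NON_EXPRESSED <- -1L

#' Bin normalized expression values
#'
#' Maps each value to `NON_EXPRESSED` when it lies below the threshold and
#' otherwise to an equal-width bin index in `0..B-1` (higher expression,
#' higher bin; the top bin is right-inclusive). Values beyond the top edge —
#' possible when the spec was built on a different split — are clamped to
#' bin `B - 1` and counted in the `"clamped"` attribute.
#'
#' @param values numeric vector (or matrix) of normalized expression values.
#' @param spec a `binning_spec`.
#' @return integer vector/matrix of bin indices, `NON_EXPRESSED` (= -1L)
#'   below threshold, with attribute `clamped` giving the number of values
#'   clamped into the top bin from above.
#' @export
bin_expression <- function(values, spec) {
  stopifnot(inherits(spec, "binning_spec"))
  if (any(!is.finite(values))) stop("values must be finite")
  edges <- spec$bin_edges
  B <- spec$B
  width <- (edges[B + 1L] - edges[1L]) / B
  idx <- as.integer(floor((values - edges[1L]) / width))
  idx[idx > B - 1L & values <= edges[B + 1L]] <- B - 1L  # top edge inclusive
  n_clamp <- sum(values > edges[B + 1L])
  if (n_clamp > 0) idx[values > edges[B + 1L]] <- B - 1L
  idx[values < spec$threshold] <- NON_EXPRESSED
  if (!is.null(dim(values))) dim(idx) <- dim(values)
  attr(idx, "clamped") <- n_clamp
  idx
}
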