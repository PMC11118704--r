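#' Build a similarity-threshold gene network
#'
#' Connects two genes whenever the cosine similarity of their context
#' embeddings exceeds a threshold. The threshold is either given absolutely
#' (`tau`) or as a quantile of all pairwise similarities (default the 0.95
#' quantile), the latter keeping edge density comparable across contexts.
#'
#' @param emb genes x h matrix of context embeddings for one context, with
#'   gene ids as row names, or a `context_embeddings` object whose rows are
#'   genes.
#' @param tau absolute similarity threshold; overrides `tau_quantile`.
#' @param tau_quantile quantile of the off-diagonal pairwise similarities
#'   used as the threshold (default 0.95), in (0, 1).
#' @return a `gene_network`: list with `graph` (igraph, undirected, no self
#'   loops), `nodes`, `tau` (resolved threshold), `degree` (named degree
#'   sequence), `similarity` (the full similarity matrix).
#' @export
build_gene_network <- function(emb, tau = NULL, tau_quantile = 0.95) {
  if (inherits(emb, "context_embeddings")) emb <- emb$vectors
  if (nrow(emb) < 2L) stop("need >= 2 genes")
  if (is.null(rownames(emb))) rownames(emb) <- paste0("g", seq_len(nrow(emb)))
  sims <- cosine_matrix(emb)
  off <- sims[upper.tri(sims)]
  if (is.null(tau)) {
    if (tau_quantile <= 0 || tau_quantile >= 1)
      stop("parameter error: tau_quantile must lie in (0, 1)")
    tau <- as.numeric(stats::quantile(off, tau_quantile))
  }
  adj <- sims > tau
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  structure(list(graph = g, nodes = rownames(emb), tau = tau,
                 degree = igraph::degree(g), similarity = sims),
            class = "gene_network")
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf("gene_network: %d nodes, %d edges (tau = %.4f)\n",
              length(x$nodes), igraph::ecount(x$graph), x$tau))
  invisible(x)
}

# Hurwitz zeta by direct summation plus an Euler-Maclaurin tail
hurwitz_zeta <- function(alpha, q, K = 1000L) {
  k <- 0:(K - 1L)
  head <- sum((q + k)^(-alpha))
  b <- q + K
  head + b^(1 - alpha) / (alpha - 1) + 0.5 * b^(-alpha) +
    alpha * b^(-alpha - 1) / 12
}

#' Fit a discrete power law to a degree sequence
#'
#' Clauset-style fit: for each candidate lower cutoff `xmin`, the exponent
#' `alpha` is the discrete maximum-likelihood estimate (zeta-function
#' likelihood), and the reported fit is the one minimizing the
#' Kolmogorov-Smirnov distance between the empirical tail and the fitted
#' distribution. A log-log regression slope of the degree histogram is also
#' reported for comparison with slope-based readings of scale-free behavior.
#'
#' @param degrees vector of positive integer degrees (zeros are dropped).
#' @param xmin optional fixed lower cutoff; when `NULL` it is selected by
#'   KS minimization over the observed degree values.
#' @param xmin_max largest candidate cutoff considered (default the 0.9
#'   quantile of the degrees, so the tail keeps enough mass).
#' @return a `power_law_fit`: list with `alpha` (> 1), `xmin`,
#'   `ks_distance`, `n_tail`, `loglog_slope`.
#' @export
fit_power_law <- function(degrees, xmin = NULL, xmin_max = NULL) {
  x <- degrees[degrees > 0]
  if (length(x) == 0L) stop("no positive degrees")
  if (length(unique(x)) == 1L)
    stop("degenerate fit: all degrees equal")
  if (length(x) < 50L)
    warning("fewer than 50 nonzero degrees; power-law fit is unstable")
  x <- as.integer(round(x))
  candidates <- if (!is.null(xmin)) as.integer(xmin) else {
    cand <- sort(unique(x))
    cap <- if (is.null(xmin_max)) stats::quantile(x, 0.9) else xmin_max
    cand <- cand[cand <= cap]
    if (length(cand) == 0L) cand <- min(x)
    cand
  }
  best <- NULL
  for (xm in candidates) {
    tail_x <- x[x >= xm]
    n <- length(tail_x)
    if (n < 2L || length(unique(tail_x)) < 2L) next
    slx <- sum(log(tail_x))
    nll <- function(a) n * log(hurwitz_zeta(a, xm)) + a * slx
    opt <- stats::optimize(nll, c(1.01, 8))
    a <- opt$minimum
    # KS distance between empirical and fitted tail CDFs
    ux <- sort(unique(tail_x))
    Z <- hurwitz_zeta(a, xm)
    pmf <- (ux^(-a)) / Z
    cdf_fit <- cumsum(pmf)
    ecdf_v <- cumsum(tabulate(factor(tail_x, levels = ux))) / n
    ks <- max(abs(ecdf_v - cdf_fit))
    if (is.null(best) || ks < best$ks_distance)
      best <- list(alpha = a, xmin = xm, ks_distance = ks, n_tail = n)
  }
  if (is.null(best)) stop("degenerate fit: no viable xmin candidate")
  # log-log regression slope on the degree histogram (descriptive only)
  tb <- table(x)
  deg <- as.numeric(names(tb))
  cnt <- as.numeric(tb)
  best$loglog_slope <- if (length(deg) >= 3L)
    unname(stats::coef(stats::lm(log(cnt) ~ log(deg)))[2L]) else NA_real_
  structure(best, class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf(
    "power_law_fit: alpha = %.3f, xmin = %d, KS = %.4f, n_tail = %d\n",
    x$alpha, x$xmin, x$ks_distance, x$n_tail))
  invisible(x)
}

#' Draw from a discrete power law
#'
#' Exact inverse-CDF sampling of `P(X = x) proportional to x^-alpha` for
#' `x >= xmin`, truncated at `xmax` (the truncated tail mass is negligible
#' for the defaults).
#'
#' @param n sample size.
#' @param alpha exponent (> 1).
#' @param xmin lower cutoff (default 1).
#' @param xmax truncation point (default 1e6).
#' @return integer vector of length `n`.
#' @export
rpowerlaw <- function(n, alpha, xmin = 1L, xmax = 1e6) {
  support <- xmin:xmax
  cdf <- cumsum(support^(-alpha))
  cdf <- cdf / cdf[length(cdf)]
  support[findInterval(stats::runif(n), cdf) + 1L]
}

#' Average-linkage gene dendrogram on cosine distance
#'
#' Agglomerative clustering of gene context embeddings under the distance
#' `1 - cosine similarity`, serialized in Newick format with gene ids as
#' leaves.
#'
#' @param emb genes x h matrix (gene ids as row names) or a
#'   `context_embeddings` object.
#' @return list with `hclust` (the average-linkage tree), `newick`
#'   (character string), `phylo` (the `ape` tree).
#' @export
gene_dendrogram <- function(emb) {
  if (inherits(emb, "context_embeddings")) emb <- emb$vectors
  if (nrow(emb) < 2L) stop("need >= 2 genes")
  if (is.null(rownames(emb))) rownames(emb) <- paste0("g", seq_len(nrow(emb)))
  d <- stats::as.dist(1 - cosine_matrix(emb))
  hc <- stats::hclust(d, method = "average")
  ph <- ape::as.phylo(hc)
  list(hclust = hc, newick = ape::write.tree(ph), phylo = ph)
}

#' Compare two gene networks
#'
#' Fits the degree power law of each network, computes per-gene degree
#' changes on the shared node set, and ranks genes by absolute degree
#' change — the comparison used to contrast, e.g., young versus old
#' endothelial-cell networks, where added low-degree connectivity flattens
#' the power-law slope.
#'
#' @param netA,netB `gene_network` objects with overlapping node sets.
#' @param fit_powerlaw logical; skip the (slower) power-law fits when FALSE.
#' @return list with `alpha_A`, `alpha_B`, `alpha_delta` (B - A), `fits`,
#'   `degree_delta` (data.frame: gene, degree_A, degree_B, delta, sorted by
#'   `abs(delta)` descending), `shared_nodes`.
#' @export
compare_networks <- function(netA, netB, fit_powerlaw = TRUE) {
  stopifnot(inherits(netA, "gene_network"), inherits(netB, "gene_network"))
  shared <- intersect(netA$nodes, netB$nodes)
  if (length(shared) == 0L)
    stop("comparison error: disjoint node sets")
  dA <- netA$degree[shared]
  dB <- netB$degree[shared]
  delta <- dB - dA
  ord <- order(-abs(delta), shared)
  dd <- data.frame(gene = shared[ord], degree_A = as.integer(dA[ord]),
                   degree_B = as.integer(dB[ord]),
                   delta = as.integer(delta[ord]),
                   stringsAsFactors = FALSE)
  fits <- NULL
  aA <- aB <- NA_real_
  if (fit_powerlaw) {
    fits <- list(A = tryCatch(fit_power_law(netA$degree),
                              error = function(e) NULL),
                 B = tryCatch(fit_power_law(netB$degree),
                              error = function(e) NULL))
    if (!is.null(fits$A)) aA <- fits$A$alpha
    if (!is.null(fits$B)) aB <- fits$B$alpha
  }
  list(alpha_A = aA, alpha_B = aB, alpha_delta = aB - aA, fits = fits,
       degree_delta = dd, shared_nodes = shared)
}
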