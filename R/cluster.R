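#' Principal component analysis of scaled expression
#'
#' PCA of the cells on the scaled (residual z-score) matrix. The sign of
#' each component is fixed by making the largest-magnitude loading entry
#' positive, so outputs are comparable across runs.
#'
#' @param scaled genes x cells scaled matrix (see
#'   \code{\link{scale_and_regress}}).
#' @param n_components number of components to keep; values above the matrix
#'   rank are truncated with a warning.
#' @return object of class \code{pc_space}: \code{scores} (cells x PCs),
#'   \code{loadings} (genes x PCs), \code{sdev}.
#' @export
run_pca <- function(scaled, n_components = 50) {
  x <- t(as.matrix(scaled))                       # cells x genes
  rank_max <- min(nrow(x) - 1L, ncol(x))
  if (n_components > rank_max) {
    warning("n_components truncated to the matrix rank (", rank_max, ")")
    n_components <- rank_max
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = n_components)
  flip <- apply(pc$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  scores <- sweep(pc$x, 2, flip, `*`)
  loadings <- sweep(pc$rotation, 2, flip, `*`)
  structure(list(scores = scores, loadings = loadings,
                 sdev = pc$sdev[seq_len(n_components)]),
            class = "pc_space")
}

#' @exportS3Method print pc_space
print.pc_space <- function(x, ...) {
  cat(sprintf("pc_space: %d cells x %d PCs (sdev %.3g .. %.3g)\n",
              nrow(x$scores), ncol(x$scores), x$sdev[1],
              x$sdev[length(x$sdev)]))
  invisible(x)
}

#' Elbow heuristic for choosing the number of PCs
#'
#' Picks the component just before the largest drop of the standard
#' deviation profile (the maximal first difference); a flat scree returns
#' the configured default with a warning.
#'
#' @param sds standard deviations per component (decreasing).
#' @param default fallback when no clear elbow exists (default 8).
#' @param flat_tol relative drop below which a scree counts as flat.
#' @return integer number of PCs to keep.
#' @export
choose_pcs_elbow <- function(sds, default = 8, flat_tol = 0.02) {
  if (length(sds) < 3) return(length(sds))
  drops <- -diff(sds)
  if (max(drops) < flat_tol * sds[1]) {
    warning("scree is flat; returning the default of ", default, " PCs")
    return(min(default, length(sds)))
  }
  which.max(drops)
}

#' JackStraw-style significance of principal components
#'
#' For each permutation round, a small fraction of genes has its cells
#' shuffled; PCA is re-run and the shuffled genes' loadings form the null
#' distribution of gene-PC association. Each PC's p-value compares the
#' observed loading magnitudes with that null (two-sample KS test).
#'
#' @param scaled genes x cells scaled matrix.
#' @param n_pcs number of PCs to score.
#' @param n_perm number of permutation rounds (>= 20).
#' @param perm_fraction fraction of genes shuffled per round (default 0.01).
#' @param seed RNG seed.
#' @return data.frame with \code{pc} and \code{p_value}.
#' @export
jackstraw <- function(scaled, n_pcs = 8, n_perm = 100, perm_fraction = 0.01,
                      seed = 1) {
  if (n_perm < 20) stop("n_perm must be >= 20")
  set.seed(seed)
  x <- as.matrix(scaled)
  n_genes <- nrow(x)
  n_fake <- max(1L, round(perm_fraction * n_genes))
  obs <- abs(run_pca(x, n_components = n_pcs)$loadings)
  null <- matrix(NA_real_, n_fake * n_perm, n_pcs)
  for (p in seq_len(n_perm)) {
    idx <- sample.int(n_genes, n_fake)
    xp <- x
    for (g in idx) xp[g, ] <- sample(xp[g, ])
    lp <- abs(run_pca(xp, n_components = n_pcs)$loadings)
    null[(p - 1) * n_fake + seq_len(n_fake), ] <- lp[idx, , drop = FALSE]
  }
  pv <- vapply(seq_len(n_pcs), function(k)
    suppressWarnings(stats::ks.test(obs[, k], null[, k])$p.value), numeric(1))
  data.frame(pc = seq_len(n_pcs), p_value = pv)
}

#' Exact Euclidean k-nearest-neighbor graph in PC space
#'
#' Self is excluded; distance ties are broken by cell index. Shared-
#' nearest-neighbor (Jaccard) weights over the k-neighborhoods (self
#' included, as is conventional for SNN graphs) are attached for
#' community detection.
#'
#' @param pcs a \code{pc_space} or a cells x dims score matrix.
#' @param k number of neighbors (default 20; must be < number of cells).
#' @return object of class \code{knn_graph}: \code{idx} (cells x k neighbor
#'   indices), \code{dist}, \code{snn} (sparse Jaccard weight matrix),
#'   \code{k}, \code{cells}.
#' @export
build_knn_graph <- function(pcs, k = 20) {
  x <- if (inherits(pcs, "pc_space")) pcs$scores else as.matrix(pcs)
  n <- nrow(x)
  if (k >= n) stop("k must be smaller than the number of cells")
  d <- as.matrix(stats::dist(x))
  idx <- matrix(0L, n, k)
  ndist <- matrix(0, n, k)
  for (i in seq_len(n)) {
    ord <- order(d[i, ], seq_len(n))       # ties broken by cell index
    ord <- ord[ord != i][seq_len(k)]
    idx[i, ] <- ord
    ndist[i, ] <- d[i, ord]
  }
  ## SNN: Jaccard overlap of the (self-inclusive) neighbor sets
  adj <- Matrix::sparseMatrix(i = rep(seq_len(n), each = k + 1),
                              j = as.vector(t(cbind(seq_len(n), idx))),
                              x = 1, dims = c(n, n))
  ov <- Matrix::tcrossprod(adj)
  snn <- ov
  snn@x <- snn@x / (2 * (k + 1) - snn@x)
  snn <- Matrix::drop0(snn)
  structure(list(idx = idx, dist = ndist, snn = as_sparse(snn), k = k,
                 cells = rownames(x)),
            class = "knn_graph")
}

#' @exportS3Method print knn_graph
print.knn_graph <- function(x, ...) {
  cat(sprintf("knn_graph: %d cells, k = %d\n", nrow(x$idx), x$k))
  invisible(x)
}

#' Graph community clustering at a given resolution
#'
#' Louvain modularity optimization on the shared-nearest-neighbor weights
#' with a resolution parameter; a fixed seed makes labels reproducible.
#'
#' @param graph a \code{\link{build_knn_graph}} result.
#' @param resolution modularity resolution (the study uses 0.1/0.2/0.3 for
#'   subset-level clustering and 2.5 for trajectory sub-clustering).
#' @param seed RNG seed (Louvain visits nodes in random order).
#' @return integer vector of cluster labels (1-based), named by cell.
#' @export
cluster_graph <- function(graph, resolution = 0.2, seed = 1) {
  g <- igraph::graph_from_adjacency_matrix(graph$snn, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  set.seed(seed)
  cl <- igraph::cluster_louvain(g, resolution = resolution)
  labels <- as.integer(igraph::membership(cl))
  sizes <- table(labels)
  if (any(sizes == 1))
    message(sum(sizes == 1), " singleton cluster(s) at resolution ", resolution)
  names(labels) <- graph$cells
  labels
}

#' Two-dimensional embedding of the PC scores
#'
#' t-SNE (via Rtsne, exact, no internal PCA) or the first two PCs. The seed
#' is mandatory for t-SNE so layouts are reproducible; a perplexity of at
#' least n/3 is clamped with a warning.
#'
#' @param pcs a \code{pc_space} or score matrix.
#' @param method \code{"tsne"} or \code{"pca"}.
#' @param seed RNG seed.
#' @param perplexity t-SNE perplexity (default 30).
#' @param ... further arguments to \code{Rtsne::Rtsne}.
#' @return cells x 2 coordinate matrix.
#' @export
run_embedding <- function(pcs, method = c("tsne", "pca"), seed = 1,
                          perplexity = 30, ...) {
  method <- match.arg(method)
  x <- if (inherits(pcs, "pc_space")) pcs$scores else as.matrix(pcs)
  if (method == "pca") {
    out <- x[, 1:2, drop = FALSE]
    colnames(out) <- c("dim1", "dim2")
    return(out)
  }
  n <- nrow(x)
  if (perplexity >= n / 3) {
    perplexity <- max(1, floor((n - 1) / 3) - 1)
    warning("perplexity clamped to ", perplexity)
  }
  set.seed(seed)
  fit <- Rtsne::Rtsne(x, dims = 2, perplexity = perplexity, pca = FALSE,
                      check_duplicates = FALSE, ...)
  out <- fit$Y
  dimnames(out) <- list(rownames(x), c("dim1", "dim2"))
  out
}

## log-likelihood of the two-component zero-inflated ("bimod") model:
## point mass at zero with probability 1 - pi, Normal(mu, sd) for positives
bimod_ll <- function(x) {
  pos <- x[x > 0]
  n <- length(x)
  pi_hat <- length(pos) / n
  ll <- 0
  if (pi_hat < 1) ll <- ll + (n - length(pos)) * log(1 - pi_hat)
  if (length(pos) > 0) {
    mu <- mean(pos)
    s <- if (length(pos) > 1) stats::sd(pos) else 0
    s <- max(s, 0.1)  # floor keeps the likelihood finite for ties
    ll <- ll + length(pos) * log(pi_hat) +
      sum(stats::dnorm(pos, mu, s, log = TRUE))
  }
  ll
}

#' Marker detection between cell groups
#'
#' Per gene: the log fold change of group means on the natural-log
#' normalized scale (\code{log(mean(expm1(x)) + 1)} difference), the
#' expressed fractions, and a p-value from either the two-component
#' zero-inflated likelihood-ratio test (\code{"bimod"}; chi-square with 3
#' df) or the Wilcoxon rank-sum test. P-values are Bonferroni-adjusted by
#' default and rows are retained at \code{adjusted_p < p_adjust_max}.
#'
#' @param norm log-normalized genes x cells matrix.
#' @param labels per-cell group labels.
#' @param group group of interest (cluster label).
#' @param versus labels to compare against (default: all other cells).
#' @param test \code{"bimod"} (default) or \code{"ranksum"}.
#' @param logfc_min,min_pct pre-filters on log fold change and expressed
#'   fraction (defaults 0: test everything).
#' @param adjust multiple-testing correction (\code{"bonferroni"} default,
#'   \code{"BH"} selectable).
#' @param p_adjust_max retention threshold on the adjusted p-value
#'   (default 1e-2); use \code{Inf} to keep all rows.
#' @return data.frame: gene, cluster, log_fc, pct_in, pct_out, p_value,
#'   adjusted_p, ordered by p-value.
#' @export
find_markers <- function(norm, labels, group, versus = NULL,
                         test = c("bimod", "ranksum"),
                         logfc_min = 0, min_pct = 0,
                         adjust = c("bonferroni", "BH"),
                         p_adjust_max = 1e-2) {
  test <- match.arg(test)
  adjust <- match.arg(adjust)
  x <- as.matrix(norm)
  in_cells <- labels == group
  out_cells <- if (is.null(versus)) !in_cells else labels %in% versus
  if (sum(in_cells) < 2 || sum(out_cells) < 2)
    stop("each compared group needs at least 2 cells")
  x1 <- x[, in_cells, drop = FALSE]
  x2 <- x[, out_cells, drop = FALSE]
  m1 <- rowMeans(expm1(x1))
  m2 <- rowMeans(expm1(x2))
  log_fc <- log(m1 + 1) - log(m2 + 1)
  pct_in <- rowMeans(x1 > 0)
  pct_out <- rowMeans(x2 > 0)
  keep <- abs(log_fc) > logfc_min & pmax(pct_in, pct_out) > min_pct
  genes <- rownames(x)[keep]
  pv <- vapply(which(keep), function(g) {
    a <- x1[g, ]; b <- x2[g, ]
    if (test == "ranksum")
      return(suppressWarnings(stats::wilcox.test(a, b)$p.value))
    lrt <- 2 * (bimod_ll(a) + bimod_ll(b) - bimod_ll(c(a, b)))
    stats::pchisq(max(lrt, 0), df = 3, lower.tail = FALSE)
  }, numeric(1))
  adj <- stats::p.adjust(pv, method = adjust, n = nrow(x))
  res <- data.frame(gene = genes, cluster = group,
                    log_fc = log_fc[keep], pct_in = pct_in[keep],
                    pct_out = pct_out[keep], p_value = pv, adjusted_p = adj,
                    stringsAsFactors = FALSE)
  res <- res[res$adjusted_p < p_adjust_max, , drop = FALSE]
  res[order(res$p_value, res$gene), , drop = FALSE]
}

#' Retain clusters expressing a lineage-defining gene
#'
#' Keeps clusters in which the fraction of cells with detectable expression
#' of \code{gene} (normalized value > 0) reaches \code{min_fraction};
#' intended for restricting to Csf1r-expressing mononuclear phagocytes.
#'
#' @param norm log-normalized matrix.
#' @param labels per-cell cluster labels.
#' @param gene gene symbol (default \code{"Csf1r"}).
#' @param min_fraction minimum expressing-cell fraction (default 0.25).
#' @return list: \code{clusters} (retained labels), \code{keep} (per-cell
#'   logical), \code{fraction} (per-cluster expressing fraction).
#' @export
retain_csf1r_clusters <- function(norm, labels, gene = "Csf1r",
                                  min_fraction = 0.25) {
  if (!gene %in% rownames(norm))
    stop("gene '", gene, "' is absent from the matrix")
  expr <- as.numeric(norm[gene, ]) > 0
  frac <- tapply(expr, labels, mean)
  keep_cl <- names(frac)[frac >= min_fraction]
  list(clusters = keep_cl, keep = as.character(labels) %in% keep_cl,
       fraction = frac)
}
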