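#' Re-cluster at high resolution and keep trajectory-relevant clusters
#'
#' Re-clusters the kNN graph at a higher resolution (2.5 in the reference
#' workflow) and retains the fine clusters whose majority base label lies
#' in \code{keep_subsets} (majority-vote mapping).
#'
#' @param graph \code{\link{build_knn_graph}} result.
#' @param base_labels coarse per-cell subset labels.
#' @param keep_subsets subset labels whose covering fine clusters are kept.
#' @param resolution community-detection resolution (default 2.5).
#' @param seed RNG seed.
#' @return list: \code{labels} (fine cluster per cell), \code{mapping}
#'   (fine cluster -> majority base label), \code{keep} (per-cell logical),
#'   \code{kept_clusters}.
#' @export
subcluster_for_trajectory <- function(graph, base_labels, keep_subsets,
                                      resolution = 2.5, seed = 1) {
  fine <- cluster_graph(graph, resolution = resolution, seed = seed)
  tab <- table(fine, as.character(base_labels))
  mapping <- colnames(tab)[apply(tab, 1, which.max)]
  names(mapping) <- rownames(tab)
  missing <- setdiff(keep_subsets, mapping)
  if (length(missing))
    stop("subset(s) map to no fine cluster: ", paste(missing, collapse = ", "))
  kept <- names(mapping)[mapping %in% keep_subsets]
  keep <- as.character(fine) %in% kept
  list(labels = fine, mapping = mapping, keep = keep, kept_clusters = kept)
}

#' Cluster-guided lineage inference
#'
#' Builds the Euclidean minimum spanning tree over cluster centroids in PC
#' space; lineages are the root-to-leaf paths starting from
#' \code{start_cluster}.
#'
#' @param centroids clusters x dims matrix of centroid coordinates (row
#'   names are cluster labels).
#' @param start_cluster label of the root cluster.
#' @return object of class \code{trajectory_model}: \code{centroids},
#'   \code{mst_edges} (two-column label matrix), \code{lineages} (list of
#'   cluster-label sequences), \code{start_cluster}.
#' @export
infer_lineages <- function(centroids, start_cluster) {
  centroids <- as.matrix(centroids)
  if (nrow(centroids) < 2) stop("need at least 2 clusters")
  labs <- rownames(centroids)
  if (!start_cluster %in% labs) stop("unknown start cluster: ", start_cluster)
  d <- as.matrix(stats::dist(centroids))
  g <- igraph::graph_from_adjacency_matrix(d, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  tree <- igraph::mst(g)
  el <- igraph::as_edgelist(tree, names = TRUE)
  deg <- igraph::degree(tree)
  leaves <- names(deg)[deg == 1 & names(deg) != start_cluster]
  if (length(leaves) == 0) leaves <- setdiff(labs, start_cluster)
  lineages <- lapply(leaves, function(lf) {
    p <- igraph::shortest_paths(tree, from = start_cluster, to = lf)$vpath[[1]]
    names(p)
  })
  structure(list(centroids = centroids, mst_edges = el,
                 lineages = lineages, start_cluster = start_cluster),
            class = "trajectory_model")
}

#' @exportS3Method print trajectory_model
print.trajectory_model <- function(x, ...) {
  cat(sprintf("trajectory_model: %d clusters, %d MST edges, %d lineage(s) from '%s'\n",
              nrow(x$centroids), nrow(x$mst_edges), length(x$lineages),
              x$start_cluster))
  for (l in x$lineages) cat("  ", paste(l, collapse = " -> "), "\n")
  invisible(x)
}

## closed-form orthogonal projection of points onto a polyline; returns the
## arc-length position of each point's nearest projection
project_to_polyline <- function(points, curve) {
  seg_vec <- diff(curve)
  seg_len <- sqrt(rowSums(seg_vec^2))
  cum <- c(0, cumsum(seg_len))
  n <- nrow(points)
  best_d2 <- rep(Inf, n)
  lambda <- numeric(n)
  for (sgm in seq_len(nrow(seg_vec))) {
    if (seg_len[sgm] == 0) next
    a <- curve[sgm, ]
    v <- seg_vec[sgm, ]
    tt <- (sweep(points, 2, a) %*% v) / sum(v^2)
    tt <- pmin(pmax(as.numeric(tt), 0), 1)
    proj <- matrix(a, n, ncol(points), byrow = TRUE) + tt %o% as.numeric(v)
    d2 <- rowSums((points - proj)^2)
    upd <- d2 < best_d2
    best_d2[upd] <- d2[upd]
    lambda[upd] <- cum[sgm] + tt[upd] * seg_len[sgm]
  }
  list(arc = lambda, dist2 = best_d2)
}

## local linear smoother of y against x at the points xout (tricube weights,
## fixed span as a fraction of the number of observations)
local_linear_smooth <- function(x, y, xout, span = 0.5) {
  n <- length(x)
  m <- max(2L, ceiling(span * n))
  vapply(xout, function(x0) {
    d <- abs(x - x0)
    h <- sort(d, partial = m)[m]
    h <- max(h, .Machine$double.eps)
    w <- (1 - pmin(d / h, 1)^3)^3
    use <- w > 0
    xw <- x[use]; yw <- y[use]; ww <- w[use]
    sw <- sum(ww)
    xb <- sum(ww * xw) / sw
    yb <- sum(ww * yw) / sw
    sxx <- sum(ww * (xw - xb)^2)
    if (sxx < 1e-12) return(yb)
    b <- sum(ww * (xw - xb) * (yw - yb)) / sxx
    yb + b * (x0 - xb)
  }, numeric(1))
}

#' Iterative principal-curve pseudotime along a lineage
#'
#' Initializes the curve with the piecewise-linear centroid path of the
#' chosen lineage and iterates: orthogonal projection of cells onto the
#' curve, arc-length ordering, and local-linear smoothing of each PC
#' coordinate against arc length (span 0.5). Pseudotime is the final
#' arc-length position scaled to [0, 1].
#'
#' @param cells_pcs cells x dims PC coordinates of the cells to order.
#' @param model a \code{\link{infer_lineages}} result.
#' @param lineage index of the lineage to follow (default 1).
#' @param n_iter maximum refinement iterations (default 10).
#' @param span smoother span (default 0.5).
#' @param n_points number of points representing the curve (default 100).
#' @param tol relative arc-length change declaring convergence.
#' @return list: \code{pseudotime} (per cell, in [0, 1]), \code{curve}
#'   (curve points), \code{converged}, \code{n_iter_used},
#'   \code{arc_length}.
#' @export
pseudotime <- function(cells_pcs, model, lineage = 1, n_iter = 10,
                       span = 0.5, n_points = 100, tol = 1e-3) {
  x <- as.matrix(cells_pcs)
  path <- model$lineages[[lineage]]
  ctr <- model$centroids[path, , drop = FALSE]
  ## resample the centroid polyline to n_points equally spaced points
  curve <- resample_polyline(ctr, n_points)
  lam_prev <- NULL
  converged <- FALSE
  it <- 0L
  for (it in seq_len(n_iter)) {
    proj <- project_to_polyline(x, curve)
    lam <- proj$arc
    rng <- diff(range(lam))
    if (rng == 0) rng <- 1
    if (!is.null(lam_prev) &&
        mean(abs(lam - lam_prev)) / rng < tol) { converged <- TRUE; break }
    lam_prev <- lam
    ord <- order(lam)
    grid <- seq(min(lam), max(lam), length.out = n_points)
    curve <- vapply(seq_len(ncol(x)), function(d)
      local_linear_smooth(lam[ord], x[ord, d], grid, span = span),
      numeric(n_points))
  }
  if (!converged && !is.null(lam_prev))
    warning("principal curve did not converge in ", n_iter,
            " iterations (mean arc shift ",
            signif(mean(abs(proj$arc - lam_prev)), 3), ")")
  lam <- project_to_polyline(x, curve)$arc
  rng <- range(lam)
  pt <- if (diff(rng) > 0) (lam - rng[1]) / diff(rng) else rep(0, length(lam))
  names(pt) <- rownames(x)
  list(pseudotime = pt, curve = curve, converged = converged,
       n_iter_used = it, arc_length = lam)
}

resample_polyline <- function(pts, n_out) {
  seg <- diff(pts)
  len <- sqrt(rowSums(seg^2))
  cum <- c(0, cumsum(len))
  s <- seq(0, cum[length(cum)], length.out = n_out)
  out <- vapply(seq_len(ncol(pts)), function(d)
    stats::approx(cum, pts[, d], xout = s)$y, numeric(n_out))
  out
}

#' Temporal-gene screen along pseudotime
#'
#' Per gene, a natural cubic spline model of expression against pseudotime
#' (\code{df} basis functions) is compared with the intercept-only model by
#' an F-test; genes are ranked by ascending p-value (ties broken by gene
#' identifier) and the top \code{top_n} form the heatmap set. Constant
#' genes get p = 1.
#'
#' @param norm genes x cells expression matrix (log-normalized).
#' @param pt per-cell pseudotime.
#' @param df spline degrees of freedom (default 4).
#' @param top_n size of the reported top set (default 100).
#' @return list: \code{results} (data.frame gene, p_value, rank),
#'   \code{top_genes}, \code{fitted} (top genes x cells fitted curves).
#' @export
temporal_genes <- function(norm, pt, df = 4, top_n = 100) {
  y <- as.matrix(norm)
  n <- ncol(y)
  if (n < df + 2) stop("need at least df + 2 cells")
  B <- splines::ns(pt, df = df)
  X <- cbind(1, B)
  qr_x <- qr(X)
  Q <- qr.Q(qr_x)
  yt <- t(y)                                   # cells x genes
  fitted_t <- Q %*% crossprod(Q, yt)
  sse <- colSums((yt - fitted_t)^2)
  sse0 <- colSums(scale(yt, scale = FALSE)^2)
  df1 <- qr_x$rank - 1
  df2 <- n - qr_x$rank
  fstat <- ((sse0 - sse) / df1) / (sse / df2)
  p <- stats::pf(fstat, df1, df2, lower.tail = FALSE)
  p[sse0 < 1e-12] <- 1                         # constant genes
  p[!is.finite(p)] <- 1
  ord <- order(p, rownames(y))
  res <- data.frame(gene = rownames(y)[ord], p_value = p[ord],
                    rank = seq_len(nrow(y)), stringsAsFactors = FALSE)
  top <- utils::head(res$gene, top_n)
  list(results = res, top_genes = top,
       fitted = t(fitted_t)[top, , drop = FALSE])
}

#' Cluster centroids in PC space
#'
#' @param pcs \code{pc_space} or cells x dims score matrix.
#' @param labels per-cell cluster labels.
#' @return clusters x dims centroid matrix (row names = cluster labels).
#' @export
cluster_centroids <- function(pcs, labels) {
  x <- if (inherits(pcs, "pc_space")) pcs$scores else as.matrix(pcs)
  lev <- sort(unique(as.character(labels)))
  out <- t(vapply(lev, function(l)
    colMeans(x[as.character(labels) == l, , drop = FALSE]),
    numeric(ncol(x))))
  rownames(out) <- lev
  out
}
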