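#' Velocity-gene filtering by within-cluster mean expression
#'
#' Genes enter the velocity field when, within at least one cluster, their
#' mean spliced expression reaches \code{spliced_min} and (rule
#' \code{"both"}, the default) their mean unspliced expression reaches
#' \code{unspliced_min}; rule \code{"either"} requires only one layer to
#' pass. Means are computed on size-normalized counts.
#'
#' @param s,u size-normalized spliced/unspliced matrices (genes x cells),
#'   e.g. from \code{\link{size_normalize}}.
#' @param clusters per-cell cluster labels.
#' @param spliced_min minimum within-cluster spliced mean (default 0.5).
#' @param unspliced_min minimum within-cluster unspliced mean (default 0.05).
#' @param rule \code{"both"} or \code{"either"}.
#' @return character vector of retained gene names.
#' @export
filter_velocity_genes <- function(s, u, clusters, spliced_min = 0.5,
                                  unspliced_min = 0.05,
                                  rule = c("both", "either")) {
  rule <- match.arg(rule)
  ms <- cluster_row_means(s, clusters)
  mu <- cluster_row_means(u, clusters)
  pass_s <- apply(ms >= spliced_min, 1, any)
  pass_u <- apply(mu >= unspliced_min, 1, any)
  keep <- if (rule == "both") pass_s & pass_u else pass_s | pass_u
  if (!any(keep))
    stop("no gene passes the velocity filter; relax spliced_min/unspliced_min")
  rownames(s)[keep]
}

cluster_row_means <- function(m, clusters) {
  cl <- as.character(clusters)
  lev <- unique(cl)
  out <- vapply(lev, function(l) rowMeans(m[, cl == l, drop = FALSE]),
                numeric(nrow(m)))
  if (is.null(dim(out))) out <- matrix(out, nrow = nrow(m))
  out
}

#' k-NN pooling of expression values
#'
#' Each cell's pooled value is the mean of the raw values over itself plus
#' its k nearest neighbors in PC space; pooling smooths the phase-plane
#' slope before the gamma fit.
#'
#' @param m genes x cells matrix.
#' @param graph a \code{\link{build_knn_graph}} result on the same cells.
#' @param include_self include the cell itself in its neighborhood
#'   (default TRUE).
#' @return pooled genes x cells matrix.
#' @export
knn_pool <- function(m, graph, include_self = TRUE) {
  n <- ncol(m)
  k <- graph$k
  if (k == 0) {
    warning("k = 0: pooling is the identity")
    return(m)
  }
  members <- if (include_self) cbind(seq_len(n), graph$idx) else graph$idx
  size <- ncol(members)
  P <- Matrix::sparseMatrix(i = as.vector(members),
                            j = rep(seq_len(n), times = size),
                            x = 1 / size, dims = c(n, n))
  out <- as.matrix(m %*% P)
  dimnames(out) <- dimnames(m)
  out
}

#' Steady-state degradation-rate fit at extreme quantiles
#'
#' Per gene, cells in the bottom and top \code{fit_quantile} of pooled
#' spliced expression (each tail separately, union) anchor a least-squares
#' fit of u = gamma * s through the origin: gamma = sum(s*u)/sum(s^2) on
#' the extreme set. Genes whose pooled spliced values are all zero are
#' returned as NA (dropped from the field, with a message).
#'
#' @param pooled_s,pooled_u pooled genes x cells matrices.
#' @param fit_quantile tail mass used on each side (default 0.02).
#' @param zero_intercept fit through the origin (default TRUE); FALSE adds
#'   an intercept and returns the slope.
#' @param eps lower floor for gamma (default 1e-4).
#' @return named numeric vector of per-gene gamma estimates.
#' @export
fit_gamma <- function(pooled_s, pooled_u, fit_quantile = 0.02,
                      zero_intercept = TRUE, eps = 1e-4) {
  stopifnot(identical(dim(pooled_s), dim(pooled_u)))
  n <- ncol(pooled_s)
  gamma <- rep(NA_real_, nrow(pooled_s))
  names(gamma) <- rownames(pooled_s)
  dropped <- 0L
  for (g in seq_len(nrow(pooled_s))) {
    s <- pooled_s[g, ]
    u <- pooled_u[g, ]
    if (all(s == 0)) { dropped <- dropped + 1L; next }
    qs <- stats::quantile(s, c(fit_quantile, 1 - fit_quantile), names = FALSE)
    ext <- which(s <= qs[1] | s >= qs[2])
    if (length(ext) < 2) ext <- seq_len(n)
    if (zero_intercept) {
      den <- sum(s[ext]^2)
      gamma[g] <- if (den > 0) sum(s[ext] * u[ext]) / den else NA_real_
    } else {
      fit <- stats::lm.fit(cbind(1, s[ext]), u[ext])
      gamma[g] <- fit$coefficients[2]
    }
    if (!is.na(gamma[g])) gamma[g] <- max(gamma[g], eps)
  }
  if (dropped > 0) message(dropped, " all-zero gene(s) dropped from the velocity fit")
  gamma
}

#' Steady-state velocity and extrapolated expression
#'
#' v = u - gamma * s per gene and cell; the extrapolated spliced state is
#' s + v * dt, floored at zero.
#'
#' @param pooled_u,pooled_s pooled matrices.
#' @param gamma per-gene degradation rates (genes with NA are dropped).
#' @param dt extrapolation step in pooled-count time units (default 1).
#' @return list with matrices \code{velocity} and \code{extrapolated}
#'   (rows restricted to genes with a finite gamma).
#' @export
compute_velocity <- function(pooled_u, pooled_s, gamma, dt = 1) {
  ok <- is.finite(gamma)
  u <- pooled_u[ok, , drop = FALSE]
  s <- pooled_s[ok, , drop = FALSE]
  v <- u - gamma[ok] * s
  list(velocity = v, extrapolated = pmax(s + v * dt, 0))
}

#' Correlation-based transition probabilities on the kNN graph
#'
#' For cell i and each neighbor j, r_ij is the Pearson correlation between
#' i's velocity vector (extrapolated minus current spliced state) and the
#' displacement s_j - s_i over the velocity genes; transition weights
#' exp(r_ij / sigma_corr) are row-normalized over the neighbors (self
#' excluded). Zero-velocity or zero-displacement vectors give r = 0 by
#' convention.
#'
#' @param s current (pooled, size-normalized) spliced matrix, velocity
#'   genes x cells.
#' @param extrapolated matching extrapolated state matrix.
#' @param graph \code{\link{build_knn_graph}} result.
#' @param sigma_corr correlation kernel bandwidth (default 0.05).
#' @return sparse row-stochastic cells x cells \code{dgCMatrix} supported
#'   on the kNN neighbor sets.
#' @export
transition_probabilities <- function(s, extrapolated, graph,
                                     sigma_corr = 0.05) {
  stopifnot(identical(dim(s), dim(extrapolated)))
  n <- ncol(s)
  k <- graph$k
  ii <- jj <- integer(n * k)
  xx <- numeric(n * k)
  pos <- 0L
  for (i in seq_len(n)) {
    nb <- graph$idx[i, ]
    di <- extrapolated[, i] - s[, i]
    ## velocities that are zero up to floating-point residue carry no
    ## direction: give them r = 0 (uniform row) rather than noise
    if (sqrt(sum(di^2)) <= 1e-8 * max(1, sqrt(sum(s[, i]^2))))
      di <- numeric(length(di))
    delta <- s[, nb, drop = FALSE] - s[, i]
    r <- safe_cor(di, delta)
    w <- exp(r / sigma_corr)
    tot <- sum(w)
    if (tot == 0 || !is.finite(tot)) next
    idx <- pos + seq_len(k)
    ii[idx] <- i; jj[idx] <- nb; xx[idx] <- w / tot
    pos <- pos + k
  }
  keep <- seq_len(pos)
  Matrix::sparseMatrix(i = ii[keep], j = jj[keep], x = xx[keep],
                       dims = c(n, n),
                       dimnames = list(colnames(s), colnames(s)))
}

## Pearson correlation of a vector against matrix columns; degenerate
## (zero-variance) vectors yield 0 by convention
safe_cor <- function(v, m) {
  vc <- v - mean(v)
  sv <- sqrt(sum(vc^2))
  if (sv == 0) return(numeric(ncol(m)))
  mc <- m - matrix(colMeans(m), nrow(m), ncol(m), byrow = TRUE)
  sm <- sqrt(colSums(mc^2))
  r <- as.numeric(crossprod(vc, mc)) / (sv * sm)
  r[sm == 0] <- 0
  r
}

#' Project transition probabilities onto a 2D embedding
#'
#' Each cell's arrow is the transition-weighted mean of the unit embedding
#' displacements to its neighbors minus the uniform baseline (1/k of their
#' plain mean), so an uninformative (uniform) transition row cancels to a
#' near-zero arrow. Coincident embedded neighbor pairs are skipped and the
#' remaining weights renormalized; all-zero transition rows give zero
#' arrows.
#'
#' @param transition row-stochastic transition matrix.
#' @param embedding cells x 2 coordinate matrix.
#' @param graph \code{\link{build_knn_graph}} result.
#' @return cells x 2 matrix of arrow displacement vectors.
#' @export
project_to_embedding <- function(transition, embedding, graph) {
  n <- nrow(embedding)
  arrows <- matrix(0, n, 2, dimnames = list(rownames(embedding),
                                            c("dx", "dy")))
  Tm <- as.matrix(transition)
  for (i in seq_len(n)) {
    nb <- graph$idx[i, ]
    disp <- embedding[nb, , drop = FALSE] -
      matrix(embedding[i, ], length(nb), 2, byrow = TRUE)
    len <- sqrt(rowSums(disp^2))
    ok <- len > 0
    if (!any(ok)) next
    e_hat <- disp[ok, , drop = FALSE] / len[ok]
    w <- Tm[i, nb][ok]
    tw <- sum(w)
    if (tw == 0) next                       # all-zero row: no information
    w <- w / tw                             # renormalize after skipped pairs
    arrows[i, ] <- colSums(e_hat * w) - colMeans(e_hat)
  }
  arrows
}

#' Relative 2D velocity of each cell
#'
#' The Euclidean length of the cell's projected arrow: the relative
#' distance from the cell position in the embedding to its projected
#' position.
#'
#' @param arrows cells x 2 arrow matrix.
#' @return numeric vector of arrow lengths.
#' @export
relative_2d_velocity <- function(arrows) {
  out <- sqrt(rowSums(arrows^2))
  names(out) <- rownames(arrows)
  out
}

#' Pairwise rank-sum comparison of a per-cell statistic between subsets
#'
#' @param values per-cell numeric values (e.g. relative 2D velocities).
#' @param labels per-cell subset labels.
#' @return data.frame of all unordered label pairs with group medians,
#'   two-sided Wilcoxon rank-sum p-values and BH-adjusted p-values.
#' @export
compare_subsets <- function(values, labels) {
  lev <- unique(as.character(labels))
  pairs <- utils::combn(lev, 2)
  res <- data.frame(
    a = pairs[1, ], b = pairs[2, ],
    median_a = NA_real_, median_b = NA_real_, p_value = NA_real_,
    stringsAsFactors = FALSE)
  for (r in seq_len(nrow(res))) {
    va <- values[labels == res$a[r]]
    vb <- values[labels == res$b[r]]
    res$median_a[r] <- stats::median(va)
    res$median_b[r] <- stats::median(vb)
    res$p_value[r] <- suppressWarnings(stats::wilcox.test(va, vb)$p.value)
  }
  res$adjusted_p <- stats::p.adjust(res$p_value, "BH")
  res
}

#' Grid-averaged velocity arrows
#'
#' Cells are assigned to an n_grid x n_grid lattice over the embedding
#' bounding box; each non-empty lattice cell's arrow is the Gaussian-kernel
#' weighted mean of its cells' arrows (weights centered at the lattice-cell
#' center). Empty lattice cells are omitted.
#'
#' @param arrows cells x 2 arrow matrix.
#' @param embedding cells x 2 coordinates.
#' @param n_grid lattice size per axis (>= 2).
#' @param bandwidth Gaussian kernel bandwidth (default: half the lattice
#'   spacing).
#' @return data.frame: grid-cell center coordinates (x, y), mean arrow
#'   (dx, dy), number of cells (n).
#' @export
grid_summarize <- function(arrows, embedding, n_grid = 20, bandwidth = NULL) {
  if (n_grid < 2) stop("n_grid must be >= 2")
  rx <- range(embedding[, 1]); ry <- range(embedding[, 2])
  bx <- seq(rx[1], rx[2], length.out = n_grid + 1)
  by <- seq(ry[1], ry[2], length.out = n_grid + 1)
  if (is.null(bandwidth))
    bandwidth <- mean(c(diff(bx)[1], diff(by)[1])) / 2
  ix <- pmin(findInterval(embedding[, 1], bx, rightmost.closed = TRUE), n_grid)
  iy <- pmin(findInterval(embedding[, 2], by, rightmost.closed = TRUE), n_grid)
  key <- (ix - 1) * n_grid + iy
  out <- lapply(unique(key), function(kk) {
    cells <- which(key == kk)
    gx <- (bx[ix[cells[1]]] + bx[ix[cells[1]] + 1]) / 2
    gy <- (by[iy[cells[1]]] + by[iy[cells[1]] + 1]) / 2
    d2 <- (embedding[cells, 1] - gx)^2 + (embedding[cells, 2] - gy)^2
    w <- exp(-d2 / (2 * bandwidth^2))
    w <- w / sum(w)
    data.frame(x = gx, y = gy,
               dx = sum(arrows[cells, 1] * w), dy = sum(arrows[cells, 2] * w),
               n = length(cells))
  })
  do.call(rbind, out)
}
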