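#' Subset-aggregated single-step transition probability (TPn)
#'
#' For a starting subset of j cells, the total transition probability onto
#' every target cell n is the sum of the single-cell transition
#' probabilities TPin over the subset, corrected by the number of cells:
#' TPn = (sum_i TPin) / j. When every subset row is stochastic, the TPn
#' vector itself sums to one. Subset cells with an all-zero transition row
#' are excluded from j with a warning.
#'
#' @param transition row-stochastic cells x cells transition matrix.
#' @param subset_cells indices, names or logical mask of the starting
#'   subset.
#' @param clusters optional per-cell cluster labels; when given, TPn mass is
#'   also summed per cluster.
#' @param subset_label label to record for the starting subset.
#' @return object of class \code{transition_summary}: \code{tpn} (per
#'   target cell), \code{j}, \code{mass_by_cluster} (or NULL),
#'   \code{starting_subset}, \code{self_cluster} (majority cluster of the
#'   subset, or NULL).
#' @export
subset_transition_probability <- function(transition, subset_cells,
                                          clusters = NULL,
                                          subset_label = "subset") {
  n <- nrow(transition)
  idx <- if (is.logical(subset_cells)) which(subset_cells)
         else if (is.character(subset_cells))
           match(subset_cells, rownames(transition))
         else as.integer(subset_cells)
  if (length(idx) == 0 || anyNA(idx)) stop("starting subset is empty or unmatched")
  rows <- transition[idx, , drop = FALSE]
  rs <- Matrix::rowSums(rows)
  dead <- rs < 1e-12
  if (any(dead)) {
    warning(sum(dead), " subset cell(s) with an all-zero transition row ",
            "excluded from j")
    rows <- rows[!dead, , drop = FALSE]
    idx <- idx[!dead]
  }
  if (nrow(rows) == 0) stop("no subset cell has a valid transition row")
  j <- nrow(rows)
  tpn <- as.numeric(Matrix::colSums(rows)) / j
  names(tpn) <- colnames(transition)
  mass <- self_cl <- NULL
  if (!is.null(clusters)) {
    cl <- as.character(clusters)
    mass <- tapply(tpn, cl, sum)
    tab <- table(cl[idx])
    self_cl <- names(tab)[which.max(tab)]
  }
  structure(list(tpn = tpn, j = j, mass_by_cluster = mass,
                 starting_subset = subset_label, self_cluster = self_cl,
                 subset_index = idx),
            class = "transition_summary")
}

#' @exportS3Method print transition_summary
print.transition_summary <- function(x, ...) {
  cat(sprintf("transition_summary: subset '%s' (j = %d), total TPn = %.6f\n",
              x$starting_subset, x$j, sum(x$tpn)))
  if (!is.null(x$mass_by_cluster)) {
    cat("  TPn mass by cluster:\n")
    print(round(sort(x$mass_by_cluster, decreasing = TRUE), 4))
  }
  invisible(x)
}

#' Call the fate of a starting subset from its TPn masses
#'
#' Ranks the per-cluster TPn masses (restricted to candidate clusters)
#' in descending order; the called fate is the top-ranked cluster other
#' than the subset's own (self transitions are reported but excluded from
#' the call).
#'
#' @param summary a \code{\link{subset_transition_probability}} result
#'   computed with cluster labels.
#' @param candidate_clusters clusters to rank (default: all).
#' @return list: \code{ranked} (named descending mass vector including
#'   self), \code{fate} (top non-self candidate), \code{self_cluster},
#'   \code{self_mass}.
#' @export
fate_call <- function(summary, candidate_clusters = NULL) {
  if (is.null(summary$mass_by_cluster))
    stop("transition summary lacks cluster masses; recompute with clusters")
  mass <- summary$mass_by_cluster
  if (!is.null(candidate_clusters)) {
    miss <- setdiff(candidate_clusters, names(mass))
    if (length(miss))
      stop("unknown candidate cluster(s): ", paste(miss, collapse = ", "))
    mass <- mass[candidate_clusters]
  }
  ranked <- sort(mass, decreasing = TRUE)
  non_self <- ranked[names(ranked) != summary$self_cluster]
  list(ranked = ranked,
       fate = if (length(non_self)) names(non_self)[1] else NA_character_,
       self_cluster = summary$self_cluster,
       self_mass = unname(summary$mass_by_cluster[summary$self_cluster]))
}

#' Gaussian confidence ellipse of a 2D point set
#'
#' Sample mean and covariance (n-1 denominator) scaled by the chi-square
#' quantile with 2 degrees of freedom at the requested coverage level;
#' semi-axes are sqrt(eigenvalue x qchisq(level, 2)). Used to mark cell
#' subsets on the embedding (95% in the fate maps, 80% in the trajectory
#' views).
#'
#' @param points_2d n x 2 coordinate matrix (n >= 3, not all collinear).
#' @param level coverage level in (0, 1).
#' @return object of class \code{confidence_ellipse}: \code{center},
#'   \code{covariance}, \code{level}, \code{semi_axes}, \code{rotation}
#'   (radians of the major axis).
#' @export
confidence_ellipse <- function(points_2d, level = 0.95) {
  p <- as.matrix(points_2d)
  if (nrow(p) < 3) stop("need at least 3 points")
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  ctr <- colMeans(p)
  cv <- stats::cov(p)
  ev <- eigen(cv, symmetric = TRUE)
  floor_val <- max(ev$values[1], .Machine$double.eps) * 1e-6
  if (ev$values[2] <= floor_val) {
    warning("points are (near-)collinear: minor axis floored")
    ev$values[2] <- floor_val
  }
  q <- stats::qchisq(level, df = 2)
  structure(list(center = ctr, covariance = cv, level = level,
                 semi_axes = sqrt(ev$values * q),
                 rotation = atan2(ev$vectors[2, 1], ev$vectors[1, 1])),
            class = "confidence_ellipse")
}

#' @exportS3Method print confidence_ellipse
print.confidence_ellipse <- function(x, ...) {
  cat(sprintf("confidence_ellipse (%.0f%%): center (%.3f, %.3f), semi-axes %.3f / %.3f\n",
              100 * x$level, x$center[1], x$center[2],
              x$semi_axes[1], x$semi_axes[2]))
  invisible(x)
}

#' Points on (or membership inside) a confidence ellipse
#'
#' @param ellipse a \code{confidence_ellipse}.
#' @param n number of boundary points to return.
#' @return n x 2 matrix tracing the ellipse boundary.
#' @export
ellipse_boundary <- function(ellipse, n = 100) {
  th <- seq(0, 2 * pi, length.out = n)
  a <- ellipse$semi_axes[1]; b <- ellipse$semi_axes[2]
  rot <- ellipse$rotation
  xy <- cbind(a * cos(th), b * sin(th))
  R <- matrix(c(cos(rot), sin(rot), -sin(rot), cos(rot)), 2, 2)
  sweep(xy %*% t(R), 2, ellipse$center, `+`)
}

#' Test whether points fall inside a confidence ellipse
#'
#' @param ellipse a \code{confidence_ellipse}.
#' @param points n x 2 coordinates.
#' @return logical vector: Mahalanobis distance within the chi-square
#'   quantile at the ellipse's level.
#' @export
ellipse_contains <- function(ellipse, points) {
  d2 <- stats::mahalanobis(as.matrix(points), ellipse$center,
                           ellipse$covariance)
  d2 <= stats::qchisq(ellipse$level, df = 2)
}
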