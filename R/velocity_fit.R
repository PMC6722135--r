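#' Fit a steady-state RNA velocity field
#'
#' One-stop fitting function tying the velocity stages together: velocity-
#' gene filtering on within-cluster means, k-NN pooling of size-normalized
#' layers, extreme-quantile degradation-rate (gamma) fitting, velocity and
#' extrapolated states, the correlation-based transition-probability matrix
#' on the kNN graph and, when an embedding is given, the projected arrows
#' and per-cell relative 2D velocities.
#'
#' @param data a \code{\link{layered_counts}} object (post-QC).
#' @param clusters per-cell cluster labels.
#' @param graph \code{\link{build_knn_graph}} result on the same cells
#'   (k = 20 in the reference workflow).
#' @param embedding optional cells x 2 embedding for arrow projection.
#' @param spliced_min,unspliced_min velocity-gene filter thresholds
#'   (defaults 0.5 / 0.05).
#' @param filter_rule \code{"both"} (default) or \code{"either"}.
#' @param fit_quantile extreme-quantile mass for the gamma fit
#'   (default 0.02).
#' @param dt extrapolation step (default 1).
#' @param sigma_corr correlation kernel bandwidth (default 0.05).
#' @return object of class \code{velocity_fit}: \code{gamma},
#'   \code{velocity}, \code{extrapolated}, \code{pooled_s},
#'   \code{pooled_u}, \code{transition}, \code{arrows} (or NULL),
#'   \code{genes} (velocity genes), \code{clusters}, \code{graph},
#'   \code{embedding}, \code{params}.
#' @export
fit_velocity <- function(data, clusters, graph, embedding = NULL,
                         spliced_min = 0.5, unspliced_min = 0.05,
                         filter_rule = c("both", "either"),
                         fit_quantile = 0.02, dt = 1, sigma_corr = 0.05) {
  filter_rule <- match.arg(filter_rule)
  norm <- size_normalize(data)
  genes <- filter_velocity_genes(norm$s, norm$u, clusters,
                                 spliced_min, unspliced_min, filter_rule)
  ps <- knn_pool(norm$s[genes, , drop = FALSE], graph)
  pu <- knn_pool(norm$u[genes, , drop = FALSE], graph)
  gamma <- fit_gamma(ps, pu, fit_quantile = fit_quantile)
  vel <- compute_velocity(pu, ps, gamma, dt = dt)
  ok <- names(gamma)[is.finite(gamma)]
  trans <- transition_probabilities(ps[ok, , drop = FALSE],
                                    vel$extrapolated, graph,
                                    sigma_corr = sigma_corr)
  arrows <- if (!is.null(embedding))
    project_to_embedding(trans, embedding, graph) else NULL
  structure(list(gamma = gamma, velocity = vel$velocity,
                 extrapolated = vel$extrapolated,
                 pooled_s = ps, pooled_u = pu,
                 transition = trans, arrows = arrows, genes = genes,
                 clusters = clusters, graph = graph, embedding = embedding,
                 params = list(spliced_min = spliced_min,
                               unspliced_min = unspliced_min,
                               filter_rule = filter_rule,
                               fit_quantile = fit_quantile, dt = dt,
                               sigma_corr = sigma_corr)),
            class = "velocity_fit")
}

#' @exportS3Method print velocity_fit
print.velocity_fit <- function(x, ...) {
  cat(sprintf("velocity_fit: %d velocity genes x %d cells (k = %d)\n",
              length(x$genes), ncol(x$pooled_s), x$graph$k))
  cat(sprintf("  gamma: median %.3f [%.3f, %.3f]\n",
              stats::median(x$gamma, na.rm = TRUE),
              stats::quantile(x$gamma, 0.05, na.rm = TRUE),
              stats::quantile(x$gamma, 0.95, na.rm = TRUE)))
  if (!is.null(x$arrows))
    cat(sprintf("  arrows: mean length %.3f\n",
                mean(relative_2d_velocity(x$arrows))))
  invisible(x)
}

#' @exportS3Method summary velocity_fit
summary.velocity_fit <- function(object, ...) {
  rs <- Matrix::rowSums(object$transition)
  out <- list(n_genes = length(object$genes),
              n_cells = ncol(object$pooled_s),
              gamma_summary = summary(object$gamma),
              stochastic_rows = sum(abs(rs - 1) < 1e-8),
              zero_rows = sum(rs == 0),
              params = object$params)
  class(out) <- "summary.velocity_fit"
  out
}

#' @exportS3Method print summary.velocity_fit
print.summary.velocity_fit <- function(x, ...) {
  cat("Steady-state velocity field\n")
  cat(sprintf("  %d velocity genes, %d cells\n", x$n_genes, x$n_cells))
  cat("  gamma:\n"); print(x$gamma_summary)
  cat(sprintf("  transition rows: %d stochastic, %d zero\n",
              x$stochastic_rows, x$zero_rows))
  invisible(x)
}

#' @export
coef.velocity_fit <- function(object, ...) object$gamma

## the velocity v = u - gamma * s is precisely the residual of the
## steady-state fit u ~ gamma * s
#' @export
residuals.velocity_fit <- function(object, ...) object$velocity

#' Extrapolated expression state of a fitted velocity field
#'
#' @param object a \code{velocity_fit}.
#' @param dt extrapolation step; default uses the fitted step.
#' @param ... unused.
#' @return genes x cells matrix of extrapolated spliced states.
#' @export
predict.velocity_fit <- function(object, dt = NULL, ...) {
  if (is.null(dt)) return(object$extrapolated)
  ok <- is.finite(object$gamma)
  pmax(object$pooled_s[ok, , drop = FALSE] + object$velocity * dt, 0)
}

#' Plot a fitted velocity field
#'
#' Embedding scatter colored by cluster with grid-averaged arrows.
#'
#' @param x a \code{velocity_fit} with an embedding.
#' @param n_grid arrow lattice size (default 20).
#' @param arrow_scale multiplier on arrow lengths (default 1).
#' @param ... passed to \code{plot}.
#' @export
plot.velocity_fit <- function(x, n_grid = 20, arrow_scale = 1, ...) {
  if (is.null(x$embedding)) stop("velocity_fit was fitted without an embedding")
  cl <- as.integer(factor(x$clusters))
  graphics::plot(x$embedding, col = grDevices::hcl.colors(max(cl), "Dark 3")[cl],
                 pch = 16, cex = 0.5, xlab = "dim1", ylab = "dim2", ...)
  g <- grid_summarize(x$arrows, x$embedding, n_grid = n_grid)
  keep <- sqrt(g$dx^2 + g$dy^2) > 1e-8
  g <- g[keep, , drop = FALSE]
  graphics::arrows(g$x, g$y, g$x + arrow_scale * g$dx, g$y + arrow_scale * g$dy,
                   length = 0.05, lwd = 1.2)
  invisible(x)
}
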