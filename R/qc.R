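#' Per-cell quality-control statistics
#'
#' Detection and the mitochondrial fraction are computed on the raw spliced
#' layer (the expression matrix that is analyzed downstream), before any
#' normalization.
#'
#' @param data a \code{\link{layered_counts}} object.
#' @param dataset_tag replicate identifier recorded per cell.
#' @return data.frame with one row per cell: \code{cell_id},
#'   \code{total_counts}, \code{n_genes_detected}, \code{mito_fraction},
#'   \code{dataset_tag}.
#' @export
compute_cell_qc <- function(data, dataset_tag = "ds1") {
  tot <- Matrix::colSums(data$spliced)
  ndet <- Matrix::colSums(data$spliced > 0)
  mito <- if (any(data$mito))
    Matrix::colSums(data$spliced[data$mito, , drop = FALSE]) else 0
  data.frame(cell_id = data$cells,
             total_counts = as.numeric(tot),
             n_genes_detected = as.integer(ndet),
             mito_fraction = ifelse(tot > 0, as.numeric(mito) / tot, 0),
             dataset_tag = dataset_tag,
             stringsAsFactors = FALSE)
}

#' Filter cells on detected genes and mitochondrial fraction
#'
#' Retains cells with \code{min_genes <= n_genes_detected <= max_genes}
#' (closed interval) and \code{mito_fraction <= max_mito}. Both layers are
#' subset identically. The defaults are the thresholds used for lung
#' CD64-expressing phagocytes; monocyte runs raise \code{max_genes} to 3000.
#'
#' @param data a \code{\link{layered_counts}} object.
#' @param min_genes,max_genes inclusive bounds on detected genes per cell.
#' @param max_mito maximum mitochondrial count fraction (default 0.05).
#' @param dataset_tag replicate identifier for the returned cell table.
#' @return list with \code{data} (filtered \code{layered_counts}) and
#'   \code{cells} (QC table of the retained cells).
#' @export
filter_cells <- function(data, min_genes = 200, max_genes = 2500,
                         max_mito = 0.05, dataset_tag = "ds1") {
  qc <- compute_cell_qc(data, dataset_tag)
  keep <- qc$n_genes_detected >= min_genes &
    qc$n_genes_detected <= max_genes &
    qc$mito_fraction <= max_mito
  if (!any(keep))
    stop("quality filtering removed every cell (min_genes=", min_genes,
         ", max_genes=", max_genes, ", max_mito=", max_mito, ")")
  list(data = subset_layers(data, cells = which(keep)),
       cells = qc[keep, , drop = FALSE])
}

#' Filter genes on the number of cells detecting them
#'
#' Detection is defined on the spliced layer (count > 0); the unspliced
#' layer is subset identically.
#'
#' @param data a \code{\link{layered_counts}} object.
#' @param min_cells minimum number of cells with a positive spliced count.
#' @return filtered \code{layered_counts}.
#' @export
filter_genes <- function(data, min_cells = 3) {
  keep <- Matrix::rowSums(data$spliced > 0) >= min_cells
  if (!any(keep)) stop("gene filtering removed every gene")
  subset_layers(data, genes = which(keep))
}

#' Library-size log-normalization
#'
#' Each cell's counts are divided by the cell total, multiplied by
#' \code{scale_factor} and log-transformed:
#' entry = ln(1 + count / cell_total * scale_factor). Consequently
#' \code{sum(expm1(column))} equals \code{scale_factor} for every cell.
#'
#' @param x a \code{layered_counts} (its spliced layer is normalized) or a
#'   genes x cells count matrix.
#' @param scale_factor global scale (default 10,000).
#' @return sparse genes x cells matrix of log-normalized expression with
#'   attribute \code{scale_factor}.
#' @export
log_normalize <- function(x, scale_factor = 1e4) {
  m <- if (inherits(x, "layered_counts")) x$spliced else as_sparse(x)
  tot <- Matrix::colSums(m)
  if (any(tot == 0))
    stop("cell(s) with zero total counts: ",
         paste(colnames(m)[tot == 0], collapse = ", "))
  norm <- m %*% Matrix::Diagonal(ncol(m), scale_factor / tot)
  norm <- log1p(norm)
  dimnames(norm) <- dimnames(m)
  norm <- as_sparse(norm)
  attr(norm, "scale_factor") <- scale_factor
  norm
}

#' Variable-gene selection by binned mean/dispersion z-scores
#'
#' Per gene, the mean and the dispersion (variance-to-mean ratio) are
#' computed on the back-transformed scale (expm1 of the log-normalized
#' values); the mean is re-logged (\code{log1p}) and the log-dispersion is
#' z-scored within \code{n_bins} equal-width bins of the mean. A gene is
#' flagged when its mean lies in \code{[x_low, x_high]} and its dispersion
#' z-score is \code{>= y_cutoff}. Bins with fewer than two genes are merged
#' with their left neighbor (a message reports how many).
#'
#' @param norm log-normalized matrix from \code{\link{log_normalize}}.
#' @param x_low,x_high bounds on the (log-scale) gene mean (defaults 0.0125
#'   and 3).
#' @param y_cutoff minimum dispersion z-score (default 0.5).
#' @param n_bins number of mean bins (default 20).
#' @return data.frame per gene: \code{gene}, \code{mean}, \code{dispersion},
#'   \code{dispersion_scaled}, \code{variable} (logical flag).
#' @export
find_variable_genes <- function(norm, x_low = 0.0125, x_high = 3,
                                y_cutoff = 0.5, n_bins = 20) {
  bt <- expm1(norm)                       # back-transformed scale
  mu <- Matrix::rowMeans(bt)
  v <- Matrix::rowMeans(bt^2) - mu^2
  v <- v * ncol(bt) / max(1, ncol(bt) - 1)
  disp <- ifelse(mu > 0, v / mu, 0)
  xm <- log1p(mu)
  yd <- log(ifelse(disp > 0, disp, NA))
  n_distinct <- length(unique(xm))
  if (n_distinct < n_bins) {
    message("only ", n_distinct, " distinct gene means; using ",
            n_distinct, " bins")
    n_bins <- n_distinct
  }
  bins <- if (n_bins < 2) rep(1L, length(xm))
          else cut(xm, breaks = n_bins, include.lowest = TRUE, labels = FALSE)
  ## merge under-filled bins into their left neighbor
  tab <- tabulate(bins, n_bins)
  merged <- 0L
  for (b in seq_len(n_bins)) {
    if (tab[b] > 0 && tab[b] < 2) {
      tgt <- if (b > 1) b - 1L else b + 1L
      bins[bins == b] <- tgt
      tab[tgt] <- tab[tgt] + tab[b]; tab[b] <- 0L
      merged <- merged + 1L
    }
  }
  if (merged > 0) message(merged, " under-filled mean bin(s) merged with a neighbor")
  z <- rep(0, length(xm))
  for (b in unique(bins)) {
    i <- which(bins == b)
    yy <- yd[i]
    m <- mean(yy, na.rm = TRUE)
    s <- stats::sd(yy, na.rm = TRUE)
    z[i] <- if (is.na(s) || s == 0) 0 else (yy - m) / s
  }
  z[is.na(z)] <- 0
  data.frame(gene = rownames(norm), mean = xm, dispersion = disp,
             dispersion_scaled = z,
             variable = xm >= x_low & xm <= x_high & z >= y_cutoff,
             stringsAsFactors = FALSE)
}

#' Scale expression with a regressed-out covariate
#'
#' Per gene, ordinary linear regression of the normalized expression on the
#' covariate (typically the per-cell total UMI count); the residuals are
#' z-scored (n-1 denominator) and clipped at \code{±clip}.
#'
#' @param norm log-normalized genes x cells matrix (usually restricted to
#'   variable genes).
#' @param covariate numeric per-cell covariate; a constant covariate falls
#'   back to plain z-scoring with a warning.
#' @param clip clip value for the scaled data (default 10).
#' @return dense genes x cells matrix of clipped residual z-scores.
#' @export
scale_and_regress <- function(norm, covariate, clip = 10) {
  y <- as.matrix(norm)
  if (length(covariate) != ncol(y))
    stop("covariate length does not match the number of cells")
  if (any(!is.finite(covariate))) stop("covariate must be finite for every cell")
  xc <- covariate - mean(covariate)
  sxx <- sum(xc^2)
  if (sxx < .Machine$double.eps * length(xc)) {
    warning("constant covariate: falling back to plain z-scoring")
    res <- y - rowMeans(y)
  } else {
    beta <- (y %*% xc) / sxx                       # per-gene slope
    res <- y - rowMeans(y) - tcrossprod(beta, xc)  # centered residuals
  }
  s <- sqrt(rowSums(res^2) / max(1, ncol(y) - 1))
  s[s == 0] <- 1
  out <- pmin(pmax(res / s, -clip), clip)
  dimnames(out) <- dimnames(y)
  out
}

#' Merge two datasets on their shared gene universe
#'
#' Genes are intersected, cells concatenated; each cell name is suffixed
#' with its dataset tag so both replicates can be analyzed simultaneously.
#'
#' @param a,b \code{layered_counts} objects (or genes x cells matrices).
#'   \code{b} may be \code{NULL}, in which case \code{a} is returned
#'   (tagged).
#' @param tags character vector of length 2 with the dataset identifiers.
#' @return merged object of the same class as \code{a}, plus attribute
#'   \code{dataset_tag} (per-cell tag vector).
#' @export
merge_datasets <- function(a, b, tags = c("ds1", "ds2")) {
  tag_cells <- function(cells, tag) paste0(cells, "_", tag)
  if (is.null(b)) {
    if (inherits(a, "layered_counts")) {
      out <- a
      out$cells <- tag_cells(a$cells, tags[1])
      colnames(out$spliced) <- colnames(out$unspliced) <- out$cells
      attr(out, "dataset_tag") <- rep(tags[1], length(out$cells))
      return(out)
    }
    colnames(a) <- tag_cells(colnames(a), tags[1])
    attr(a, "dataset_tag") <- rep(tags[1], ncol(a))
    return(a)
  }
  ga <- if (inherits(a, "layered_counts")) a$genes else rownames(a)
  gb <- if (inherits(b, "layered_counts")) b$genes else rownames(b)
  common <- intersect(ga, gb)
  if (length(common) == 0) stop("datasets share no genes; cannot merge")
  if (inherits(a, "layered_counts")) {
    s <- cbind(a$spliced[common, , drop = FALSE], b$spliced[common, , drop = FALSE])
    u <- cbind(a$unspliced[common, , drop = FALSE], b$unspliced[common, , drop = FALSE])
    cells <- c(tag_cells(a$cells, tags[1]), tag_cells(b$cells, tags[2]))
    if (anyDuplicated(cells)) {
      message("duplicate barcodes across tags; suffixing with index")
      cells <- make.unique(cells)
    }
    colnames(s) <- colnames(u) <- cells
    out <- layered_counts(s, u, mito_pattern = a$mito_pattern)
    attr(out, "dataset_tag") <- rep(tags, c(length(a$cells), length(b$cells)))
    return(out)
  }
  m <- cbind(a[common, , drop = FALSE], b[common, , drop = FALSE])
  cells <- c(tag_cells(colnames(a), tags[1]), tag_cells(colnames(b), tags[2]))
  if (anyDuplicated(cells)) {
    message("duplicate barcodes across tags; suffixing with index")
    cells <- make.unique(cells)
  }
  colnames(m) <- cells
  attr(m, "dataset_tag") <- rep(tags, c(ncol(a), ncol(b)))
  m
}

#' Size-normalize both layers by the spliced per-cell total
#'
#' Both layers are divided by the same per-cell factor (spliced total over
#' its median), which removes library-size variation while preserving each
#' cell's unspliced-to-spliced ratio — the quantity the steady-state
#' velocity fit depends on.
#'
#' @param data a \code{layered_counts} object.
#' @return list with dense matrices \code{s} and \code{u} and the per-cell
#'   \code{size_factor}.
#' @export
size_normalize <- function(data) {
  tot <- Matrix::colSums(data$spliced)
  if (any(tot == 0))
    stop("cell(s) with zero spliced counts: ",
         paste(data$cells[tot == 0], collapse = ", "))
  sf <- tot / stats::median(tot)
  s <- as.matrix(data$spliced %*% Matrix::Diagonal(length(sf), 1 / sf))
  u <- as.matrix(data$unspliced %*% Matrix::Diagonal(length(sf), 1 / sf))
  dimnames(s) <- dimnames(u) <- list(data$genes, data$cells)
  list(s = s, u = u, size_factor = sf)
}
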