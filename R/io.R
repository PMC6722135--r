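#' Write a layered dataset to an MTX + TSV directory
#'
#' Layout: \code{spliced.mtx} and \code{unspliced.mtx} (Matrix Market,
#' 1-based coordinate format), \code{barcodes.tsv}, \code{features.tsv}
#' (gene id + mito flag), and, when ground truth is supplied,
#' \code{truth.tsv}.
#'
#' @param data a \code{\link{layered_counts}} object.
#' @param path output directory (created if needed).
#' @param truth optional per-cell truth table (data.frame with a
#'   \code{cell_id} column).
#' @return \code{path}, invisibly.
#' @export
write_dataset <- function(data, path, truth = NULL) {
  stopifnot(inherits(data, "layered_counts"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(data$spliced, file.path(path, "spliced.mtx"))
  Matrix::writeMM(data$unspliced, file.path(path, "unspliced.mtx"))
  writeLines(data$cells, file.path(path, "barcodes.tsv"))
  utils::write.table(
    data.frame(gene_id = data$genes, mito = as.integer(data$mito)),
    file.path(path, "features.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(truth)) {
    if (!"cell_id" %in% names(truth)) stop("truth table must have a cell_id column")
    if (!identical(truth$cell_id, data$cells))
      stop("truth table cell_id does not match dataset barcodes")
    utils::write.table(truth, file.path(path, "truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a layered dataset written by \code{\link{write_dataset}}
#'
#' @param path directory containing \code{spliced.mtx}, \code{unspliced.mtx},
#'   \code{barcodes.tsv} and \code{features.tsv}.
#' @return list with \code{counts} (\code{layered_counts}) and \code{truth}
#'   (data.frame or NULL when no \code{truth.tsv} is present).
#' @export
read_dataset <- function(path) {
  need <- c("spliced.mtx", "unspliced.mtx", "barcodes.tsv", "features.tsv")
  miss <- need[!file.exists(file.path(path, need))]
  if (length(miss)) stop("missing dataset files: ", paste(miss, collapse = ", "))
  s <- as_sparse(Matrix::readMM(file.path(path, "spliced.mtx")))
  u <- as_sparse(Matrix::readMM(file.path(path, "unspliced.mtx")))
  cells <- readLines(file.path(path, "barcodes.tsv"))
  feats <- utils::read.table(file.path(path, "features.tsv"), sep = "\t",
                             header = TRUE, stringsAsFactors = FALSE)
  if (nrow(s) != nrow(feats))
    stop("feature count (", nrow(feats), ") does not match matrix rows (",
         nrow(s), ")")
  if (ncol(s) != length(cells))
    stop("barcode count (", length(cells), ") does not match matrix columns (",
         ncol(s), ")")
  if (!identical(dim(s), dim(u)))
    stop("spliced and unspliced matrices have different dimensions")
  dimnames(s) <- dimnames(u) <- list(feats$gene_id, cells)
  counts <- layered_counts(s, u)
  ## the stored mito flag is authoritative over the name pattern
  if ("mito" %in% names(feats)) counts$mito <- as.logical(feats$mito)
  truth <- NULL
  tf <- file.path(path, "truth.tsv")
  if (file.exists(tf))
    truth <- utils::read.table(tf, sep = "\t", header = TRUE,
                               stringsAsFactors = FALSE)
  list(counts = counts, truth = truth)
}
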