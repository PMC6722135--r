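#' Layered spliced/unspliced count container
#'
#' Holds a genes x cells pair of count matrices (spliced and unspliced) with a
#' shared gene and cell ordering, plus a flag marking mitochondrial genes.
#' This is the raw input of the whole pipeline; both layers are stored as
#' sparse \code{dgCMatrix}.
#'
#' @param spliced genes x cells matrix of non-negative integer counts
#'   (mature transcripts).
#' @param unspliced genes x cells matrix with identical dimnames
#'   (intronic/nascent transcripts).
#' @param mito_pattern regular expression identifying mitochondrial genes by
#'   name (default \code{"^mt-"}, the mouse convention).
#' @return An object of class \code{layered_counts} with elements
#'   \code{spliced}, \code{unspliced}, \code{genes}, \code{cells},
#'   \code{mito} (logical per gene).
#' @export
layered_counts <- function(spliced, unspliced, mito_pattern = "^mt-") {
  spliced <- as_sparse(spliced)
  unspliced <- as_sparse(unspliced)
  if (!identical(dim(spliced), dim(unspliced)))
    stop("spliced and unspliced layers have different dimensions")
  if (ncol(spliced) == 0L) stop("layered_counts requires at least one cell")
  if (nrow(spliced) == 0L) stop("layered_counts requires at least one gene")
  if (is.null(rownames(spliced)) || is.null(colnames(spliced)))
    stop("layers must carry gene (row) and cell (column) names")
  if (!identical(dimnames(spliced), dimnames(unspliced)))
    stop("layers must share identical gene and cell ordering")
  check_counts(spliced, "spliced")
  check_counts(unspliced, "unspliced")
  structure(
    list(
      spliced = spliced,
      unspliced = unspliced,
      genes = rownames(spliced),
      cells = colnames(spliced),
      mito = grepl(mito_pattern, rownames(spliced)),
      mito_pattern = mito_pattern
    ),
    class = "layered_counts"
  )
}

as_sparse <- function(m) {
  if (inherits(m, "dgCMatrix")) return(m)
  methods::as(methods::as(methods::as(Matrix::Matrix(m, sparse = TRUE),
                                      "dMatrix"), "generalMatrix"), "CsparseMatrix")
}

check_counts <- function(m, layer) {
  x <- m@x
  if (length(x) && (any(x < 0) || any(x != floor(x))))
    stop("layer '", layer, "' contains negative or non-integer entries")
  invisible(TRUE)
}

#' @export
dim.layered_counts <- function(x) dim(x$spliced)

#' @exportS3Method print layered_counts
print.layered_counts <- function(x, ...) {
  cat(sprintf("layered_counts: %d genes x %d cells (%d mitochondrial genes)\n",
              nrow(x$spliced), ncol(x$spliced), sum(x$mito)))
  cat(sprintf("  spliced nnz: %d  unspliced nnz: %d\n",
              length(x$spliced@x), length(x$unspliced@x)))
  invisible(x)
}

#' Subset a layered_counts object
#'
#' @param x a \code{layered_counts} object
#' @param genes,cells index vectors (logical, integer or character); missing
#'   means keep all.
#' @param ... unused
#' @export
subset_layers <- function(x, genes = NULL, cells = NULL, ...) {
  stopifnot(inherits(x, "layered_counts"))
  if (is.null(genes)) genes <- seq_len(nrow(x$spliced))
  if (is.null(cells)) cells <- seq_len(ncol(x$spliced))
  layered_counts(x$spliced[genes, cells, drop = FALSE],
                 x$unspliced[genes, cells, drop = FALSE],
                 mito_pattern = x$mito_pattern)
}
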