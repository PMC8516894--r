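#' Spot-level expression dataset
#'
#' Container for a spot x gene count matrix together with the array
#' coordinates and the section / patient labels of every spot. Counts are
#' stored sparse (\code{\link[Matrix]{dgCMatrix}}) with spots as rows.
#'
#' @param counts spot x gene matrix of non-negative integer counts; row names
#'   are spot identifiers, column names gene identifiers. Dense matrices are
#'   converted to sparse storage.
#' @param coordinates data frame with columns \code{spot}, \code{x}, \code{y}
#'   (array coordinates, stored as floating point), and optionally
#'   \code{section} and \code{patient}; one row per spot, same order as
#'   \code{counts}.
#' @param gene_info optional data frame with columns \code{gene} and
#'   \code{biotype}; one row per gene.
#'
#' @return An object of class \code{spot_dataset}: a list with elements
#'   \code{counts}, \code{spots} (the coordinate/label table) and
#'   \code{genes}.
#' @export
spot_dataset <- function(counts, coordinates, gene_info = NULL) {
  orig_dn <- dimnames(counts)
  counts <- Matrix::Matrix(counts, sparse = TRUE)
  counts <- methods::as(methods::as(methods::as(counts, "dMatrix"),
                                    "generalMatrix"), "CsparseMatrix")
  if (is.null(dimnames(counts)) && !is.null(orig_dn)) dimnames(counts) <- orig_dn
  if (nrow(counts) > 0 && is.null(rownames(counts)))
    stop("counts must carry spot row names")
  if (ncol(counts) > 0 && is.null(colnames(counts)))
    stop("counts must carry gene column names")
  dimnames(counts) <- list(rownames(counts) %||% character(0),
                           colnames(counts) %||% character(0))
  if (anyDuplicated(rownames(counts))) stop("duplicate spot identifiers")
  if (anyDuplicated(colnames(counts))) stop("duplicate gene identifiers")
  if (any(counts@x < 0)) stop("counts must be non-negative")

  coordinates <- as.data.frame(coordinates)
  req <- c("spot", "x", "y")
  if (!all(req %in% names(coordinates)))
    stop("coordinates must have columns spot, x, y")
  if (!"section" %in% names(coordinates))
    coordinates$section <- rep_len("section1", nrow(coordinates))
  if (!"patient" %in% names(coordinates))
    coordinates$patient <- rep_len("patient1", nrow(coordinates))
  coordinates <- coordinates[, c("spot", "x", "y", "section", "patient")]
  coordinates$x <- as.numeric(coordinates$x)
  coordinates$y <- as.numeric(coordinates$y)
  if (!identical(as.character(coordinates$spot),
                 rownames(counts) %||% character(0)))
    stop("coordinate table must list the same spots, in the same order, as the count matrix")
  dup <- duplicated(coordinates[, c("section", "x", "y")])
  if (any(dup))
    stop("duplicate coordinates within a section: ", coordinates$spot[which(dup)[1]])

  if (is.null(gene_info)) {
    gene_info <- data.frame(gene = colnames(counts),
                            biotype = NA_character_,
                            stringsAsFactors = FALSE)
  } else {
    gene_info <- as.data.frame(gene_info)
    if (!all(c("gene", "biotype") %in% names(gene_info)))
      stop("gene_info must have columns gene, biotype")
    if (!identical(as.character(gene_info$gene),
                   colnames(counts) %||% character(0)))
      stop("gene_info must list the same genes, in the same order, as the count matrix")
  }
  rownames(coordinates) <- NULL
  rownames(gene_info) <- NULL
  structure(list(counts = counts, spots = coordinates, genes = gene_info),
            class = "spot_dataset")
}

#' @export
print.spot_dataset <- function(x, ...) {
  cat(sprintf("spot_dataset: %d spots x %d genes\n", nrow(x$counts), ncol(x$counts)))
  cat(sprintf("  sections: %s\n", paste(unique(x$spots$section), collapse = ", ")))
  cat(sprintf("  patients: %s\n", paste(unique(x$spots$patient), collapse = ", ")))
  invisible(x)
}

#' @export
dim.spot_dataset <- function(x) dim(x$counts)

# subset a spot_dataset by spot and/or gene index, keeping tables aligned
subset_dataset <- function(dataset, spots = NULL, genes = NULL) {
  if (!is.null(spots)) {
    dataset$counts <- dataset$counts[spots, , drop = FALSE]
    dataset$spots <- dataset$spots[spots, , drop = FALSE]
    rownames(dataset$spots) <- NULL
  }
  if (!is.null(genes)) {
    dataset$counts <- dataset$counts[, genes, drop = FALSE]
    dataset$genes <- dataset$genes[genes, , drop = FALSE]
    rownames(dataset$genes) <- NULL
  }
  dataset
}
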