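# Neighbor graph construction and the spatial-lag autocorrelation filter.

#' Build the spot adjacency graph
#'
#' Two spots are adjacent iff they lie on the same section and their
#' Manhattan distance in array units falls within
#' \code{[1 - tolerance, 1 + tolerance]} — the orthogonal (rook)
#' 4-neighborhood on a regular grid, with the tolerance absorbing small
#' fractional alignment offsets. Edges never cross sections.
#'
#' @param dataset a \code{\link{spot_dataset}} (coordinates required).
#' @param tolerance half-width of the accepted distance band.
#' @return a \code{neighbor_graph}: sparse symmetric spot x spot adjacency
#'   matrix (\code{Matrix::sparseMatrix}) with an \code{adjacency} attribute
#'   describing the rule.
#' @export
build_neighbor_graph <- function(dataset, tolerance = 0.5) {
  stopifnot(inherits(dataset, "spot_dataset"))
  sp <- dataset$spots
  dup <- duplicated(sp[, c("section", "x", "y")])
  if (any(dup)) stop("duplicate coordinates within a section")
  n <- nrow(sp)
  ii <- integer(); jj <- integer()
  for (sec in unique(sp$section)) {
    idx <- which(sp$section == sec)
    if (length(idx) < 2) next
    x <- sp$x[idx]; y <- sp$y[idx]
    d <- abs(outer(x, x, "-")) + abs(outer(y, y, "-"))
    hit <- which(d >= 1 - tolerance & d <= 1 + tolerance, arr.ind = TRUE)
    hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
    ii <- c(ii, idx[hit[, 1]]); jj <- c(jj, idx[hit[, 2]])
  }
  adj <- Matrix::sparseMatrix(i = c(ii, jj), j = c(jj, ii), x = 1,
                              dims = c(n, n),
                              dimnames = list(sp$spot, sp$spot))
  structure(list(adjacency = adj,
                 rule = sprintf("manhattan distance in [%g, %g], per section",
                                1 - tolerance, 1 + tolerance)),
            class = "neighbor_graph")
}

#' @export
print.neighbor_graph <- function(x, ...) {
  cat(sprintf("neighbor_graph: %d spots, %d edges (%s)\n",
              nrow(x$adjacency), Matrix::nnzero(x$adjacency) / 2, x$rule))
  invisible(x)
}

#' Spatial-lag autocorrelation gene filter
#'
#' For each gene, the spatial lag at a spot is the summed expression over
#' the spot's adjacent neighbors (no averaging; boundary spots simply use
#' the neighbors they have). The gene's spatial autocorrelation is the
#' Pearson correlation between its expression vector and its lag vector,
#' pooled over all spots. Genes with correlation strictly greater than
#' \code{r_min} are kept. Genes whose expression or lag vector has zero
#' variance have undefined correlation and are excluded with a message.
#'
#' @param x a \code{\link{spot_dataset}}, a \code{normalized_matrix}, or a
#'   spot x gene matrix.
#' @param graph a \code{\link{build_neighbor_graph}} result covering the
#'   matrix's spots.
#' @param r_min correlation cutoff (exclusive).
#' @return data frame with columns \code{gene}, \code{r}, \code{kept}.
#' @export
spatial_autocorrelation <- function(x, graph, r_min = 0.1) {
  m <- if (inherits(x, "spot_dataset")) x$counts
       else if (inherits(x, "normalized_matrix")) x$values
       else x
  stopifnot(inherits(graph, "neighbor_graph"))
  if (!identical(rownames(m), rownames(graph$adjacency)))
    stop("neighbor graph must cover the matrix spots, in the same order")
  lag <- as.matrix(graph$adjacency %*% m)
  m <- as.matrix(m)
  sd_e <- col_sds(m)
  sd_l <- col_sds(lag)
  ok <- sd_e > 0 & sd_l > 0
  r <- rep(NA_real_, ncol(m))
  if (any(ok)) {
    em <- scale(m[, ok, drop = FALSE], scale = FALSE)
    lm_ <- scale(lag[, ok, drop = FALSE], scale = FALSE)
    r[ok] <- colSums(em * lm_) / ((nrow(m) - 1) * sd_e[ok] * sd_l[ok])
  }
  if (any(!ok))
    message(sprintf("%d gene(s) with zero expression or lag variance excluded", sum(!ok)))
  data.frame(gene = colnames(m), r = r,
             kept = !is.na(r) & r > r_min,
             stringsAsFactors = FALSE)
}
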