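# Spot-wise gene-set enrichment via a two-sided Fisher's exact test on the
# top-ranked genes of each spot.

# two-sided Fisher p for the 2x2 table with margins (m = |Q|, n_other,
# k = n_top) and observed overlap x, using the minimum-likelihood
# convention: sum the probabilities of all overlap values whose
# hypergeometric probability does not exceed the observed one (within a
# small relative tolerance, as in stats::fisher.test)
fisher_two_sided <- function(x, m, n_other, k) {
  lo <- max(0L, k - n_other)
  hi <- min(k, m)
  support <- lo:hi
  d <- stats::dhyper(support, m, n_other, k)
  sum(d[d <= d[x - lo + 1L] * (1 + 1e-7)])
}

#' Spot-wise pathway enrichment
#'
#' Expression is gene-centered (each gene's mean across the spots of the
#' matrix as passed is subtracted); within each spot the genes are ranked
#' by adjusted expression from highest to lowest (ties broken by gene
#' identifier) and the top \code{n_top} genes form the spot's top set. For
#' each spot a 2 x 2 contingency table partitions the gene universe G by
#' (top-ranked vs lower-ranked) x (in the gene set vs not), and a two-sided
#' Fisher's exact test gives the probability \eqn{p(s)} of the observed
#' partition under no association. The enrichment score is
#' \eqn{E_p(s) = -\log_2 p(s)}. No multiple-testing adjustment is applied:
#' a single hypothesis is tested per spot.
#'
#' Because the table margins are identical across spots, \eqn{p} only
#' depends on the overlap count, which is computed once per possible value.
#'
#' @param x a \code{\link{spot_dataset}}, \code{normalized_matrix}, or
#'   spot x gene matrix.
#' @param gene_set character vector of pathway genes; members absent from
#'   the matrix are dropped (count messaged).
#' @param n_top number of top-ranked genes per spot.
#' @return an \code{enrichment_map} data frame: \code{spot},
#'   \code{overlap}, \code{p}, \code{score}; parameters in attributes.
#' @export
spotwise_enrichment <- function(x, gene_set, n_top = 100) {
  m0 <- if (inherits(x, "spot_dataset")) as.matrix(x$counts)
        else if (inherits(x, "normalized_matrix")) x$values
        else as.matrix(x)
  genes <- colnames(m0)
  if (is.null(genes)) stop("expression matrix must have gene column names")
  q <- unique(as.character(gene_set))
  absent <- setdiff(q, genes)
  if (length(absent))
    message(sprintf("%d gene-set member(s) absent from the matrix dropped", length(absent)))
  q <- intersect(q, genes)
  if (!length(q)) stop("empty effective gene set: no members present in the matrix")
  n_genes <- length(genes)
  if (!(n_top > 0 && n_top < n_genes))
    stop("n_top must satisfy 0 < n_top < number of genes")

  centered <- sweep(m0, 2, colMeans(m0), "-")
  in_set <- genes %in% q
  # per spot: order by adjusted expression desc, gene id ascending on ties
  gene_order <- order(genes)
  overlap <- integer(nrow(centered))
  for (s in seq_len(nrow(centered))) {
    v <- centered[s, ]
    top <- gene_order[order(-v[gene_order], method = "radix")][seq_len(n_top)]
    overlap[s] <- sum(in_set[top])
  }
  m <- length(q)
  n_other <- n_genes - m
  p_by_overlap <- vapply(0:min(n_top, m), function(k2) {
    if (k2 < max(0L, n_top - n_other)) NA_real_
    else fisher_two_sided(k2, m, n_other, n_top)
  }, numeric(1))
  p <- p_by_overlap[overlap + 1L]
  out <- data.frame(spot = rownames(m0) %||% seq_len(nrow(m0)),
                    overlap = overlap, p = p, score = -log2(p),
                    stringsAsFactors = FALSE)
  attr(out, "n_top") <- n_top
  attr(out, "universe_size") <- n_genes
  attr(out, "set_size") <- m
  class(out) <- c("enrichment_map", "data.frame")
  out
}

#' Read gene sets from a GMT file
#'
#' Standard tab-separated GMT: one set per line — name, description, then
#' member genes.
#'
#' @param path GMT file path.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) stop("malformed GMT line: ", substr(l, 1, 40))
    unique(parts[-(1:2)])
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], "", USE.NAMES = FALSE)
  sets
}
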