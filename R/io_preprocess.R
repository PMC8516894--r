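# On-disk formats and the pre-processing filters.
#
# A dataset directory holds:
#   counts.mtx       sparse matrix-market counts (spots x genes)
#   genes.tsv        gene, biotype
#   spots.tsv        spot, x, y, section, patient
# Sidecar tables (proportions, annotations, marker statistics) are plain TSV
# with a header row.

#' Write a spot dataset to a directory
#'
#' Counts are written as sparse matrix-market with gene and spot sidecar
#' tables, so that \code{\link{read_spot_dataset}} round-trips the object
#' losslessly.
#'
#' @param dataset a \code{\link{spot_dataset}}.
#' @param path directory to write into (created if missing).
#' @return \code{path}, invisibly.
#' @export
write_spot_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "spot_dataset"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(dataset$counts, file.path(path, "counts.mtx"))
  utils::write.table(dataset$genes, file.path(path, "genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$spots, file.path(path, "spots.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a spot dataset from a directory
#'
#' @param path directory written by \code{\link{write_spot_dataset}}.
#' @return a \code{\link{spot_dataset}}.
#' @export
read_spot_dataset <- function(path) {
  mtx <- file.path(path, "counts.mtx")
  gf <- file.path(path, "genes.tsv")
  sf <- file.path(path, "spots.tsv")
  for (f in c(mtx, gf, sf))
    if (!file.exists(f)) stop("missing dataset file: ", f)
  counts <- methods::as(Matrix::readMM(mtx), "CsparseMatrix")
  genes <- utils::read.delim(gf, colClasses = "character")
  spots <- utils::read.delim(sf,
    colClasses = c(spot = "character", x = "numeric", y = "numeric",
                   section = "character", patient = "character"))
  if (nrow(genes) != ncol(counts))
    stop(sprintf("format error in %s: %d genes listed but matrix has %d columns",
                 gf, nrow(genes), ncol(counts)))
  if (nrow(spots) != nrow(counts))
    stop(sprintf("format error in %s: %d spots listed but matrix has %d rows",
                 sf, nrow(spots), nrow(counts)))
  dimnames(counts) <- list(spots$spot, genes$gene)
  genes$biotype[genes$biotype == "NA"] <- NA_character_
  spot_dataset(counts, spots, genes)
}

#' Write / read a spot annotation or proportion sidecar table
#'
#' Sidecars are TSV tables keyed by a \code{spot} column; reading validates
#' that every listed spot exists in the dataset.
#'
#' @param table data frame with a \code{spot} column.
#' @param path file path.
#' @param dataset optional \code{\link{spot_dataset}} used to validate spot
#'   identifiers on read.
#' @return the table (read) or \code{path} invisibly (write).
#' @export
write_sidecar <- function(table, path) {
  stopifnot("spot" %in% names(table))
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sidecar
#' @export
read_sidecar <- function(path, dataset = NULL) {
  tab <- utils::read.delim(path, colClasses = c(spot = "character"))
  if (!is.null(dataset)) {
    unknown <- setdiff(tab$spot, dataset$spots$spot)
    if (length(unknown))
      stop(sprintf("format error in %s: unknown spot id '%s'", path, unknown[1]))
  }
  tab
}

#' Default biotypes retained by the gene filter
#' @export
default_biotypes <- function() {
  c("protein_coding", "IG_C_gene", "IG_J_gene", "IG_V_gene",
    "TR_C_gene", "TR_J_gene", "TR_V_gene")
}

#' Gene-level filtering
#'
#' Retains genes that (i) match one of the requested biotypes (skipped when
#' \code{keep_biotypes} is \code{NULL}), (ii) are not ribosomal
#' (\code{RPL}/\code{RPS} prefix), mitochondrial (\code{MT-} prefix, hyphen
#' required) or \code{MTRNR} genes, (iii) are not on the user-supplied
#' exclusion list (e.g. known technical-artifact genes), and (iv) are
#' expressed (count > 0) in at least \code{min_spots} spots. Prefix matching
#' is case-sensitive on official symbols. Expression support is evaluated on
#' the spot set as passed in, before any spot filtering.
#'
#' @param dataset a \code{\link{spot_dataset}}.
#' @param keep_biotypes character vector of biotypes to keep, or \code{NULL}
#'   to skip the biotype rule.
#' @param exclusion_list character vector of gene identifiers to drop.
#' @param min_spots minimum number of spots a gene must be expressed in.
#' @return the filtered \code{spot_dataset}.
#' @export
apply_gene_filters <- function(dataset,
                               keep_biotypes = default_biotypes(),
                               exclusion_list = character(),
                               min_spots = 10) {
  stopifnot(inherits(dataset, "spot_dataset"))
  g <- dataset$genes$gene
  keep <- rep(TRUE, length(g))
  if (!is.null(keep_biotypes) && length(keep_biotypes)) {
    if (all(is.na(dataset$genes$biotype)))
      stop("biotype annotation required when keep_biotypes is non-empty")
    keep <- keep & dataset$genes$biotype %in% keep_biotypes
  }
  keep <- keep & !grepl("^(RPL|RPS|MT-|MTRNR)", g)
  keep <- keep & !(g %in% exclusion_list)
  support <- Matrix::colSums(dataset$counts > 0)
  keep <- keep & support >= min_spots
  subset_dataset(dataset, genes = which(keep))
}

#' Spot-level filtering
#'
#' Removes spots with fewer than \code{min_genes} expressed genes
#' (count > 0).
#'
#' @param dataset a \code{\link{spot_dataset}}.
#' @param min_genes minimum number of unique expressed genes per spot.
#' @return the filtered \code{spot_dataset}.
#' @export
apply_spot_filter <- function(dataset, min_genes = 300) {
  stopifnot(inherits(dataset, "spot_dataset"))
  n_feat <- Matrix::rowSums(dataset$counts > 0)
  keep <- n_feat >= min_genes
  if (!any(keep)) warning("all spots fall below the feature threshold; empty dataset returned")
  subset_dataset(dataset, spots = which(keep))
}

#' Library-size and gene-dispersion normalization
#'
#' Two-step normalization used before linear modelling: each spot's
#' expression vector is divided by its library size (sum over genes), then
#' each gene's vector is divided by its sample standard deviation computed
#' after the library-size step, so every retained gene has unit standard
#' deviation. Genes whose post-library-size variance is zero are dropped
#' with a warning.
#'
#' @param x a \code{\link{spot_dataset}} or a dense spot x gene matrix of
#'   non-negative values with dimnames.
#' @return a \code{normalized_matrix}: list with dense \code{values}
#'   (spot x gene) and a \code{normalization} tag.
#' @export
normalize_libsize_sd <- function(x) {
  m <- if (inherits(x, "spot_dataset")) x$counts else x
  m <- as.matrix(m)
  if (nrow(m) < 2L) stop("at least 2 spots required: gene standard deviation undefined")
  libsize <- rowSums(m)
  if (any(libsize <= 0)) stop("every spot must have library size > 0")
  m <- m / libsize
  sds <- col_sds(m)
  zero <- sds <= 0 | !is.finite(sds)
  if (any(zero)) {
    warning(sprintf("dropping %d gene(s) with zero variance after library-size scaling", sum(zero)))
    m <- m[, !zero, drop = FALSE]
    sds <- sds[!zero]
  }
  if (!ncol(m)) stop("no genes left after dropping zero-variance genes")
  m <- sweep(m, 2, sds, "/")
  structure(list(values = m, normalization = "libsize_sd"),
            class = "normalized_matrix")
}

#' Gene-wise mean centering
#'
#' Subtracts each gene's average expression across the spots of the matrix
#' as passed in; used to rank genes within spots for spot-wise pathway
#' enrichment.
#'
#' @inheritParams normalize_libsize_sd
#' @return a \code{normalized_matrix} with tag \code{"mean_centered"}.
#' @export
center_genes <- function(x) {
  m <- if (inherits(x, "spot_dataset")) x$counts else x
  m <- as.matrix(m)
  m <- sweep(m, 2, colMeans(m), "-")
  structure(list(values = m, normalization = "mean_centered"),
            class = "normalized_matrix")
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat(sprintf("normalized_matrix [%s]: %d spots x %d genes\n",
              x$normalization, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Filter a marker statistics table into per-cluster marker sets
#'
#' Keeps, per cluster, the genes with adjusted p-value strictly below
#' \code{max_padj} and average natural-log fold change strictly above
#' \code{min_lnfc}; the fold-change rule discards down-regulated genes.
#'
#' @param table data frame with columns \code{cluster}, \code{gene},
#'   \code{p_adj}, \code{ln_fc}; typically the output of a per-cluster
#'   differential expression test.
#' @param max_padj adjusted p-value cutoff (exclusive).
#' @param min_lnfc natural-log fold-change cutoff (exclusive).
#' @return a \code{marker_gene_sets} object: named list of character vectors
#'   (cluster id -> marker genes), with a \code{patients} attribute when the
#'   table carries a \code{patient} column.
#' @export
filter_markers <- function(table, max_padj = 0.01, min_lnfc = 0.15) {
  table <- as.data.frame(table)
  req <- c("cluster", "gene", "p_adj", "ln_fc")
  if (!all(req %in% names(table)))
    stop("marker table must have columns cluster, gene, p_adj, ln_fc")
  if (nrow(table) && (any(table$p_adj < 0) || any(table$p_adj > 1)))
    stop("adjusted p-values must lie in [0, 1]")
  keep <- table$p_adj < max_padj & table$ln_fc > min_lnfc
  kept <- table[keep, , drop = FALSE]
  clusters <- unique(as.character(table$cluster))
  sets <- lapply(clusters, function(cl)
    unique(as.character(kept$gene[as.character(kept$cluster) == cl])))
  names(sets) <- clusters
  patients <- NULL
  if ("patient" %in% names(table))
    patients <- vapply(clusters, function(cl)
      as.character(table$patient[as.character(table$cluster) == cl][1]), "")
  marker_gene_sets(sets, patients)
}

#' Construct a marker gene set collection
#'
#' @param sets named list: cluster id -> character vector of marker genes.
#' @param patients optional named character vector giving the originating
#'   patient of each cluster.
#' @return a \code{marker_gene_sets} object.
#' @export
marker_gene_sets <- function(sets, patients = NULL) {
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stop("cluster ids must be unique and named")
  sets <- lapply(sets, function(s) unique(as.character(s)))
  structure(sets, patients = patients, class = "marker_gene_sets")
}

#' @export
print.marker_gene_sets <- function(x, ...) {
  cat(sprintf("marker_gene_sets: %d clusters, %d genes total\n",
              length(x), length(unique(unlist(x)))))
  invisible(x)
}
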