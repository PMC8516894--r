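# Cross-sample comparison of cluster marker sets and shared core signatures.

#' Pairwise Jaccard similarity of marker gene sets
#'
#' \eqn{J(A, B) = |A \cap B| / |A \cup B|}; the Jaccard index of two empty
#' sets is defined as 0 (with a message). The diagonal is 1 for non-empty
#' sets.
#'
#' @param sets a \code{\link{marker_gene_sets}} object or a named list of
#'   character vectors.
#' @return symmetric cluster x cluster similarity matrix.
#' @export
jaccard_matrix <- function(sets) {
  if (!inherits(sets, "marker_gene_sets")) sets <- marker_gene_sets(sets)
  k <- length(sets)
  if (k < 2) stop("at least 2 clusters required")
  ids <- names(sets)
  # deterministic ordering regardless of input order
  ord <- order(ids)
  sets <- sets[ord]; ids <- ids[ord]
  genes <- unique(unlist(sets))
  mem <- vapply(sets, function(s) genes %in% s,
                logical(length(genes)))
  mem <- matrix(mem, nrow = length(genes))
  sizes <- colSums(mem)
  inter <- crossprod(mem)
  uni <- outer(sizes, sizes, "+") - inter
  j <- ifelse(uni > 0, inter / uni, 0)
  if (any(uni == 0)) message("empty set pair(s): Jaccard defined as 0")
  diag(j) <- ifelse(sizes > 0, 1, 0)
  dimnames(j) <- list(ids, ids)
  j
}

#' Group clusters across samples and extract shared core signatures
#'
#' Each cluster's row of the pairwise Jaccard similarity matrix serves as
#' its feature vector; Euclidean distances between these rows feed a
#' complete-linkage agglomerative dendrogram, which is cut into \code{k}
#' groups. A group is robust iff at least one gene is shared between at
#' least two of its member clusters (set \code{robust_rule = "all"} to
#' require a gene shared by every member instead). For robust groups the
#' core signature is the set of genes present in at least
#' \code{core_fraction} of the member clusters' sets (ties at exactly the
#' fraction included).
#'
#' @param sets a \code{\link{marker_gene_sets}} object or named list.
#' @param k number of groups to cut the dendrogram into.
#' @param core_fraction minimum fraction of member clusters a core gene
#'   must appear in.
#' @param robust_rule \code{"pair"} (default: a gene shared by >= 2
#'   members) or \code{"all"} (a gene shared by all members).
#' @return a \code{signature_groups} object: list with \code{groups}
#'   (data frame of cluster, group), \code{robust} (named logical),
#'   \code{cores} (named list of core gene vectors for robust groups) and
#'   the \code{jaccard} matrix used.
#' @export
extract_core_signatures <- function(sets, k = 5, core_fraction = 0.8,
                                    robust_rule = c("pair", "all")) {
  robust_rule <- match.arg(robust_rule)
  if (!inherits(sets, "marker_gene_sets")) sets <- marker_gene_sets(sets)
  if (k > length(sets))
    stop(sprintf("k (%d) exceeds the number of clusters (%d)", k, length(sets)))
  jac <- jaccard_matrix(sets)
  d <- stats::dist(jac, method = "euclidean")
  hc <- stats::hclust(d, method = "complete")
  grp <- stats::cutree(hc, k = k)
  groups <- split(names(grp), grp)
  names(groups) <- paste0("group", names(groups))

  robust <- logical(length(groups)); names(robust) <- names(groups)
  cores <- list()
  for (gn in names(groups)) {
    members <- groups[[gn]]
    msets <- sets[members]
    counts <- table(unlist(msets))
    shared <- if (robust_rule == "pair") {
      names(counts)[counts >= 2]
    } else {
      names(counts)[counts == length(members)]
    }
    robust[gn] <- length(members) >= 2 && length(shared) > 0
    if (robust[gn]) {
      need <- core_fraction * length(members)
      core <- names(counts)[counts >= need - 1e-9]
      cores[[gn]] <- sort(core)
    }
  }
  structure(list(groups = data.frame(
                   cluster = unlist(groups, use.names = FALSE),
                   group = rep(names(groups), lengths(groups)),
                   stringsAsFactors = FALSE),
                 robust = robust, cores = cores, jaccard = jac,
                 k = k, core_fraction = core_fraction),
            class = "signature_groups")
}

#' @export
print.signature_groups <- function(x, ...) {
  cat(sprintf("signature_groups: %d clusters in %d groups (%d robust)\n",
              nrow(x$groups), x$k, sum(x$robust)))
  for (gn in names(x$cores))
    cat(sprintf("  %s core: %d genes\n", gn, length(x$cores[[gn]])))
  invisible(x)
}
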