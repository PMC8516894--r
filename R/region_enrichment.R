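# Permutation-based enrichment / depletion of cell types within regions.

#' Region-wise cell-type enrichment scores
#'
#' For each (region, cell type): the true average proportion within the
#' region is compared with a permutation null obtained by shuffling the
#' spot indices of the proportion matrix while keeping the region labels
#' fixed (one global permutation per iteration, all types shuffled jointly,
#' so within-spot composition is preserved). The enrichment score is the
#' mean of the differences (true average minus permuted average) divided by
#' the standard deviation of those differences; positive scores indicate
#' enrichment, negative depletion. Spots without a region label are
#' excluded before permutation. Cells with zero permutation variance (e.g.
#' constant proportions) yield undefined scores, reported as \code{NA} with
#' a warning.
#'
#' @param props spot x cell-type proportion matrix (rows sum to 1); row
#'   names are spot ids.
#' @param regions named character vector or data frame
#'   (\code{spot}, \code{region}) mapping spots to region labels.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return an \code{enrichment_scores} object: list with \code{scores},
#'   \code{true_average} and \code{perm_mean} matrices (region x type) and
#'   a long-format \code{table}.
#' @export
enrichment_scores <- function(props, regions, n_perm = 10000, seed = 1) {
  props <- check_proportions(props)
  if (is.data.frame(regions)) {
    stopifnot(all(c("spot", "region") %in% names(regions)))
    regions <- stats::setNames(as.character(regions$region), regions$spot)
  }
  if (is.null(names(regions))) {
    if (length(regions) != nrow(props))
      stop("unnamed region vector must have one label per spot")
    names(regions) <- rownames(props)
  }
  unknown <- setdiff(names(regions), rownames(props))
  if (length(unknown))
    stop("region annotation references unknown spot: ", unknown[1])
  keep <- rownames(props) %in% names(regions)
  props <- props[keep, , drop = FALSE]
  lab <- factor(regions[rownames(props)])
  if (nlevels(lab) < 2) stop("at least 2 regions required")

  n <- nrow(props)
  counts <- as.integer(table(lab))
  true_avg <- rowsum(props, lab) / counts

  set.seed(seed)
  diffs <- array(0, dim = c(nlevels(lab), ncol(props), n_perm))
  for (p in seq_len(n_perm)) {
    idx <- sample.int(n)
    diffs[, , p] <- true_avg - rowsum(props[idx, , drop = FALSE], lab) / counts
  }
  mean_d <- apply(diffs, c(1, 2), mean)
  sd_d <- apply(diffs, c(1, 2), stats::sd)
  score <- ifelse(sd_d > 0, mean_d / sd_d, NA_real_)
  if (anyNA(score))
    warning(sprintf("%d (region, type) score(s) undefined: zero permutation variance",
                    sum(is.na(score))))
  dimnames(score) <- list(levels(lab), colnames(props))
  dimnames(true_avg) <- dimnames(score)
  perm_mean <- true_avg - mean_d
  dimnames(perm_mean) <- dimnames(score)

  tab <- data.frame(region = rep(rownames(score), ncol(score)),
                    cell_type = rep(colnames(score), each = nrow(score)),
                    score = as.numeric(score),
                    true_average = as.numeric(true_avg),
                    perm_mean = as.numeric(perm_mean),
                    stringsAsFactors = FALSE)
  structure(list(scores = score, true_average = true_avg,
                 perm_mean = perm_mean, table = tab,
                 n_perm = n_perm, seed = seed),
            class = "enrichment_scores")
}

#' @export
print.enrichment_scores <- function(x, ...) {
  cat(sprintf("enrichment_scores: %d regions x %d cell types (%d permutations)\n",
              nrow(x$scores), ncol(x$scores), x$n_perm))
  print(round(x$scores, 2))
  invisible(x)
}
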