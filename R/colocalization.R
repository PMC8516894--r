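# Pairwise cell-type colocalization with bootstrap confidence intervals,
# per-spot diversity entropy, and joint cell-state scores.

# validate a spot x cell-type proportion matrix
check_proportions <- function(props, tol = 1e-6) {
  props <- as.matrix(props)
  if (is.null(colnames(props)))
    colnames(props) <- paste0("type", seq_len(ncol(props)))
  if (any(props < 0)) stop("proportions must be non-negative")
  rs <- rowSums(props)
  if (any(abs(rs - 1) > tol))
    stop(sprintf("proportion rows must sum to 1 (max deviation %.3g)", max(abs(rs - 1))))
  props
}

#' Bootstrap cell-type colocalization
#'
#' Spot-wise Pearson correlation between each pair of cell types' proportion
#' vectors is used as a proxy for colocalization. Confidence intervals come
#' from resampling spots with replacement: the same resample indices are
#' shared across all pairs within one bootstrap iteration, each iteration
#' recomputes every pairwise correlation, the bootstrap mean is reported as
#' the representative correlation and the 2.5th/97.5th percentiles form the
#' 95\% confidence interval. A pair is significant iff its interval excludes
#' zero. Types with zero variance across spots have undefined correlations
#' and are reported as missing with a warning; bootstrap resamples in which
#' a type degenerates to zero variance are skipped for the affected pairs
#' and counted.
#'
#' @param props spot x cell-type proportion matrix (rows sum to 1).
#' @param n_boot number of bootstrap resamples.
#' @param seed integer seed for the resampling stream.
#' @param conf confidence level of the percentile interval.
#' @return a \code{colocalization_matrix}: list with \code{pairs} (data
#'   frame: u, v, r (plug-in), boot_mean, ci_low, ci_high, significant,
#'   n_skipped), plus square matrices \code{r}, \code{boot_mean} and
#'   \code{significant}.
#' @export
bootstrap_correlation <- function(props, n_boot = 10000, seed = 1, conf = 0.95) {
  props <- check_proportions(props)
  n <- nrow(props)
  if (n < 3) stop("at least 3 spots required")
  z <- colnames(props)
  sds <- col_sds(props)
  degenerate <- sds == 0
  if (any(degenerate))
    warning(sprintf("type(s) with zero variance: %s; correlations undefined",
                    paste(z[degenerate], collapse = ", ")))

  point <- suppressWarnings(stats::cor(props))
  point[degenerate, ] <- NA; point[, degenerate] <- NA
  diag(point)[!degenerate] <- 1

  set.seed(seed)
  k <- length(z)
  pair_idx <- which(upper.tri(point), arr.ind = TRUE)
  boot <- array(NA_real_, dim = c(n_boot, nrow(pair_idx)))
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    rb <- suppressWarnings(stats::cor(props[idx, , drop = FALSE]))
    boot[b, ] <- rb[pair_idx]
  }

  alpha <- (1 - conf) / 2
  pairs <- data.frame(u = z[pair_idx[, 1]], v = z[pair_idx[, 2]],
                      r = point[pair_idx],
                      boot_mean = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                      significant = NA, n_skipped = 0L,
                      stringsAsFactors = FALSE)
  bm <- matrix(NA_real_, k, k, dimnames = list(z, z))
  sig <- matrix(NA, k, k, dimnames = list(z, z))
  for (i in seq_len(nrow(pair_idx))) {
    vals <- boot[, i]
    skipped <- sum(!is.finite(vals))
    vals <- vals[is.finite(vals)]
    pairs$n_skipped[i] <- skipped
    if (!length(vals) || degenerate[pair_idx[i, 1]] || degenerate[pair_idx[i, 2]]) next
    pairs$boot_mean[i] <- mean(vals)
    qq <- stats::quantile(vals, c(alpha, 1 - alpha), names = FALSE)
    pairs$ci_low[i] <- qq[1]; pairs$ci_high[i] <- qq[2]
    pairs$significant[i] <- qq[1] > 0 || qq[2] < 0
    u <- pair_idx[i, 1]; v <- pair_idx[i, 2]
    bm[u, v] <- bm[v, u] <- pairs$boot_mean[i]
    sig[u, v] <- sig[v, u] <- pairs$significant[i]
  }
  diag(bm)[!degenerate] <- 1
  structure(list(pairs = pairs, r = point, boot_mean = bm, significant = sig,
                 n_boot = n_boot, conf = conf, seed = seed),
            class = "colocalization_matrix")
}

#' @export
print.colocalization_matrix <- function(x, ...) {
  cat(sprintf("colocalization_matrix: %d types, %d bootstrap resamples, %d%% CI\n",
              nrow(x$r), x$n_boot, round(100 * x$conf)))
  print(utils::head(x$pairs, 10))
  invisible(x)
}

#' Per-spot cell-type diversity entropy
#'
#' Shannon entropy (bits) of each spot's cell-type proportion vector:
#' \eqn{E_s = -\sum_z p_{sz} \log_2 p_{sz}}, with zero-proportion terms
#' contributing 0. Ranges from 0 (a single dominating type) to
#' \eqn{\log_2 |Z|} (uniform composition).
#'
#' @param props spot x cell-type proportion matrix (rows sum to 1).
#' @return named numeric vector of entropies in bits.
#' @export
spot_entropy <- function(props) {
  props <- check_proportions(props)
  terms <- ifelse(props > 0, props * log2(props), 0)
  -rowSums(terms)
}

#' Joint score of two cell states
#'
#' Within each sample group, the paired proportion values of the two states
#' are multiplied spot-wise and the products are z-transformed (mean
#' subtracted, divided by the standard deviation). High positive scores mark
#' joint presence.
#'
#' @param props spot x cell-type proportion matrix.
#' @param type_u,type_v the two cell states.
#' @param group_by optional factor/vector (one value per spot) defining the
#'   sample groups; default treats all spots as one group.
#' @return named numeric vector of per-spot z-scores.
#' @export
joint_score <- function(props, type_u, type_v, group_by = NULL) {
  props <- check_proportions(props)
  if (!all(c(type_u, type_v) %in% colnames(props)))
    stop("both cell types must be present in the proportion matrix")
  if (is.null(group_by)) group_by <- rep("all", nrow(props))
  if (length(group_by) != nrow(props))
    stop("group_by must have one value per spot")
  prod_ <- props[, type_u] * props[, type_v]
  out <- numeric(length(prod_))
  for (g in unique(group_by)) {
    sel <- group_by == g
    if (sum(sel) < 2) stop(sprintf("group '%s' has fewer than 2 spots", g))
    s <- stats::sd(prod_[sel])
    if (s == 0) {
      warning(sprintf("zero variance of products in group '%s'; scores set to 0", g))
      out[sel] <- 0
    } else {
      out[sel] <- (prod_[sel] - mean(prod_[sel])) / s
    }
  }
  names(out) <- rownames(props)
  out
}
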