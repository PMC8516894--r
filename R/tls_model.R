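# TLS scoring, OLS modelling of the score from expression, gene-signature
# extraction from the ranked coefficient curve, and cross-dataset
# prediction with quintile stratification.

#' Spot-wise TLS score
#'
#' The raw score of a spot is twice the product of its B- and T-cell
#' proportions: under unbiased independent sampling of two cells from the
#' spot's composition, this is the probability that the pair consists of
#' one B and one T cell. The adjusted score subtracts the spot's average
#' probability of picking any distinct-type pair — the mean of
#' \eqn{2 p_u p_v} over all \eqn{C(|Z|, 2)} unordered type pairs, equal to
#' \eqn{(1 - \sum_z p_z^2) / C(|Z|, 2)} — so that spots whose B/T pairing
#' is no more likely than an average pairing score at or below zero. Set
#' \code{include_same_type = TRUE} to average over same-type pairs as well
#' (probability \eqn{p_z^2}), i.e. over all \eqn{C(|Z|+1, 2)} multisets.
#'
#' Proportions should come from the major cell-type tier.
#'
#' @param props spot x cell-type proportion matrix (rows sum to 1).
#' @param b_type,t_type column names of the B- and T-cell types.
#' @param include_same_type include same-type pairs in the pair-probability
#'   average (default \code{FALSE}: distinct-type pairs only).
#' @return a \code{tls_scores} data frame with columns \code{spot},
#'   \code{raw} and \code{adjusted}.
#' @export
tls_score <- function(props, b_type = "B-cells", t_type = "T-cells",
                      include_same_type = FALSE) {
  props <- check_proportions(props)
  z <- ncol(props)
  if (z < 2) stop("at least 2 cell types required")
  if (b_type == t_type) stop("b_type and t_type must differ")
  if (!all(c(b_type, t_type) %in% colnames(props)))
    stop("b_type and t_type must be columns of the proportion matrix")
  raw <- 2 * props[, b_type] * props[, t_type]
  sum_sq <- rowSums(props^2)
  if (include_same_type) {
    # pair probabilities sum to 1 over all C(z+1, 2) multisets, so the
    # average is a constant shift
    avg_pair <- 2 / (z * (z + 1))
  } else {
    avg_pair <- (1 - sum_sq) / choose(z, 2)    # mean over C(z, 2) distinct pairs
  }
  out <- data.frame(spot = rownames(props) %||% seq_len(nrow(props)),
                    raw = raw, adjusted = raw - avg_pair,
                    stringsAsFactors = FALSE)
  attr(out, "b_type") <- b_type
  attr(out, "t_type") <- t_type
  class(out) <- c("tls_scores", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit the linear TLS model by ordinary least squares
#'
#' Models the adjusted TLS score as a linear function of normalized
#' expression, \eqn{y = \beta_0 + \beta^T x}, with no regularization.
#' Expression must be library-size + gene-standard-deviation normalized
#' (\code{\link{normalize_libsize_sd}}). When there are at least as many
#' spots as genes (plus intercept) the usual OLS solution is returned; in
#' the under-determined case (more genes than spots) the minimum-norm
#' least-squares solution is used, with a warning.
#'
#' @param expr a \code{normalized_matrix} with tag \code{"libsize_sd"}, or
#'   a plain spot x gene matrix already so normalized.
#' @param scores a \code{\link{tls_score}} result (the \code{adjusted}
#'   column is modelled) or a numeric vector aligned with the rows of
#'   \code{expr}.
#' @return a \code{tls_model}: list with \code{intercept}, named
#'   \code{coefficients}, \code{fitted}, and the normalization tag.
#' @export
fit_tls_model <- function(expr, scores) {
  norm_tag <- "libsize_sd"
  if (inherits(expr, "normalized_matrix")) {
    norm_tag <- expr$normalization
    expr <- expr$values
  }
  expr <- as.matrix(expr)
  if (!ncol(expr)) stop("empty gene set")
  y <- if (inherits(scores, "tls_scores")) scores$adjusted else as.numeric(scores)
  if (length(y) != nrow(expr)) stop("scores and expression spot sets are not aligned")
  if (nrow(expr) < 2) stop("at least 2 spots required")
  X <- cbind(`(Intercept)` = 1, expr)
  if (nrow(X) >= ncol(X)) {
    fit <- stats::lm.fit(X, y)
    beta <- fit$coefficients
    beta[is.na(beta)] <- 0
  } else {
    warning("more genes than spots: returning the minimum-norm least-squares solution")
    sv <- svd(X)
    pos <- sv$d > max(dim(X)) * .Machine$double.eps * sv$d[1]
    beta <- sv$v[, pos, drop = FALSE] %*%
      ((crossprod(sv$u[, pos, drop = FALSE], y)) / sv$d[pos])
    beta <- stats::setNames(as.numeric(beta), colnames(X))
  }
  structure(list(intercept = unname(beta[1]),
                 coefficients = beta[-1],
                 fitted = as.numeric(X %*% beta),
                 normalization = norm_tag),
            class = "tls_model")
}

#' @export
print.tls_model <- function(x, ...) {
  cat(sprintf("tls_model: intercept %.4g, %d gene coefficients [%s normalization]\n",
              x$intercept, length(x$coefficients), x$normalization))
  invisible(x)
}

#' Extract the gene signature from a fitted TLS model
#'
#' Coefficients are ordered from largest to smallest and treated as a
#' function \eqn{f} of gene rank. The curve is Gaussian-smoothed, its
#' second-order differences (an approximation of \eqn{f''}) are computed
#' and smoothed again with the same filter. Scanning from the top-ranked
#' gene, the threshold is the first rank at which the smoothed second
#' derivative drops below zero after having been non-negative — the first
#' point where the descending curve turns concave, i.e. the end of the
#' initial high-coefficient regime. (A leading negative run is ignored: it
#' is the reflection boundary artifact that any strictly decreasing curve
#' produces at rank one, not a curvature signal.) The signature consists
#' of the genes ranked strictly above (before) the threshold; genes at or
#' past it are excluded. If the smoothed second derivative never turns
#' negative after being non-negative there is no concave bend and hence no
#' defensible cutoff: an error is raised rather than returning all genes.
#'
#' @param model a \code{\link{fit_tls_model}} result, or a named numeric
#'   vector of coefficients.
#' @param sigma standard deviation of the Gaussian smoothing kernel, in
#'   rank units.
#' @return a \code{gene_signature}: list with \code{genes} (the members, in
#'   rank order), \code{threshold_rank}, \code{ranked} (data frame of gene,
#'   rank, coefficient), \code{sigma}.
#' @export
extract_signature <- function(model, sigma = 10) {
  beta <- if (inherits(model, "tls_model")) model$coefficients else model
  if (is.null(names(beta))) stop("coefficients must be named by gene")
  n <- length(beta)
  if (n < 3 * sigma)
    stop(sprintf("need at least %d genes for sigma = %g (got %d): smoothing degenerate",
                 ceiling(3 * sigma), sigma, n))
  ord <- order(beta, decreasing = TRUE, method = "radix")
  f <- unname(beta[ord])
  fs <- gaussian_smooth(f, sigma)
  d2 <- diff(fs, differences = 2)            # f''[rank i] ~ fs[i+1] - 2 fs[i] + fs[i-1]
  d2s <- gaussian_smooth(d2, sigma)
  neg <- d2s < 0
  crossing <- which(neg[-1] & !neg[-length(neg)])  # non-negative -> negative
  if (!length(crossing))
    stop("no threshold found: the smoothed second derivative never drops below zero after being non-negative")
  threshold <- crossing[1] + 2L              # d2s[i] approximates f'' at rank i + 1
  ranked <- data.frame(gene = names(beta)[ord], rank = seq_len(n),
                       coefficient = f, stringsAsFactors = FALSE)
  structure(list(genes = ranked$gene[seq_len(threshold - 1L)],
                 threshold_rank = threshold, ranked = ranked, sigma = sigma),
            class = "gene_signature")
}

#' @export
print.gene_signature <- function(x, ...) {
  cat(sprintf("gene_signature: %d genes (threshold rank %d, sigma %g)\n",
              length(x$genes), x$threshold_rank, x$sigma))
  invisible(x)
}

#' Predict TLS scores on new data and stratify into quintiles
#'
#' The new expression data are normalized within themselves (library size,
#' then per-gene sample standard deviation) and scored with the fitted
#' model over the genes shared with it; model genes absent from the new
#' data are dropped (their count is messaged). Samples are stratified by
#' quintiles of the predicted score: the first, third and fifth quintiles
#' become \code{low}, \code{intermediate} and \code{high}, the second and
#' fourth are \code{unassigned}. Quintile boundaries use the inclusive
#' empirical-quantile convention with ties assigned to the lower stratum.
#'
#' @param model a \code{\link{fit_tls_model}} result.
#' @param new_expr sample x gene matrix of raw counts or bulk expression
#'   (non-negative), or a \code{\link{spot_dataset}}.
#' @param min_overlap minimum fraction of model genes that must be present
#'   in the new data.
#' @return data frame with columns \code{sample}, \code{score},
#'   \code{stratum}.
#' @export
predict_and_stratify <- function(model, new_expr, min_overlap = 0.5) {
  stopifnot(inherits(model, "tls_model"))
  m <- if (inherits(new_expr, "spot_dataset")) as.matrix(new_expr$counts) else as.matrix(new_expr)
  shared <- intersect(names(model$coefficients), colnames(m))
  frac <- length(shared) / length(model$coefficients)
  if (frac < min_overlap)
    stop(sprintf("gene overlap with the model is %.1f%%, below the required %.1f%%",
                 100 * frac, 100 * min_overlap))
  dropped <- length(model$coefficients) - length(shared)
  if (dropped) message(sprintf("%d model gene(s) absent from the new data dropped", dropped))
  norm <- normalize_libsize_sd(m)
  shared <- intersect(shared, colnames(norm$values))
  score <- model$intercept +
    as.numeric(norm$values[, shared, drop = FALSE] %*% model$coefficients[shared])
  q <- stats::quantile(score, probs = seq(0.2, 0.8, by = 0.2), names = FALSE)
  quint <- findInterval(score, q, left.open = TRUE) + 1L  # ties go to the lower stratum
  stratum <- c("low", "unassigned", "intermediate", "unassigned", "high")[quint]
  data.frame(sample = rownames(m) %||% seq_len(nrow(m)),
             score = score, stratum = stratum, stringsAsFactors = FALSE)
}
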