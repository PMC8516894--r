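# Internal helpers shared across modules.

#' Gaussian smoothing of a numeric sequence
#'
#' Convolves a vector with a discrete Gaussian kernel, handling boundaries by
#' half-sample reflection (the sequence is mirrored at each end before the
#' convolution). The kernel is truncated at \code{truncate * sigma} points on
#' each side and renormalised to sum to one.
#'
#' @param x numeric vector.
#' @param sigma standard deviation of the Gaussian kernel, in index units.
#' @param truncate kernel truncation radius in multiples of \code{sigma}.
#' @return numeric vector of the same length as \code{x}.
#' @keywords internal
gaussian_smooth <- function(x, sigma, truncate = 4) {
  stopifnot(is.numeric(x), sigma > 0)
  n <- length(x)
  radius <- as.integer(truncate * sigma + 0.5)
  if (radius == 0L) return(x)
  k <- exp(-0.5 * (seq(-radius, radius) / sigma)^2)
  k <- k / sum(k)
  # half-sample reflection: [d c b a | a b c d ... w x y z | z y x w],
  # valid for any pad width via the period-2n sawtooth index map
  pos <- seq(1L - radius, n + radius)
  j <- ((pos - 1L) %% (2L * n)) + 1L
  j <- ifelse(j > n, 2L * n - j + 1L, j)
  padded <- x[j]
  out <- stats::filter(padded, k, method = "convolution", sides = 2)
  as.numeric(out[(radius + 1L):(radius + n)])
}

# strictly positive scalar check
check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(sprintf("'%s' must be a positive finite scalar", name), call. = FALSE)
  invisible(x)
}

# sample standard deviation by column, without the overhead of apply()
col_sds <- function(m) {
  n <- nrow(m)
  if (n < 2L) stop("standard deviation undefined for fewer than 2 rows")
  mu <- colMeans(m)
  sqrt((colSums(m * m) - n * mu^2) / (n - 1))
}

# deterministic seed derivation: offset a base seed, staying inside 32-bit range
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + 9973 * offset) %% .Machine$integer.max)
}
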