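# Small fixture builders used across the suite.

# dense toy dataset on a full rows x cols grid, counts supplied or Poisson
toy_dataset <- function(rows = 3, cols = 3, counts = NULL, n_genes = 5,
                        genes = NULL, biotype = "protein_coding",
                        section = "section1", seed = 42) {
  g <- expand.grid(x = seq_len(rows), y = seq_len(cols))
  n <- nrow(g)
  if (is.null(genes)) genes <- paste0("g", seq_len(n_genes))
  if (is.null(counts)) {
    set.seed(seed)
    counts <- matrix(rpois(n * length(genes), 5), nrow = n)
  }
  dimnames(counts) <- list(paste0("s", seq_len(n)), genes)
  coords <- data.frame(spot = rownames(counts), x = g$x, y = g$y,
                       section = section, patient = "p1")
  info <- data.frame(gene = genes, biotype = rep_len(biotype, length(genes)))
  spot_dataset(counts, coords, info)
}

# proportion matrix with rows summing to 1
toy_props <- function(m) {
  m <- as.matrix(m)
  if (is.null(rownames(m))) rownames(m) <- paste0("s", seq_len(nrow(m)))
  m / rowSums(m)
}

# random proportion matrix (Dirichlet via gamma), n spots x k types
random_props <- function(n, k, seed = 1, types = paste0("t", seq_len(k))) {
  set.seed(seed)
  m <- matrix(rgamma(n * k, shape = 2), n, k,
              dimnames = list(paste0("s", seq_len(n)), types))
  m / rowSums(m)
}

# two-regime coefficient curve with a planted elbow: a gently convex
# high-coefficient regime that turns concave (the shoulder) at the given
# rank and plunges thereafter; strictly decreasing throughout
planted_coefficient_curve <- function(n = 1000, elbow = 170, seed = 1,
                                      curvature = 1e-5, slope = 0.0034,
                                      noise = 2e-6) {
  set.seed(seed)
  r <- seq_len(n)
  f_elbow <- 1 - slope * elbow + 0.5 * curvature * elbow^2
  s_elbow <- -slope + curvature * elbow
  f <- ifelse(r <= elbow,
              1 - slope * r + 0.5 * curvature * r^2,
              f_elbow + s_elbow * (r - elbow) - 0.5 * curvature * (r - elbow)^2)
  f <- f + rnorm(n, sd = noise)
  names(f) <- paste0("g", sample(n))  # scrambled names: order must not matter
  f
}
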