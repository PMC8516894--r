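# Synthetic spatial datasets with planted, recoverable ground truth.
#
# The generator emulates a printed spot array: a 33 x 35 grid (200 um pitch)
# masked to an elliptical "tissue" of <= 1007 usable spots, spot-level
# cell-type mixtures built from Gaussian radial foci on a flat baseline,
# and gamma-Poisson (negative binomial) counts whose spot-level mean is
# library_size_mean * sum_z p_sz * profile_zg.

#' Configuration for the synthetic dataset generator
#'
#' @param grid_rows,grid_cols dimensions of the printed spot grid.
#' @param spacing coordinate step between adjacent spots, in array units
#'   (the physical pitch of the emulated array is 200 um; coordinates are
#'   kept in array units so one step = one unit by default).
#' @param n_genes number of genes.
#' @param n_cell_types number of cell types. The first two default type
#'   names are \code{"B-cells"} and \code{"T-cells"}; these are the types
#'   elevated inside \code{tls_foci}.
#' @param cell_types optional character vector of type names.
#' @param type_profiles optional cell-type x gene matrix of non-negative
#'   expression rates; rows are renormalised to sum to one. By default each
#'   type gets an elevated block of marker genes over a shared baseline.
#' @param foci list of foci, each \code{list(center = c(x, y), radius = r,
#'   weights = c(type = amplitude, ...))}: a Gaussian radial bump of the
#'   given amplitude is added to each named type's latent field, and spots
#'   within \code{radius} of the center are labelled as that focus's region.
#' @param colocal_pairs list of \code{list(u = type, v = type, target = rho)}
#'   planting a target Pearson correlation between the two types'
#'   proportion fields (rho strictly inside (-1, 1)).
#' @param tls_foci list of \code{list(center = c(x, y), radius = r)} where
#'   B- and T-cell proportions are jointly elevated.
#' @param spatial_genes identifiers of genes given smooth spatial expression
#'   fields (planted positive spatial autocorrelation).
#' @param pathway_region optional \code{list(genes = ids, region = name,
#'   fold = k)}: the listed genes' expression rates are multiplied by
#'   \code{fold} inside the named region.
#' @param nb_dispersion negative binomial dispersion phi
#'   (variance = mu + phi * mu^2), shared across genes.
#' @param library_size_mean expected total counts per spot.
#' @param noise_sd standard deviation of the smooth spatial noise added to
#'   each type's latent field (0 disables it).
#' @param mask \code{"ellipse"} to keep only spots inside an elliptical
#'   tissue area (987 of the 1155 grid positions at the default 33 x 35
#'   size), or \code{"none"} for the full grid.
#' @param seed integer seed; identical configurations generate identical
#'   datasets.
#' @return a \code{synthetic_config} list.
#' @export
synthetic_config <- function(grid_rows = 33, grid_cols = 35, spacing = 1,
                             n_genes = 500, n_cell_types = 8,
                             cell_types = NULL, type_profiles = NULL,
                             foci = list(), colocal_pairs = list(),
                             tls_foci = list(), spatial_genes = character(),
                             pathway_region = NULL,
                             nb_dispersion = 0.25, library_size_mean = 2000,
                             noise_sd = 0.15, mask = c("ellipse", "none"),
                             seed = 1) {
  check_positive(nb_dispersion, "nb_dispersion")
  check_positive(library_size_mean, "library_size_mean")
  check_positive(spacing, "spacing")
  stopifnot(grid_rows >= 1, grid_cols >= 1, n_genes >= 1, n_cell_types >= 1)
  mask <- match.arg(mask)
  if (is.null(cell_types)) {
    cell_types <- c("B-cells", "T-cells",
                    paste0("type", seq_len(max(0, n_cell_types - 2))))
    cell_types <- cell_types[seq_len(n_cell_types)]
  }
  stopifnot(length(cell_types) == n_cell_types, !anyDuplicated(cell_types))
  for (p in colocal_pairs) {
    stopifnot(all(c(p$u, p$v) %in% cell_types))
    if (!(p$target > -1 && p$target < 1))
      stop("colocalization targets must lie strictly inside (-1, 1)")
  }
  for (f in c(foci, tls_foci)) if (f$radius <= 0) stop("focus radius must be > 0")
  if (!is.null(type_profiles)) {
    stopifnot(nrow(type_profiles) == n_cell_types, ncol(type_profiles) == n_genes,
              all(type_profiles >= 0))
  }
  structure(list(grid_rows = grid_rows, grid_cols = grid_cols, spacing = spacing,
                 n_genes = n_genes, n_cell_types = n_cell_types,
                 cell_types = cell_types, type_profiles = type_profiles,
                 foci = foci, colocal_pairs = colocal_pairs,
                 tls_foci = tls_foci, spatial_genes = spatial_genes,
                 pathway_region = pathway_region,
                 nb_dispersion = nb_dispersion,
                 library_size_mean = library_size_mean,
                 noise_sd = noise_sd, mask = mask, seed = as.integer(seed)),
            class = "synthetic_config")
}

# grid coordinates after tissue masking
array_coordinates <- function(config) {
  g <- expand.grid(x = seq_len(config$grid_rows), y = seq_len(config$grid_cols))
  if (config$mask == "ellipse") {
    cx <- (1 + config$grid_rows) / 2
    cy <- (1 + config$grid_cols) / 2
    a <- (config$grid_rows - 1) / 2 + 1.5
    b <- (config$grid_cols - 1) / 2 + 1.5
    g <- g[((g$x - cx) / a)^2 + ((g$y - cy) / b)^2 <= 1, , drop = FALSE]
  }
  g$x <- g$x * config$spacing
  g$y <- g$y * config$spacing
  rownames(g) <- NULL
  g
}

# smooth standardized field over the spot coordinates: iid gaussian noise
# convolved with a gaussian kernel of length-scale ell (array units)
smooth_field <- function(coords, ell = 3) {
  n <- nrow(coords)
  d2 <- outer(coords$x, coords$x, "-")^2 + outer(coords$y, coords$y, "-")^2
  k <- exp(-d2 / (2 * ell^2))
  f <- as.numeric(k %*% stats::rnorm(n))
  if (stats::sd(f) == 0) return(rep(0, n))
  (f - mean(f)) / stats::sd(f)
}

# gaussian radial bump, unit height at the center
radial_bump <- function(coords, center, radius) {
  d2 <- (coords$x - center[1])^2 + (coords$y - center[2])^2
  exp(-0.5 * d2 / (radius / 1.5)^2)
}

# default profiles: shared baseline plus a distinct marker block per type
default_profiles <- function(config) {
  z <- config$n_cell_types
  g <- config$n_genes
  base <- stats::rgamma(g, shape = 0.6, rate = 1) + 0.05
  prof <- matrix(rep(base, each = z), nrow = z)
  block <- max(1L, g %/% (2L * z))
  for (i in seq_len(z)) {
    lo <- (i - 1L) * block + 1L
    hi <- min(i * block, g)
    if (lo <= g) prof[i, lo:hi] <- prof[i, lo:hi] * 8
  }
  dimnames(prof) <- list(config$cell_types, paste0("gene", seq_len(g)))
  prof
}

#' Generate a synthetic spot dataset with ground truth
#'
#' Builds smooth per-type latent abundance fields (flat baseline + Gaussian
#' radial foci + smooth noise), plants pairwise colocalization by mixing a
#' shared latent field into both members of each pair (the mixing weight is
#' solved numerically so that the final, row-normalised proportions attain
#' the target correlation), elevates B- and T-cell proportions inside TLS
#' foci, and draws counts from a gamma-Poisson mixture with spot mean
#' \code{library_size_mean * sum_z p_sz * profile_zg} and shared dispersion.
#'
#' @param config a \code{\link{synthetic_config}}.
#' @return list with elements \code{dataset} (a \code{\link{spot_dataset}})
#'   and \code{truth} (proportions matrix, region labels, realised planted
#'   correlations, spatial gene ids).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  coords <- array_coordinates(config)
  n <- nrow(coords)
  z <- config$n_cell_types
  types <- config$cell_types

  profiles <- config$type_profiles
  if (is.null(profiles)) profiles <- default_profiles(config)
  profiles <- profiles / rowSums(profiles)
  rownames(profiles) <- types
  if (is.null(colnames(profiles))) colnames(profiles) <- paste0("gene", seq_len(config$n_genes))

  # latent abundance fields: baseline + foci bumps + smooth noise
  latent <- matrix(1, n, z, dimnames = list(NULL, types))
  region <- rep("background", n)
  fi <- 0L
  for (f in config$foci) {
    fi <- fi + 1L
    bump <- radial_bump(coords, f$center, f$radius)
    for (ty in names(f$weights))
      latent[, ty] <- latent[, ty] + f$weights[[ty]] * bump
    name <- if (!is.null(f$name)) f$name else paste0("focus", fi)
    inside <- (coords$x - f$center[1])^2 + (coords$y - f$center[2])^2 <= f$radius^2
    region[inside & region == "background"] <- name
  }
  ti <- 0L
  for (f in config$tls_foci) {
    ti <- ti + 1L
    bump <- radial_bump(coords, f$center, f$radius)
    amp <- if (!is.null(f$amplitude)) f$amplitude else 4
    latent[, "B-cells"] <- latent[, "B-cells"] + amp * bump
    latent[, "T-cells"] <- latent[, "T-cells"] + amp * bump
    inside <- (coords$x - f$center[1])^2 + (coords$y - f$center[2])^2 <= f$radius^2
    region[inside & region == "background"] <- paste0("tls", ti)
  }
  if (config$noise_sd > 0 && n > 1) {
    for (j in seq_len(z)) {
      f <- smooth_field(coords)
      latent[, j] <- pmax(latent[, j] + config$noise_sd * f, 0.02)
    }
  }

  # planted colocalization: both members share a latent field; the mixing
  # weight w is solved (1-d root finding) so that the correlation of the
  # final normalised proportions hits the target
  planted <- NULL
  if (length(config$colocal_pairs) && n > 2) {
    for (p in config$colocal_pairs) {
      a <- smooth_field(coords)
      b <- smooth_field(coords)
      amp <- if (!is.null(p$amplitude)) p$amplitude else 1.5
      shift <- function(f) f - min(f)
      props_at <- function(w) {
        lat <- latent
        lat[, p$u] <- lat[, p$u] + amp * shift(a)
        lat[, p$v] <- lat[, p$v] + amp * shift(w * a + sqrt(1 - w^2) * b)
        pr <- lat / rowSums(lat)
        stats::cor(pr[, p$u], pr[, p$v])
      }
      obj <- function(w) props_at(w) - p$target
      lo <- obj(-0.999); hi <- obj(0.999)
      if (sign(lo) == sign(hi)) {
        warning(sprintf("target correlation %.2f for (%s, %s) unreachable; using closest endpoint",
                        p$target, p$u, p$v))
        w <- if (abs(lo) < abs(hi)) -0.999 else 0.999
      } else {
        w <- stats::uniroot(obj, c(-0.999, 0.999), tol = 1e-6)$root
      }
      latent[, p$u] <- latent[, p$u] + amp * shift(a)
      latent[, p$v] <- latent[, p$v] + amp * shift(w * a + sqrt(1 - w^2) * b)
      realized <- {
        pr <- latent / rowSums(latent)
        stats::cor(pr[, p$u], pr[, p$v])
      }
      planted <- rbind(planted, data.frame(u = p$u, v = p$v, target = p$target,
                                           weight = w, realized = realized))
    }
  }

  props <- latent / rowSums(latent)

  # spot-level gene expression rates; rows sum to 1 so the expected library
  # size is exactly library_size_mean
  rates <- props %*% profiles
  extras <- FALSE
  if (length(config$spatial_genes)) {
    for (gname in config$spatial_genes) {
      f <- if (n > 1) smooth_field(coords) else 0
      rates[, gname] <- rates[, gname] * exp(1.2 * f)
    }
    extras <- TRUE
  }
  if (!is.null(config$pathway_region)) {
    pr <- config$pathway_region
    inside <- region == pr$region
    fold <- if (!is.null(pr$fold)) pr$fold else 5
    rates[inside, intersect(pr$genes, colnames(rates))] <-
      rates[inside, intersect(pr$genes, colnames(rates)), drop = FALSE] * fold
    extras <- TRUE
  }
  if (extras) rates <- rates / rowSums(rates)

  mu <- config$library_size_mean * rates
  phi <- config$nb_dispersion
  lambda <- matrix(stats::rgamma(length(mu), shape = 1 / phi, scale = as.numeric(mu) * phi),
                   nrow = n)
  counts <- matrix(stats::rpois(length(lambda), lambda), nrow = n,
                   dimnames = list(sprintf("spot_%04d", seq_len(n)), colnames(rates)))

  coords_tab <- data.frame(spot = rownames(counts), x = coords$x, y = coords$y,
                           section = "section1", patient = "patient1",
                           stringsAsFactors = FALSE)
  gene_info <- data.frame(gene = colnames(counts), biotype = "protein_coding",
                          stringsAsFactors = FALSE)
  rownames(props) <- rownames(counts)
  names(region) <- rownames(counts)

  list(dataset = spot_dataset(counts, coords_tab, gene_info),
       truth = structure(list(proportions = props, region_labels = region,
                              planted_correlations = planted,
                              spatial_genes = config$spatial_genes,
                              profiles = profiles),
                         class = "ground_truth"))
}

#' Generate marker gene sets with known shared cores
#'
#' Fixture generator for the core-signature machinery: each cluster's marker
#' set is the core of its group (if any) plus private noise genes, so the
#' shared cores are known exactly.
#'
#' @param n_clusters number of clusters; ids are \code{cluster1..n} unless
#'   a group names others.
#' @param core_spec named list: group id -> \code{list(core = genes,
#'   members = cluster ids)}. Member sets must be disjoint across groups.
#' @param noise_genes_per_cluster number of private noise genes per cluster.
#' @param seed integer seed.
#' @return list with \code{sets} (a \code{marker_gene_sets}) and
#'   \code{cores} (the planted group cores).
#' @export
generate_marker_sets <- function(n_clusters, core_spec = list(),
                                 noise_genes_per_cluster = 10, seed = 1) {
  set.seed(seed)
  clusters <- paste0("cluster", seq_len(n_clusters))
  members <- unlist(lapply(core_spec, `[[`, "members"))
  if (anyDuplicated(members))
    stop("duplicate cluster ids: groups must be disjoint over clusters")
  if (length(members) && !all(members %in% clusters))
    stop("core_spec references unknown cluster ids")
  sets <- stats::setNames(vector("list", n_clusters), clusters)
  pool <- paste0("noise_", seq_len(n_clusters * noise_genes_per_cluster * 3))
  pool <- sample(pool)
  k <- 0L
  for (cl in clusters) {
    core <- character()
    for (grp in core_spec)
      if (cl %in% grp$members) core <- as.character(grp$core)
    noise <- pool[seq_len(noise_genes_per_cluster) + k]
    k <- k + noise_genes_per_cluster
    sets[[cl]] <- c(core, noise)
  }
  list(sets = marker_gene_sets(sets),
       cores = lapply(core_spec, function(g) as.character(g$core)))
}
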