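# Run configuration and the end-to-end pipeline on synthetic or on-disk data.

#' Read / write a pipeline run configuration
#'
#' Configurations are flat YAML key-value files; every stochastic stage has
#' an explicit seed derived from the top-level seed. Unspecified parameters
#' take the package defaults.
#'
#' @param path YAML file.
#' @param config named list of parameters.
#' @return the configuration list (read) or \code{path} invisibly (write).
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  utils::modifyList(default_run_config(), cfg)
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname read_run_config
#' @export
default_run_config <- function() {
  list(seed = 1,
       input = NULL,                 # dataset directory; NULL -> generate
       min_spots = 10, min_genes = 300,
       exclusion_list = character(),
       r_min = 0.1,
       n_boot = 1000, n_perm = 1000,
       b_type = "B-cells", t_type = "T-cells",
       signature_sigma = 10,
       n_top = 100,
       pathway_genes = NULL)
}

#' Run the full downstream pipeline
#'
#' Executes: generate (when no input directory is given) -> gene/spot
#' filters -> spatial-lag autocorrelation filter -> colocalization,
#' entropy, region enrichment -> TLS scoring, model fit and signature
#' extraction -> spot-wise pathway enrichment. Every stage's output is
#' written to \code{out_dir} as TSV and a JSON manifest records the
#' package version, seed, parameters and artifact list. Identical
#' configurations produce identical outputs.
#'
#' @param config a run configuration (see \code{\link{default_run_config}}).
#' @param out_dir output directory.
#' @param quiet suppress progress messages.
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config = default_run_config(), out_dir, quiet = FALSE) {
  config <- utils::modifyList(default_run_config(), config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  artifacts <- character()
  emit <- function(obj, name) {
    f <- file.path(out_dir, name)
    utils::write.table(obj, f, sep = "\t", quote = FALSE, row.names = FALSE)
    artifacts <<- c(artifacts, name)
    f
  }
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE))
    say("stage %-14s %.2fs", name, as.numeric(Sys.time() - t0, units = "secs"))
    res
  }

  if (is.null(config$input)) {
    gen <- stage("generate", {
      sc <- synthetic_config(
        seed = config$seed,
        foci = list(list(center = c(8, 9), radius = 5,
                         weights = c(type1 = 6), name = "tumor"),
                    list(center = c(26, 27), radius = 5,
                         weights = c(type2 = 6), name = "immune")),
        colocal_pairs = list(list(u = "type3", v = "type4", target = 0.6)),
        tls_foci = list(list(center = c(10, 26), radius = 4)),
        spatial_genes = paste0("gene", 151:160),
        pathway_region = list(genes = paste0("gene", 161:180),
                              region = "immune", fold = 5))
      generate_dataset(sc)
    })
    dataset <- gen$dataset
    props <- gen$truth$proportions
    regions <- gen$truth$region_labels
    write_spot_dataset(dataset, file.path(out_dir, "dataset"))
    artifacts <- c(artifacts, "dataset")
    emit(data.frame(spot = rownames(props), round(props, 6)), "proportions.tsv")
    emit(data.frame(spot = names(regions), region = regions), "regions.tsv")
  } else {
    inputs <- stage("read", {
      dataset <- read_spot_dataset(config$input)
      pf <- file.path(config$input, "proportions.tsv")
      if (!file.exists(pf)) stop("missing proportions file: ", pf)
      pr <- read_sidecar(pf, dataset)
      props <- as.matrix(pr[, setdiff(names(pr), "spot"), drop = FALSE])
      rownames(props) <- pr$spot
      rg <- read_sidecar(file.path(config$input, "regions.tsv"), dataset)
      list(dataset = dataset, props = props,
           regions = stats::setNames(rg$region, rg$spot))
    })
    dataset <- inputs$dataset
    props <- inputs$props
    regions <- inputs$regions
  }

  dataset <- stage("filter", {
    d <- apply_gene_filters(dataset, exclusion_list = config$exclusion_list,
                            min_spots = config$min_spots)
    apply_spot_filter(d, min_genes = config$min_genes)
  })
  props <- props[rownames(props) %in% dataset$spots$spot, , drop = FALSE]
  regions <- regions[names(regions) %in% dataset$spots$spot]

  sfilter <- stage("spatialfilter", {
    graph <- build_neighbor_graph(dataset)
    spatial_autocorrelation(dataset, graph, r_min = config$r_min)
  })
  emit(sfilter, "spatial_autocorrelation.tsv")

  coloc <- stage("coloc", bootstrap_correlation(
    props, n_boot = config$n_boot, seed = derive_seed(config$seed, 1)))
  emit(coloc$pairs, "colocalization.tsv")

  ent <- stage("entropy", spot_entropy(props))
  emit(data.frame(spot = names(ent), entropy_bits = ent), "entropy.tsv")

  enr <- stage("enrich", enrichment_scores(
    props, regions, n_perm = config$n_perm, seed = derive_seed(config$seed, 2)))
  emit(enr$table, "region_enrichment.tsv")

  tls <- stage("tls", {
    scores <- tls_score(props, config$b_type, config$t_type)
    norm <- normalize_libsize_sd(dataset)
    scores <- scores[match(rownames(norm$values), scores$spot), ]
    model <- fit_tls_model(norm, scores)
    sig <- tryCatch(extract_signature(model, sigma = config$signature_sigma),
                    error = function(e) NULL)
    list(scores = scores, model = model, signature = sig)
  })
  emit(tls$scores, "tls_scores.tsv")
  emit(data.frame(gene = c("(Intercept)", names(tls$model$coefficients)),
                  coefficient = c(tls$model$intercept, unname(tls$model$coefficients))),
       "tls_model.tsv")
  if (!is.null(tls$signature))
    emit(data.frame(gene = tls$signature$genes,
                    rank = seq_along(tls$signature$genes)), "tls_signature.tsv")

  pw_genes <- config$pathway_genes
  if (is.null(pw_genes)) pw_genes <- paste0("gene", 161:180)
  pw <- stage("pathway", spotwise_enrichment(dataset, pw_genes, n_top = config$n_top))
  emit(pw, "pathway_enrichment.tsv")

  manifest <- list(
    package = "spotscape",
    version = as.character(utils::packageVersion("spotscape")),
    seed = config$seed,
    parameters = config[setdiff(names(config), "seed")],
    artifacts = artifacts)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(manifest)
}
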