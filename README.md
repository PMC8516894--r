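# spotscape

Downstream statistics for deconvolved spatial transcriptomics.

Spot-based spatial transcriptomics measures gene expression at hundreds of
barcoded capture locations across a tissue section; each spot mixes the
transcripts of up to a few hundred cells. After an external deconvolution
tool (e.g. stereoscope) has estimated per-spot cell-type proportions from
an annotated single-cell reference, the interesting questions become
spatial and compositional: which cell types co-occur, where is the tissue
diverse or monotypic, which types are enriched in annotated regions, where
do B- and T-cell aggregates (tertiary lymphoid structures, TLS) form, and
which genes and pathways track those structures. `spotscape` implements
that statistical layer as tested, reusable functions for analysts working
with deconvolved spot data — the proportions, annotations and marker
statistics are inputs; the package never re-implements deconvolution,
normalization-by-regression, clustering or survival modelling.

## What it computes

- **Pre-processing filters** — biotype/prefix/exclusion gene filters,
  expression-support (≥10 spots) and spot-complexity (≥300 unique genes)
  rules, library-size + per-gene-SD normalization, and strict marker
  thresholds (p_adj < 0.01, ln fold change > 0.15).
- **Spatial-lag autocorrelation filter** — for each gene, the Pearson
  correlation r between expression and its spatial lag (summed expression
  over rook-adjacent neighbors); genes with r > 0.1 are kept.
- **Core signatures** — Jaccard similarity of cluster marker sets across
  patients, complete-linkage grouping of similarity profiles cut into k
  groups, robustness flags, and per-group cores = genes in ≥80% of member
  sets.
- **Colocalization** — spot-wise Pearson correlation r_uv between cell-type
  proportion vectors with a spot-resampling bootstrap (default 10,000
  resamples): bootstrap mean, 95% percentile interval, significance =
  interval excludes zero.
- **Diversity entropy** — per-spot Shannon entropy
  E_s = −Σ_z p_sz log2 p_sz (bits).
- **Region enrichment** — permutation test shuffling proportions against
  fixed region labels; score = mean(true − permuted) / sd(true − permuted).
- **Joint scores** — per-sample z-transformed products of two cell states'
  proportions.
- **TLS model** — raw score 2·p_B·p_T, adjusted by the spot's average
  distinct-type pair probability (1 − Σ p²) / C(|Z|,2); unregularized OLS of
  the adjusted score on normalized expression; gene signature from the
  ranked coefficient curve via Gaussian-smoothed second differences
  (σ = 10); cross-dataset prediction with quintile stratification into
  low / intermediate / high.
- **Spot-wise pathway enrichment** — two-sided Fisher's exact test on the
  overlap of each spot's top-n centered-expression genes with a gene set;
  score E_p(s) = −log2 p(s).
- **Synthetic data** — a generator emulating a 33 × 35 printed array
  (elliptical tissue mask, 987 usable spots) with planted colocalization,
  TLS foci, spatially autocorrelated genes, region-restricted pathway
  activity and marker-set cores, so every statistic can be validated
  against known ground truth.

## Worked example

Generate a synthetic tissue with a planted type3/type4 colocalization
(target correlation 0.6) and a planted B/T-cell focus, then quantify both:

```r
library(spotscape)

cfg <- synthetic_config(
  colocal_pairs = list(list(u = "type3", v = "type4", target = 0.6)),
  tls_foci = list(list(center = c(10, 26), radius = 4)),
  seed = 42)
gen <- generate_dataset(cfg)
gen$dataset
#> spot_dataset: 987 spots x 500 genes
#>   sections: section1
#>   patients: patient1

coloc <- bootstrap_correlation(gen$truth$proportions, n_boot = 2000, seed = 1)
subset(coloc$pairs, u == "type3" & v == "type4")
#>        u     v   r boot_mean ci_low ci_high significant n_skipped
#> 15 type3 type4 0.6     0.599  0.546   0.649        TRUE         0
```

The plug-in correlation `r` recovers the planted 0.6; the bootstrap mean
(0.599) is the reported colocalization value and the 95% interval
[0.546, 0.649] excludes zero, so the pair is flagged significant.

```r
ent <- spot_entropy(gen$truth$proportions)
summary(round(ent, 3))
#>    Min. 1st Qu.  Median    Mean 3rd Qu.    Max.
#>   2.233   2.392   2.504   2.516   2.613   2.993

scores <- tls_score(gen$truth$proportions)
range(scores$adjusted)
#> [1] -0.0226  0.0508
```

Entropy sits between 0 (monotypic) and log2(8) = 3 bits (uniform over the
8 simulated types). The adjusted TLS score is positive where a B/T pair is
likelier than an average type pairing: inside the planted focus it averages
+0.019 versus −0.019 elsewhere, which is exactly the contrast the score is
designed to expose. Fitting the OLS model on normalized expression
(`fit_tls_model()`) and extracting the signature (`extract_signature()`)
then yields the genes tracking that structure, and
`predict_and_stratify()` transfers the model to external expression data.

`run_pipeline(list(seed = 1), "out/")` executes all stages end-to-end and
writes per-stage TSVs plus a JSON manifest recording version, seed and
parameters.

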