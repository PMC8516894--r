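---
title: "Statistical methods in spotscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods in spotscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spotscape)
```

## Scope

`spotscape` implements the statistical layer that sits *downstream* of
cell-type deconvolution for spot-based spatial transcriptomics. Its inputs
are (a) spot × gene count matrices with array coordinates and
section/patient labels, (b) spot × cell-type proportion matrices produced
by an external deconvolution tool, (c) region annotations, and (d) marker
statistics from an external differential-expression test. The package
never performs deconvolution, normalization-by-regression, clustering, or
survival model fitting itself — those belong to the established tools a
study would already have run. What it does provide are the bespoke
statistics built on top of such outputs: spatial feature selection,
cross-sample core signatures, colocalization/diversity/enrichment
statistics, tertiary lymphoid structure (TLS) scoring with gene-signature
extraction, and spot-wise pathway enrichment — plus a synthetic generator
that plants recoverable ground truth for all of them.

## Pre-processing filters

Counts are filtered genes-first, in one pass:

1. **Biotype**: keep `protein_coding` and immunoglobulin/T-cell-receptor
   constant/joining/variable genes (`IG_C/J/V_gene`, `TR_C/J/V_gene`).
2. **Symbol prefix**: drop ribosomal (`RPL`, `RPS`), mitochondrial
   (`MT-`, hyphen required) and `MTRNR` genes. Matching is case-sensitive
   on official symbols.
3. **Exclusion list**: a user-supplied set of identifiers (e.g. genes
   known to carry a technical ring-like array artifact).
4. **Support**: a gene must be expressed (count > 0) in at least 10 spots.
5. **Spot complexity**: spots with fewer than 300 unique expressed genes
   are removed, *after* the gene filters.

The support rule is evaluated on the spot set as passed in, before spot
filtering, and the pipeline makes exactly one pass — no iteration until a
fixed point. Order matters: a low-complexity spot can carry a gene's 10th
supporting count, so reversing the order can change the surviving gene
set. The suite pins this convention with a constructed counterexample.
All thresholds are strict where the rules say "fewer than" / "lower than"
/ "higher than"; in particular a marker row with adjusted *p* exactly 0.01
or ln-fold-change exactly 0.15 is discarded.

## Spatial-lag autocorrelation filter

For gene *g* and spot *s*, the spatial lag is the **summed** (not
averaged) expression over the spot's adjacent neighbors. Adjacency is the
orthogonal rook 4-neighborhood: two spots are neighbors iff they share a
section and their Manhattan distance in array units lies in
`[1 − tolerance, 1 + tolerance]` (default tolerance 0.5, absorbing small
alignment offsets). The gene's score is the Pearson correlation *r*
between its expression vector and its lag vector, pooled over all spots;
genes with *r* strictly above 0.1 are kept.

Two consequences of "summed, not averaged" are documented and tested:
boundary spots simply use the neighbors they have, and an additive shift
of a gene's expression is *not* exactly neutral (the constant enters each
spot's lag in proportion to its neighbor count); pure rescaling is. Genes
whose expression or lag has zero variance have undefined *r* and are
excluded with a message rather than an error. When multiple sections are
merged, the lag is computed per section (edges never cross sections) and
the correlation is pooled across all spots.

## Core marker signatures across samples

Given per-cluster marker sets from several patients, similarity is the
Jaccard index \(J(A,B) = |A\cap B|/|A\cup B|\) over all cluster pairs
(the Jaccard index of two empty sets is defined as 0). Each cluster's
*row* of the Jaccard matrix is its feature vector; Euclidean distances
between rows feed complete-linkage agglomeration, and the dendrogram is
cut into *k* = 5 groups by default. A group is **robust** iff at least one
gene is shared between at least two of its members (`robust_rule = "all"`
switches to the stricter all-member reading, since the narrative around
the original procedure supports both). For robust groups the **core
signature** is the set of genes present in at least 80% of the member
sets, with ties at exactly 0.8 included ("at least"). Cluster identifiers
are sorted before clustering so the grouping is invariant to input order;
there is no randomness anywhere in this module.

## Cell-type colocalization

Colocalization of types *u*, *v* is the spot-wise Pearson correlation of
their proportion vectors,

\[
r_{uv} = \frac{\sum_s (p_{su}-\bar p_u)(p_{sv}-\bar p_v)}
  {\sqrt{\sum_s (p_{su}-\bar p_u)^2}\sqrt{\sum_s (p_{sv}-\bar p_v)^2}}.
\]

Uncertainty comes from a spot-level bootstrap: spots are resampled with
replacement (pairs kept intact), every pairwise correlation is recomputed
per resample, the bootstrap mean is reported as the representative value
and the 2.5th/97.5th percentiles form the 95% interval. A pair is
significant iff its interval excludes zero. One design choice the
procedure description leaves open is whether resample indices are shared
across pairs; `spotscape` resamples **once per iteration and correlates
all pairs on the same resample**, which is cheaper and keeps the pairwise
estimates statistically coherent. The default of 10,000 resamples is the
production setting; tests and the acceptance script use 400–2,000, which
is ample for percentile intervals at the problem sizes involved.
Degenerate types (zero variance) yield missing correlations with a
warning; resamples in which a type degenerates are skipped and counted.

## Diversity entropy and joint scores

Per-spot diversity is Shannon entropy in bits,
\(E_s = -\sum_z p_{sz}\log_2 p_{sz}\), with \(0\log 0 = 0\); it ranges
from 0 (one dominating type) to \(\log_2|Z|\) (uniform composition). The
joint score of two cell states multiplies their proportions spot-wise and
z-transforms the products within each sample group, so positive values
mark joint presence relative to that sample's background. A group whose
products have zero variance gets all-zero scores with a warning.

## Region enrichment by permutation

For each (region, type): the *true average* proportion inside the region
is compared against a null built by permuting the spot indices of the
proportion matrix — one global permutation per iteration, all types
shuffled jointly so within-spot composition is preserved — while region
labels stay fixed. The enrichment score is
\(\mathrm{mean}(d)/\mathrm{sd}(d)\) where \(d_i\) = true average −
permuted average of iteration *i*; because the true average is constant
this equals \((\text{true} - \mathrm{mean(perm)})/\mathrm{sd(perm)}\),
and both routes are asserted equal in the tests. Positive scores mean
enrichment, negative depletion. Unannotated spots are excluded before
permutation. There is deliberately no p-value or FDR machinery: the
standardized score itself is the reported effect.

## TLS score, model, signature, prediction

**Score.** With major-tier proportions, the raw TLS score of a spot is
\(2\,p_B\,p_T\): the probability, under unbiased independent sampling of
two cells from the spot's composition, that the pair is one B and one T
cell. It is adjusted by subtracting the spot's average probability of
picking *any* distinct-type pair,
\(\binom{|Z|}{2}^{-1}\bigl(1-\sum_z p_{sz}^2\bigr)\), so compositions
whose B/T pairing is no likelier than an average pairing score at or
below zero. Same-type pairs are excluded from the average because the raw
score is itself a distinct-type pair probability; the `include_same_type`
variant is provided but collapses to the constant shift
\(2/(|Z|(|Z|+1))\), since multiset pair probabilities sum to one.

**Model.** Expression is normalized by library size per spot, then each
gene is divided by its sample (n−1) standard deviation computed after the
library-size step. The adjusted score is regressed on the normalized
expression by ordinary least squares with an intercept and no
regularization. When genes outnumber spots, the minimum-norm
least-squares solution (via SVD) is returned with a warning — a
deterministic, canonical resolution of the under-determined case.

**Signature.** Coefficients are sorted descending and treated as a curve
over gene rank. The curve is Gaussian-smoothed (σ = 10 ranks, kernel
truncated at 4σ, reflect boundary), its second-order differences are
smoothed again with the same filter, and the threshold is the first rank
at which this smoothed second derivative turns negative **after having
been non-negative** — the first concave bend of the descending curve,
i.e. the end of the high-coefficient regime. The qualifier matters: with
reflect boundary handling the smoothed second derivative of *any*
strictly decreasing curve is negative at rank one (the mirrored boundary
forms a concave peak), so taking literally "the first rank below zero"
would always return an empty signature. Ignoring that leading artifact
run and requiring a genuine non-negative→negative crossing makes the
detector well-posed; a curve with no such crossing (e.g. purely convex
decay, or sign-flipped input on the test fixtures) raises an error rather
than silently returning all genes. Signature members are exactly the
genes ranked strictly above the threshold.

**Prediction.** New data — spot-level or bulk — are normalized *within
themselves* (library size, then per-gene SD), scored with the fitted
coefficients over shared genes (model genes absent from the target are
dropped with a message; an overlap below 50% is an error), and stratified
by score quintiles: quintile 1 → `low`, 3 → `intermediate`, 5 → `high`,
2 and 4 → `unassigned`. Quintile boundaries use the inclusive empirical
quantile with ties assigned to the lower stratum.

## Spot-wise pathway enrichment

Each gene is centered by its mean across the matrix as passed (grouping
by section or patient is the caller's responsibility). Within each spot,
genes are ranked by adjusted expression, ties broken by gene identifier
for determinism, and the top *n* genes form \(T_n(s)\). The 2 × 2 table
(top/lower-ranked × in-set/not) is tested with a two-sided Fisher's exact
test under the minimum-likelihood convention — the sum of all
hypergeometric outcomes whose probability does not exceed the observed
one, evaluated within the same 1e−7 relative tolerance R's `fisher.test`
uses, with which the implementation is cross-checked. The score is
\(E_p(s) = -\log_2 p(s)\). Since the margins are identical across spots,
*p* is computed once per possible overlap count. No multiple-testing
adjustment is applied — a single hypothesis is tested per spot. The value
of *n* is a free parameter (default 100); it trades sensitivity for
specificity roughly like a gene-set size prior, and the planted-region
recovery in the tests is insensitive to it across 20–100.

## The synthetic generator

The generator emulates a printed 33 × 35 spot array (200 μm pitch in
physical units; coordinates are kept in array units) masked to an
elliptical "tissue" covering 987 of the 1155 grid positions. Cell-type
proportion fields are built additively on a flat baseline: Gaussian
radial bumps per focus, smooth noise fields (spatially convolved Gaussian
noise), joint B/T elevation inside TLS foci, then row normalization.
Planted colocalization shares a smooth latent field between the two pair
members; the mixing weight is solved by 1-D root finding so that the
correlation of the *final normalized proportions* — not the latents —
hits the target, which is why recovered correlations land within a few
thousandths of the target. Counts are gamma–Poisson: the spot mean is
`library_size_mean` × (proportions × type profiles), with one shared
dispersion φ (variance μ + φμ²).

Defaults are chosen to be realistic at desk scale: 500 genes (the
smallest scale at which the 300-unique-feature spot filter is meaningfully
exercised rather than degenerate), library size 2,000 counts per spot and
φ = 0.25, in line with spot-level depth and overdispersion on
first-generation arrays. What the generator deliberately does **not**
emulate: sequencing reads/UMIs, segment-level batch effects, the
deconvolution model's estimation error (proportions are handed to the
pipeline noise-free), or transcriptome-scale gene counts. Passing tests
therefore demonstrate that the statistics recover planted structure under
clean conditions, not that deconvolution errors propagate benignly.

## Numerical conventions

- All stochastic routines take an explicit integer seed; identical
  configurations are byte-identical across runs.
- Proportion rows must sum to 1 within 1e−6; generated rows are exact to
  1e−9.
- Strict inequalities wherever a rule reads "fewer/lower/higher than".
- Agglomeration ties and ranking ties are broken lexicographically.
- Degenerate inputs (zero-variance genes/types/groups) warn and yield
  missing or zero results; they never abort a whole run except where the
  output would be meaningless (single-spot normalization, empty gene
  sets).
- Tests run the full pipeline at reduced sizes (hundreds to ~1,000 spots,
  60–500 genes, 200–2,000 resamples), chosen so the whole suite completes
  in well under a minute of compute per file while keeping Monte-Carlo
  margins wide.

## Known limitations

- The rook 4-neighborhood assumes an orthogonal array; hexagonal
  platforms would need a different adjacency rule.
- The signature threshold detector requires an initial convex or flat
  descent; coefficient curves that are concave from the very start are
  indistinguishable from the boundary artifact and raise an error.
- Bootstrap percentile intervals are mildly anti-conservative at small
  spot counts; the coverage property is tested at n = 1000.
- Cross-platform prediction assumes the target data's within-dataset
  normalization is comparable to the training normalization; no explicit
  batch alignment is attempted.
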