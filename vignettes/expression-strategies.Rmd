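---
title: "Six-variable profiles: models, parameters and design choices"
author: "sixvp maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Six-variable profiles: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sixvp)
```

## The model

Under steady-state growth, the cellular amount of an mRNA is set by the
balance of its synthesis and decay, and the amount of a protein by the
balance of its translation and decay.  `sixvp` works with the six variables
that capture this flux for every gene:

* **TR** — transcription rate (mRNA synthesis),
* **RS** — mRNA stability (inverse decay rate, proportional to half-life),
* **RA** — mRNA abundance,
* **TLRi** — translation rate per mRNA molecule (e.g. ribosome density),
* **PS** — protein stability,
* **PA** — protein abundance,

related by the steady-state identities **RA = TR × RS** and
**PA = RA × TLRi × PS** (so the total translation rate TLR = RA × TLRi is
derivable and never stored).  Because the variables come from wildly
different measurement technologies, every downstream comparison happens on
the *rank* scale: within each variable, genes are assigned fractional ranks
rescaled to [0, 1] ((rank − 1)/(n − 1), ties averaged).  The ordered
6-vector of a gene's (or gene group's mean) rank values is its
*six-variable profile* (6VP), always in the fixed order TR, RS, RA, TLRi,
PS, PA.  Shape similarity between profiles is measured as 1 − Pearson R
across the six components, ranging 0 (same strategy) to 2 (opposite
strategy), with uncorrelated profiles at 1 in expectation.

## Harmonization of multi-source data

When a variable was measured by several studies, datasets are merged in
four steps, in this order:

1. **Correlation gate** (`gate_datasets`): if every pairwise Pearson R on
   the gene intersection is strictly above 0.3 all datasets are kept,
   otherwise only the dataset covering most genes survives.  The strict
   inequality matters: a dataset pair at exactly R = 0.31 is just above the
   limit and kept.  Whether to correlate raw or log values is not
   determined by the protocol; raw is the default and `log_values = TRUE`
   is available.
2. **KNN imputation** (`impute_knn`): each missing cell of a gene is
   replaced by the mean of that column over the k = 10 nearest genes
   (Euclidean distance on shared observed columns, rescaled to the full
   column count); rows more than half missing fall back to column means
   (`rowmax = 0.5`, `colmax = 0.8`).  These are the long-standing defaults
   of KNN imputation for expression matrices.
3. **Median matching** (`match_medians`): every dataset is multiplied by
   (grand median / its median), the grand median being the median of the
   per-table medians.  Multiplicative matching is the natural choice for
   ratio-scale rates and abundances; an additive log-scale match is a
   config option.  A table with median 0 cannot be matched and errors.
4. **Averaging** (`average_datasets`): per-gene arithmetic mean over the
   sources carrying the gene.

Missing TR or TLRi tables are derived from the identities: TR = RA / RS
(`derive_tr`) and TLRi = PA / (RA × PS) (`derive_tlri`), dropping genes
with zero denominators.  Stability units only matter up to a constant
factor (ln 2 between half-life and inverse decay rate), which cancels on
the rank scale, so no unit conversion is applied.  Protein abundances
reported as iBAQ intensities are put on the copies-per-cell scale by an
ordinary least-squares fit of log10(PCN) on log10(iBAQ) over shared genes
(`ibaq_to_pcn`, at least 10 shared positive genes).

## Profiles, clustering and enrichment

Genes enter profile clustering if they carry at least four of the six
variables, at least two on the mRNA side (TR, RS, RA) **and** at least two
on the protein side (TLRi, PS, PA) (`filter_genes`).  Residual missing
cells are KNN-imputed so every gene has a complete 6-vector.

`sota_cluster` implements a self-organizing tree: a divisive neural tree
that starts as one cell at the grand centroid and repeatedly splits the
leaf cell with the highest *resource* (mean correlation distance of its
members to its centroid) into two daughters, training daughter centroids by
presenting the member genes in seeded random order with winner, mother and
sister learning rates (defaults 0.01 / 0.005 / 0.001, at most 1000 epochs
per cycle, relative-improvement tolerance 1e-6).  Growth stops at the
requested leaf count (typically 10, 15, 20 or 30), and a post-pass merges
any cluster below five genes into the cluster with the nearest centroid —
the minimum-size rule is stated for the method but not *how* it is
enforced, so the merge pass is this package's choice.  The "correlation
coefficient as distance" phrase is read as 1 − R (not (1 − R)/2): random
gene pairs then sit near 1, matching the reported near-0.9 background
means.

Each cluster is tested for GO term over-representation with the one-sided
hypergeometric test against the universe of clustered genes — the
background the clusters were formed from — for the BP and CC ontologies.
Terms with zero overlap are reported at p = 1 rather than skipped so the
Benjamini–Hochberg denominator is reproducible; records are kept when the
adjusted p is strictly below 0.001.  Redundant significant terms are
collapsed greedily: take the record with the lowest adjusted p, discard
every remaining term whose SimREL similarity to it exceeds 0.7 (strictly;
the strictness at exactly 70% is unstated upstream and documented here),
repeat.  Because several clustering levels yield overlapping candidates,
`rank_cluster_candidates` makes the selection reproducible: candidates are
taken greedily by ascending best adjusted p, skipping any whose gene set
overlaps an already-selected cluster, with a full audit trail.

## Semantic similarity and redundancy reduction

Information content is IC(t) = −ln(|genes(t)| / |universe|) on the
ancestor-propagated annotation sets (`part_of` edges count as parental by
GOSemSim convention; both are configurable).  The log base is cosmetic: the
Lin ratio in SimREL is base-invariant and the (1 − p) factor is base-free.
Schlicker's relevance similarity is

SimREL(t1, t2) = [2·IC(MICA) / (IC(t1) + IC(t2))] · (1 − p(MICA)),

where the MICA (most informative common ancestor) is found by explicit
enumeration of common ancestors — in a DAG a pair may have several disjoint
ancestors, so the maximum IC is taken.  Self-similarity is 1 − p(t), and
terms whose only shared ancestor is the root score 0.

For tree building, term sets are first de-duplicated REVIGO-style
(`reduce_redundancy`): UPGMA clustering on 1 − SimREL, cut at the number
of clusters maximizing the mean silhouette width, keeping per cluster the
term with the highest *uniqueness* (1 − mean SimREL to all other terms;
ties break lexicographically for determinism).  The silhouette is searched
over k = 2 … m − 1: a one-cluster division has no silhouette, so the stated
"from 1" range is taken to start at 2, and because k = m is outside the
stated range a set of mutually dissimilar terms resolves to the best
k ≤ m − 1 representatives rather than literally all m.

## Complexes, pair distances and regression

Gene pairs are classified into three exhaustive, mutually exclusive
categories: **Complex** (sharing a complex of more than 5 and fewer than
150 members), else **Same_GO** (sharing a selected non-complex GO category
of fewer than 350 genes), else **No_group**.  Complex precedence is what
makes the three counts partition all C(m, 2) pairs.  Mean 6VP distances per
category are compared by one-way ANOVA and pairwise Welch t-tests (the
unequal-variance form; the upstream description says only "t-test").
Complete-case profiles are the default gene set for this analysis, with the
4-of-6 filtered set available.

The contribution of the five upstream variables to PA is estimated by
Bayesian model averaging over all 2^p subset regressions of z-scored data.
Each model is scored by its closed-form marginal likelihood under a Zellner
g-prior with unit information (g = n) and a uniform model prior; the
reference package used upstream defaults to a different ("robust") prior,
and the g-prior is chosen here for exact, enumerable, testable marginal
likelihoods — the package records this in its output metadata.  Under the
g-prior the conditional posterior mean of a coefficient is the OLS estimate
shrunk by g/(1+g); averaged coefficients weight these by model posterior
probabilities, and 95% credible intervals come from 20,000 seeded draws of
the posterior mixture (multivariate-t within each model, zeros where a
covariate is excluded).  Covariates that were computed mathematically from
PA are excluded up front via the `excluded` argument to avoid circularity,
and exactly collinear covariate sets (condition number above 1e10) are
rejected — which is also why regressions on synthetic truth run on the rank
scale, where the exact multiplicative identities no longer induce exact
linear dependence.

## Phenograms

GO-term-level 6VPs give each organism a (terms × 6)-dimensional profile:
per term, the mean rank of its member genes (mapped through per-organism
ortholog tables), keeping only terms with 5–275 genes in *every* organism
and data for all six variables.  The inter-organism distance is not
specified upstream; the default here is Euclidean distance on the
concatenated profiles normalized by the square root of the column count, so
trees built from different term subsets share a scale, with 1 − Pearson as
an alternative.  Trees are built by neighbor-joining (Saitou–Nei, negative
branch lengths clamped to zero with a warning) and UPGMA (average linkage,
node height at half the merge distance, hence ultrametric output).
`curated_group_tree` rebuilds both trees on named term subsets (e.g.
cytoplasmic translation, mitochondrion, transcription, replication) on the
common scale.

## The synthetic generator

`sixvp_sim_config` / `generate_organism` / `generate_clade` produce
ground-truth-labeled inputs with the statistical structure the analysis
assumes:

* a latent per-gene expression level L ~ N(0, 1) drives the log-scale
  primitives: log TR = L + noise, log RS = 0.35·L + noise (so TR–RA
  correlations exceed RS–RA by construction), log TLRi = 0.3·L + noise
  (the translational "potentiation" of abundant mRNAs), log PS independent;
* RA = TR × RS and PA = RA × TLRi × PS hold **exactly** in the truth, so
  the derivation operations are testable as exact inversions;
* genes belong to one of 8 functional groups whose 6VP *archetypes* shift
  the primitives by `archetype_effect` × (component − 0.5) on the log
  scale; only the TR, RS, TLRi and PS archetype components are free — RA
  and PA components emerge through the identities;
* complexes are subsets of groups with tighter dispersion (0.2 vs 0.5 log
  units), which plants the Complex < Same_GO < No_group ordering of mean
  pair distances by construction;
* replicate datasets multiply the truth by lognormal noise (sd 0.3) and
  delete 10% of cells; a toy three/four-level GO DAG has the groups as BP
  leaves (with 5% sibling overlap so MICAs are informative) and the
  complexes as CC leaves;
* in clades, gene-level draws are shared across organisms and only the
  archetypes drift along the planted tree, N(0, divergence_rate × branch
  length) per component clipped to [0, 1] — with zero divergence all
  organisms are literally identical, and divergence is the *only* source
  of inter-organism profile difference.

Defaults (1200 genes, 8 groups, 4 complexes of 12, tree
`((A:0.1,B:0.1):0.1,C:0.2)`) are desk-scale stand-ins for the
3350–4139-gene matrices of real organisms, chosen so the full pipeline and
test suite run in seconds while keeping group sizes (~150) and complex
sizes (12) in the range of real functional categories and stable complexes.
What the generator does **not** emulate: organism-specific biology,
realistic absolute scales (molecules per cell), shared measurement biases
between variables from a common platform, and annotation noise — so
passing recovery tests demonstrates correctness of the machinery under the
model's assumptions, not performance on any real dataset.

## Numerical and degenerate-input conventions

* Constant rank columns become 0.5 with a warning; zero-variance profiles
  have distance 1 to everything (uninformative), with a warning.
* Empty gene groups, empty universes, trees without branch lengths,
  all-missing matrix columns and inconsistent hypergeometric counts are
  errors, not silent results.
* Tie-breaking is deterministic everywhere (average ranks; lexicographic
  term IDs in de-duplication and uniqueness ties; seeded presentation
  order in SOTA; seeded mixture draws in BMA).
* Newick round-trips preserve topology and branch lengths to 1e-9; UPGMA
  ultrametricity and NJ additivity are checked to the same tolerance in
  the test suite.

## Recovery checks and their problem sizes

The test suite validates the pipeline by parameter recovery on the
generator at fixed seeds: SOTA reaches ARI 1.0 on two well-separated
archetypes (V-shaped vs inverted-V — a literally flat archetype has no
shape under correlation distance, so "flat" is not a recoverable target)
and >0.8 per-archetype purity on four; BMA recovers a unit coefficient
with inclusion probability >0.99 at n = 500; NJ recovers the planted
4-taxon topology in ≥95 of 100 seeded replicates on a tree with the same
1:1 internal-to-tip branch ratio as the default clade (a 3-taxon unrooted
NJ tree has only one topology, so the 4-taxon form is the smallest
informative recovery problem, with UPGMA covering the rooted 3-taxon
case); and random-control profiles stay within [0.49, 0.51] of the flat
0.5 line over 1000 samplings of size 50.  Null calibration uses 200
seeded random clusters to confirm the BH procedure keeps the fraction of
adjusted-significant terms within its nominal bound.

## Known limitations

* SOTA cluster memberships are initialization- and implementation-
  sensitive; only planted-structure recovery and enrichment behavior are
  guaranteed, not any particular membership list.
* The BMA prior differs from the upstream reference package's default;
  coefficient point estimates agree closely in well-determined settings
  but posterior model probabilities need not match it.
* The inter-organism metric and several strictness conventions (silhouette
  range, 70% similarity cutoff) are this package's documented choices
  where the upstream description is silent.
* Identifier mapping (isoform collapsing beyond mean/max/sum, cross-
  nomenclature conversion) is the caller's responsibility: ortholog and
  ID maps are inputs, never guessed.

## A short end-to-end run

```{r pipeline, eval = FALSE}
cfg <- sixvp_pipeline_config(
  synth = sixvp_sim_config(n_genes = 240, n_groups = 4, n_complexes = 2,
                           complex_size = 8, seed = 7),
  cluster = list(targets = c(4L, 8L)),
  control = list(size = 30L, reps = 200L),
  seed = 7, out_dir = "sixvp_demo"
)
res <- run_pipeline(cfg)
res$pair_stats$summary
res$bma
ape::read.tree(file.path(cfg$out_dir, "phenogram_upgma.nwk"))
```
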