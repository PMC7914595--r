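# sixvp — six-variable gene expression profiles

Under steady-state growth, the amount of every protein in a cell is set by
six coupled variables: the transcription rate (TR), mRNA stability (RS) and
mRNA abundance (RA) on the mRNA side, and the per-mRNA translation rate
(TLRi), protein stability (PS) and protein abundance (PA) on the protein
side, tied together by the balance equations

    RA = TR × RS        PA = RA × TLRi × PS

Different genes can reach the same protein level through different
*expression strategies* — transcribe hard and degrade fast, or transcribe
little and stabilize — and functionally related genes tend to share a
strategy. `sixvp` is a toolkit for studying these strategies across
organisms. It harmonizes heterogeneous omics datasets into one genes × 6
matrix per organism, rank-transforms each variable to [0, 1], and
characterizes every gene or gene group by its **six-variable profile
(6VP)**: the ordered vector of mean rank values (TR, RS, RA, TLRi, PS, PA).
On top of that it provides:

* **harmonization** — correlation-gated dataset merging, KNN imputation,
  multiplicative median matching, per-gene averaging, and derivation of
  missing variables from the balance equations (`harmonize_variable`,
  `derive_tr`, `derive_tlri`, `ibaq_to_pcn`);
* **profiles** — rank matrices, coverage filtering (≥4 variables, ≥2 per
  side), group 6VPs with standard errors, and random-sampling control
  bands (`rank_matrix`, `filter_genes`, `group_profile`, `random_control`);
* **clustering** — a self-organizing tree algorithm (SOTA) over the
  1 − Pearson profile distance, grown to a chosen cluster count with a
  minimum-size merge pass, plus reproducible cross-level cluster selection
  (`sota_cluster`, `rank_cluster_candidates`);
* **enrichment** — hypergeometric GO over-representation per cluster with
  Benjamini–Hochberg control and SimREL-based semantic de-duplication
  (`enrich_clusters`, `significant_terms`, `dedupe_by_similarity`);
* **semantic similarity** — information content, Schlicker's SimREL over
  the GO DAG, uniqueness scores and REVIGO-style redundancy reduction via
  UPGMA + silhouette (`information_content`, `sim_rel`, `reduce_redundancy`);
* **complex proximity** — classification of all gene pairs into
  Complex / Same_GO / No_group and ANOVA + Welch t-tests on their profile
  distances (`classify_pairs`, `pair_distance_stats`);
* **association** — pairwise correlations and Bayesian model averaging of
  PA on the other five variables under a Zellner g-prior with exact,
  enumerable marginal likelihoods (`pairwise_correlations`, `bma_regression`);
* **phenograms** — GO-term-level 6VPs across organisms, inter-organism
  distances, and NJ / UPGMA trees exported as Newick (`build_go_profiles`,
  `nj_tree`, `upgma_tree`, `curated_group_tree`);
* **synthetic data** — a ground-truth-labeled generator for all of the
  above, with planted groups, complexes, replicate noise, missingness and
  an organism tree that controls profile divergence (`sixvp_sim_config`,
  `generate_organism`, `generate_clade`), plus an end-to-end driver
  (`run_pipeline`).

File formats are deliberately plain: two-column TSV for expression values,
annotations, ortholog maps and complex catalogs; OBO 1.2 for ontologies;
GAF 2.x for annotation files; Newick for trees.

## Worked example

Generate a synthetic organism under the default configuration, rank it,
and compare a planted 12-gene complex against the random-sampling control:

```r
library(sixvp)

cfg   <- sixvp_sim_config(seed = 7)
org   <- generate_organism(cfg, "A")
ranks <- rank_matrix(org$truth)

cpx <- names(org$ground_truth$complex)[!is.na(org$ground_truth$complex) &
                                        org$ground_truth$complex == 1]
group_profile(ranks, cpx, "complex 1")
#> 6VP 'complex 1' (max n = 12)
#>          TR     RS     RA   TLRi     PS     PA
#> mean  0.753  0.295  0.598  0.733  0.504  0.687
#> se    0.063  0.042  0.077  0.031  0.020  0.071
#> n    12.000 12.000 12.000 12.000 12.000 12.000

round(random_control(ranks, size = 12, reps = 1000, seed = 7)$grand_mean, 3)
#>    TR    RS    RA  TLRi    PS    PA
#> 0.502 0.501 0.502 0.500 0.495 0.500
```

The complex transcribes high (TR 0.75) but keeps unstable mRNAs (RS 0.30)
— a V-shaped mRNA arm — and translates well (TLRi 0.73), ending at a high
protein level (PA 0.69); the matched random control is flat at 0.5 for
every variable, so the profile shape is group-specific signal, not a
ranking artifact. Pair distances confirm that shared membership tightens
profiles:

```r
cls <- classify_pairs(rownames(ranks), org$complexes,
                      split(names(org$ground_truth$group),
                            org$ground_truth$group))
pair_distance_stats(unclass(ranks), cls)
#> pair_distance_stats
#>   category      n      mean        sd
#> 1  Complex    264 0.2241989 0.2864005
#> 2  Same_GO  89136 0.3690737 0.3719905
#> 3 No_group 630000 1.0893139 0.5522291
#> ANOVA F = 71536.613, p = 0
```

Complex pairs are closest (mean distance 0.22), same-functional-group
pairs intermediate (0.37), and unrelated pairs near the uncorrelated
baseline of 1 (1.09) — the ordering the analysis is designed to detect.
`run_pipeline(sixvp_pipeline_config())` chains all stages (generation →
harmonization → profiles → clustering → enrichment → pair distances → BMA
→ phenograms) into an output directory with a hashed manifest.

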