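# shirocore

Cross-study integration of the *Tricholoma matsutake* (TM) mycosphere
("shiro") microbiome.

Amplicon surveys of shiro communities are scattered across sequencing
platforms, marker regions, and reference databases, so their taxon tables
cannot be compared directly. `shirocore` implements the tree-based pipeline
that makes them comparable and the downstream cross-study analyses, for
microbial ecologists studying matsutake (or any mycosphere system with a
dominant focal taxon):

1. **Phylotyping** — tips of reference-anchored subtrees are clustered by
   single linkage at a branch-length threshold (two tips are linked when
   their path distance is ≤ 0.02 substitutions/site), every cluster is
   iteratively refined to monophyly (non-monophyletic clusters split into
   the major contained clade plus outlier clades), and each phylotype gets
   a consensus taxonomy: the strict rank-wise consensus of its database
   tips, or — for query-only phylotypes — a tree walk from the MRCA toward
   the root that ignores long-branched and monotypic database tips and
   truncates the consensus above species rank. Names follow the
   `pt x.y`/`pt x.y.z` convention (`x` subtree, `y` cluster, `z`
   subcluster; `M` replaces `y` for monotypic phylotypes), or the species
   binomial when the consensus resolves one.
2. **Community handling** — unlabeled soil samples are reclassified to
   shiro soil (S-soil) vs non-shiro soil (NS-soil) by an exact univariate
   2-means split of TM relative abundance; paired bacterial samples inherit
   the fungal call. Samples with < 100 reads are removed per study and the
   rest rarefied to the study minimum.
3. **Core phylotypes** — detected in every region, present in ≥ 50% of
   studies, and ≥ 0.1% mean relative abundance across S-soil samples.
4. **Niche specificity** — per study, three statistics: a LEfSe-style
   effect size (Kruskal–Wallis screen at p ≤ 0.05, then the mean over
   1,000 bootstrap subsamples of `log10(max(1, (|w_f| + |Δμ_f|)/2))` where
   `w_f` is the unit-within-class-variance LDA coefficient and `Δμ_f` the
   class mean difference of abundances scaled to 1e6 per sample; called at
   LDA ≥ 3); the group-equalized indicator correlation
   `r.g` (weighted point-biserial with weights `1/(K·n_g)`, one-sided
   permutation p with 1,000 permutations); and TM co-occurrence (Pearson
   r ≥ 0.35 after a 20% prevalence filter). A phylotype is S-soil-specific
   when ≥ 1 method is significant in ≥ 2 independent studies. Cross-niche
   comparisons (S-soil / S-root / S-fruitbody) use the LEfSe score at
   LDA ≥ 4 (bacteria) or ≥ 3.5 (fungi).
5. **Networks** — the S-fruitbody co-occurrence network (edges at
   |r| ≥ 0.35) is clustered with the Markov clustering algorithm
   (expansion/inflation iterations at inflation 2.0 on the
   column-stochastic |r| matrix) and clusters are labeled TM-positive /
   TM-negative by their members' correlations with TM.
6. **Phenotype MicroArrays** — per-well growth parameters (carrying
   capacity, AUC, maximum rate) from OD590/OD750 time series, normalized by
   the A1 negative control, scaled to [−100, 100] per strain, and summarized
   as the 1–9 activity index (AV) via exact univariate k-means.

Seeded generators (`make_tree_scenario`, `make_community_scenario`,
`make_pm_scenario`) emulate the multi-study structure of the real surveys —
including the observed TM abundance contrast between S-soil
(62.1% ± 19.7%) and NS-soil (2.0% ± 4.7%) — with a ground-truth ledger, so
the whole pipeline runs and is tested without any external data.

## Worked example

The `analysis/` directory is a numbered workflow over the package. Running
it end to end:

```sh
Rscript analysis/01_simulate.R    # synthetic studies -> results/data/
Rscript analysis/02_phylotype.R
Rscript analysis/03_community.R
Rscript analysis/04_core_niche.R
Rscript analysis/05_network.R
Rscript analysis/06_pm_assay.R
```

prints, among other things:

```
phylotype_set: 30 phylotypes over 102 tips in 3 subtree(s)
planted species recovered by 100.0% of 48 non-outlier query tips
reclassified 20 unlabeled soil samples (90% agree with the generating labels): 9 S-soil, 11 NS-soil
core phylotypes: 14 called; planted recall 1.00, precision 1.00
S-soil-specific consensus: 4 phylotypes (3 of 3 planted recovered)
network: 210 nodes, 1718 edges, 25 MCL clusters (converged in 21 iterations)
AV matches the planted utilization level for 100.0% of 758 substrate wells
```

Every query tip planted within 0.02 of its reference species recovers that
species name; the planted core and S-soil-specific phylotypes are recovered
exactly; the 90% reclassification agreement reflects the genuine overlap of
the two TM abundance distributions (see the vignette); and the activity
index reproduces the planted 9-level utilization ranking. Tables land under
`results/`.

Equivalent single call from R:

```r
library(shirocore)
run_all("results/run", seed = 42)   # writes TSVs + manifest.json
```

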