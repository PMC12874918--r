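---
title: "Methods: tree-based phylotyping and cross-study shiro analyses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tree-based phylotyping and cross-study shiro analyses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shirocore)
```

# The problem

Amplicon surveys of the *Tricholoma matsutake* mycosphere ("shiro") differ
in platform, marker region, reference database, and the taxonomic rank at
which results are reported. Taxon names therefore do not line up across
studies, and neither do OTU/ASV identifiers. The pipeline in this package
sidesteps names entirely: all sequences — database references with a known
7-rank lineage and query sequences from the surveys — are assumed to sit as
tips on a common set of refined phylogenetic subtrees, and the unit of
analysis becomes the *phylotype*: a monophyletic (or single-tip) cluster of
tips. Everything downstream (core membership, niche specificity, networks)
operates on phylotype count tables, which are comparable across studies by
construction.

The package consumes already-refined subtrees (newick plus a tip sidecar
table). Building those trees — alignment, backbone inference, phylogenetic
placement, tree refinement — is upstream of this package and out of its
scope, as are diversity analyses and function prediction.

# Phylotyping

**Clustering.** Each subtree is midpoint-rooted, then tips are clustered by
single linkage at a branch-length threshold: tips `a`, `b` belong to one
cluster iff a chain of tips connects them with consecutive path distances
`<= 0.02` substitutions/site (the default mirrors the threshold used for
the real surveys). This equals cutting a single-linkage dendrogram over the
cophenetic matrix at the threshold; the implementation uses graph
components over the thresholded distance matrix, and the test suite checks
it against `hclust`/`cutree` on random trees.

**Monophyly refinement.** Single-linkage clusters need not be clades. Each
non-monophyletic cluster is split into its *major clade* — the tree node
with the most tips whose full tip set lies inside the cluster, ties broken
by the earliest tip in left-to-right DFS order — plus outliers; the
outliers are re-partitioned into maximal contained clades, each becoming a
subcluster of the parent (an alternative one-singleton-per-outlier mode is
available). Every split strictly shrinks a cluster, so the process
terminates, and after refinement every multi-tip phylotype is monophyletic
(asserted on every run). "Major = maximal" is a design choice: the
refinement procedure we mirror does not define "major", and maximality is
the only reading that is deterministic without extra parameters.

**Taxonomy.** A phylotype containing database tips takes the strict
rank-wise consensus of their lineages (the deepest prefix of
domain→species on which all agree; a majority rule is available but not
default — strict consensus is conservative and order-independent).
Query-only phylotypes walk from their MRCA toward the root; at the first
ancestor subtending a *valid* database tip — not flagged as long-branched,
not the sole member of a monotypic phylotype (both signs of likely
misplacement) — the strict consensus of those tips is taken and truncated
above species rank, dropping the species even when unanimous: placement
adjacency alone is not species-level evidence. Reaching the root with no
valid tip yields an empty lineage, which is a legal result.

**Long branches.** The upstream pipeline delegates long-branch detection to
a per-species significance test; at package scale we use a deterministic
surrogate: a tip is flagged when removing it shrinks the tree diameter by a
factor `>= 1.5` (configurable). The rule only uses path distances, so it is
invariant under rerooting; flags are computed once per subtree, before
clustering.

**Naming.** Phylotypes resolving to a species by direct consensus are named
by the binomial; all others are `"<deepest taxon> pt x.y"` with `x` the
subtree index and `y` numbering the original clusters by DFS order of their
first tip. Subclusters created by refinement append `.z` in creation order.
Monotypic phylotypes take `M` in the `y` position with a subtree-wide
counter as `z` (`pt x.M.k`), which keeps single-tip IDs unique without
consuming cluster numbers. Species-name collisions (two phylotypes
resolving to the same binomial) fall back to the suffixed form. We claim
determinism of the numbering, not equality with any external pipeline's
printed IDs.

# Community handling

**Reclassification.** Some public soil samples carry no shiro/non-shiro
label. The TM relative abundance of every unlabeled fungal soil sample is
split by exact univariate 2-means (dynamic programming over sorted values —
deterministic, globally WCSS-optimal; Lloyd-style iteration is never used);
the high-center cluster becomes S-soil. A single unlabeled sample cannot be
split on its own, so it is pooled with the labeled soil samples' TM
abundances. Paired bacterial samples inherit the fungal call. We cluster
relative abundance rather than raw reads (a flag restores raw counts)
because read depth varies by orders of magnitude across studies.

There is a hard ceiling on how accurate this step can be. With the S-soil
TM abundance modeled as Beta with mean 0.62, SD 0.197 and NS-soil as Beta
with mean 0.02, SD 0.047 (moments matched to the observed survey values),
the two densities overlap: even the best possible fixed threshold (~0.18)
misclassifies ~1.8% of samples, and a WCSS-optimal 2-means boundary
necessarily sits near the midpoint of the cluster centers (~0.3), where
~7% of the S-soil mass lies below. The package's measured accuracy over 100
replicate mixtures is therefore ~94–95%, and that is a property of the
distributions, not of the implementation; the test suite and acceptance
script report it honestly.

**Filtering and rarefaction.** Within each study, samples under 100 total
reads are dropped and the remainder subsampled without replacement to the
study's minimum depth (per-study, not global, since depths differ by
platform). Rarefaction is used for the niche-specificity statistics; core
abundance screening uses the unrarefied table, so low-depth S-soil samples
still contribute. Mean relative abundance is always the unweighted mean of
per-sample proportions, never a pooled-read ratio, so deep samples do not
dominate.

# Core phylotypes and niche specificity

A phylotype is **core** when (a) it is detected (count > 0 in at least one
S-soil sample) in every geographic region, (b) present in at least half of
the studies — by default studies that contribute S-soil samples — and
(c) its mean S-soil relative abundance is at least 0.1%. Both thresholds
are inclusive (`>=`), and the prefilter for niche analyses drops phylotypes
*strictly below* 0.1% mean abundance across all samples.

**Per-study statistics.** Three methods run per study with both soil
niches, each reimplemented from its published definition:

* *LEfSe-style effect size*: abundances scaled to 1e6 per sample;
  Kruskal–Wallis screen at p ≤ 0.05; for survivors, the effect size is the
  mean over 1,000 bootstrap subsamples (two thirds of each class) of
  `log10(max(1, (|w_f| + |Δμ_f|)/2))`, with `w_f` the feature's
  linear-discriminant coefficient scaled to unit within-class variance and
  `Δμ_f` the scaled class-mean difference; one-vs-rest with a max over axes
  for more than two classes. The discriminant uses a ridge-regularized
  pooled within-class covariance, which keeps the solve well-posed when
  features outnumber samples. We claim recovery of planted effects, not
  numeric parity with any particular LEfSe build.
* *Indicator correlation* `r.g`: the group-equalized point-biserial
  correlation (sample weights `1/(K n_g)`), with a one-sided permutation
  p-value `(#{r* >= r} + 1)/(B + 1)` at `B = 1000`, or exact enumeration of
  all label arrangements for small n. Zero-variance features return NA with
  p = 1.
* *TM co-occurrence*: after a 20% prevalence filter, Pearson correlation
  with TM relative abundance (Spearman available); `r >= 0.35` is called
  S-soil-related. No p-value is attached — the threshold is the rule.

No multiple-testing correction is applied within methods, matching the
conventions of the tools they mirror; replication across studies is the
error control: the **consensus** rule calls a phylotype S-soil-specific
when at least one method is significant *toward S-soil* in at least two
independent studies. Directions are recorded per result, so a phylotype can
be S-soil-specific overall yet NS-soil-significant in one study, and only
the S-soil direction counts toward consensus.

**Cross-niche comparisons** (S-soil / S-root / S-fruitbody) reuse the LEfSe
machinery with kingdom-specific thresholds (LDA ≥ 4 bacteria, ≥ 3.5 fungi);
the winning niche is the class with the highest mean scaled abundance.

# Co-occurrence network and MCL

Edges connect phylotype pairs with `|r| >= 0.35` over fruitbody samples
(at least 5 samples required; below that, correlations are unstable and the
builder refuses to run). Markov clustering runs on the `|r|` weights —
signs are kept separately for TM labeling, since both signs are meaningful
edges — with self-loops set to each node's maximum incident weight (floor
1e-3), column normalization, and alternating expansion (matrix squaring)
and inflation (elementwise power 2.0, renormalize) until the transition
matrix changes by less than 1e-6; clusters are connected components of the
symmetrized attractor graph. The iteration is deterministic and invariant
to node order (cluster IDs are renumbered by first node appearance);
column-stochasticity is tracked at every step and exposed in the result.
Clusters are labeled TM-positive/TM-negative by the majority sign among
members with `|r| >= 0.35` against TM, neutral on ties or no such member.

# Phenotype MicroArray scoring

Growth curves (OD every 24 h for 8 days, 590 nm respiration / 750 nm
growth) are smoothed with a centered 3-point running median — enough to
suppress single-read spikes at this sampling interval without a model fit;
a Gaussian-process fit would add nothing downstream because the activity
index consumes only summary parameters. Per well: carrying capacity = max
smoothed OD, AUC = trapezoidal integral, max rate = largest forward
difference per hour. Wells showing abiotic dye reduction are excluded by a
t0 heuristic (first-timepoint OD above the plate median by > 3 MAD; the
original protocol states no criterion, so this one is ours). Parameters are
normalized by the A1 negative control (A1 maps exactly to 0) and scaled to
[−100, 100] per strain, positive and negative sides independently so the
zero point is preserved. The 1–9 activity index is exact univariate k-means
over the pooled scaled values of one wavelength (pooling across strains
keeps AVs comparable between strains; a per-strain mode exists); clusters
are labeled 1–9 in center order, so AV is monotone in the scaled value by
construction. AUC feeds the AV by default — it integrates both capacity and
rate — with the other two parameters reported alongside.

# The synthetic-data generators

The generators produce every input the pipeline consumes, with a
ground-truth ledger, and their defaults are the study conditions used by
the tests and the acceptance script.

**Trees** (`make_tree_scenario`): 3 subtrees × 8 species, each species a
clade of 2 database + 2 query tips with pairwise distances 0.01 (below the
0.02 threshold) and between-species distances ≥ 0.2; 2 outlier query tips
per subtree on pendant edges of 2.0 (an order of magnitude above the
backbone edges), which the diameter-ratio rule flags by construction.

**Communities** (`make_community_scenario`): 4 studies over 3 regions, 10
samples per niche per study, 300 phylotypes, 20,000 reads per sample. TM
relative abundance is drawn per niche from Beta distributions matching the
observed moments (S-soil 0.62 ± 0.197, NS-soil 0.02 ± 0.047; S-root
0.45 ± 0.15 and S-fruitbody 0.85 ± 0.08 are our choices reflecting TM
dominance in its own tissues). Planted effects are defined on *final
relative abundance*: 6 core phylotypes flat at 0.8% in every niche — high
enough that a 40-sample mean almost never dips below the 0.1% core
threshold under the configured noise — and niche-specific phylotypes at a
baseline (1.5% for S-soil targets, 0.4% for root/fruitbody) multiplied by
`2^log2FC` (default log2FC = 2) in their target niche. Fruitbody-specific
phylotypes additionally scale their share of the non-TM remainder with the
TM odds, emulating taxa that grow with the fruitbody. All remaining
phylotypes are *study-endemic* background (present in one study only,
uniform weights within ±30%), reflecting the cross-study taxonomic
turnover that motivates a core definition based on prevalence: endemic taxa
can never satisfy the region or study criteria, so the planted core set is
exactly recoverable. When a sample's TM draw leaves less mass than the
planted block demands, the planted proportions are scaled down to fit —
high-TM samples genuinely crowd out everything else, which is the main
power cost the statistics face. Per-sample noise is Dirichlet with
concentration 50 around the expected proportions, then multinomial reads.
The ledger records planted IDs, the expected core set (planted features
whose expected S-soil mean meets the core threshold, plus TM itself), the
honest null set (the flat cores), and the true niche of every
label-withheld sample.

**PM plates** (`make_pm_scenario`): logistic curves
`OD(t) = 0.05 + 0.12·level / (1 + e^{-0.06 (t - 72)})` at 9 planted levels
cycling over the 95 substrate wells, A1 flat at baseline, read at
0–192 h in 24 h steps at both wavelengths, optional Gaussian OD noise.

**What passing on these data does and does not show.** The generators
emulate the *structure* of the surveys — multi-study design, TM dominance,
compositional closure, planted effects, overdispersed counts — but not
real-data pathologies: no chimeras or sequencing error (trees arrive
clean), no study-specific depth or primer biases, no correlated background
taxa, species are perfectly separated on the tree by construction. Perfect
recovery here validates the logic and determinism of the implementation,
not its behavior on raw survey data.

# Numerical and design notes

* All clustering primitives are exact (dynamic programming / graph
  components), never heuristic iterations, so every result is reproducible
  bit-for-bit given the seed; the orchestrator derives per-stage seeds from
  one root seed and writes MD5 checksums of every output into its manifest.
* Branch lengths missing from newick default to 0 with a warning; negative
  lengths are rejected.
* Strict-consensus ties and DFS tie-breaks are documented above; `y`
  numbering can skip values taken by monotypic clusters, which keeps IDs
  stable under refinement.
* The LDA ridge is `1e-4 · mean(diag(S_w))`, large enough to stabilize the
  solve and orders of magnitude below the between-class signal the score
  thresholds care about.
* In the exact ISA mode the observed arrangement is included in the
  enumeration; in the Monte Carlo mode the `+1/(B+1)` correction keeps the
  p-value valid.
* Problem sizes in the tests (trees ≤ 32 tips for oracle comparisons, 20
  scenario replicates for consensus operating characteristics, 100
  replicates for reclassification) were chosen to give stable Monte Carlo
  estimates while keeping the whole suite interactive.

# Known limitations

* The long-branch surrogate is diameter-based and global; it will miss a
  moderately long branch hidden inside a large-diameter tree where a
  per-tip statistical test might flag it.
* Strict consensus returns an empty lineage when database tips disagree at
  the domain rank; we do not attempt partial-agreement repair.
* The soil reclassifier is bounded by the overlap of the TM abundance
  distributions (see above); with better-separated communities it is
  exact.
* LEfSe scores are comparable within a run, not across implementations.
* MCL granularity depends on the inflation parameter; 2.0 is the
  conventional default, not a fitted value.
* pvclust-style bootstrap clustering of PM substrates is not implemented;
  only the activity index and its inputs are.
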