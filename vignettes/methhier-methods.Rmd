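---
title: "Hierarchical classification of tumor type from DNA methylation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical classification of tumor type from DNA methylation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem and the model

DNA methylation patterns are strongly tissue- and lineage-specific, which
makes genome-wide beta values (the methylated fraction at each CpG,
`M/(M + U + 100)` from methylated and unmethylated array intensities) a
natural substrate for classifying the primary type of a tumor. A flat
multi-class classifier over dozens of cancer types must find features that
separate *all* types at once; closely related types (squamous carcinomas of
different organs, the kidney carcinomas, the gliomas) then compete for the
same feature budget, and a poorly measured class can degrade every other
class. `methhier` instead classifies *through a hierarchy*: cancer types are
first organized into lineage groups by unsupervised clustering of their
methylomes; a first-layer classifier assigns a sample to a group, and a
second-layer classifier within the predicted group resolves the type. Groups
containing a single type are emitted directly by the first layer.

The pipeline has four stages, each exposed as ordinary functions and run
end-to-end by `methhier()`:

1. **Preprocessing** (`filter_probes()`, `filter_subtypes()`,
   `stratified_split()`). Probes are restricted to those shared by all
   cohorts, off the sex chromosomes, and without missing values (no
   imputation at this stage: a probe with any missing cell is dropped).
   Clinical subtypes with fewer than 5 samples or less than 10% of their
   cancer type are removed. Samples are split 4:1 into training and test
   sets, stratified by cancer type; the training count per type is
   `floor(0.8 n)` with the remainder (always at least one sample) held out.

2. **Taxonomy** (`subtype_means()`, `top_variance_probes()`,
   `pearson_distance()`, `upgma_tree()`, `choose_groups()`). Each clinical
   subtype is collapsed to its mean methylome; the top 1% most variable
   CpGs across all samples define the clustering space; subtype profiles
   are clustered by UPGMA (average linkage) on Pearson correlation distance
   `d = 1 - r`. The dendrogram is cut into `k` clades for every `k` in
   2..min(20, leaves-1) and the mean silhouette of each induced partition
   picks `k` (ties go to the smaller `k`). The silhouette is a *reference*,
   not an oracle: `choose_groups(overrides=)` accepts explicit subtype-to-
   group overrides so a curator can force merges or splits, which we prefer
   to hidden heuristics. A cancer type whose subtypes land in different
   groups is split into per-subtype class labels (`TYPE.subtype`), the way
   esophageal and cervical tumors split into adenocarcinoma and squamous
   classes in practice.

3. **Marker cascade** (`anova_screen()`, `tukey_kramer()`,
   `select_markers()`, `boruta_confirm()`). For each classification problem
   (the group problem, and each multi-type group's internal problem, using
   only that group's training samples): a one-way ANOVA per CpG screens
   probes at `p < 0.05`; the Tukey-Kramer test (studentized range
   distribution, valid for unequal class sizes) then requires, for a probe
   to mark class *g*, that *every* other class differs with adjusted
   `p < 0.01` *and* absolute mean difference above a delta-beta threshold.
   The threshold relaxes down a schedule (0.2, then 0.15, then 0.1) per
   class until at least `min_markers` (default 20) probes are found; the
   accepted level is recorded per class. Finally Boruta confirms markers
   against "shadow" features (see below). The trained model keeps the
   confirmed union as its panel.

4. **Forests and top-k² prediction** (`train_layer()`,
   `predict.methhier()`, `topk2_accuracy()`). Each problem gets a
   200-tree probability forest (ranger) with balanced class weights.
   At prediction time the top-2 first-layer groups are selected; singleton
   groups contribute their type, multi-type groups contribute the top-2
   types of their second-layer forest, so the candidate set holds 2-4
   labels; `top1` follows the best group's best type. Probes missing from a
   new cohort (e.g. another platform) are imputed with training-set means,
   with an error when more than half the panel is absent.

# Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `split_ratio` | 0.8 | training fraction of the 4:1 stratified split |
| `top_fraction` | 0.01 | fraction of most-variable CpGs used for clustering |
| `k_range` | 2..min(20, n-1) | candidate group counts for the silhouette scan |
| `anova_alpha` | 0.05 | ANOVA screen level (beta fraction scale) |
| `p_threshold` | 0.01 | Tukey-adjusted p cut-off for one-vs-all-others |
| `delta_schedule` | 0.2, 0.15, 0.1 | delta-beta relaxation ladder |
| `min_markers` | 20 | panel size below which delta relaxes |
| `boruta_max_iter` | 100 | shadow rounds before undecided features lapse |
| `n_trees` | 200 | trees per forest |
| `class_weight` | "balanced" | inverse-frequency class weights (switchable) |
| `k` (predict) | 2 | branching factor per layer; candidates number 2..k² |

Two published settings deserve comment. The source description of this
procedure prints an ANOVA screen threshold of "p < 0.5", which we read as a
typo for 0.05; the default is 0.05 and the literal value remains available
through `anova_alpha`. It likewise prints `class_weight = 'not-balanced'`
while motivating the setting by class imbalance; because the motivation and
the literal string contradict each other, the default here is balanced
weighting with `class_weight = "none"` available.

# The Boruta stage

Boruta decides, per feature, whether its forest importance is better than
chance. Each round appends a freshly permuted ("shadow") copy of every
feature, fits a forest, and scores a *hit* for each undecided feature whose
impurity importance exceeds the best shadow importance. Hit counts are
tested two-sided against Binomial(rounds, 1/2); the level is Bonferroni-
corrected across the undecided features *and across the rounds*, since the
same feature is re-tested every round. Two design details matter in
practice, and both are exercised by the tests: shadows are drawn for the
full original feature set every round (if shadows shrank with the undecided
set, the max-shadow bar would drop late in a run and features whose chance
correlation with the labels sits in the upper tail of the null maximum
would be confirmed spuriously), and features still undecided at
`boruta_max_iter` are dropped by default (`tentative = "rough_fix"` instead
compares their median importance with the median shadow maximum).

# The synthetic cohort generator

No external data ships with the package; `simulate_cohort()` generates
cohorts in which every downstream stage has a known right answer. The
default spec is a desk-scale analogue of a pan-cancer 450K compendium:
12 groups whose type counts (1,2,1,2,4,4,2,2,1,3,4,4) include three
singleton groups, 30 cancer types, 2 clinical subtypes per type, 20 samples
per subtype (1200 samples), 5000 background CpGs, 40 group-marker and 30
type-marker CpGs per class with delta-beta 0.3, beta noise at concentration
kappa = 50, two cohort tags, and 100 sex-chromosome probes. Batch shift and
missingness default to 0 and are exercised explicitly in tests; note that
the preprocessing rule (drop probes with any missing cell) makes uniform
per-cell missingness extremely destructive at 1200 samples, which is why
missingness is a scenario parameter rather than a default.

The group hierarchy is planted as a random **ultrametric** binary tree:
merge `t` of `n-1` happens at height `0.2 + 0.8 (t/(n-1))^1.5` on a unit
depth. Ultrametricity is not cosmetic — UPGMA estimates an ultrametric
tree, so only an ultrametric planted truth makes "recover the planted
topology" a well-posed check; the height floor keeps even the most recently
diverged groups far from the within-group scale, and the convex profile
spaces consecutive merges by a roughly constant relative gap.

Lineage signal is carried by a designated fraction (default 1.28%, i.e. 64
CpGs at default scale — matching the top-1% variance window the taxonomy
uses) of background CpGs with intermediate baselines (U(0.4, 0.6)), the way
real tissue-variable CpGs sit at intermediate methylation while most CpGs
are bimodally methylated and lineage-stable. Drift along the tree is a
variance-exact discretization of Brownian motion: each edge contributes a
fixed-magnitude sign pattern (`sd * sqrt(edge length)`, cumulative
root-to-leaf sd 0.2) across the lineage panel, and patterns of distinct
edges are mutually orthogonal columns of a Sylvester/Hadamard matrix,
randomly chosen and randomly flipped. Squared distance between two groups'
profiles then equals the drift variance times their tree distance (exactly
at power-of-two panel sizes), so recovery failures indicate taxonomy bugs
rather than simulation luck. Types and subtypes add independent Gaussian
profile deviations (sd 0.02 and 0.01). Marker CpGs carry no drift: a
marker's mean is a common baseline everywhere except its focal class,
shifted by ±delta with feasibility checked before sampling.

What the generator does **not** emulate: Type I/II probe chemistry, copy-
number contamination, tumor purity, spatially correlated methylation
(neighboring-CpG correlation), or realistic batch geometry (a scalar
per-cohort mean shift stands in for it). Passing tests on this generator
therefore show the pipeline's statistics and routing are correct under the
planted model — not that the classifier would reach any particular accuracy
on real arrays, where the headline numbers require the original cohorts.

# Numerical choices and degenerate inputs

* Beta values live in `[0, 1)` by construction (the +100 pseudo-count);
  draws that round to 1 are clipped just below.
* ANOVA with zero within-class variance: equal means give `p = 1`
  (excluded), distinct means give `p = 0` (retained); no crash.
* Tukey comparisons of exactly equal means report adjusted `p = 1` even
  when the pooled variance is 0.
* Variance ties in `top_variance_probes()` break by probe id; probability
  ties in top-k ranking break by class label — both stable and
  deterministic.
* Singleton clusters score silhouette 0; `k = n` (all singletons) scores 0.
* UPGMA merge ties follow `stats::hclust`'s convention; the output is
  deterministic for a fixed input.
* Probes absent from the annotation are kept (treated as autosomal) with a
  warning; unknown subtypes in overrides are errors.
* All randomness (split, Boruta, forests, generator) is seeded; seeded
  helpers restore the caller's RNG state.

# Problem sizes used by the test suite

The suite runs the full pipeline at the default generator scale (1200
samples by ~6400 probes) once, plus a 4-group routing cohort (240 samples)
and many micro-instances for the oracle equivalences (UPGMA cophenetic
round-trips, Tukey vs direct numerical integration of the studentized range
distribution, silhouette vs a brute-force transcription of its definition,
ANOVA vs `aov`). Five generator seeds are used for the tree-recovery
property. These sizes were chosen to exercise every code path at the
default study conditions while keeping a full run in minutes on a laptop.

# Known limitations

* The silhouette criterion prefers well-separated, roughly balanced groups;
  on data whose true structure is a gradient it will under-split, which is
  precisely why manual overrides are part of the interface.
* Marker panels are selected on training data only, but the taxonomy is
  derived from all samples (the procedure this package follows does the
  same); in a strict generalization study the taxonomy should be re-derived
  per training fold.
* Batch effects are not corrected, only simulated; cross-platform
  prediction relies on mean imputation of absent probes, which degrades
  gracefully but is no substitute for harmonization.
* Local methylation correlation (neighboring CpGs) is ignored throughout.
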