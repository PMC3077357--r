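---
title: "Discovering sample progressions from unordered expression data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering sample progressions from unordered expression data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spd)
```

## The model

Many expression datasets are snapshots of a gradual biological process —
a cell-cycle time course, a differentiation hierarchy, stages of tumour
progression — but arrive with no usable ordering of the samples. The working
assumption of this package is that (i) such an ordering (possibly branched)
exists, (ii) it is reflected in the *gradual* change of subsets of
co-expressed genes, and (iii) samples that are adjacent in the progression
are close in the expression space of those gene subsets. Under that
assumption a minimum spanning tree (MST) over the samples, built from the
right genes, traces the progression: an MST connects all samples with
minimal total edge weight and therefore links each sample to its most
similar neighbours. The scientific problem is *which genes*: on all genes,
sample distances are dominated by whatever varies most (often noise or an
unrelated signal), so the tree is meaningless. The pipeline is therefore
feature selection wrapped around tree building:

1. **Module discovery.** Genes are clustered into coherent modules by
   iterative consensus 2-means. Each cluster is split by running k-means
   (k = 2, random initialisation) `kmeans_runs` times, collecting the 0/1
   labels into a genes x runs matrix, and clustering *that* matrix once more
   with 2-means: genes that co-segregate across runs stay together
   regardless of per-run label flips. A cluster stops splitting when its
   *coherence* — the average Pearson correlation between each member gene
   and the cluster's per-sample mean — reaches `coherence_threshold`.
   Afterwards, any two modules whose centers correlate above
   `merge_threshold` are merged (highest pair first, centers recomputed
   after each merge, iterated to a fixpoint), and modules smaller than
   `min_module_size` are set aside as unassigned.
2. **Per-module trees.** For each module, Euclidean distances between
   sample profiles (on row-standardized data) feed an MST, grown by
   repeatedly picking one of the smallest components at random and adding
   the cheapest single-linkage edge leaving it. The result always attains
   the minimum spanning weight; the randomness only breaks size ties.
3. **Concordance testing.** A module and a tree are *concordant* when the
   sum of the module's sample distances over the tree's edges is smaller
   than expected by chance. The null is generated by permuting the sample
   labels of the module's distance matrix (`n_permutations` times); the
   p-value is `(1 + #smaller) / (1 + n_permutations)`, and concordance means
   p below `p_threshold`. Only edge distances are scored — distances between
   unconnected samples are ignored — so progressions that drift away from a
   state and return (the cell cycle) are not penalised. The module x module
   *progression similarity matrix* counts, for each pair, the trees
   concordant with both; modules sharing many concordant trees support a
   common progression even when their expression profiles are uncorrelated.
4. **Selection and the overall tree.** After average-linkage reordering of
   the similarity matrix, the analyst picks a diagonal block of mutually
   concordant modules (`select_modules()`); the MST over the union of their
   genes is the progression hypothesis. `auto_select_block()` automates the
   choice for pipelines and simulations; it is advisory, since no block
   criterion we know of is reliable across datasets.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `kmeans_runs` | 50 | k-means restarts pooled into each consensus split |
| `coherence_threshold` | 0.7 | minimum mean gene-to-center correlation of a module |
| `merge_threshold` | 0.9 | center correlation above which modules merge |
| `min_module_size` | 5 genes | smaller modules become unassigned |
| `n_permutations` | 1000 | permutations per concordance test |
| `p_threshold` | 0.002 | concordance call; 0.002 = 2/1001 is attainable at 1000 permutations |
| `top_n_variance_genes` | `"all"` | optional variance pre-filter |
| `seed` | 1 | root of every random stream |

All randomness (k-means initialisations, MST tie-breaks, permutations,
bootstrap draws) derives from `seed` through fixed per-stage streams, so a
run is reproducible end to end.

## Design choices

**Standardization.** Gene rows are z-scored before clustering and before
distance computation. k-means with a Euclidean metric on raw intensities is
dominated by high-magnitude genes, while the coherence statistic is
scale-free; standardization makes the two consistent. Constant genes become
all-zero rows and contribute nothing.

**Consensus label matrix.** Labels are coded 0/1 and the final 2-means runs
on raw label vectors with Euclidean distance. A global 0/1 swap in one run's
column is a rigid transformation of all gene vectors, so no label alignment
across runs is needed. The internal 2-means re-seeds an emptied cluster at
the point farthest from the surviving center, guaranteeing a bipartition;
a cluster of identical rows is the only unsplittable case and simply stops.

**Merging order.** Merges take the highest-correlation pair first. The
fixpoint of pairwise merging is not order-independent in general; greedy-max
is reproducible and favours the most redundant pair.

**p-value smoothing.** The raw permutation frequency can be zero; the
add-one form keeps p positive without changing which calls pass a 0.002
threshold at 1000 permutations. The count uses strictly smaller statistics,
so a module is never penalised for ties with itself. A distance matrix whose
off-diagonal entries are all equal (including the n = 2 case) makes the
statistic permutation-invariant; such tests return p = 1 with a warning.

**Multiple testing.** The m&sup2; module-by-tree tests are *not* corrected;
the fixed 0.002 threshold is the operating point of the method. BH
adjustment is available in the enrichment helper, off by default.

**Block selection score.** `auto_select_block()` maximises
`block size x minimum within-block similarity` over contiguous blocks of
the reordered matrix. The minimum alone prefers the tightest redundant
*pair* of modules, which spans a single expression direction and yields a
degenerate (folded) tree; weighting by size reproduces what an analyst does
with the heatmap — take the largest block whose entries are all clearly
above background. Ties prefer the larger block, then the earlier start, so
the choice is deterministic.

**Concordance with one's own tree.** Each tree is counted concordant with
the module it was built from by construction (the test is still run and its
p-value recorded): a tree's own statistic is the minimum over all spanning
trees, so any sample permutation can only increase it.

## The synthetic-data generator

`simulate_progression()` plants a known progression so that recovery can be
scored exactly. Samples lie on a path (positions equally spaced on [0, 1])
or a star (a root plus arms; the progression coordinate is depth along the
arm). Each progression module has a latent curve over that arrangement —
a monotone ramp (direction alternating between modules), a unimodal bump,
or a sinusoid with module-specific phase emulating phase-shifted cell-cycle
programs — and each member gene is the curve scaled by a loading drawn
Uniform(0.5, 1.5) plus i.i.d. Gaussian noise (`noise_sd`). Loadings keep
module members co-expressed but not identical, so clustering is stressed the
way real data would. Noise genes are i.i.d. standard Gaussian. Columns are
emitted shuffled: the pipeline never sees order in column position.

Three generator conventions matter for interpreting results:

* **Curves are scaled to unit variance across samples**, so `noise_sd` means
  "noise relative to unit signal" identically for every pattern and
  topology. Without this, a ramp over a short arm would carry far less
  variance than a sinusoid and the same nominal noise level would mean a
  much harder problem.
* **Sinusoids span 0.75 of a period by default** (`frequency`). Samples from
  a full period close a loop in module space; the two ends of the series
  coincide and no acyclic tree can represent the arrangement. Three quarters
  of a period keeps the endpoints far apart (the chord across the gap is
  several times the between-neighbour spacing) while remaining genuinely
  cyclic in shape, matching a synchronised time course that does not quite
  complete its cycle.
* **Star arm programs are drawn under an identifiability constraint.** On a
  star, every module responds on every arm with an arm- and module-specific
  random rate and sign (lineages run shared programs at differing rates, and
  some modules — `n_arm_specific` — are specific to one arm). Draws are
  rejected until, in the latent space of *any* subset of at least three
  shared modules plus any arm-specific ones, every base-to-base distance
  exceeds the larger root-to-base distance by at least 10%. Module selection
  can legitimately return such sub-blocks, and with unconstrained random
  rates two arms are occasionally near-collinear in a sub-block's space; the
  planted star is then not the minimum-spanning geometry of its own
  noiseless data, and a failure to recover it would say nothing about the
  method. The constraint encodes the biological premise that distinct
  lineages run geometrically distinct programs.

What passing these simulations does *not* show: the generator's modules are
rank-one (one latent curve per module), its noise is i.i.d. Gaussian with a
single scale, and there are no batch effects, probe effects, missing values
or count-type mean-variance relationships. Recovery here demonstrates the
machinery is correct and calibrated, not that any particular real dataset
will order cleanly.

## Evaluation machinery

Recovered trees are compared with a reference ordering (a unit-weight path)
through a topological overlap measure: for tree adjacency `A`, nodes `i != j`
get `(shared neighbours + A_ij) / (min(degree_i, degree_j) + 1 - A_ij)`,
diagonal 1, and the distance between two trees is the L1 difference of these
matrices over unordered pairs. This is a pseudometric that is zero exactly
on equal adjacency and rewards agreement of local branching structure; the
single-number aggregation (an L1 sum) is our choice and is stated here
prominently because other aggregations exist and would scale differently.
Null context comes from uniformly random labeled trees (Pruefer sampling):
their topological-overlap distance to the reference and their diameters
locate a recovered tree's path-likeness relative to chance. Robustness is
assessed by rerunning the full pipeline on random 90% gene subsamples
(`bootstrap_spd()`; selection inside the loop uses the block heuristic, as
manual selection is impossible there — the report records this).

## Numerical and degenerate-input behaviour

Distance ties in the MST are broken toward the smallest sample-index pair,
and component-size ties uniformly at random under the seed, so trees are
reproducible; with tied distances the edge *set* may differ from another
solver's but the total weight never does. Clusters whose mean profile is
constant (e.g. two perfectly anti-correlated genes) have no direction to be
coherent about and are treated as incoherent rather than erroring the run.
Pure-noise datasets run to completion: they produce few or no concordant
module pairs, and a selection over them is flagged in a message as a
low-confidence hypothesis.

## Problem sizes used in the checks

The shipped tests exercise the pipeline at the scale of a synchronised
cell-cycle series — 17 samples, 9 phase-shifted sinusoid modules of 20 genes
with 60% noise genes (and 80% for the feature-selection comparison) — and a
three-armed differentiation star with 19 samples and 6 modules; calibration
uses 500 noise replicates at 200 permutations, and the sampler checks use
32,000 draws. These sizes keep a full check run in minutes on one core while
leaving each statistical verdict (KS, chi-square, 9-of-10 recovery) well
resolved.

## Known limitations

Manual module selection is the canonical procedure; the block heuristic is
a labelled convenience. The concordance test's power depends on modules
having more than one effective expression dimension: a strictly rank-one
module's own MST folds the progression through its level sets, which lowers
cross-module concordance counts — visible in the simulations as similarity
blocks with moderate rather than maximal counts. Cycles cannot be
represented (trees are acyclic); a cyclic process must be sampled over less
than a full period, or it will be recovered cut at an arbitrary point.
Expression values are assumed already normalized and log-scaled; no
preprocessing is attempted.
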