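---
title: "Climbing a tree of hypotheses: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Climbing a tree of hypotheses: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(treepin)
```

## The problem

Many assays measure entities that live on a hierarchy: microbial taxa on a
phylogenetic or taxonomic tree, miRNA sequences grouped by transcript and
genomic cluster, cell subpopulations from successive over-clustering.
Testing each leaf on its own can miss weak but *coherent* changes that are
shared by a whole branch; testing only at a coarse level cannot pinpoint
which entities actually drive an association. `treepin` searches the tree
for a data-dependent resolution: a set of non-nested nodes whose
descendant-leaf sets partition the leaves, chosen so that detection power is
high while the false discovery rate (FDR) is controlled *at the leaf level*.

Two analysis modes share the machinery:

* **DA** (differential abundance): one feature per entity — a K × J count
  table and a two-group sample factor.
* **DS** (differential state): G features per entity — cell-level feature
  values with cell-to-leaf and cell-to-sample maps. Each feature climbs the
  tree independently, so different features may stop at different
  resolutions; multiplicity is then corrected jointly across features.

## The procedure

Five steps, all deterministic given the data and the node-testing engine.

**1. Aggregation.** For every node $i$ and sample $j$ the node value is a
summary of its descendant leaves $b(i)$: for counts,
$Y_{ij} = \sum_{k \in b(i)} Y_{kj}$ (so the root row is the library size);
for cell-level state markers the default is the median over the cells mapped
below the node. Node × sample cells with no contributing cells are treated
as missing, not imputed.

**2. Node-level testing.** Any engine producing a raw p-value $p_i$ and a
direction $\mathrm{sign}(\theta_i) \in \{-1, 0, +1\}$ per node works
(`attach_external_stats()` is the integration point). Two engines are
built in:

* `nb_glm_node_test()`: a negative-binomial log-linear model per node with
  a group effect, leaf-level library sizes as offsets, edgeR dispersion
  estimation and the quasi-likelihood F-test. The QL test is used rather
  than the likelihood-ratio test because it keeps the type I error
  calibrated at small replicate numbers; with 10 samples per group the LRT
  tail is visibly anti-conservative.
* `wilcoxon_node_test()`: the exact two-sided rank-sum test (exact null
  when both groups have ≤ 10 samples and no ties, normal approximation with
  tie correction otherwise), with optional library-size normalization. Its
  p-values are distribution-free, which matters for heavily overdispersed
  count data (see "Engine choice" below).

**3. Candidate proposal.** For a tuning value $t \in [0, 1]$, each node $k$
gets a signed significance score $q_k(t) = \mathrm{sign}(\theta_k)\,
I(p_k \le t)$, and each node $i$ a coherence score

$$U_i(t) = \left| \frac{\sum_{k \in B(i)} q_k(t)}{n_B} \right|,$$

where $B(i)$ is node $i$ together with all of its descendants and
$n_B = |B(i)|$. $U_i(t) = 1$ exactly when every node in the branch is
significant at $t$ with a single shared direction. The candidate at $t$ is
found by climbing from the root: on each root-to-leaf path, stop at the
first node with $U_i(t) = 1$ **and** $p_i < 0.05$, or at the leaf. The
$p_i < 0.05$ admission threshold keeps null branches represented near the
leaf level: a three-leaf branch without signal is represented by its
internal node with probability about $0.25 \times 0.05 = 0.0125$ (all three
leaves agree in direction with probability $1/4$), and much lower for larger
branches. The indicator in $q$ is non-strict ($p \le t$) while the admission
rule is strict ($p < 0.05$); nodes with missing p-values contribute $q = 0$,
still count in $n_B$, and can never be termini, which keeps the partition
property intact. In DS mode, per-feature candidates at the same $t$ are
pooled by union, with provenance tracking which nodes terminate which
feature.

**4. Per-candidate correction.** BH is applied within each candidate, over
the node-feature pairs for pooled candidates, so the global FDR across
features is controlled jointly rather than feature-by-feature. A rejected
internal node propagates to all of its descendant leaves.

**5. Selection.** From each candidate's own rejections we estimate the mean
signal-branch size $\hat r = l / s$ ($s$ distinct rejected nodes, $l$ unique
descendant leaves; $\hat r = 1$ when $s = 0$). Candidates are kept only if
$t \le 2\alpha(\hat r - 1)$ — the data-dependent bound that keeps the
leaf-level FDR near the nominal $\alpha$; $t = 0$ (the leaf-level candidate,
equivalent to plain BH) is always admissible, so a selection always exists.
Among admissible candidates the winner maximizes the number of rejected
leaves, then minimizes the number of rejected nodes, and remaining ties go
to the smallest $t$ — the final tie-break favors resolutions closer to the
leaves, where individual entities remain identifiable.

For DS selection, rejected leaves are counted as the unique union across
features, and the same union-based $\hat r$ feeds the admissibility bound;
counting leaves per feature instead would inflate $\hat r$ when several
features reject the same branch.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `alpha` | 0.05 | nominal leaf-level FDR |
| `t_grid` | 25 values: 0–0.04 by 0.01, then 0.05–1 by 0.05 | tuning values at which candidates are proposed; finer near 0 because the admissible range usually is |
| `p_thresh` | 0.05 | admission threshold for an internal terminus; a fixed constant of the method (the ≈ 0.0125 null three-leaf probability above derives from it), exposed for sensitivity analysis only |
| `fun` | `"sum"` (DA), `"median"` (DS) | aggregation summary |
| `engine` | `"nb"` (DA), `"wilcoxon"` (DS) | node-testing engine |

## Engine choice and calibration

The admissibility bound controls the leaf-level FDR only insofar as the
node-level p-values are honest. For Dirichlet-multinomial counts with
overdispersion around $\theta = 0.02$ and 10 samples per group — the
simulator's default study conditions — the parametric NB tail is inflated
even with the QL test (roughly 1.5× the nominal mass below $10^{-2}$),
which propagates into an inflated realized FDR precisely when per-leaf
power is low and every rejection is borderline. The exact rank-sum engine
has no such tail problem, at the price of a granular p-value distribution
(with 10 + 10 samples the smallest achievable two-sided p is
$2/\binom{20}{10} \approx 1.1 \times 10^{-5}$). The package therefore
defaults to the NB engine for count data, as is conventional, but the
simulation benchmarks in the test suite and the acceptance script use the
rank-sum engine, where FDR calibration is the property under study.

## The simulator

`simulate_dataset()` draws counts per sample as
$p \sim \mathrm{Dirichlet}(\alpha)$, $x \sim \mathrm{Multinomial}(n, p)$
with $\alpha_k = \pi_k(1 - \theta)/\theta$, the depth $n$ resampled with
replacement from a depth pool. Parameters can be estimated from a real
count table by maximum likelihood (`estimate_dm()`: fixed-point iteration
on $\alpha$ with moment initialization, convergence at $10^{-8}$
log-likelihood change, $\hat\theta$ clamped to $[10^{-6}, 1 - 10^{-6}]$) or
set synthetically. Signal is written into the *proportions*, not the
counts, so the relative abundance of unaffected leaves is exactly unchanged
between groups — the compositionally clean way to spike differences:

* **BS** (balanced): two disjoint branches $A$, $B$ swap their total mass,
  $\pi^T_k = r\pi^C_k$ on $A$ and $\pi^T_k = \pi^C_k/r$ on $B$ with
  $r = \sum_B \pi^C / \sum_A \pi^C$; every leaf in a branch shares one fold
  change.
* **US** (unbalanced): per-leaf multipliers drawn log-uniformly within one
  log unit of $\log r$, then rescaled so the branch-mass swap is preserved.
  The published description fixes only "same direction, different
  magnitude"; the log-uniform half-width of 1 is this package's
  construction, isolated in `apply_us()` so it can be swapped. Directions
  are recorded from the realized multipliers.
* **SS** (sporadic): the swap is applied to random subsets (default half)
  of each branch; unaffected leaves inside the branches keep $\pi$ exactly,
  and with `fraction = 1` the output is identical to BS.

Default study conditions, used throughout the tests: a random 100-leaf
binary coalescence tree, $\pi$ from a symmetric Dirichlet (shape 2) draw,
$\theta = 0.02$ (the order of magnitude typical of 16S surveys), depth pool
10,000–50,000, signal branches of 5–10 leaves, 10 samples per group, 50
repetitions for rate estimates. These sizes keep a full benchmark under a
minute while leaving Monte-Carlo standard errors on FDR around 0.01–0.06.

What the simulator does *not* emulate: real taxon-abundance skew (a real
$\hat\pi$ spans many orders of magnitude; the symmetric Dirichlet draw is
milder), zero inflation beyond what DM sampling produces, correlation
between branch location and abundance, and uneven tree shapes from real
phylogenies. Passing benchmarks therefore demonstrate the algorithm's
statistical behavior under its own assumptions, not field performance on
any particular survey.

## Numerical choices and degenerate inputs

* $U = 1$ is detected by the integer identity $|\sum q| = n_B$ — no
  floating-point tolerance is involved.
* Identical values in both groups give $p = 1$, direction 0; a direction
  tie (exact zero mean difference) gives sign 0 and blocks $U = 1$ on
  multi-node branches.
* All-zero count nodes get missing p-values; missing p never rejects and
  does not count toward $m$ in BH.
* `estimate_dm()` clamps $\alpha_k$ below by $10^{-10}$ so empty leaves
  cannot derail the fixed point; replicate-free data drives $\hat\theta$ to
  the lower clamp.
* A null swap ($r = 1$, equal-mass branches) yields an empty truth set by
  construction.
* Newick round trips preserve topology, labels and branch lengths but not
  child order within a node (trees are unordered); unlabeled internal nodes
  get synthetic `node_<id>` labels that are not written back out.

## Known limitations

* The admissibility bound assumes independent-ish, calibrated node
  p-values; trees built from the same data being tested ("double dipping",
  e.g. correlation trees from the test samples) overestimate $\hat r$ and
  void the FDR guarantee. Keep tree construction independent of the
  group contrast.
* The rank-sum engine needs ≥ 2 samples per group per node and has granular
  p-values below ~8 samples per group, which caps how many hypotheses can
  survive BH in pooled DS candidates.
* `benchmark()` scores at the leaf level only; cell-level weighting for DS
  evaluation is exposed via per-node cell counts but not implemented.
* The t grid is fixed; no adaptive refinement between grid points.
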