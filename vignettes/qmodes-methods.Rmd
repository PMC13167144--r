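---
title: "Aligning replicate admixture clustering runs: models and methods"
author: "Qmodes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Aligning replicate admixture clustering runs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(Qmodes)
```

## The cluster alignment problem

Unsupervised mixed-membership clustering programs used in population
structure analysis (Structure, ADMIXTURE, fastStructure) return, per run, an
N × K membership matrix Q whose row i gives individual i's estimated
membership coefficients across K latent clusters (rows sum to 1).  Replicate
runs on the same data are hard to compare directly for three reasons:

1. **Label switching.** Cluster labels are arbitrary: all K! column
   permutations of the same solution are equally likely.
2. **Multimodality.** Runs can converge to genuinely distinct local optima
   ("modes") that no relabeling reconciles.
3. **Varying K.** Users typically scan a range of K values, and structure
   visible at one K must be traced to the clusters it descends from at
   smaller K.

Qmodes resolves the three in sequence: optimal pairwise matching of clusters
between same-K runs, community detection of modes on the resulting
similarity network, and anchored alignment of modes across K values, with
bar-plot and pattern-graph visualizations and a model-comparison view.

## The matching objective

For a target run $Q_a$ (N × $K_1$) and a source run $Q_b$ (N × $K_2$,
$K_2 \ge K_1$), a matching $m$ assigns each source cluster to exactly one
target cluster, covering every target cluster.  Qmodes scores it by

$$\mathrm{cost}(m) \;=\; \frac{\lVert Q_a - M_m(Q_b)\rVert_F^2}{2N},
\qquad \mathrm{similarity} = 1 - \mathrm{cost},$$

where $M_m(Q_b)$ **sums** the source columns mapped to each target cluster.
Summing (not averaging) conserves membership mass, so a column that is
cleanly split in two at a larger K merges back exactly and the alignment
cost is 0.  Because $Q_a$ and $M_m(Q_b)$ are both row-stochastic, each row
contributes at most 2 to the squared norm, so the cost lies in $[0,1]$ and
cost 0 holds iff the matched matrices agree entrywise.  This quadratic
functional is this package's fixed design choice for the matching objective;
it reduces to a standard linear-assignment objective at equal K, and it is
isolated in `alignmentCost()` so an alternative functional is a one-function
change.

**Equal K.** The cost decomposes over matched column pairs, so the optimal
bijection is a linear sum assignment over the K × K matrix of squared column
distances; `alignSameK()` solves it with an $O(K^3)$ shortest-augmenting-path
solver (compiled).  One K = 40 alignment takes milliseconds, consistent with
polynomial-in-K behavior.

**Unequal K.** With $K_1 < K_2$ the feasible set is that of the binary
program with variables $x_{cd} \in \{0,1\}$, $\sum_d x_{cd} = 1$ per source
cluster and $\sum_c x_{cd} \ge 1$ per target cluster.  Because merged
columns interact quadratically, this is not a plain assignment problem.
`alignCrossK()` solves it *exactly* by observing that every surjection is a
set partition of the $K_2$ source clusters into $K_1$ non-empty blocks plus
a bijection of blocks onto targets: it enumerates the partitions (costs via
Gram matrices, so enumeration is independent of N) and solves one linear
assignment per partition.  The enumeration count is the Stirling number
$S(K_2, K_1)$, which is small whenever the K gap is small — the regime the
workflow uses, since only adjacent present K values are aligned (for
K = 39 vs 40 it is 780).  A guard (default $5\times10^5$ partitions) makes
the blow-up regime an explicit error rather than a silent stall.

**Determinism.** Among cost-tied optima the lexicographically smallest
assignment vector is returned (prefix-fixing re-solves), so every downstream
artifact is bit-reproducible.  `bruteForceAlign()` retains full enumeration
(all bijections or all surjections, K ≤ 7) as an independent oracle; the
test suite checks exact agreement on hundreds of random instances.

## Mode detection

For the R runs at one K, `buildSimilarityNetwork()` computes all
$\binom{R}{2}$ optimal pairwise similarities.  `detectModes()` partitions
the network by community detection — Louvain modularity optimization
(default) or Markov clustering — after removing edges whose similarity falls
below an absolute floor (`minEdgeSimilarity`, default 0.7).

The floor is a deliberate design decision, not a tuning knob.  Newman–Girvan
modularity is invariant to a uniform rescaling of edge weights, so Louvain
on the raw complete network cannot distinguish "all runs mutually similar"
from "all runs mutually dissimilar": both are near-uniform weight matrices
and both would collapse into a single community.  An absolute similarity
floor restores the intended semantics — runs whose alignment similarity is
below it are never forced into a mode — and mode-grouping thresholds on
absolute similarity are standard practice in this field's tooling.  The
default 0.7 sits well below within-mode similarities observed in practice
(≈0.8 and up under this quadratic similarity) and well above the ≈0.55
similarity of structurally distinct solutions; setting it to 0 recovers
raw-weight behavior.  Markov clustering runs on the same floored network
(self-loops keep isolated runs as their own attractors) with inflation 2.0
by default.

Two extremes follow: replicates identical up to permutation give one mode of
size R, and mutually dissimilar runs give R singletons.  Separately,
`forceSingleTol` (off by default) bypasses community detection entirely and
returns a single mode whenever *every* pairwise dissimilarity is below the
tolerance (e.g. $10^{-6}$) — useful when minor disagreements are acceptable
for summarization.

Modes are numbered by decreasing size (M1 is the major mode), with ties
broken by higher within-mode similarity and then by the smallest member run
ID.  Within a mode, members are re-aligned to the mode **medoid** (the
member with the highest total similarity to the others — deterministic and
robust, since no external reference exists), and the representative is the
entrywise mean of the aligned members with rows renormalized.  The
within-mode similarity reported everywhere is the mean over unordered member
pairs (1 for singletons).

## Alignment across K

For each *adjacent pair of present* K values (absent K values are skipped
and the neighbors aligned directly), an **anchor mode pair** is chosen:
either the cross-K pair with maximal alignment similarity (`"best"`) or the
two major modes (`"major"`).  The anchor pair is aligned by the exact
surjective solver.  Every other mode is aligned to the anchor mode *of its
own K* by same-K alignment of representatives, and its cross-K matching is
the composition through the anchor's matching.  Composition (rather than
independent pairwise cross-K alignment) guarantees a single consistent
global labeling across all modes; the reported cost of a composed edge is
the cost functional evaluated at the composed matching, which need not be
the pairwise optimum.

Global cluster labels propagate upward from the smallest K: the major mode
there takes labels 1..K in column order; at each step, the child column
closest in squared distance to its parent's column inherits the parent's
label, and each remaining child receives the next unused label (several new
labels at a K gap are assigned in decreasing order of the new columns' total
membership).  Consequently exactly $K_2 - K_1$ new labels appear between
adjacent present values, and a cluster chain keeps its label (and hence its
color) through every figure.  `patternEdges()` flattens the graph into
parent→child records, flagging anchor edges and edges into newly emerged
clusters; these drive the alignment pattern graph.

## Visualization

`reorderIndividuals()` implements the display rule: individuals are grouped
by their population labels, and within each group sorted in descending
membership in the group's *dominant* cluster (the cluster with largest total
membership over the group) of a reference mode — the major mode at the
largest K by default, or the smallest K.  The sort is stable, hence
idempotent on its own output.

`plotMultipartite()` arranges mode bar plots in rows by K (ascending
top-to-bottom), annotates each with its size and within-mode similarity, and
connects adjacent-K modes with edges labeled by cost; edge gray level maps
similarity linearly from black (1) to light gray (the graph's minimum
similarity, floored at 0.8 luminance — the direction is the established
convention, the scale is this package's choice).  `plotAlignmentPattern()`
draws each mode as K label-colored nodes (new labels appended to the right)
and emphasizes connections to newly emerged clusters while dimming
direct-match connections to 20% opacity; anchor-pair edges are solid, others
dashed.  Colors come from a fixed, documented 48-color palette keyed by
global label.  Bar rendering subsamples only the *drawing* resolution above
2000 bars (with a warning); the data are never subsampled.

## Model comparison

`compareModels()` runs the entire per-model pipeline independently (the
per-model results are bitwise identical to single-model runs — tested), then
aligns each non-reference model's modes to the reference model's major mode
at every K present in both, on representatives, so that colors are
comparable across models.  Alignment only relabels; representatives are
never altered.  Clusters whose mean membership falls below
`epsilon` (default 0.01 — configurable; the phenomenon it flags is the
near-empty clusters some programs produce at large K) are flagged in the
summary and annotated in the figure.  The comparison figure interleaves
models within each K, K increasing downward, with alternating background
shading per model.

## The synthetic generator

`syntheticSpec()` plants a study: G labeled groups (one distinct dominant
cluster each, dominant membership `profileStrength = 0.95`), rows drawn from
a Dirichlet with concentration `noiseScale × profile` (so draws stay on the
simplex and `Inf` recovers the profile exactly).  `noiseScale = 50` is the
default "moderate noise": per-coefficient jitter of a few hundredths,
comparable to replicate scatter of well-converged runs, giving within-mode
pairwise similarities above 0.99.

Alternative modes shift the dominant cluster of the leading
`reassignFraction = 0.5` of each group's individuals cyclically, which no
label permutation can undo; with strength 0.95 the optimal cross-mode
similarity is ≈0.55, i.e. planted modes are separated by construction
(within ≥ 0.95, cross ≤ 0.6).  These values were fixed from this analysis,
not fitted to any test outcome.  `makeSplitHierarchy()` builds K + 1 bases
by splitting the largest column of the K base into children of 55%/45% of
its mass (child 1 replacing the parent, child 2 appended), recording the
plant, so cross-K recovery is exactly checkable.  `makeReplicates()` applies
noise and a recorded uniform random column permutation per replicate.

What the generator does *not* emulate: linkage between individuals,
K-dependent convergence failure, correlated (non-Dirichlet) noise, and
near-empty clusters arising spontaneously.  Passing tests therefore
demonstrate correctness of alignment, detection and propagation under
controlled conditions, not robustness to every pathology of real inference
output.

## Numerical choices and degenerate inputs

* Row sums drifting from 1 by ≤ 0.05 are silently renormalized at parse
  time (rounding drift in program output); larger drift is an error.
  Validated rows must sum to 1 within 1e-6.
* Solver cost comparisons use 1e-9; assignment ties break lexicographically.
* K = 1 runs align trivially with cost 0; all-zero columns are legal in a
  source matrix and map wherever the cost increase is smallest.
* Singleton modes have within-mode similarity 1 by definition.
* Write/read round trips are exact to 1e-12 (15 significant digits in every
  text artifact, which also makes artifacts byte-reproducible).

## Pipeline sizes used in the tests

The default test and acceptance workloads use N between 30 and 60, R up to
10 runs per K, and K from 2 to 6 (plus a K = 40 alignment smoke check);
oracle comparisons run on a few hundred random instances with N ≤ 20.
These sizes were chosen so the full suite exercises every code path in
minutes while remaining far above the scales at which the combinatorial
oracles are exact.

## Known limitations

* The cost functional is this package's documented choice; numeric
  similarity values are not interchangeable with tools using a different
  objective, although cost-0/similarity-1 statements are.
* Cross-K alignment is exact only while the set-partition count is within
  the guard; enormous K gaps (e.g. K = 5 vs K = 30 directly) are refused.
* Composed (non-anchor) edge costs are evaluations, not optima — by design,
  to keep one consistent labeling.
* Individual identity is positional: all runs must list individuals in the
  same row order (Structure per-individual IDs are not used to reorder).
* Louvain below the similarity floor cannot subdivide a mode whose internal
  similarities dip under `minEdgeSimilarity`; lower the floor for such data.
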