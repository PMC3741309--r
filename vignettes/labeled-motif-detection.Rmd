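---
title: "Detecting sample-specific labeled network motifs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting sample-specific labeled network motifs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(samplemotifs)
```

## The problem and the model

Classical network-motif analysis decomposes a *single* network into small
directed subgraphs and asks which isomorphism classes are overrepresented
relative to a randomized null model. `samplemotifs` addresses a different
setting: a **sample** of simple directed networks of equal size — for
example effective connectivity networks (ECNs) estimated from the EEG of a
group of subjects — in which every network carries the *same pairwise
different vertex labels* (electrode names such as `F3`, `Fz`, `Cz`).

Unique labels change the combinatorics fundamentally. Two subnetworks are
identical if and only if they have the same edge set (their adjacency
matrices coincide), so no isomorphism testing is needed, each subnetwork can
occur at most once per network, and every detected pattern has an
unambiguous *location*. The statistic of interest is therefore the **sample
count** of an induced, weakly connected, k-vertex labeled subnetwork: the
number of sample elements whose induced subgraph on the pattern's vertices
equals the pattern. Patterns whose counts are significantly larger than
expected under a suitable null model are the sample's motifs — conserved,
locatable interaction patterns. Because even a size-2 pattern is pinned to a
specific vertex pair, k = 2 is already informative here, unlike in unlabeled
motif analysis.

### Enumeration

`enumerateSubnetworks()` scans all `choose(n, k)` vertex combinations of
each network and keeps those inducing a weakly connected subgraph. For the
small, dense networks this method targets (n about 9–20, k in 2–5) the
combination scan is faster and simpler than recursive enumeration schemes
designed for large sparse graphs, which are deliberately out of scope. On
k distinctly labeled vertices there are `countConnectedTopologies(k)`
possible connected patterns (3 for k = 2, 54 for k = 3, 3834 for k = 4,
verified exhaustively), so with n = 9 vertices a network sample can realize
up to `choose(9, 3) * 54` distinct 3-patterns and 72 directed pairwise
interactions.

"Connected" means **weak** connectivity (directions ignored). The
convention matters only for which vertex sets count as patterns at all; it
is the standard choice in motif detection, and the package applies it
consistently in enumeration, containment checks and validity of
`LabeledSubnetwork` objects.

### The null model

The null hypothesis is that edges attach without preference *given each
network's in- and out-degree sequence* — the degree sequence constrains
where edges can sit and must not itself be mistaken for structure. Null
networks are generated by the **edge-switching** Markov chain: two distinct
directed edges `(t1,h1)`, `(t2,h2)` are drawn uniformly and their heads
exchanged, the proposal being rejected (a counted self-transition) whenever
it would create a loop or multi-edge. One randomization performs
`round(Q * m)` attempts. The chain preserves the degree sequence exactly and
keeps the graph simple at every step; it does **not** preserve the number of
bidirectional pairs, which is accepted behavior and surfaced in run metadata
(`bidirectionalObserved`) rather than corrected.

Two caveats motivate the calibration machinery:

* the chain is **not irreducible** for every degree sequence — the directed
  3-cycle is a fixed point (every proposal creates a loop), and
  `switchSpace()` computes the exact reachable class for small networks;
* no useful a-priori bound on the mixing time exists, so "Q large enough"
  must be checked, not assumed.

### Calibrating Q

Calibration runs on one **representative** element per sample
(`selectRepresentative()`: the network whose concatenated (in, out) degree
vector is closest to the sample mean in the maximum norm, ties to the lowest
index), since calibrating every element would be needlessly expensive.

For each Q on a grid, `NperQ` realizations are generated and scored with the
**performance index** `performanceIndex()` — a chi-square-style statistic
comparing the category counts of the distinct generated networks against the
uniform hypothesis, where each category is one network with the prescribed
degree sequence. The common category probability is `p0 = 1/S` with `S` the
number of pairwise-different networks seen across *all* Q values pooled
(plus the input network): chains with very different Q explore different
regions of the space, so pooling gives the best available lower bound on the
space size. Because `S` is only a lower bound, the index is conservative in
an unknown direction; the report carries `n_distinct` and `p0` so this is
visible. Since expected category counts are typically far below
chi-squared rules of thumb, the critical value is the **Monte-Carlo**
(1 − alpha) quantile of the index under multinomial uniformity
(`mcQuantile()`; in the two-category, large-N limit it reproduces the
chi-squared 3.84 to within simulation error). The smallest Q passing the
check is chosen; if none passes, the minimal-index Q is used with
`uniform = FALSE`.

Two degenerate single-category cases are distinguished by checking whether
any accepted, state-changing switch exists: a genuinely one-state space
(the 3-cycle) is trivially uniform, whereas a single observed category on a
switchable network (e.g. Q = 0) is reported as non-uniform.

The default grid `c(1, 3, 10, 30, 100, 300)` spans the range from clearly
insufficient to the "about 100 attempts per edge" region that empirical
motif-detection practice considers more than adequate; it is configurable
and always recorded in output metadata.

### Calibrating the ensemble size

`estimateEnsembleSize()` asks how many randomizations per element are enough
for stable relative subnetwork frequencies. `Bmax` bootstrap ensembles are
generated (one randomization of every element each); the relative frequency
distribution over the first `B` of them is compared to the full-`Bmax`
reference in the sup norm, and the smallest `B` within `epsilon` is
accepted, else `Bmax`. Using nested prefixes rather than independent
regenerations keeps the cost linear in `Bmax` and makes the distance
decrease essentially monotone. Defaults (`Bgrid = c(25, 50, 100, 200)`,
`Bmax = 400`, `epsilon = 0.02`) suit the 9-vertex geometry; for production
analyses `M = 1000` (the field's customary ensemble size) is the fixed
default when no estimate is requested.

### Significance

For a candidate pattern with observed sample count `c`, each element `i`
contributes an occurrence probability `q_i`: the fraction of *its own*
ensemble's realizations that contain the pattern as an induced subnetwork.
The count under the null is then Poisson-binomial — a sum of independent,
unequal Bernoulli variables, one per subject — and the one-sided p-value
`P(X >= c)` is computed **exactly** by dynamic programming
(`poissonBinomialTail()`), avoiding the normality assumption that z-score
motif statistics make. Modelling per-element probabilities (rather than one
pooled frequency) respects that each subject has its own degree sequence;
when all `q_i` coincide the distribution reduces to a binomial, and the
pooled-frequency variant could be swapped in behind
`occurrenceProbabilities()` without touching anything else.

Finite ensembles of size M cannot distinguish probabilities below `1/M`
from zero, so frequencies are clamped to `[1/(M+1), M/(M+1)]`; this
prevents spurious p-values of exactly 0 and makes every reported p-value
achievable. Multiplicity over the candidate family is controlled by the
**Bonferroni–Holm** step-down rule (`holmAdjust()`, backed by
`stats::p.adjust`), controlling the familywise error rate in the strong
sense — deliberately stricter than false-discovery-rate control, because a
motif claim here is a pointed statement about one specific labeled pattern.

### The candidate filter and the test family

`filterCandidates()` keeps patterns reaching a minimum count in at least one
analyzed sample; `runDetect()` then tests the *union* family across samples
so all samples face the same hypotheses. The defaults follow the intended
use (`minCount = 4` at k = 3, `minCount = 1` at k = 2), but the filter has a
statistical price worth stating plainly: selecting candidates by their
counts and then correcting only over the selected few does **not** control
the familywise error over all patterns. In unplanted simulations the
familywise rate at k = 2 is far below alpha with `minCount = 1` (family =
all observed keys) and severely inflated with `minCount = 4`. The filter
buys power and interpretability at k = 3, where testing every one of the
thousands of observable patterns would destroy power; users wanting strict
error control should set `minCount = 1`.

## What the synthetic generator does and does not emulate

`generateSample()` draws each element as a directed G(n, p) over the
9-electrode label set (every ordered pair independently with `pBase`), then
adds each planted pattern in full with its planting probability. This
matches the geometry of EEG group samples — 9 vertices, 15–16 subjects,
element-to-element degree variation — and gives exact control of
overrepresentation for testing recovery and error rates. It does *not*
emulate spatial correlation between neighbouring electrodes, hemispheric
symmetry, subject-level edge-density differences, or the signal-level
estimation pipeline that produces real connectivity networks (out of scope
by design). Passing tests therefore demonstrate correctness of the
statistical machinery under a clean null, not robustness to the structured
noise of real EEG data.

Defaults: `sampleSize = 16` (the typical group size; 15 as a common
variant), `pBase = 0.1` for unplanted nulls (about 7 of 72 possible arcs,
a sparse-but-connected regime typical of thresholded connectivity
networks), `pBase = 0.05` under planting so the planted pattern dominates
its background.

## Numerical and implementation choices

* **Keys.** A subnetwork's canonical key is its radix-sorted `tail>head`
  token list joined by `|` — locale-independent, order-independent, and
  injective on edge sets (property-tested).
* **Reproducibility.** The switching chain runs on a self-contained
  splitmix64-seeded xoshiro256** generator; realization r of an ensemble is
  the chain on stream r, so ensembles are bitwise reproducible from
  `(network, Q, M, seed)` alone and the fused counting path used by
  `detectMotifs()` is provably identical to materializing
  `generateEnsemble()` (tested). All element- and purpose-level seeds are
  derived deterministically from the one run seed and stay below 2^31.
* **Degenerate inputs.** Networks with fewer than 2 edges cannot be
  switched: randomization warns and returns the input, and such elements
  contribute a deterministic ensemble. Empty candidate sets yield an empty
  result with full metadata. `alpha = 0` never flags.
* **Ties.** Representative selection breaks distance ties by lowest index;
  Holm ranks ties by first occurrence; the Monte-Carlo quantile uses the
  default empirical quantile (type 7), whose p = 0 case is the simulated
  minimum.
* **Problem sizes.** The validation suite runs enumeration oracles on 50
  random networks up to n = 6, exact Poisson-binomial cross-checks up to
  n = 12, uniformity certification on a brute-forced 9-network degree
  class (450 realizations), 200 unplanted detection runs for the
  familywise rate and 50 planted runs for recovery (M = 500, Q = 100) —
  sizes chosen so the full suite completes on a laptop-class single core
  in a few minutes while keeping every Monte-Carlo bound meaningful.

## Known limitations

* The edge-switching chain's non-irreducibility means some degree classes
  are only partially explored no matter how large Q is; the calibration
  detects non-uniformity but cannot repair it (triangle-reversal moves,
  which would, are out of scope).
* The distinct-network count entering `p0` is a lower bound; on large
  degree classes the uniformity check can be far from sharp, and with
  desk-scale `NperQ` most categories are unobserved.
* Occurrence probabilities are plug-in estimates; their Monte-Carlo error
  propagates into p-values. The clamp bounds, but does not remove, this
  effect — increase M for small target p-values.
* The candidate filter's selection effect (above) is inherited from the
  method's design; it is reported, not hidden.
* Only overrepresentation is tested; underrepresented ("forbidden")
  patterns are a non-goal, as are weighted or undirected networks.

## A minimal session

```{r example, eval = FALSE}
pl <- list(list(edges = rbind(c("Fz", "F4"), c("F4", "Fz")), prob = 1))
s <- generateSample(pBase = 0.05, planted = pl, seed = 7)
ma <- detectMotifs(s, k = 2, minCount = 1, Q = 100, M = 500, seed = 1)
significantMotifs(ma)
```
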