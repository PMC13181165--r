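---
title: "Mining structured missingness in bipartite nominal data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining structured missingness in bipartite nominal data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bimiss)
```

## The setting

A table with two nominal columns — and optionally one numeric column — is a
weighted bipartite network: rows of the incidence matrix $A$ are the levels
of the first variable (set $V$), columns the levels of the second (set
$W$), and $A_{ij}$ the measured edge weight. Cells never observed are
*missing*, and `bimiss` treats them as **unknown interactions, not zeros**:
an observed weight of 0 is data; an absent weight is absence of knowledge.
Every analysis in the package respects that distinction through an explicit
observation mask.

The package's organizing idea is that the *arrangement* of missing cells
carries information. Holes produced by detection limits pile up where
signals are weak; holes produced by uneven sampling form blocks; holes
produced by random dropout scatter. The pipeline quantifies which of these
regimes a dataset is in, extracts fully observed cores, and only then — and
explicitly marked as optional — imputes.

## Packing and the nestedness temperature

### Packing

`pack_matrix()` sorts rows and columns by decreasing presence counts so
that a nested matrix concentrates its presences in the upper-left corner.
Marginal counts alone leave ties, and how ties are ordered changes the
temperature, so packing must be *canonical*: the tie-break chain is

1. marginal presence count (decreasing);
2. presence-weighted sum of the opposite margin's totals (decreasing);
3. bipartite colour refinement: rows and columns repeatedly receive the
   sorted multiset of their partners' current colours until the colouring
   stabilizes;
4. lexicographic pattern individualization with respect to the evolving
   opposite order, which collapses automorphic layouts (tied rows whose
   swap is equivalent to a swap of tied columns) onto one representative;
5. original index, which at this point only separates *identical* lines.

Keys 1–4 are invariants of the underlying labelled bipartite graph, so the
packed layout — and everything derived from it — does not depend on the
order in which the input happened to arrive. This is deliberately stronger
than count-based packing: without steps 3–4 the temperature of a matrix
could change under a row/column shuffle of its own data.

### Temperature

The Atmar–Patterson temperature measures departure from perfect
nestedness on a 0–100 scale. Cell $(i,j)$ of the packed $m \times n$ matrix
is mapped to the unit square at $x = (j-\tfrac12)/n$,
$y = 1-(i-\tfrac12)/m$. The **isocline** is the boundary of the canonical
perfectly nested arrangement with the same fill: cells are filled in
increasing $(i-\tfrac12)/m + (j-\tfrac12)/n$, and the resulting staircase
polyline is extended along the bottom and top edges of the square so that
every diagonal of slope $-1$ crosses it exactly once. The staircase is kept
as-is rather than smoothed: it is already a continuous monotone curve, and
any smoothing would break the exact guarantee that the canonical
arrangement itself scores $T = 0$.

A presence below-right of the isocline, or an absence above-left, is
*unexpected* — equivalently, the unexpected cells are exactly those where
the packed matrix differs from the canonical arrangement. Each contributes
$u_{ij} = (d_{ij}/D_{ij})^2 \in [0,1]$, with $d_{ij}$ the distance from the
cell centre to the isocline along the slope $-1$ diagonal through it, and
$D_{ij}$ that diagonal's length inside the square. Then

$$T = 100 \cdot \frac{U}{U_{max}}, \qquad
  U = \frac{1}{mn}\sum_{i,j} u_{ij}, \qquad U_{max} = 0.04145,$$

clipped into $[0, 100]$; $U_{max}$ is the classic scaling constant for the
maximally "hot" matrix. Degenerate inputs are handled explicitly: fill 0 or
1 returns $T = 0$ (there is nothing to disperse), and $1 \times n$ /
$m \times 1$ matrices are rejected.

Two subtleties are worth stating. First, $T = 0$ holds exactly for the
canonical nested family (what `simulate_bipartite(type = "nested")`
generates); a different staircase at the same fill is *near* zero but not
exactly zero, because a single fill-determined isocline cannot agree with
two staircases that disagree about the same cell. Second, for matrices with
missing entries the default presence pattern is the observation mask itself
— temperature then describes how *missingness* is organised; a flag
(`presence = "positive"`) switches to the ecological binary reading
(weight > 0).

By default the test suite cross-checks the implementation against a
brute-force geometric oracle (explicit polyline walk, cell-by-cell) to
$10^{-9}$ on hundreds of random masks.

## The runs-based ordering test

Given a sequence of categorical labels — e.g. organism labels read down the
rows of a packed matrix — the number of maximal constant runs measures how
clustered the ordering is. The observed count is compared with `n_perm`
(default 5,000) uniform permutations of the same multiset, preserving label
frequencies. The test is one-sided on the lower tail (few runs = clustered)
because that is the alternative of interest, and uses the add-one estimator
$p = (1+\#\{runs \le runs_{obs}\})/(n_{perm}+1)$, whose floor is
$1/(n_{perm}+1) \approx 2\times10^{-4}$ at the default. Number-of-runs is
the statistic; other run functionals (longest run, etc.) would be possible
but are not implemented, to keep the test's meaning unambiguous. Families
of such tests are adjusted jointly with Benjamini–Hochberg
(`bh_adjust()`, a validating wrapper over `stats::p.adjust`); with eight
tests of which six sit at the floor, the six share the adjusted value
$8/(6 \cdot 5001) \approx 0.00027$ — a fixed point of the design that makes
a useful end-to-end check.

## Complete-submatrix extraction

Finding the largest all-observed block is NP-hard, but the instances this
package meets are rarely hard: one dimension is usually small. The solver
is therefore chosen by shape:

* **Exact, min(m, n) ≤ 16.** For every subset $C$ of the smaller
  dimension, the number of opposite lines fully observed on $C$ is a
  superset-count, computable for all $2^{|C|}$ subsets at once by an
  $O(n2^n)$ bit-DP that is independent of the larger dimension. The
  optimum for both the element-count and the square objective falls out
  directly. Ties prefer keeping lines of the larger dimension, then the
  lowest subset in enumeration order — fully deterministic.
* **Greedy otherwise.** Peel: while missing cells remain, remove the row or
  column whose removal leaves the most observed cells (or the largest
  squared minimum dimension for `Square`), ties to the line with the most
  missing cells, then to the larger dimension (rows when equal), then the
  lowest index. Re-add: restore any removed line that is clean on the
  survivors. Local improvement: repeatedly try to force one outside line
  in, dropping its conflicts and re-adding, keeping any strict gain. All
  steps are deterministic; re-adding certifies *maximality* (nothing
  removed fits back).

`Rectangular_row` / `Rectangular_col` are solved exactly for any size —
the optimal rows-only solution is simply the set of fully observed rows —
with a warned fallback (drop worst-missing columns first) when no complete
row exists.

## Projections, clustering, validation

Projections are the raw products $AA^T$ (rows) and $A^TA$ (columns) with
missing cells contributing zero: edge weights count shared *observed*
partners, unnormalized, and self-similarities (the diagonal) are stored
but excluded from the graph. No degree normalization is applied — raw
co-occurrence strength is what downstream pruning thresholds refer to.

Community detection delegates to igraph's seven standard algorithms; the
package's added value is orchestration and validation, not re-implementing
Louvain. Stochastic methods run under a caller-supplied seed (the global
RNG state is saved and restored), and spinglass — which requires
connectivity — runs per component with offset cluster ids.

Internal validation uses the average silhouette width in the graph's own
metric space: path distances with edge length $1/w$, so strong edges are
short, and unreachable pairs set to twice the finite diameter. That
penalty makes cross-component separation finite but dominant; with it, two
disconnected equal cliques under their natural partition score
$s = (2d - d)/2d = 0.5$, not 1 — the score is bounded away from 1 whenever
within-cluster distances are non-negligible relative to the penalty, which
is a property of this metric convention, not a defect of a particular
partition. A single cluster returns `NA` (undefined), singleton clusters
contribute 0 by the usual convention.

External validation and imputation scoring share one primitive: pair
counts $(a, b, c, d)$ over all node pairs, from which Rand, Jaccard,
Sørensen–Dice, Fowlkes–Mallows and Minkowski indices are computed with the
standard degenerate-denominator conventions (0 for the first three when no
pair is co-clustered anywhere; `NA` for Minkowski when the benchmark has no
co-clustered pair).

## Imputation and structure-preservation validation

Four methods, in increasing structural awareness:

* **mean / median** — a missing $(i,j)$ gets the average of the row-$i$ and
  column-$j$ statistic; symmetric in the two nominal variables, global
  fallback for empty margins.
* **CA** — iterative correspondence analysis: initialize with mean
  imputation, then alternate \{truncated SVD of the mass-standardized
  table, reconstruct, overwrite missing cells, clip at 0\} until the
  largest missing-cell change drops below `tol`. `n_dims` counts singular
  dimensions *including the trivial axis*: `n_dims = 1` converges to the
  independence model $r_ic_j/N$, `n_dims = 2` (default) adds one
  association axis — the smallest structure-bearing choice. Requires
  non-negative weights (contingency-table semantics; clipping keeps the
  iteration in that cone).
* **ALS** — rank-$r$ factorisation fitted to observed cells only by exact
  alternating ridge solves, $\lambda = 0.01$ by default to keep solves well
  posed without noticeably biasing the fit, $r = 2$ as the smallest rank
  that can express two-group structure. The penalised loss is
  non-increasing by construction (each half-step is an exact minimiser),
  which the tests assert on every iteration; convergence is declared when
  the observed-cell RMSE improves by less than `tol`.

All methods pin observed cells bitwise — imputation never rewrites data.

`validate_edge_prediction()` asks not "are the imputed values close?" but
"does the imputed network *cluster like the trustworthy part*?": it
clusters the projection of the element-max complete submatrix (the
benchmark), then clusters each fully imputed network with the **same
algorithm and seed** — so index differences reflect imputation, not
algorithm stochasticity — restricts each partition to the benchmark's node
set, and compares with the five pair-counting indices. The restriction to
the benchmark nodes (rather than re-clustering benchmark nodes inside the
full graph being compared on all nodes) is a deliberate alignment choice:
it scores whether imputation *disturbs* the structure where ground truth
exists. Ranking defaults to Jaccard, with Minkowski inverted when chosen.
A degenerate single-cluster benchmark yields `NA` indices and no ranking.

## The synthetic generator

`simulate_bipartite()` plants known structure: `modular` (contiguous
equal blocks, $\mathcal N(\mu_{in}, \sigma)$ within and
$\mathcal N(\mu_{out}, \sigma)$ between, clipped at 0 so CA stays
applicable), `nested` (exactly the canonical staircase the temperature's
isocline is built from, uniform weights on presences), and `random`
(Bernoulli fill). `apply_missingness()` overlays MCAR (independent
masking), block (whole rectangular regions, the stand-in for subgroups
never measured), and threshold censoring (cells below $\tau$ vanish —
missingness that depends on the unobserved value, i.e. MNAR, as under a
detection limit).

Default study conditions used throughout the tests: $40 \times 30$
matrices, $k = 2$ blocks, $\mu_{in} = 10$, $\mu_{out} = 1$,
$\sigma = 0.5$, MCAR rate 0.1, and 25 simulation seeds for pipeline-level
properties (50 for cheaper per-matrix properties); these sizes give stable
behaviour while keeping the full suite under a minute of compute. One
empirical note: threshold censoring of a modular matrix leaves a
block-diagonal observation mask that is highly *structured but
anti-nested* — its temperature is consistently **higher** than an MCAR mask
at the same rate. Structure and nestedness are not synonyms; the tests
therefore verify threshold-MNAR by the concentration of censored cells in
the between-block region, not by a temperature comparison.

What the generator does *not* emulate: realistic proteomics intensity
distributions (LC–MS noise, intensity-dependent CVs), correlated
missingness beyond blocks, or degree heterogeneity within blocks. Passing
tests on these synthetic conditions demonstrate correctness of the
machinery and recoverability of planted structure — they do not certify
performance on any particular real dataset.

## Known limitations

* The temperature's packing is canonical, but the statistic itself remains
  layout-based: matrices whose tied lines the colour refinement cannot
  separate are ordered by a lexicographic convention, and a different
  convention would give (slightly) different temperatures. This is
  inherent to the Atmar–Patterson construction.
* The greedy submatrix path carries no approximation guarantee; the exact
  path is limited to min(m, n) ≤ 16. Both are deterministic, so published
  block sizes are reproducible but possibly sub-optimal for large, dense
  missingness patterns.
* Null-model significance for temperature and modularity (degree-preserving
  randomization) is out of scope.
* Imputation validation scores structure preservation in well-observed
  regions; it says nothing about accuracy inside large never-observed
  blocks, especially under MNAR.
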