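# bimiss — bipartite network analysis of structured missingness

`bimiss` mines pairs of nominal variables (drug x patient, insect x plant,
protein x sample, herb x ingredient, ...) as **weighted bipartite
networks**, and treats the *missing* edge weights as a first-class signal.
In many real tables the holes are not scattered at random: they form
blocks, staircases and clusters that reflect how the data were generated —
detection limits, uneven sampling, software-specific filtering. `bimiss`
quantifies that structure, carves out fully observed sub-networks for
trustworthy downstream analysis, and scores imputation methods by whether
they *preserve* the structure found in the observed part, rather than by
reconstruction error alone.

It is aimed at anyone whose data reduce to "two nominal columns plus an
optional measurement": systems biologists, ecologists, proteomics core
facilities, pharmacology screens.

## What it computes

Given records \((x_i, y_i, w_i)\) with \(x_i \in V\), \(y_i \in W\), the
package builds the biadjacency (incidence) matrix \(A\) with an explicit
missingness mask, then offers:

* **Missingness structure.** Matrix packing and the Atmar–Patterson
  nestedness temperature \(T = 100\,U/U_{max}\), where
  \(U = \frac{1}{mn}\sum (d_{ij}/D_{ij})^2\) sums squared relative
  distances of *unexpected* cells from the isocline of a perfectly nested
  matrix at the same fill, and \(U_{max} = 0.04145\); \(T=0\) is perfect
  nestedness, \(T=100\) maximal disorder. Newman modularity
  \(Q = \sum_c (e_{cc} - a_c^2)\) scores community structure. A runs-based
  permutation test (observed label sequence vs 5,000 reshuffles, empirical
  \(p = (1+\#\{runs_{perm} \le runs_{obs}\})/(n_{perm}+1)\), BH-corrected)
  flags non-random label ordering.
* **Complete submatrices.** `extract_submatrix()` approximates the largest
  all-observed block (NP-hard in general) under four shape modes — exactly,
  by subset enumeration, when the smaller dimension has ≤ 16 lines, and by
  a deterministic greedy peel + re-add + local improvement otherwise.
* **Projections and clustering.** Unipartite projections \(AA^T\) /
  \(A^TA\) (missing contributes zero), optional weak-edge pruning, seven
  community-detection algorithms (walktrap, multilevel, infomap, label
  propagation, leading eigenvector, spinglass, fast greedy) with average
  silhouette width and external Jaccard/Rand validation.
* **Edge-weight imputation and its validation.** Mean/median marginal
  imputation, iterative correspondence analysis, and ridge-regularized
  alternating least squares; `validate_edge_prediction()` compares the
  clustering of each imputed network against the complete-submatrix
  benchmark via Rand, Jaccard, Sørensen–Dice, Fowlkes–Mallows and
  Minkowski pair-counting indices.
* **Synthetic benchmarks.** `simulate_bipartite()` plants modular, nested
  or random structure; `apply_missingness()` overlays MCAR, block or
  value-threshold (MNAR) censoring — so the whole pipeline is testable
  against known ground truth.

## Worked example

```r
library(bimiss)

sim <- simulate_bipartite(40, 30,
  list(type = "modular", k = 2, mu_in = 10, mu_out = 1, sigma = 0.5),
  seed = 42)
M <- apply_missingness(sim$matrix, list(type = "mcar", rate = 0.15), seed = 42)
M
#> Incidence matrix: 40 x 30 (weighted)
#>   observed: 985 / 1200 cells (82.1% non-missing)
#>   weight range: [0, 11.6145]

nestedness_temperature(M)
#> Nestedness temperature T = 54.048 (U = 0.02240, fill = 0.821, 304 unexpected cells)
```

A temperature of 54 says the MCAR holes are scattered, far from a nested
arrangement — as planted. Now extract the trustworthy core and cluster the
row projection:

```r
sub <- extract_submatrix(M, "Rectangular_element_max")
sub
#> Complete submatrix (Rectangular_element_max): 14 x 12 = 168 cells (35.0% of rows)

cl <- find_clusters(project(M, "rows"), "multilevel", seed = 1)[[1]]
cl
#> multilevel: 2 clusters, Q = 0.3218, asw = 0.7720
external_validation(cl$membership, setNames(sim$truth$row_blocks, rownames(M$A)))
#> $jaccard [1] 1     $rand [1] 1
```

The two planted row blocks are recovered exactly. Which imputation method
best preserves that structure?

```r
validate_edge_prediction(M, seed = 1)
#> Imputation validation against a 14 x 12 complete-submatrix benchmark (multilevel):
#>  method rand jaccard dice fowlkes_mallows minkowski
#>    mean    1       1    1               1         0
#>  median    1       1    1               1         0
#>      ca    1       1    1               1         0
#>     als    1       1    1               1         0
#> Ranking (best first): mean > median > ca > als
```

At 15% MCAR on a strongly modular matrix, every method keeps the benchmark
clustering intact (all indices perfect); under heavier or structured
missingness the simple methods start to fall behind. Finally, the ordering
test used to ask whether labels (say, organisms down a packed protein
matrix) cluster non-randomly:

```r
runs_permutation_test(rep(c("org1", "org2", "org3"), each = 100),
                      n_perm = 5000, seed = 1)
#> Runs permutation test: 3 runs observed, p = 0.00019996 (***, 5000 permutations)
```

## A note on method documentation

The methods vignette (`vignettes/structured-missingness.Rmd`) documents the
model choices in detail: the isocline construction behind the temperature,
packing canonicalization, solver selection in the submatrix extraction,
convergence rules for ALS/CA imputation, and what the synthetic generator
does and does not emulate.
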