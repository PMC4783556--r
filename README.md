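# catfuzz

Fuzzy clustering for purely categorical data, built for tables — common in
medical diagnostics — whose columns are unordered category codes rather than
numbers. The motivating application is unsupervised grouping of cytological
cohorts such as the Wisconsin breast cancer dataset (9 features coded 1–10,
classes benign/malignant), where records cannot always be assigned crisply
to one group and soft memberships are informative in themselves.

## The method

Records `X_1, …, X_n` over `s` categorical features are partitioned into
`K` fuzzy clusters by alternating minimization of

```
J = Σ_j Σ_i  u_ij^m · d(X_i, v_j),      subject to Σ_j u_ij = 1,
```

where `U = (u_ij)` is the membership matrix and `m > 1` the fuzzifier.
Two ingredients replace the numeric mean and Euclidean distance of ordinary
fuzzy c-means:

* **Fuzzy centroids.** A cluster centre `v_j` is, per feature, a weight
  distribution over that feature's categories: the weight of value `A_lk`
  is `N_lkc / N_c` with `N_lkc = Σ_i 1(x_il = A_lk) u_ij^m` and
  `N_c = Σ_i u_ij^m`. The record–centre distance is
  `d(X_i, v_j) = Σ_l Σ_t (N_ltc/N_c) · δ_l(x_il, A_lt)`.
* **Learned value distances.** Instead of the 0/1 Hamming rule,
  `δ_l(x, y)` is estimated from co-occurrence: against each other feature
  `j`, the distance between values `x` and `y` of feature `l` is the
  maximum over events `w` of `p(w|x) + p(¬w|y) − 1` — the total-variation
  distance `½ Σ_v |p(v|x) − p(v|y)|` between their conditional
  co-occurrence rows — and `δ_l(x, y)` is the average over the `s − 1`
  co-features. Values that behave alike get small distances even though
  they are distinct symbols.

Memberships are updated by the row-wise minimizer
`u_ij ∝ d_ij^{−1/(m−1)}`, and iteration stops when the objective changes
by at most `ε`. Baselines: plain Hamming value distances, and hard mode
centres scored by Hamming distance (fuzzy K-modes). Clusterings are scored
against known classes by the clustering error — the percentage of records
outside their class's cluster under the optimal one-to-one cluster-to-class
matching — aggregated over repeated random initializations.

## Worked example

The bundled generator builds a two-cluster mixture in which six of nine
features carry *redundant* surface coding: each cluster's characteristic
category is split 50/50 into two sibling codes (`a1`/`a2`, `b1`/`b2`), so
same-cluster records often disagree symbol-wise while the sibling codes
keep identical co-occurrence profiles.

```r
library(catfuzz)

spec    <- make_redundant_scenario(n = 2000, s = 9, seed = 1)
dataset <- generate_categorical(spec)

vt <- value_distance_table(dataset, "cooccurrence")
round(vt$tables$F1, 3)
#>       a1    a2    b1    b2
#> a1 0.000 0.038 0.249 0.251
#> a2 0.038 0.000 0.264 0.266
#> b1 0.249 0.264 0.000 0.038
#> b2 0.251 0.266 0.038 0.000
```

The learned table puts sibling codes at distance ≈ 0.04 where Hamming
would put 1: the co-occurrence statistics have recovered the latent
category structure. Clustering with it:

```r
report <- evaluate_runs(dataset,
                        clustering_config(K = 2, m = 1.1, seed = 1),
                        runs = 10, table = vt)
report
#> Clustering evaluation over 10 run(s)
#> Mean error: 4.7%  (sd 0.0)
#> Confusion matrix (representative run 1 ):
#>      cluster
#> class   1   2
#>    c1 908  53
#>    c2  41 998
#> Cluster -> class mapping: 1 -> c1, 2 -> c2
```

The same protocol with Hamming value distances gives a mean error of
8.0% on this data: discarding the sibling structure costs three points.

A command-line interface wraps the same pipeline
(`inst/cli/catfuzz cluster|distances|evaluate|simulate`); for the
Wisconsin file use `cluster --wbc --input breast-cancer-wisconsin.data`.

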