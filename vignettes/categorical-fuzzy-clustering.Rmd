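---
title: "Fuzzy clustering of categorical data with co-occurrence value distances"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fuzzy clustering of categorical data with co-occurrence value distances}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(catfuzz)
```

## The problem

Diagnostic tables often consist entirely of categorical features: the
Wisconsin breast cancer cohort codes nine cytological characteristics
(clump thickness, bare nuclei, mitoses, ...) as categories, with two
clinical classes, benign and malignant. Two modelling facts drive the
design of this package. First, borderline samples exist, so a record
should be allowed graded membership in several clusters — fuzzy rather
than hard clustering. Second, category codes are symbols: treating every
pair of distinct codes as equally dissimilar (the Hamming or simple
matching rule used by K-modes and most of its fuzzy descendants) throws
away the fact that some values behave almost interchangeably while others
mark genuinely different populations.

`catfuzz` combines a fuzzy c-means style alternating loop with two
categorical-specific components: distribution-valued cluster centres and
a value distance learned from co-occurrence statistics.

## Model and updates

With memberships $U = (u_{ij})$, $\sum_j u_{ij} = 1$, fuzzifier $m > 1$,
and record–centre distances $d_{ij}$, the loop drives down

$$J \;=\; \sum_{j=1}^{K}\sum_{i=1}^{n} u_{ij}^m \, d_{ij}.$$

One iteration performs, in order: centroid update from the current $U$;
distance computation $d_{ij}$ for all records and centres; the membership
update
$$u_{ij} = \frac{1}{\sum_k \left(d_{ij}/d_{ik}\right)^{1/(m-1)}},$$
which is the exact row-wise minimizer of $J$ given the distances; and the
evaluation of $J$. Rows with one or more *zero* distances get their full
membership split equally among the zero-distance centres (the update is
undefined there; this is the standard fuzzy c-means convention).

**Fuzzy centroids.** The centre of cluster $c$ holds, for feature $l$, a
weight for every category $A_{lk}$:
$$w_{lkc} = \frac{N_{lkc}}{N_c}, \qquad
  N_{lkc} = \sum_i \mathbf{1}(x_{il} = A_{lk})\,u_{ic}^m, \qquad
  N_c = \sum_i u_{ic}^m,$$
and the record–centre distance sums, over features, the centroid-weighted
value distances $\Omega_l = \sum_t w_{ltc}\,\delta_l(x_{il}, A_{lt})$.
With hard memberships the weights are the within-cluster category
frequencies.

**Learned value distances.** For two values $x, y$ of feature $l$ and a
co-feature $j$, the per-pair distance is the largest probability advantage
any event can achieve between the two conditional co-occurrence rows,
$\max_w \, p(w\mid x) + p(\lnot w \mid y) - 1$. The maximizing event is
$\{v : p(v\mid x) > p(v\mid y)\}$ and the maximum equals the
total-variation distance $\tfrac12 \sum_v |p(v\mid x) - p(v \mid y)|$,
which is how it is computed — the subset enumeration exists in the test
suite only, as an independent oracle. The value distance is the average
over the $s-1$ co-features, so each per-feature table is symmetric, zero
on the diagonal, bounded by $[0,1]$ and satisfies the triangle inequality
(total variation is a metric and averaging preserves all three
properties). Tables are estimated once from the full dataset and frozen
during iteration.

**Baselines.** `distance = "hamming"` replaces the learned tables by the
0/1 rule (for which $\Omega_l$ reduces to one minus the centroid's weight
on the record's own value); `centroid = "mode"` uses hard single-value
centres — the weighted modal category — scored by plain Hamming counts,
i.e. the fuzzy K-modes baseline. The mode centre always uses Hamming
scoring regardless of the `distance` setting, since that is how the
baseline is defined.

## Parameters

| parameter  | default | meaning |
|-----------|---------|---------|
| `K`        | 2       | number of clusters |
| `m`        | 1.1     | fuzzifier (dimensionless, $>1$); 1.1 gives near-hard memberships, larger values softer ones |
| `epsilon`  | 1e-6    | stop when $|J_t - J_{t-1}| \le \varepsilon$ (objective units) |
| `max_iter` | 100     | iteration cap; hitting it sets `converged = FALSE` |
| `distance` | cooccurrence | value-distance kind |
| `centroid` | fuzzy   | centre representation |
| `seed`     | 42      | random initialization; multi-run drivers use `seed, seed+1, ...` |

The default `m = 1.1` is the headline setting of the reference experiments
on the Wisconsin cohort; 1.5 and 1.9 are the standard softer alternatives
exercised alongside it.

## Numerical and degenerate-case choices

* **Initialization.** $U$ starts as row-normalized uniform draws. A row of
  all-zero draws (probability zero in exact arithmetic) would be redrawn.
* **Membership overflow.** At `m = 1.1` the update exponent is 10; raw
  powers $d^{-10}$ overflow easily, so ratios are taken against the row
  minimum first, keeping every factor in $[0,1]$.
* **Convergence bookkeeping.** The first iteration compares $J$ against
  the objective of the *initial* memberships under the first centroids, so
  an enormous `epsilon` stops after exactly one iteration rather than two.
* **Empty clusters.** If a cluster's fuzzy mass $N_c$ falls below
  $10^{-12}$, its centroid is reset to the point-mass profile of a
  uniformly drawn record, a warning is emitted, and iteration continues.
* **Ties.** Mode imputation and mode centres break ties by the
  lexicographically smallest code (vocabularies are radix-sorted, so this
  is locale-independent); defuzzification breaks membership ties toward
  the lowest cluster index; values with exactly equal conditional
  probabilities are excluded from the reported maximizing event, which
  leaves the distance unchanged.
* **Codes are symbols.** `"10"` sorts before `"2"`; nothing downstream
  ever interprets codes numerically. Vocabularies contain observed values
  only, so conditional rows are always well defined.

## Is the objective monotone?

The membership step is an exact minimizer, but the fuzzy-centroid step is
not: given $U$, $J$ is *linear* in the centroid weights, so its exact
minimizer is a vertex of the simplex — the weighted mode — not the fuzzy
centroid. The fuzzy centroid is the defining update of the method, adopted
for its representational value, and descent of $J$ is therefore not
guaranteed. Empirically the trace decreases until convergence in most
runs, but roughly a quarter of seeded runs on synthetic mixtures show at
least one relative increase of order $10^{-6}$ to $10^{-5}$ (with either
value distance). The mode-centroid variant, whose centre step *is* the
exact minimizer, is observed exactly monotone — which localizes the effect
to the fuzzy-centroid step rather than an implementation defect. The test
suite asserts strict monotonicity at relative tolerance $10^{-8}$ and the
acceptance script reports the measured worst increase; that assertion
documents the gap between the method's fixed-point definition and a true
descent algorithm, and is expected to fail by those few parts per million.
Runs converge regardless, because the stopping rule needs only
$|J_t - J_{t-1}| \le \varepsilon$.

## Evaluation protocol

Fuzzy output is hardened by maximum membership, cross-tabulated against
the known classes, and scored as the percentage of records outside their
class's cluster under the *optimal* one-to-one cluster-to-class matching
(exhaustive over injective maps, supported up to 8 clusters or classes;
nothing short of optimal matching reproduces published error tables
consistently). Repeated runs differ only in the membership initialization;
their errors are aggregated as mean and *population* standard deviation
(divisor equal to the number of runs — at 100 runs the two conventions
differ far below reporting precision). Averaging confusion matrices over
runs has no unique definition, so the reported matrix is the one of the
run whose error is closest to the mean, with all per-run errors available
alongside. Display rounding is half-up to one decimal.

## The synthetic generator

`generator_spec()` draws records from a mixture of multinomials: latent
cluster, then each feature independently from that cluster's category
distribution, then an optional redundancy map that splits a latent
category into sibling surface codes. Conditional independence given the
cluster is deliberate — it is the simplest structure under which the
conditional probabilities behind the value distance are consistently
estimable — and it is also the generator's main idealization: real
diagnostic features are correlated within classes, classes are not
multinomial, and missingness is not simulated. Passing the synthetic
checks therefore demonstrates correctness of the machinery and the
claimed qualitative behaviours, not performance on any real cohort; the
real-data check is the separate validation script for the Wisconsin file.

Two designed scenarios:

* **Separable** (`make_separable_scenario`): cluster $k$ emits its own
  preferred category with probability $1 - \text{separation} +
  \text{separation}/p$ and every category uniformly with the remainder,
  so separation 0 gives disjoint supports and separation 1 removes all
  structure. At separation 0.1, $n = 600$, $s = 9$, $K = 2$, both value
  distances recover the latent labels to within 2% — the sanity regime.
* **Redundant** (`make_redundant_scenario`): two clusters at uniform
  latent overlap 0.5, with the preferred categories of `ceiling(2s/3)` of
  the features split 50/50 into sibling codes. The partial split is the
  point of the design: when *every* feature is split identically, the
  Hamming and co-occurrence discriminants for two clusters coincide up to
  a common scale and both recover the same partition, so no gap can
  appear. Splitting only a subset makes Hamming halve the evidence of the
  redundantly coded features relative to the plain ones, while the
  learned distance — sibling distance $\approx 0.04$ versus 1 — restores
  their weight. Overlap 0.5 was chosen as a moderately ambiguous regime
  (a few percent of records are genuinely mixed) where that misweighting
  is visible: at $n = 2000$, $s = 9$, the co-occurrence distance averages
  about 5% error versus about 8% for Hamming, a gap reproduced on every
  tested seed.

## Problem sizes

The shipped tests and the acceptance script use desk-scale sizes chosen to
make every stochastic claim reproducible in seconds: 200 random datasets
(up to 60 records, 4 features, 6 categories) for the distance oracle, 50
seeded runs (25 seeds × 2 distances, $n = 200$) for trace and
normalization properties, 20 seeds at $n = 600$ for the separable scenario
and at $n = 2000$ for the redundant one, and a 699-record synthetic cohort
in the Wisconsin file dialect for the end-to-end protocol.

## Known limitations

* Categorical features only; numeric or mixed tables are out of scope.
* Distance tables are $O(s^2 p^2 n)$ to build and are estimated from the
  same data being clustered; very small datasets give noisy distances.
* Random initialization only; different seeds can reach different local
  fixed points, which is precisely why the multi-run protocol exists.
* The optimal-matching error is only computed exhaustively (≤ 8 clusters
  or classes).
* Mode imputation is the only missing-data strategy, applied once before
  clustering.
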