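---
title: "Interaction-adjusted community similarity: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interaction-adjusted community similarity: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tina)
```

## The model

Community similarity is usually computed from compositional overlap,
treating taxa as independent. This package takes a different view: two
communities are similar to the extent that their taxa are *ecologically
associated*, whether or not they overlap. The inputs are a taxa-by-sample
count table, optionally a phylogenetic tree, and a square taxa
interaction matrix `I` — inferred from co-occurrence patterns, derived
from cophenetic tree distances, or supplied directly (e.g. a known
ground-truth matrix in simulations).

Because different inference methods produce matrices on different
scales (correlations on [-1, 1], similarities on [0, 1], ...), all raw
matrices pass through one canonical transform before use: taxa are
correlated by their full association profiles — row `I[i, ]` against row
`I[j, ]`, diagonal included — and the Pearson correlation is mapped to

$$C_{ij} = \frac{1 + r(I_{i*}, I_{j*})}{2} \in [0, 1],$$

so 0 means avoidance, 0.5 neutrality and 1 complete association. `C`
equals `(J + R)/2` with `R` a correlation matrix, hence it is symmetric,
has unit diagonal and is positive semi-definite. The transform sharpens
network structure (profile correlation rewards agreement across the
whole system) while largely preserving the rank order of strong
associations; on *structureless* raw matrices there is no rank order to
preserve, and the transformed values scatter around 0.5.

Given `C` (co-occurrence) or `Φ` (phylogeny), the four indices are

- `tina_unweighted()` / `pina_unweighted()`: the mean of `C[i, j]` over
  taxa `i` observed in A and `j` observed in B;
- `tina_weighted()` / `pina_weighted()`: the abundance-weighted bilinear
  form `p_A' C p_B`, normalised by the geometric mean of `p_A' C p_A`
  and `p_B' C p_B`.

The weighted form is exactly 1 for a sample against itself — the
normalisation cancels — and lies in [0, 1] whenever `C` is positive
semi-definite (Cauchy–Schwarz in the `C` inner product). The unweighted
form deliberately carries no self-normalisation: its verbal definition
is a plain average, so `TU(A, A) < 1` in general; the self-similarity
claim of the family is a property of the weighted form, and the test
suite validates it there. For disjoint samples both forms equal the mean
cross-community association: 0.5 under neutrality, 0 under avoidance, up
to 1 under complete association — the behaviour that distinguishes the
family from every count-based index, which must return 0.

All indices are reported as similarities; distance matrices use
`D = max(0, 1 - S)` so that ordination and PERMANOVA always see
dissimilarities on [0, 1].

## Network inference

`infer_cooccurrence()` supports four association metrics. Spearman
correlation and the taxa-wise Bray–Curtis / weighted-Jaccard
similarities are direct; the workhorse is `sparcc_correlations()`, a
compositionally robust estimator built on log-ratio variances
`T_ij = var(log x_i / x_j)`. Under a sparsity assumption the basis
variances `ω` satisfy a linear system assembled from the per-taxon
partner sets; we solve that system exactly (`solve()`), which reduces to
the familiar closed form when no pairs are excluded, then iteratively
exclude the most strongly correlated pair (default: up to 10 exclusions
above |ρ| = 0.1, never letting a taxon drop below 3 partners) and
average correlations over 20 Dirichlet(counts + 1) resamples. All
randomness is governed by a single `seed` argument; the same seed
reproduces the matrix bit for bit.

Two conventions are worth stating. Zero-variance association profiles
(taxa carrying no information) are mapped to the neutral midpoint 0.5
with a warning rather than propagating `NA`. And the cophenetic
similarity used for `Φ` is the max-normalised complement
`1 - d_coph / max(d_coph)`: no canonical mapping from cophenetic
distance to similarity exists, and the global-maximum normalisation is
the simplest choice that pins the observed range onto [0, 1]. An
`exclude_focal` option removes the two focal columns before the profile
correlation; the default keeps full rows, since the definition of the
transform refers to associations "to all other taxa in the system"
without exclusions. The choice matters only for tiny systems: on a star
tree the excluded-focal version is exactly neutral (0.5) while the
full-row version gives `(1 - 1/(n-1))/2`, converging to 0.5 as `n`
grows.

## Multivariate statistics

`permanova()` partitions the squared-distance sum of squares by the
Anderson/McArdle Gower-matrix identity `SS = tr(H G)` and tests the
pseudo-F by free permutation of sample labels. Defaults follow the
standard convention: 999 permutations and the +1-corrected p-value
`(1 + #{F_perm ≥ F_obs}) / (1 + n_perm)`, so p is never 0 and the test
is valid (super-uniform under the null; the suite checks this by
simulation). `permanova_formula()` extends the same engine to ordered
multi-term models with sequential (Type I) sums of squares, the adonis
convention — term order is the caller's responsibility, and terms that
add no rank (e.g. a factor interacted with itself) raise an aliasing
error rather than silently absorbing 0 df.

`pcoa()` is classical scaling (via `stats::cmdscale`): negative
eigenvalues are reported, not corrected — the use case is correlating
axis 1 with an environmental gradient, which `gradient_correlation()`
does directly on the pairwise level as a Spearman correlation between
distances and absolute covariate differences.

## The simulation engines

The generator exists to create benchmark data in which habitat
preference and taxa interactions can be switched on independently.

* `dmm_base_table()` emulates a two-habitat microbiome survey: 200 taxa
  split into two preference groups, per-taxon lognormal(0, 1) alpha
  templates with off-habitat taxa down-weighted ×0.02, two
  Dirichlet-multinomial components, 25 + 25 samples at depth 5000.
  These sizes mirror a modest re-sampled survey subset (two habitats,
  200 taxa) and make co-occurrence inference meaningful while keeping a
  full benchmark replicate ~1–2 s.
* `glv_simulate()` integrates generalized Lotka–Volterra dynamics with a
  multiplicative (Ricker-type) update, `Δt = 0.1`, 100 steps: the
  exponential form keeps abundances positive without an ODE solver, and
  interactions are scaled by 1/K so dynamics stay bounded. Carrying
  capacity defaults to each sample's total count, with starting counts
  scaled to 10% of capacity. Final states become integer counts by
  stochastic rounding, so expectations are unbiased and integer inputs
  at a fixed point pass through unchanged.
* `make_interaction_matrix()` plants ground truth: within-group
  interactions on Barabási–Albert edges (2 edges/node, magnitudes
  Uniform(0, 0.5), random signs), between-group competition
  Uniform(-0.5, -0.1) with ±0.05 uniform noise, symmetric, zero
  diagonal. The magnitudes are not prescribed anywhere; these keep
  r = 0.5 dynamics stable while making competitive exclusion reliable.
* `shuffle_counts()`, `poisson_counts()`, `assign_mock_habitats()`,
  `sample_dirichlet_multinomial()` and `rarefy()` supply the remaining
  moving parts; `make_benchmark_scenario()` wires them into four named
  setups (negative control, habitat-only, interaction-only, combined),
  deriving per-stage seeds deterministically from one master seed.

What the generator does **not** emulate: real OTU tables have far
heavier taxa-abundance tails, thousands of rare taxa, sequencing-depth
variation and batch structure. Passing benchmarks on these simulations
shows that each index responds to the signal it is designed for — not
that effect sizes on real surveys will match.

## Numerical choices and degenerate inputs

* Distance clamp `D = max(0, 1 - S)`; matrices symmetrised and
  zero-diagonal enforced before any statistic.
* TSV output at 10 significant digits — enough for lossless round trips
  at test tolerance.
* Association/correlation values clipped to their nominal ranges after
  floating-point arithmetic; SparCC basis variances floored at 1e-12
  before the square root.
* Unrooted Newick input is midpoint-rooted (root-to-leaf lengths need a
  root; none is given by the format); trees with all-zero branch lengths
  are rejected.
* Chao's shared-abundance estimators substitute 1 for an absent
  doubleton count (`f_{+2} = 0`) and are capped at 1 before combination.
* `harmonise()` restricts table, tree and matrices to their common taxa
  and refuses empty intersections; taxa absent from an auxiliary
  structure are an error at index time, pointing back to `harmonise()`.
* Ties in `assign_mock_habitats()` go to the first group, with a
  warning.

## Problem sizes

The shipped checks run at deliberately small scale: oracle comparisons
on ≤ 8 samples × ≤ 6 taxa (exact to 1e-10), permutation calibration at
20 replicates × 999 permutations, and 20 replicates per simulation
scenario at 50 samples × 200 taxa — the scale at which each qualitative
ranking (interaction-adjusted indices dominating count-based ones under
habitat structure; ground-truth networks beating inferred ones) is
already stable.

## Known limitations

Interaction-adjusted values are context-dependent by construction: `C`
is estimated from the dataset under analysis, so adding samples changes
the network and hence the index values — a feature when networks carry
signal, but it means values are not comparable across independently
built networks. SparCC assumes sparsity of true correlations; dense
interaction structures violate the basis-variance approximation.
Unweighted TINA is not 1 on self-comparison (see above). And the GLV
engine is a benchmark generator, not a fitted ecological model — its
parameters are chosen for stability and signal, not estimated from
data.
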