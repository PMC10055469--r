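---
title: "Exchangeable site-pattern models on rooted species trees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exchangeable site-pattern models on rooted species trees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uephylo)
```

# The models

A genomic data set reduced to site patterns is an *n*-way probability tensor
`P`: entry `p[i1,...,in]` is the probability that the *n* taxa show states
`(i1,...,in)` at a site, with `kappa` states per taxon (`kappa = 4` for DNA,
ordered `A, G, C, T`). Under the multispecies coalescent on an *ultrametric*
rooted species tree with one constant population size and one scalar mutation
rate — here called the coalescent-mixture or CK model — the two taxa of any
cherry are statistically exchangeable: nothing distinguishes their lineages
until they meet, so swapping their tensor indices leaves `P` invariant, and
the same holds for every cherry of every induced subtree after
marginalization.

The **ultrametric exchangeable (UE) model** of a rooted binary topology keeps
exactly these symmetries and forgets the mechanism: it is the set of
probability tensors whose marginal to every taxon subset is invariant under
exchanging the indices of every cherry of the induced subtree. Each symmetry
is a homogeneous linear equation with coefficients in {+1, -1}, so the UE
model is the intersection of a linear space with the probability simplex —
a very convenient geometry: mixtures (rate variation across sites, mixtures
of coalescent mixtures, varying population sizes along the tree) never leave
the model.

The **extended exchangeable (EE) model** relaxes ultrametricity: a tensor `P`
belongs to EE of a topology if acting on each index by some invertible
`kappa x kappa` Markov matrix produces a UE tensor. Mechanistically the
matrices absorb unequal pendant substitution lengths or lineage-specific
rates; algebraically the model is a nonlinear (Zariski-dense image) object,
so membership is probed through polynomial invariants instead of linear
residuals.

The package implements, in plain R:

* the constraint systems of the UE model (full, and the reduced per-vertex
  systems), model dimensions by three independent routes, membership tests,
  and generic model-point sampling (`full_constraints()`,
  `reduced_constraints()`, `dimension_recursive()`,
  `dimension_rank_oracle()`, `closed_form_dimension()`, `is_member()`,
  `sample_ue_point()`);
* the cofactor (adjugate) invariants of 3-taxon EE models and their
  block-matrix rank form, with a rooted-triple ranking heuristic built on
  them (`triple_invariant_matrices()`, `triple_symmetry_residual()`,
  `ottaviani_block()`, `infer_rooted_triple()`, `ee_local_dimension()`);
* SVD-score quartet inference from tensor flattenings with exhaustive exact
  amalgamation (`svd_score()`, `infer_quartet()`, `amalgamate_exact()`,
  `infer_unrooted_tree()`, `consistency_experiment()`);
* a mechanistic simulator: multispecies-coalescent gene trees, per-gene-tree
  Markov substitution, Monte-Carlo averaging, and *closed-form* CK
  distributions for small trees (`sample_gene_tree()`,
  `ck_distribution_mc()`, `ck_distribution_exact()` and relatives).

# Dimension theory

Writing `c` for the dimension of the solution cone of the symmetry equations
and `d = c - 1` for the affine dimension once the sum-to-one condition is
added, the cone dimension satisfies a structural recursion: a leaf
contributes `c = kappa`, and joining two subtrees at a root multiplies their
cone dimensions and subtracts `choose(kappa, 2)` (the root's cherry-exchange
equations are independent of everything below). Closed forms follow for the
extreme shapes: a caterpillar on `n` taxa has `d = (kappa^n + kappa)/2 - 1`,
while balanced shapes are asymptotically much smaller — more cherries mean
more symmetry. The package always offers two independent numerical checks:
the rank of the full constraint system and the rank of the reduced
per-vertex system.

```{r dims}
tr <- parse_newick("((a,b),(c,d));")
dimension_recursive(tr, 4)
dimension_rank_oracle(tr, 4)
dimension_table(4, 4)
```

The per-vertex equation sets use a fixed pair-choice rule: for an internal
vertex, the lexicographically smallest leaf labels of its two child subtrees.
Any consistent rule defines the same cone; fixing one makes the generated
systems reproducible.

# The flattening rank principle and quartet inference

For four taxa, reshaping the tensor by a bipartition `ab|cd` gives a
`kappa^2 x kappa^2` matrix. If `{a,b}` is a cherry of the induced quartet,
index exchangeability makes the `(i,j)` and `(j,i)` rows identical, so the
matching flattening has rank at most `choose(kappa+1, 2)` (10 for DNA),
while the two mismatched flattenings are generically full rank (16). The SVD
score — the sum of the `choose(kappa, 2)` smallest singular values — is
therefore zero exactly on the matching split, and the split minimizing the
score over empirical frequencies is a statistically consistent quartet
estimator. Whole trees are assembled by scoring every 4-subset and searching
all unrooted topologies for the one displaying every call (exact
amalgamation; exhaustive up to 8 taxa, which is the scale this package
targets).

```{r svdq}
spec <- coalescent_spec(
  scale_tree_lengths(parse_newick("((a:1,b:1):1,(c:1,d:1):1);"), sub = 0.05),
  rate_scale = 0.05)
P <- ck_distribution_exact(spec, jc_model(4))
infer_quartet(P)
```

# Rooted-triple invariants of the EE model

On three taxa the EE model is not linear, but it satisfies explicit
polynomial constraints: with marginals `P_{+..}` (over the first cherry
taxon), `P_{.+.}` (over the second), and outgroup slices `P_{..k}`, the
matrices

```
Qa = P_{+..} Cof(P_{.+.})^T P_{..k}
Qb = P_{..k} Cof(P_{+..}) P_{.+.}^T
```

are symmetric for every slice `k` whenever the tensor lies in the EE model
of `((x,y),z)` — `Cof` is the cofactor matrix, so these are degree
`kappa + 1` polynomial identities in the tensor entries. Equivalently, a
`3 kappa x 3 kappa` block matrix assembled from the same pieces drops to
rank `2 kappa`. Both forms are implemented; the residual reported by
`triple_symmetry_residual()` is the *relative* asymmetry
`max|Q - Q^T| / max|Q|`, which is scale-invariant (the invariants are
homogeneous, so raw magnitudes mean nothing across data sets). Ranking the
three rooted triples by this residual gives a root-placement heuristic — the
analogue, one taxon down, of the SVD quartet score.

Two boundaries of the method are worth stating plainly. For `kappa = 2`
the invariants vanish identically on *all* tensors, so two-state data carry
no rooted-triple signal and `infer_rooted_triple()` refuses. And for the
Jukes-Cantor process the CK construction below is not generic enough for
root identification even at `kappa = 4`; the separation witness requires an
asymmetric process such as the two-parameter (K2P) rate matrix.

```{r triple}
w <- sample_ee_witness(parse_newick("((a,b),c);"), 4, seed = 11)
Pee <- suppressWarnings(make_ee_point(w))
infer_rooted_triple(Pee)
```

# The simulator and its closed forms

Units: species-tree edges carry a duration in coalescent units (`2N`
generations; pair-coalescence rate 1) and a substitution length; within an
edge substitutions accrue at `slen/clen` per coalescent unit, and in the
unbounded root population at `rate_scale` (default 1, the `mu = 1/2N`
convention under which coalescent and substitution lengths coincide — the
convention needed to realize printed constructions like
`((a:2,c:0):1,b:1)` literally). A pendant edge of zero duration with
positive substitution length is a pure substitution burst; for internal
edges that combination is ambiguous and rejected.

`sample_gene_tree()` runs the Kingman process edge by edge; survivors enter
the parent population and the root runs to completion. Lineages entering a
population are treated as arriving together — exactly the semantics under
which pendant durations of non-ultrametric trees affect substitutions only.
`ck_distribution_mc()` averages the exact per-gene-tree Markov distributions
(no site noise), so its only error is Monte Carlo over gene trees.

For trees whose non-root internal edges each subtend a cherry (all 2- and
3-taxon trees and the balanced quartet), `ck_distribution_exact()` computes
the CK distribution *in closed form*: `exp(Qt)` is a finite sum of
`e^{lambda t}` spectral projectors of the (reversible) rate matrix, every
coalescent waiting time is exponential, and each history's integral
collapses to rational functions of the eigenvalues. No quadrature and no
Monte Carlo appear anywhere; the 2-taxon formula
`F = diag(pi) M_ell sum_j A_j / (1 - 2 lambda_j rate_scale)` is the smallest
instance, and an adaptive-quadrature implementation of the defining integral
is kept only as an independent oracle in the test suite. Caterpillar
quartets and larger trees fall back to `ck_distribution_mc()`.

## The exponent-basis mode

One identifiability computation needs more than double precision: on the
tree `((a:2,c:0):1,b:1)` with the K2P matrix, the cherry-slice asymmetry
that separates the rooted triples is a three-term exponential sum of order
`e^{-20}/10^4 ~ 1e-13`, i.e. far below the resolution at which two tensor
entries of size `1e-2` can be subtracted reliably once any quadrature or
rounding noise enters. Rather than pulling in arbitrary-precision
arithmetic, `ck3_exponent_decomposition()` keeps every tensor entry in the
exact form `sum_q c_q e^q` with the exponents `q` held symbolically
(integer combinations of eigenvalues and branch lengths) and only the
rational coefficients `c_q` in floating point. Differences of entries are
then examined coefficient-by-coefficient: a leading coefficient of order
`1e-4`, computed to ~15 significant digits, certifies a nonzero asymmetry
regardless of how small `e^q` is. This is strictly stronger than evaluating
the collapsed sum at any fixed precision, and it doubles as a sharp
cross-check of the collapsed double-precision engine (the two agree to
`1e-15` on well-scaled trees).

```{r expsum}
spec7 <- coalescent_spec(parse_newick("((a:2,c:0):1,b:1);"))
es <- ck3_exponent_decomposition(spec7, k2p_model())
ck3_slice_asymmetry(es, "a", "b", "c", 0, 1, 0)
```

# Numerical choices

* **Coordinates.** Tensor coordinates are ordered pattern-lexicographically
  (first taxon most significant); for DNA the state order is `A, G, C, T`,
  chosen so the printed K2P matrix is usable without permutation. Flattening
  rows/columns are lexicographic in the side's taxon tuples.
* **Rank.** Numerical rank counts singular values above
  `max(dim) * eps * sigma_max`, or above an absolute tolerance (`1e-9` is
  used where a fixed scale is meaningful, e.g. probability-tensor
  flattenings). Constraint matrices have entries in {+1, -1} and behave
  benignly.
* **Generic UE points.** `sample_ue_point()` perturbs the uniform tensor by
  a seeded random direction projected onto the constraint null space (sum
  component removed), scaled so all entries stay at or above `kappa^-n / 2`.
  This guarantees exact membership, strict positivity, and full affine span
  over seeds.
* **EE witnesses.** Markov matrices are sampled as `expm(tau R)` with
  seeded sum-zero-row `R` and `tau` uniform in `[0.05, 0.5]` — always
  invertible with positive entries. The *inverse* action defining the EE
  point can leave the probability simplex; such witnesses are flagged with a
  warning but retained, since the algebraic invariants are insensitive to
  the simplex boundary.
* **Degeneracies.** The uniform tensor satisfies every symmetry and
  annihilates every invariant: quartet and triple rankings flag such
  three-way ties as degenerate instead of breaking them silently
  (lexicographic order is used only for reporting).
* **Ties to mechanism.** `ee_local_dimension()` differentiates the
  parameterization (UE affine coordinates, off-diagonal Markov entries)
  analytically — no finite differences — and reports the Jacobian rank at a
  seeded generic point inside the sum-one hyperplane: 7 at `kappa = 2` (the
  model fills the simplex), at most 25 at `kappa = 3`, at most 57 at
  `kappa = 4`.

# What the simulations do and do not show

The synthetic generators are the study conditions for every test in the
package: exact CK distributions on small ultrametric (and deliberately
non-ultrametric) trees, generic UE points, and seeded EE witnesses. The
quartet consistency experiment uses a balanced species tree with all
coalescent durations 1 and a mutation scale of `theta/2 = 0.05` expected
substitutions per coalescent unit (`theta = 0.1`, a standard value in
coalescent simulation studies); at the nominal `rate_scale = 1` a rate-1
process would be mutationally saturated (~3 substitutions per site per
coalescent unit), which no empirical data set resembles. Problem sizes are
desk-scale throughout — trees up to 8 taxa, exhaustive tree enumerations to
5-6 taxa, 200 replicates per stochastic property — chosen so the whole suite
runs in about a minute while leaving the stochastic assertions several
standard errors of slack.

Passing these tests shows that the algebra (constraint systems, dimensions,
ranks, invariants) is implemented exactly and that the inference rules
behave as the theory predicts *under the generating models*. It does not
show robustness to alignment error, substitution-model misspecification
beyond the mixtures the UE model absorbs, intra-locus recombination, or
gene flow — phenomena the generators do not emulate (though some, like
rate-matrix mixtures on a fixed ultrametric tree, are provably inside UE and
therefore covered by construction).

# Known limitations

* Exhaustive amalgamation and dense tensors cap the package at 8 taxa; this
  is a deliberate scope, matching the desk-scale algebraic experiments the
  package exists for, not an algorithmic frontier.
* The exact CK engine covers species trees whose non-root internal edges
  subtend cherries; other shapes use Monte Carlo.
* The rooted-triple heuristic is a ranking, not a test with calibrated
  error rates; its sampling distribution under finite data is unexplored
  here.
* The more restrictive EE variant in which the extension matrices are
  required to be symmetric and commuting is not implemented; the witness
  structure (`ee_witness()`) is the natural hook for adding such
  constraints.
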