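---
title: "Modularity-preserving tri-factorization for miRNA-disease association prediction: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modularity-preserving tri-factorization for miRNA-disease association prediction: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdnmtf)
```

## The problem

Experimentally validated miRNA-disease associations are sparse: most
miRNA-disease pairs have simply never been tested. `mdnmtf` treats the known
associations as a partially observed bipartite network and predicts which of
the unobserved pairs are likely true associations. Two empirical regularities
drive the model: functionally similar miRNAs tend to associate with the same
diseases (and vice versa), and both miRNAs and diseases organize into
*modules* — groups whose members share association partners.

## Input networks

Four similarity constructions feed the model.

**Disease semantic similarity (`Dss`).** Disease terms live in a MeSH-style
hierarchy (a DAG of child-parent edges). A disease contributes semantic
value 1 to itself, and each ancestor receives `delta` times the largest
value among its children on paths to the disease (`delta = 0.5` by default,
so contributions halve per level). The similarity of two diseases is the sum
of the values both assign to shared ancestors, normalized by the sum of
their profile totals. It is 1 exactly for identical profiles and 0 for
diseases in disjoint branches.

**Disease functional similarity (`Dfs`).** Diseases with similar gene
evidence are similar: each gene of one disease's gene set is matched to its
most similar gene in the other set (gene-gene similarity from a weighted
pair table, e.g. HumanNet-style scores; self-similarity is 1, unlisted pairs
0), and matched similarities are averaged over both directions.

**miRNA functional similarity (`Mfs`).** The same best-match averaging
applied to the two miRNAs' associated-disease sets, with `Dss` as the
element-level similarity. Because `Mfs` is built from the association
matrix, it must be recomputed whenever associations are masked (see
cross-validation below).

**GIP kernels.** The Gaussian interaction-profile kernel
`exp(-gamma * ||IP_i - IP_j||^2)` on the binary rows (miRNAs) or columns
(diseases) of the association matrix, with bandwidth `gamma` equal to a
reference bandwidth (default 1) divided by the mean squared profile norm.

The integrated networks take the functional similarity where it is positive
and fall back to the GIP kernel elsewhere: `Rm = Mfs | gip`,
`Rd = Dfs | gip`. Entities with no evidence (no known disease, no gene set)
get functional similarity 0 and are therefore covered entirely by the
kernel — that is the purpose of the integration. The disease semantic
similarity enters only through `Mfs`; the integrated disease network uses
the gene-evidence similarity, which keeps the two sides symmetric in kind
(evidence-based similarity with an association-profile fallback).

## Dynamic neighborhood regularization

Rather than a fixed k-nearest-neighbor graph, each entity gets its own
neighbor count: the longest prefix `H` of its descending similarity vector
such that `1 - sim_l <= epsilon^l` for all `l <= H` (`epsilon = 0.56`). The
dissimilarity budget tightens geometrically, so only genuinely close
neighbors survive; an entity with no similar partners gets none. We read the
condition as a *consecutive prefix* (the first failing rank ends the
neighborhood); a rank that fails is not skipped. Self-similarity is excluded
from the ranking — otherwise the trivial `1 - 1 = 0` would always pass and
inflate every count. Candidates tied with the last kept similarity are all
included, which makes the graph independent of sort order.

Row `i` of the weight matrix `A` holds the similarities to `i`'s selected
neighbors. The Laplacian `L = (Dout + Din) - (A + t(A))` (row- plus
column-degree diagonals) gives the penalty
`trace(t(G) L G) = sum_{i,u} a_iu ||g_i - g_u||^2`, pulling neighbors toward
nearby latent representations.

## The factorization model

With `Rm` (n_m x n_m), `Rd` (n_d x n_d) and the binary association matrix
`D` (n_m x n_d), the model learns non-negative factors `Gm` (n_m x k_m),
`Gd` (n_d x k_d), symmetric cores `Sm`, `Sd`, and a bipartite core `K`
(k_m x k_d) minimizing

```
lambda1 ||Rm - Gm Sm Gm'||^2 + lambda2 ||Y o (D - Gm K Gd')||^2
  + lambda3 ||Rd - Gd Sd Gd'||^2 + alpha1 ||Gm||^2 + alpha2 ||Gd||^2
  + beta1 tr(Gm' Lm Gm) + beta2 tr(Gd' Ld Gd) + omega ||K'K - I||^2
```

subject to positivity of all factors (Frobenius norms squared throughout).
`Gm` and `Gd` are soft module loadings; `Sm`/`Sd` encode module-module
relationships inside each similarity network; `K` couples miRNA modules to
disease modules and is pushed toward orthonormal columns by the `omega`
term. The label-weight matrix `Y` is 1 on known positives, `w_neg = 0.2` on
known negatives and 0 on unknown pairs — absence of annotation is weak
evidence, and unknown pairs (the prediction targets) carry no weight at all,
so they provably cannot influence the fit.

Predictions are the reconstruction `D1 = Gm K Gd'`.

### Parameters

| parameter | default | role |
|---|---|---|
| `lambda1`, `lambda2`, `lambda3` | 0.001, 5, 0.1 | reconstruction weights (miRNA net, associations, disease net) |
| `alpha1`, `alpha2` | 0.2, 0.8 | ridge penalties on `Gm`, `Gd` |
| `beta1`, `beta2` | 90, 1.5 | neighborhood regularizer weights |
| `omega` | 160 | `K` orthonormality weight |
| `k_m`, `k_d` | 200 | latent dimensions (candidate module counts) |
| `epsilon` | 0.56 | dynamic-neighborhood control |
| `w_neg` | 0.2 | known-negative label weight |
| `floor` | 1e-9 | positivity floor after each update |
| `tol`, `max_iter` | 1e-6, 1000 | convergence threshold and iteration cap |
| `t` | 1.5 | module threshold multiplier (module extraction) |

The weights are dimensionless multipliers on squared-Frobenius terms of a
similarity-scaled (all inputs in `[0, 1]`) objective. The latent dimension
defaults suit association networks with hundreds of entities per side; for
small problems `k_m`/`k_d` are clamped to `n - 1` with a warning. Our test
and benchmark runs use `k = 8` on 60 x 40 planted instances with 4 true
modules per side — twice the planted module count, enough spare columns for
the thresholding step to discard.

### Optimization and numerical choices

All five factors are updated by multiplicative rules
(`update_sm()`, `update_sd()`, `update_gm()`, `update_gd()`, `update_k()`),
each the elementwise ratio of the negative to the positive part of the
corresponding gradient, in the sweep order `Sm, Sd, Gm, Gd, K`. After every
update, entries below `floor` are raised to `floor` (keeping denominators
positive and the factors strictly positive), and `Sm`/`Sd` are
re-symmetrized. Iteration stops when the objective changes by less than
`tol` or at `max_iter`.

Two of the objective terms are *quartic* in their factor (`Gm` through
`Gm Sm Gm' Gm Sm`, `K` through `K K'K`), and for quartic terms the plain
ratio update is not a descent method. The `K` update is the worst case: with
only the orthonormality term active, the scalar version of the rule maps
`k -> 1/k`, a pure period-2 oscillation around the fixed point; on random
instances the raw sweep increases the objective in roughly a fifth of the
iterations. `mdn_fit()` therefore applies a **monotone safeguard** (default
`monotone = TRUE`): if a sub-update would increase the objective, the update
ratio is raised to successively halved exponents (1, 1/2, 1/4, 1/8) until it
no longer does, and the sub-update is skipped if no exponent helps. This is
the standard damping for quartic NMF terms; the fractional exponent keeps
the fixed points unchanged and preserves positivity. With the safeguard, the
objective trace is non-increasing by construction, and in practice strictly
decreasing in > 99% of sweeps. `monotone = FALSE` reproduces the raw sweep.

Two further documented choices:

* **Laplacian term in the updates.** The penalty gradient is
  `2 beta (Dout + Din - A - A') G`, but the update rules as commonly printed
  use the one-sided `A` and out-degree diagonal. The one-sided form is the
  default; `symmetrize_laplacian = TRUE` switches to the gradient-consistent
  symmetrized form. (The objective itself always uses the full symmetric
  Laplacian.)
* **Initialization.** Factors start at seeded uniform-random positive
  values: `Gm`, `Gd` scaled by `sqrt(mean(D) / k)` so the initial bipartite
  reconstruction sits near the data scale, `K` with near-unit-norm columns
  (`sqrt(3 / k_m)` scaling) so its orthogonality update starts in its stable
  regime, and `Sm`, `Sd` symmetrized uniform matrices. All randomness flows
  through the single `seed` parameter; identical seeds give bitwise
  identical fits.

## Module extraction and module-based re-scoring

Each factor column is a candidate module. Entity `i` joins module `k` when
its loading exceeds its own profile's threshold
`Th(i) = mean_i + t * sd_i` (sample standard deviation, `t = 1.5`), so
membership is relative to the entity's loading distribution: a flat profile
(sd 0) joins nothing, and multi-membership is allowed — the threshold rule
does not force a partition. Modules with at most one member are dropped.

The re-scoring propagates known associations through modules. For each
retained miRNA module, the score of pair `(i, j)` is the
cosine-similarity-weighted vote of the module members' known associations
with `j`, normalized by `i`'s total latent similarity to *all* miRNAs (the
denominator is deliberately unrestricted, as the model defines it; the
numerator includes the self-term `Sim(i, i) D(i, j)`). Per-module scores are
averaged over the *retained* modules rather than the nominal `k_m` — dropped
modules contribute nothing, and dividing by a nominal 200 would scale scores
by an arbitrary constant; `average_over = "nominal"` restores the literal
reading. The disease-side twin votes over disease modules along the rows of
`D`. The final fused score is

```
D2 = minmax(D1) + minmax(Pm) / 2 + minmax(Pd) / 2
```

with whole-matrix min-max normalization (a constant matrix maps to zeros),
so `D2` lies in `[0, 2]`.

## Evaluation protocols

**Randomly-zeroing CV.** Known positives are split into 5 near-equal folds.
Per fold, held-out positives become *unknown* (`D = 0`, `Y = 0`); `Mfs` and
both GIP kernels — everything derived from `D` — are recomputed from the
training matrix only, which prevents similarity leakage; `Dss` and `Dfs` do
not depend on `D` and are computed once. The fold AUC (rank-sum estimator,
ties counting one half) ranks held-out positives against all pairs that are
not training positives.

**Single-column CV.** Cold start for a new disease: one disease's entire
column is masked, similarities recomputed, and the column's held-out
positives are ranked against the column's remaining miRNAs. Columns with no
positives are excluded (their AUC is undefined); the summary is the
arithmetic mean of per-column AUCs.

Both protocols accept `method = "both"` to score the reconstruction (`D1`)
and the module-fused (`D2`) predictions on the same fits and folds, making
the comparison paired.

## The synthetic benchmark

`generate_planted()` builds a fully self-contained dataset with known ground
truth: contiguous equal-size miRNA and disease modules, module pair `c`
matched one-to-one, associations drawn at `p_in = 0.6` within matched
modules and `p_out = 0.02` elsewhere; a hierarchy making same-module
diseases siblings (block-structured `Dss`); and gene sets drawn from
module-specific pools (8 genes per pool, 5 per disease, within-pool
gene-gene similarity 0.9) so `Dfs` is block-structured too. The default
60 x 40 instance with 4 module pairs gives roughly 400 positives — sparse
enough to resemble association data, dense enough for stable 5-fold CV. The
one-to-one module matching keeps recovery tests unambiguous.

What the generator does *not* emulate: the heavy-tailed degree
distributions of real association databases, annotation bias (well-studied
diseases have more recorded miRNAs), multi-scale hierarchy depth, or
overlapping ground-truth modules. Passing the recovery tests shows the
machinery works on clean modular signal; it does not certify performance on
any particular real database.

## Known limitations

* The multiplicative updates find a local optimum; different seeds give
  different factors (the tests average over seeds where it matters).
* The absolute convergence tolerance (`tol = 1e-6`) interacts with the
  objective's scale; very large problems may hit `max_iter` first, which is
  reported in `converged`.
* Module extraction on strongly overlapping latent columns can assign one
  entity to many modules; the summary statistics make this visible rather
  than preventing it.
* Unlisted association pairs default to *known negative* (weight `w_neg`),
  a convention: the data formats cannot distinguish "tested and negative"
  from "never tested". Use `absent = "unknown"` in
  `read_association_table()` for the conservative reading.
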