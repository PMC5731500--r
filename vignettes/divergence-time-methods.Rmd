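---
title: "Models and algorithms behind chronosite"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and algorithms behind chronosite}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

chronosite estimates species divergence times on a **fixed, rooted binary
topology** from multi-gene DNA alignments by MCMC. This vignette is the
package's own account of the statistical model, the two algorithms that
make the sampler fast — subtree site-pattern compression for the exact
likelihood, and incremental maintenance of the birth-death-sampling
order-statistics prior — and the design and numerical choices made where
the design was genuinely open.

## The posterior

The target is proportional to the product of four components:

1. the **exact phylogenetic likelihood** of every gene under HKY+Γ,
2. the **prior on node ages**: a birth-death-sampling (BDS)
   order-statistics density conditional on the root age, combined with
   soft-bound fossil calibration densities,
3. the **prior on branch rates**: independent log-normal rates per branch
   per gene, `ln r ~ N(ln mu_g - sigma2_g/2, sigma2_g)` so `E[r] = mu_g`,
4. hyperpriors: `Gamma(2, 2/mean)` on kappa, alpha and each gene's mean
   rate `mu_g`; `Gamma(1, 1)` on each `sigma2_g`. The BDS rates
   (lambda, mu, rho) are fixed from configuration, not sampled.

Tips are contemporaneous (age exactly 0); ages are in abstract units, by
convention 100 Myr per unit. One MCMC step is one full sweep: every
internal node age, every branch rate of every gene, and each
hyperparameter receives one Metropolis–Hastings proposal. Age proposals
are uniform sliding windows reflected into `(max child age, parent age)`
(the root reflects only at its lower bound); positive parameters move by
log-scale windows with the Jacobian in the acceptance ratio, so all
kernels are effectively symmetric on their sampling scale. Window widths
self-tune toward roughly 30% acceptance during burn-in only.

## Subtree site-pattern compression

After classic full-site compression (duplicate alignment columns
collapsed with repeat weights), every inner node of the fixed tree
deduplicates the columns *projected onto its own leaf set*. The
concatenated child codes of a column form a key into a per-node hash; the
first occurrence of a key appends a row to the node's site lookup table
holding, per child, either the leaf's code (selecting a column of the
child's transition-matrix emission block) or the row index in the child's
own compressed likelihood vector. The root additionally aggregates the
full-site weights of all columns mapping to the same root pattern into a
repeat count, so the gene log-likelihood is a weighted sum over root
rows.

Because the topology never changes, these structures are built once and
are immutable during sampling; after construction only the lookup tables
and row counts are retained (the hashes are construction-time scaffolding
— a deliberate memory/speed trade documented here). The pattern count at
any node is bounded by `min(5^n, s')` for `n` leaves below and `s'` kept
sites; a cherry can never exceed `5^2 = 25` rows, which is where the
method wins most on balanced trees, while on caterpillar shapes the bound
degrades toward `s'` — both shapes are exercised in the tests.

Implementation notes:

* The key at a node is realised as the pair of its children's row
  indices, which is in bijection with the concatenated leaf codes and
  lets construction run in one integer pass per node.
* Partial likelihoods for the K gamma categories are stored as one
  `4K x n_patterns` matrix and all branch transition matrices as one
  `4K x 4K` block-diagonal matrix, so a node update is a single dense
  product — the natural vectorisation in R, playing the role compiled
  kernels play elsewhere.
* **Scaling.** Partial-likelihood columns are rescaled by their maximum
  whenever that maximum falls below `1e-100`, accumulating the logs per
  pattern and category; category mixing at the root uses a max-shifted
  log-sum-exp. The check is a cheap whole-matrix minimum in the common
  case where no scaling is needed.
* Natural logarithms throughout.

A **plain Felsenstein pruning** implementation (per-column partials, no
subtree sharing) ships as a first-class oracle; compressed and plain
log-likelihoods agree to 1e-10 relative over randomized trees of 4–20
taxa, 10–1,000 sites, balanced, caterpillar and random shapes.

## The node-age prior and its incremental maintenance

Conditional on the root age `t_R` and the number of leaves `n`, non-root
internal ages are modelled through the BDS kernel density `g(t)` and CDF
`G(t)` (lambda ≠ mu general form, with dedicated closed forms for the
lambda = mu limit and for the `rho*lambda + ... = 0` boundary that pure
birth with full sampling hits). The density of the non-calibration ages
given the `c` calibration ages factorises into per-node `ln g` terms plus
`c + 1` segment terms: for segment `i` between consecutive calibration
ranks, a factorial `h(i)` of the number of free ages inside the segment
and a power `G'(i)` of the CDF mass it spans. The log prior is
`sum ln g + sum ln h - sum ln G'`; with no internal calibrations it
degenerates to `sum ln g + ln((n-2)!)` (a constant under fixed `n`).
Segment bookkeeping uses the boundary convention `rank_0 = 0`,
`rank_(c+1) = n - 1`, `G_0 = 0`, `G_(c+1) = 1`, under which the factorial
arguments and the `G'` exponents coincide segment-by-segment and always
partition `n - 2 - c` — the invariant the tests pin.

Rather than resorting and recomputing every term per proposal, the state
keeps an **Age Pointer Vector** (all non-root internal nodes sorted by
age; a node's rank is its index), per-node caches of `ln g` or
`(G, ln f_cal)`, and a **conditional density vector** of per-segment
`(ln h, ln G')`. A proposed age repositions its node by adjacent swaps
and is classified by (calibration?, position changed?):

* free node, no move — only its `Δ ln g` is applied;
* free node, moved — additionally, exactly the segments whose rank
  boundaries changed (those bordering any crossed calibration) are
  recomputed;
* calibration node, no move — ranks are untouched; the two bordering
  segments' `G'` terms are updated from the single new CDF value (the
  one-CDF shortcut, verified against direct recomputation);
* calibration node, moved — bordering segments' `h` and `G'` both
  recomputed.

Every transaction is revertible (rejection restores caches bitwise), and
the cached log prior is verified against a from-scratch recomputation —
the package's oracle and simultaneously the baseline strategy it
improves on — to 1e-9 after 10,000 randomized proposals spanning all four
classes. A root-age proposal changes the conditioning of `g` and `G`
themselves, so it triggers a full (still revertible) cache rebuild; this
is the one intentionally non-incremental move.

Age ties have measure zero under continuous proposals and are broken by
node id at initialisation. Calibration densities are **soft-uniform**
bounds only — uniform mass `1 - 2p` on `[t_L, t_U]` with exponential
tails of mass `p` each, continuous at the bounds; they are not truncated
to `(0, t_R)` or renormalised, so a bound whose tail leaks past the root
age is acceptable but slightly diffuse. The root must carry a
calibration: the prior conditions on `t_R`, and without an anchor the
time scale is unidentifiable from rate–time confounding.

## Synthetic data

The generator draws the tree directly from the prior the inference
assumes: root age 1, the other `n - 2` ages i.i.d. `G^-1(uniform)`,
attached by uniformly random merges consistent with the age order.
Sequences evolve natively down the tree (root states from the stationary
frequencies, one gamma category per site, child states sampled from
transition-matrix rows), with defaults matching the study conditions:
kappa 2, 4 gamma categories, trees of 20–200 taxa at full scale, genes of
1,000–10,000 sites. Unit-scale tests use smaller instances of the same
process.

What passing tests on these data do **not** show: robustness to model
misspecification (the generator and the inference share the HKY+Γ and
BDS assumptions by construction), alignment error, non-contemporaneous
tips, or partial ambiguity codes (all IUPAC ambiguity collapses to the
single unknown code, which contributes a factor of one and is equivalent
to pruning the taxon at that site).

One empirical note: site-pattern diversity *increases* with the gamma
shape alpha under these conditions (small alpha concentrates most sites
at near-zero rate, freezing them), while diversity increases with taxon
count as expected; the sanity tests assert these observed directions.

## Problem sizes used in the automated checks

Chosen as the package's own desk-scale validation protocol: likelihood
oracle agreement on 100 random instances (4–20 taxa, up to 1,000 sites);
prior oracle agreement over 10,000 proposals (5–40 taxa, 0–5 internal
calibrations); a prior-only chain of 50,000 sweeps on a 6-leaf
caterpillar against direct order-statistics simulation (the caterpillar's
total order is what makes sorted i.i.d. draws the exact oracle;
Kolmogorov–Smirnov distance below 0.05); and a recovery run on a seeded
10-taxon, 2-gene × 1,000-site dataset with the root soft-bounded to
±10%, requiring at least 90% of node posterior means within 15% of
truth. Cross-tool validation against MCMCTree's exact-likelihood mode is
a documented manual procedure — run both programs on one fixture with
identical model settings and require the per-node relative difference
`d = 2(d1 - d2)/(d1 + d2)` to stay within ±0.005 — and is not part of
the automated suite because it needs the external binary.

## Known limitations

* No topology inference, polytomies, or tip dating; one alignment
  partition model (HKY+Γ) only.
* BDS hyperparameters are fixed, not sampled.
* The sampler is single-chain; convergence diagnostics beyond the
  built-in cache-consistency and seed-reproducibility checks are the
  user's responsibility.
* Likelihood cost still grows with unique subtree patterns; data with
  little repetition (long, highly divergent alignments on caterpillar
  trees) approach plain pruning cost.
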