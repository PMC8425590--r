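---
title: "ngpm: model, inference and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ngpm: model, inference and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ngpm)
```

## The generative model

`ngpm` treats an annotated protein–protein interaction (PPI) network as a
draw from an attributed stochastic block model. The data are a four-part
object: the protein set `V` (n proteins), a symmetric hollow 0/1 adjacency
matrix `A`, per-protein Gene Ontology (GO) annotations `X` as flat
(category, value) pairs, and the catalog of categories with their value
domains. The latent structure is a partition of proteins into `K`
functional modules:

1. Module proportions `α ~ Dirichlet(ζ)`, and each protein's module label
   `C_i ~ Categorical(α)`.
2. Annotations are drawn per slot in two steps, so the coupling between a
   GO category and its admissible values is preserved: the category from
   the module-specific distribution `θ_{C_i}` (`θ_k ~ Dirichlet(λ_k)`),
   then the value from the module- and category-specific distribution
   `β_{C_i m}` over that category's domain (`β_km ~ Dirichlet(μ_km)`).
3. Each unordered pair is an independent Bernoulli edge with probability
   `ε_{C_i C_j}`, where `ε` is a symmetric `K × K` matrix with entries
   `ε_kl ~ Beta(τ_kl)`.

Two proteins in the same module therefore share both their interaction
propensities and their annotation regularities — the modelling claim being
that functional modules express themselves simultaneously in topology and
in GO.

A note on the edge law: the per-pair outcome is binary, so its
"multinomial" reading is the two-outcome case, and the conjugate Dirichlet
prior on a two-outcome distribution *is* a Beta. We draw one `ε_kl` per
unordered module pair and mirror it, since the network is undirected.

The number of annotation slots per protein is not part of the module
structure; the simulator takes it as a fixed count or as Poisson with a
configurable mean. The default, Poisson(5), matches the typical handful of
curated GO terms per protein in small curated PPI datasets.

## What the simulator emulates — and what it does not

`generate_network()` composes exactly the four sampling steps above, under
one master seed with an independent child seed per sampler, and returns the
full ground truth (labels and parameters) for recovery testing.
`planted_params()` provides the fixed-parameter planted-partition world
used throughout the tests: equal module sizes in expectation, within-module
edge probability 0.15 and between-module 0.01 at `K = 3, n = 300` (giving a
mean degree of about 16, in the range of dense curated PPI maps), three
annotation categories of six values with 90% of each module's probability
mass on its own slice of each domain.

The simulator does *not* emulate several features of real PPI data, and a
green recovery test should be read accordingly: degree heterogeneity within
a module (real networks have hubs; the block model is Erdős–Rényi within a
block), GO term hierarchy (annotations are flat categorical values; no
ancestry or semantic similarity), annotation noise correlated with study
bias, and the experimentally induced false positives/negatives whose
mitigation is the method's motivation. What a green test establishes is
that the inference machinery recovers the posterior its own model implies,
and that the scoring/calibration pipeline ranks held-out edges above
non-edges when modular structure is present.

## Inference

The label posterior is intractable, so `fit_modules()` uses mean-field
variational inference with the fully factorised family
`q(C) q(α) q(θ) q(β) q(ε)` and coordinate ascent:

- Each protein's categorical factor `q_i` is updated sequentially (an Rcpp
  sweep) from the expected log-likelihood of its annotations, its expected
  log module proportion, and its edge *and non-edge* terms against every
  other protein's current `q_j`. Non-edges are included deliberately: with
  only observed edges the block densities `ε` are not identifiable.
- The global factors are conjugate and update in closed form: Dirichlet
  posteriors from expected annotation counts, Beta posteriors from expected
  block edge/pair counts.

Because every update is an exact coordinate maximisation, the evidence
lower bound (ELBO) is non-decreasing across sweeps; the implementation
recomputes it each sweep and the tests assert monotonicity to a `1e-8`
relative slack (floating-point only). On degenerate one-hot states with
`K = 1` the ELBO is the exact log marginal likelihood, which the tests
check against the closed form.

Numerical and procedural choices:

- **Initialisation**: `q` rows drawn from a symmetric Dirichlet(1), with
  `n_restarts = 5` by default and the best-ELBO restart returned. The
  surface is multi-modal; on weakly separated data different restarts can
  reach different local optima, which is why the recovery tests use
  well-separated planted worlds.
- **Convergence**: relative ELBO change below `tol = 1e-6`, capped at
  `max_iter = 500` sweeps. In practice well-separated instances converge in
  well under 20 sweeps.
- **Expected logs** use digamma differences throughout; probabilities are
  floored at `1e-300` before any logarithm.
- **Determinism**: one integer seed drives a hierarchy of child seeds (one
  per restart, one per sampler in the simulator), so every result in the
  package is bit-reproducible given `--seed`.
- **Hard labels**: `derive_labels()` takes the row argmax with ties broken
  toward the lowest module index, making downstream scoring deterministic.
- Proteins with no annotations simply contribute no annotation terms; the
  edge channel alone then drives their membership (and conversely, an
  empty network is classified from annotations alone — both paths are
  tested).

Internally proteins are indexed 1-based over the sorted identifier list —
the natural R convention — while all files carry original identifiers.

## Scoring candidate pairs

The score of a pair sums, over all simple paths between them with 1 to
`max_interior` interior proteins, the product of the interior proteins'
memberships in module `k`, divided by a decay penalty:

- `k` is the argmax module of the **first** protein of the pair, as the
  scoring function is defined; scores are therefore asymmetric when the
  endpoints' modules differ. Batch drivers score pairs exactly as given, so
  callers who want symmetry should canonicalise pair order first (the
  evaluation harness passes pairs in canonical sorted order).
- `|L_w|`, the path size used in both the weight product and the decay, is
  the number of *interior* proteins. The defining text is ambiguous
  ("number of proteins on the path" vs a product over "the remaining
  proteins"); counting interiors keeps the direct edge out of the path set,
  makes the decay strictly positive, and aligns the default cap of 3 with
  degree-normalised length-3-path baselines (two interiors = a three-edge
  path). The alternative total-count convention is available via
  `lw_mode = "total"`, which then also multiplies the endpoints'
  memberships into the weight.
- The decay is linear, `φ·|L_w|`, as the formula is printed; the
  surrounding prose suggests an exponential reading, so `decay_mode = "exp"`
  (`φ^|L_w|`) is provided as a switch. `φ` defaults to 1 — the definition
  only constrains `φ ≥ 1`, and with the default cap of 3 the linear/`φ=1`
  variant leaves path counts dominant.
- A pair with no connecting path (within the cap) scores 0 and is reported
  with interaction probability 0 — with no path evidence the method
  declines to predict.

`brute_force_score()` re-derives the same quantity by naive recursive
enumeration in R and is kept deliberately independent of the Rcpp DFS; the
acceptance suite equates the two on 100 random graphs to `1e-12`.

## Rank-window calibration

Raw scores are heterogeneous across networks, so they are calibrated by
rank: all candidate pairs *and* the known (training) interactions are
scored and sorted descending, and a pair's interaction probability is the
fraction of known interactions among the up-to-50 entries above and
up-to-50 below it. Three reading decisions, each recorded because the
defining description is silent:

- at the two ends of the board the window truncates (no wrap-around — rank
  neighbourhoods have no cyclic meaning), so the reference set can be
  smaller than 100;
- the queried pair itself never counts toward its own window (a known test
  pair would otherwise inflate its own probability);
- score ties are ordered by canonical pair identifier so every window is
  reproducible.

`half_width = 50` is the stated default and is configurable.

## Evaluation protocol

`five_fold_cv()` partitions the positive edges into five folds; per fold
the test edges are removed from the training adjacency, the model refitted,
and the test positives scored against a fixed negative set, with the
training edges also on the board to populate the windows with known
interactions. Negatives are 244 non-adjacent pairs, exactly 100 of which
must touch a protein from the top-500 pairs ranked by the degree-normalised
length-3-path baseline (`l3_score`: `Σ 1/sqrt(deg(x)·deg(y))` over i–x–y–j
chains); they are drawn once per network and reused across folds, since the
protocol describes one negative set per network. Decisions the protocol
leaves open: the precision/recall threshold on calibrated probabilities is
0.5 (configurable); PR-AUC uses the average-precision step convention
(trapezoidal interpolation between recall points is optimistic for PR
curves); ROC-AUC uses the mid-rank Mann–Whitney form so massed ties score
0.5 exactly. `k_sweep()` re-runs the CV across a K grid with shared folds
and negatives, mirroring the usual sensitivity analysis (K from 2 to 20).

## Known limitations

- Path enumeration is exponential in `max_interior`; the default cap of 3
  is a deliberate accuracy/time trade-off and raising it on dense networks
  is expensive.
- The variational sweep is O(n·K² + |E|·K) per iteration but the scoreboard
  scores O(n²) candidate pairs if asked to rank all non-edges; the package
  targets curated networks of 10²–10⁴ proteins, not proteome-scale maps.
- `K` is user-chosen; `k_sweep()` supports the choice empirically but no
  automatic selection is attempted.
- The generative model gives each protein a single latent label; soft
  multi-module behaviour lives entirely in the posterior membership matrix,
  not in the generator.
- Calibrated probabilities are relative to the board they were computed on:
  adding or removing candidates shifts windows.

## A minimal run

```{r example, eval = FALSE}
hyper <- hyperparams(K = 3)
params <- planted_params(K = 3, n_categories = 3, domain_sizes = c(6, 6, 6))
sim <- generate_network(hyper, 300, 3, c(6, 6, 6), rng_seed = 42,
                        params = params)
fit <- fit_modules(sim$network, K = 3, hyper, rng_seed = 1)
adjusted_rand_index(derive_labels(fit), sim$params$labels)
ev <- five_fold_cv(sim$network, K = 3, hyper, rng_seed = 1)
ev$mean
```
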