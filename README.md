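# ngpm

Network- and Gene-Ontology-based prediction of protein–protein interactions
(PPIs).

## The problem

High-throughput PPI screens produce networks with substantial false-positive
and false-negative rates, and purely topological link predictors inherit that
noise. Proteins, however, organise into *functional modules* — groups that
interact densely with one another and share Gene Ontology (GO) regularities —
and two proteins in the same module are far more likely to interact than two
proteins in different modules. `ngpm` exploits this: it fuses the structural
channel (the network) and the biological channel (flat GO annotations) in a
single generative model, infers each protein's posterior module membership,
and uses those memberships to score candidate interactions.

The package is for computational biologists who have an undirected PPI edge
list plus per-protein GO annotations (a 3-column table or GAF 2.x) and want
calibrated interaction probabilities for unobserved pairs, together with a
reproducible evaluation harness.

## The model

A network of `n` proteins with annotations is modelled as an attributed
stochastic block model with `K` latent modules:

- module proportions `α ~ Dirichlet(ζ)`; label `C_i ~ Categorical(α)`;
- each annotation of protein `i` draws a GO category
  `Λ_ip ~ Categorical(θ_{C_i})` with `θ_k ~ Dirichlet(λ_k)`, then a value
  `x_ip ~ Categorical(β_{C_i,m})` over that category's domain, with
  `β_km ~ Dirichlet(μ_km)`;
- each unordered pair gets an edge `A_ij ~ Bernoulli(ε_{C_i C_j})` with
  `ε_kl ~ Beta(τ_kl)`.

`fit_modules()` approximates the label posterior by mean-field variational
inference (coordinate ascent with conjugate Dirichlet/Beta updates; the ELBO
is monotone over sweeps), returning the row-stochastic membership matrix
`α̂`. A candidate pair `(v_i, v_j)` is then scored over the simple network
paths `L_w` connecting it (up to `max_interior` intermediate proteins,
default 3):

    score(v_i, v_j) = Σ_w  weight(L_w) / decay(L_w),
    weight(L_w) = Π_{z interior of L_w} α̂_{z,k},   k = argmax module of v_i,
    decay(L_w)  = φ · |L_w|   (φ ≥ 1; |L_w| = number of interior proteins)

Raw scores are calibrated by ranking all scored pairs (known PPIs included)
and taking, for each pair, the fraction of known PPIs among its 50 upper and
50 lower rank neighbours — a rank-based sliding window — as its interaction
probability. Pairs with no connecting path get probability 0.

## Worked example

```r
library(ngpm)

# a planted three-module world: within-module edge probability 0.15,
# between-module 0.01, three GO categories of six module-specific values
hyper  <- hyperparams(K = 3)
params <- planted_params(K = 3, n_categories = 3, domain_sizes = c(6, 6, 6))
sim <- generate_network(hyper, n_proteins = 300, n_categories = 3,
                        domain_sizes = c(6, 6, 6), rng_seed = 42,
                        params = params)
sim$network
#> annotated_network: 300 proteins, 2501 edges (avg degree 16.67, CC 0.117)
#>   annotations: 1505 rows over 3 categories

fit <- fit_modules(sim$network, K = 3, hyper, rng_seed = 1)
fit
#> ngpm_fit: 300 proteins x 3 modules; ELBO -11527.1366 after 5 sweeps (converged)
adjusted_rand_index(derive_labels(fit), sim$params$labels)
#> [1] 1

score_pair(sim$network, fit$membership, "p0001", "p0002")$score
#> [1] 15.66667   # 93 paths, all through protein p0001's module

ev <- five_fold_cv(sim$network, K = 3, hyper, rng_seed = 1)
ev
#> ngpm_eval (5 folds): precision 0.750  recall 0.942  F 0.835  ROC-AUC 0.803  PR-AUC 0.855
```

The fit recovers the planted modules exactly (adjusted Rand index 1), and
five-fold cross-validation — holding out 20% of edges per fold, scoring them
against 244 sampled non-adjacent pairs (100 constrained to touch the top-500
pairs of a degree-normalised length-3-path baseline) — ranks held-out true
interactions well above the negatives.

## Command line

A launcher is installed at `exec/ngpm` with subcommands `simulate`, `stats`,
`fit`, `score`, `predict`, `evaluate`, `sweep-k`; see `R -e 'ngpm::ngpm_main()'`
or any subcommand's `--help`. Results go to `--out-dir`; logs to stderr.

```sh
Rscript exec/ngpm simulate --k 3 --n-proteins 300 --seed 42 --out-dir demo
Rscript exec/ngpm fit --edges demo/edges.tsv --annotations demo/annotations.tsv \
    --k 3 --out-dir demo
Rscript exec/ngpm evaluate --edges demo/edges.tsv --annotations demo/annotations.tsv \
    --k 3 --out-dir demo
```

## Vignette

`vignettes/ngpm-methods.Rmd` documents the model, the inference scheme, every
tunable parameter with its default and rationale, what the simulator does and
does not emulate, and known limitations.
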