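---
title: "Pathway analysis with genetic metabolomic scores: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathway analysis with genetic metabolomic scores: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hiscomsm)
```

## The model

`hiscomsm` tests pathways for association with a binary phenotype through
the *genetic* component of metabolite levels. The hierarchical structural
component model has three layers. Per-metabolite genetic metabolomic
scores (GMS) `x_jkt` form the input layer; each pathway `k` owns a latent
score `f_jk = sum_t w_kt x_jkt`, a weighted sum of the scores of its
`T_k` member metabolites; the outcome layer is a logistic regression of
the phenotype on the `K` latent pathway scores:

$$\mathrm{logit}(\pi_j) = \beta_0 + \sum_{k=1}^{K}
  \Big[\sum_{t=1}^{T_k} w_{kt}\, x_{jkt}\Big]\beta_k .$$

Fitting maximizes the ridge-penalized Bernoulli log-likelihood

$$\phi = \sum_{j=1}^{N}\log p(y_j;\gamma_j)
  \;-\; \tfrac12\lambda_M \sum_{k}\sum_{t} w_{kt}^2
  \;-\; \tfrac12\lambda_P \sum_{k=0}^{K} \beta_k^2 ,$$

with `gamma_j` the linear predictor and dispersion fixed at 1. Note the
pathway penalty runs from `k = 0`: the intercept is penalized by default
(`penalize_intercept = TRUE` in `penalty_config()`). Penalizing an
intercept is unusual for GLMs, but it is the form of the objective this
model family states, so it is the default and the conventional
unpenalized-intercept variant is a switch. With a near-balanced phenotype
the practical difference is small because the optimal `beta_0` is near
zero either way.

A metabolite mapped to several pathways contributes one column — and one
independent weight — per containing pathway. This follows the structural
component convention in which `w_kt` is indexed by pathway: pathway latent
scores remain separately parameterized even when membership overlaps.

Covariates (age, sex) are absorbed upstream, during score construction;
the outcome model itself carries only the intercept.

## Estimation: alternating least squares

The objective is bilinear in `(w, beta)`, so it is maximized by
alternation, each step a full ridge-penalized IRLS to convergence:

1. **beta-step** — with `w` fixed, form the latent scores `F` and update
   `(beta_0, beta)` by Newton/IRLS with ridge `lambda_P` (step-halving
   keeps every update monotone in the objective);
2. **w-step** — with `beta` fixed, the linear predictor is linear in all
   `w_kt` jointly through the column-scaled design `X[, (k,t)] * beta_k`;
   update all weights in one ridge-IRLS with penalty `lambda_M`.

The outer loop stops when both the largest parameter change and the
largest entry of the analytic gradient of `phi` fall below `1e-6`
(at most 500 alternations, flagged if hit). Because each step solves its
conditional problem exactly, the fixed point is a stationary point of
`phi` in *all* parameters; the test suite verifies this with central
finite differences on random instances (tolerance `1e-4`).

**Scale identification.** The product `w_k beta_k` is what the likelihood
sees, but the penalties themselves fix the scale split: at a stationary
point, `||w_k|| = sqrt(lambda_P / lambda_M)\,|beta_k|`. For this reason
we deliberately do *not* renormalize `w_k` inside the iteration — forcing
`||w_k|| = 1` every sweep would move the iterate off the stationary
manifold of the stated objective and the fit would no longer satisfy its
own gradient check. Instead the conventional unit-norm reporting scale is
applied after convergence: `w_k / ||w_k||` with the sign set so the
largest-magnitude weight is positive, and `beta_eff_k = beta_k ||w_k||`.
This transform leaves the linear predictor unchanged (asserted to
`1e-10`), and `beta_eff` — invariant to the internal scale split — is the
quantity permuted, ranked and reported.

Initialization is symmetric and deterministic: `w_kt = 1/sqrt(T_k)`,
`beta = 0`, `beta_0 = logit(mean(y))`. With `lambda_M = 0` a pathway whose
`beta_k` is exactly zero leaves its weights unidentified; those weights
are simply frozen for that sweep.

## Penalty selection, permutation, FDR

`cv_select_lambda()` scores each `(lambda_M, lambda_P)` pair by mean
held-out Bernoulli deviance over five class-stratified folds (fold
assignment is seeded). Ties prefer the larger `lambda_M + lambda_P`, then
the larger `lambda_P` — when the data cannot distinguish, shrink more.

`permutation_pvalues()` refits the model on permuted phenotypes with the
*same* penalties — re-running CV inside every permutation would be both
infeasible at `B = 100{,}000` and unnecessary, since the null being
simulated is "no phenotype–pathway association under the fixed fitting
pipeline". Refits are cold-started so permuted datasets are processed
exchangeably with the original. The empirical p-value uses the add-one
correction `p_k = (1 + \#\{|\beta^*_{bk}| \ge |\hat\beta_k|\})/(B+1)`, so
`p_k \in [1/(B+1), 1]` and a zero observed coefficient yields `p = 1`.
Benjamini–Hochberg adjustment (via `stats::p.adjust`) produces the
q-values; `pathway_report()` sorts by q then by `|beta_eff|` descending,
matching the usual short-listing of pathways with large effects and small
q.

## Score construction choices

* **Clumping** interprets the conventional "250 k" genetic distance as
  250 kilobases of physical distance with inclusive window arithmetic on
  1-based positions, and uses squared Pearson correlation of dosages over
  pairwise-complete samples. Ties on p break by (chromosome, position,
  id), making the greedy selection fully deterministic.
* The **thresholding p-value cutoff** has no canonical value; it is a
  required configuration field with default `1e-4`, logged in outputs.
* **Scoring** counts allele 1 of the `.bim` record as the effect allele;
  effects stated on the other allele are applied to the reflected dosage.
  Missing dosages are mean-imputed at twice the effect-allele frequency,
  the convention of standard scoring tools.
* **GBLUP** estimates per-SNP effects by the dual ridge identity
  `a = W'(WW' + lambda I)^{-1} y` with `lambda = m sigma_e^2/sigma_g^2`
  on the standardized genotype scale, then converts to dosage-scale
  effects. Variance components come from a profile-REML over
  `h^2` on a 50-point grid refined once — a deliberately simple,
  derivative-free scheme whose restricted likelihood is evaluated through
  one eigendecomposition of the GRM. The top 20% of SNPs by `|effect|`
  keep their *original* BLUP estimates — the most literal reading of
  "the remaining SNP effects are used", and the one that preserves the
  joint shrinkage structure. Selection is per metabolite: each metabolite
  has its own mixed model.
* **QC** order is fixed and logged: SNP missingness, then exact HWE
  (the conditional exact test, computed across all supplied samples —
  subset to controls first if a controls-only test is wanted), then
  MAF, then sample call rate. MAF uses non-missing genotypes only.

## What the simulators emulate — and what they do not

`simulate_genotypes()` draws Binomial(2, MAF) dosages with
linkage disequilibrium from a Gaussian-copula block factor: within-block
latent correlation `ld_rho`, zero between blocks. This gives clean,
controllable LD for exercising clumping and GRM code at desk scale; it
does **not** reproduce human LD decay, recombination hotspots, population
structure or relatedness. `simulate_metabolites()` makes metabolites
exactly linear in their causal dosages plus Gaussian noise scaled to a
target heritability — no batch effects, non-linearity, or missingness.
`simulate_phenotype()` draws from the hierarchical logistic model itself.

`make_scenario()` fixes the study conditions used throughout the checks:
5 pathways of 2 metabolites, 3 causal SNPs per metabolite (block LD 0.5,
MAF 0.15–0.4), heritability 0.3, age Uniform(40, 70), sex Bernoulli(0.5),
and an intercept of `logit(0.507)` emulating a near-balanced case
fraction (318/627). The active-pathway scenario sets one coefficient to
1.2. Passing tests on these bundles demonstrates internal statistical
correctness (calibration, recovery, stationarity) — not performance on
real cohort data, where LD structure, metabolite distributions and
pathway overlap are all richer.

Problem sizes for the verification runs were chosen as the smallest that
make the statistical assertions sharp: stationarity on 50 instances of
N = 60, K = 3, T_k = 2; type-I error on 100 null replicates of N = 200
with B = 99 permutations (pooled over pathways against the exact binomial
band around 0.05); recovery on 20 replicates of N = 400 with the active
coefficient 1.2. The permutation count B = 99 keeps the smallest
attainable p at 0.01, enough to rank 5 pathways.

## Numerical details and degenerate inputs

* IRLS weights are floored at `1e-10`; Hessians get a `1e-10` ridge only
  if a solve fails. Step-halving backstops every Newton update.
* The exact HWE test uses the standard mid-out recurrence on heterozygote
  counts, with label symmetry (swapping which homozygote is "minor"
  changes nothing). Monomorphic sites return p = 1. Being a discrete
  exact test it is conservative: p-values are super-uniform under
  equilibrium, which is what the calibration test asserts.
* A constant dosage vector cannot be tested for association: the scan
  records it as degenerate (`beta = 0`, `p = 1`) rather than failing the
  whole scan; `ld_r2()` defines its correlation with anything as 0 with a
  warning.
* An identity-like GRM (flat spectrum) makes `sigma_g^2` and `sigma_e^2`
  inseparable; `estimate_variance_components()` flags the degeneracy and
  returns NA components rather than an arbitrary split.
* Metabolites mapped but unmeasured are dropped with a warning; pathways
  left empty are dropped; zero-variance design columns are left at zero
  rather than producing NaNs from z-scoring.
* Empirical p-values can never be zero (add-one correction), so BH input
  is always in `(0, 1]`.

## Known limitations

* Binary outcomes only; no Gaussian/continuous outcome layer.
* Ridge penalties only (no lasso/elastic-net), and SNPs reach pathways
  only through metabolites.
* The REML grid profile is robust but slower than second-order schemes
  for large n; it is intended for cohort-scale (hundreds to low
  thousands) sample sizes.
* Permutation refits scale linearly in B; genome-scale designs with
  `B = 100{,}000` call for a compute cluster, not a laptop. All defaults
  in examples and tests use smaller B with the same machinery.
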