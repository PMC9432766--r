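---
title: "polyboost: models, simulator and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{polyboost: models, simulator and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`polyboost` is a pipeline for polygenic phenotype prediction built around
gradient boosted decision trees: a windowed, warm-started SNP selection
algorithm; depth-controlled boosted prediction models with an optional
gene–covariate interaction restriction; an L1 linear baseline; simplex
ensembling; and a phenotype simulator used to validate epistasis detection.
This vignette explains the models, the parameters that matter, the
numerical conventions, and why the open design questions were settled the
way they were.

## The selection model

A boosted tree ensemble fitted to a phenotype ranks features by
*importance*: the total training-loss reduction attributed to splits on
each feature. Fitting one model on all SNPs at biobank scale is infeasible
and, more subtly, marginal refitting per SNP (GWAS-style) over-selects SNP
clumps in linkage disequilibrium. `run_window_selection()` therefore walks
the genome in disjoint windows of `window_size` SNPs. Window 1 gets an
ordinary boosted fit. Window `n > 1` is fitted with the previous chain
prediction supplied as a per-sample additive *base margin*, the standard
boosting-continuation semantics: new trees see only the residual between
the phenotype and everything the chain has already explained. A SNP
correlated with already-captured signal has little residual gain to offer
and is not re-selected — the mechanism behind the decorrelated SNP sets
that `mean_pairwise_r2()` measures.

Choices worth knowing:

* **Warm start as base margin.** "Use the previous window's predictions as
  the starting point" admits several mechanisms (feature augmentation,
  stacking, offset). The additive offset is exact boosting continuation:
  the chained models together form one boosted ensemble whose trees are
  grouped by window. It also makes the single-window case *identically*
  equal to a plain boosted fit, which the test suite asserts at tolerance
  zero.
* **Chain margins propagate to the validation split too**, so per-window
  early stopping measures genuine residual fit, not a shifted objective.
* **Importance = raw total gain**, summed over the trees kept by early
  stopping, and aggregated across windows without per-window
  normalization. Gains are loss reductions on the same squared-error (or
  logistic) scale throughout the chain, so they are comparable across
  windows; normalizing per window would inflate windows with little signal.
* **Traversal order** (`forward`, `backward`, `shuffled`) changes which
  window "claims" shared signal first. Accuracy is empirically stable
  across orders, but the selected sets differ enough that ensembling
  forward- and backward-based models helps.
* **Defaults**: window size 10,000 SNPs (sized for ~10^5–10^6 SNP panels;
  the simulation studies here use 100 so that 1,000 SNPs still span ten
  windows), tree depth 2, learning rate 0.1, L1 penalty `alpha = 15`, at
  most 2,000 trees per window with early-stopping patience 25 on the
  validation metric. Depth 2 suffices for pairwise epistasis; the learning
  rate and stopping knobs are declared package defaults, not claims from
  any reference analysis.

## Prediction models

`fit_model()` fits either a boosted model (depth 1 or 2) or an L1 linear
baseline on a selected SNP set plus covariates.

* A **depth-1** boosted model is a sum of univariate step functions — an
  additive model, equivalent to a linear model on one-hot-encoded
  genotypes. Depth 2 adds pairwise interactions. The depth-1 vs depth-2
  comparison is therefore a controlled test for exploitable interaction,
  and `verify_additivity()` checks the structural claim directly.
* **Interaction restriction** (`interaction_mode = "restricted"`) uses the
  learner's interaction constraints to keep SNPs and covariates in separate
  trees, forcing `f(snps, cov) = g(snps) + h(cov)`.
  `verify_group_decomposition()` verifies the constraint rather than
  trusting it. Both probes evaluate the fitted trees in double precision:
  the learner predicts in single precision, whose ~1e-7 rounding noise
  would otherwise mask an exactly-zero residual.
* The **L1 baseline** is a lasso (quantitative) or L1-logistic (binary)
  path with the penalty chosen to maximize the validation metric. At
  desk-scale SNP counts after selection no screening heuristics are
  needed. Missing genotypes are mean-imputed with training means for the
  linear model and for GWAS/PCA; the boosted learner routes missing values
  natively, so they are kept as `NA` end to end.
* **Binary phenotypes** use logistic loss, probability outputs and AUC for
  early stopping and evaluation.

## Ensembling

`fit_ensemble_weights()` scans the full simplex lattice at step
`grid_resolution` (default 0.01) and returns the validation-metric-
maximizing weights. Exhaustive scanning is exact within the grid, trivially
reproducible, and doubles as the surface for ternary plots
(`simplex_grid_metrics()`). Since the lattice contains the vertices, the
weighted ensemble's validation metric can never fall below the best
individual model — an invariant the tests assert unconditionally. Ties are
resolved toward the uniform point. Beyond four models the scan is replaced
by coordinate-wise refinement from the uniform point with a final vertex
check (an extension; the reference use case is three models). For binary
phenotypes ensembling operates on probabilities: AUC is rank-based, so a
common scale across models is all that matters.

One behavior worth understanding: maximizing r² over the simplex can
assign small weight to uninformative models even when one model carries
all the signal, because down-weighting an uncalibrated prediction acts as
shrinkage. With calibrated constituents (as fitted models produce) the
optimum sits at the informative vertex.

## Metrics and standard errors

* `r_squared()` is `1 - SS_res/SS_tot` about the target mean;
  `auc()` is the Mann–Whitney probability with ties counted 1/2.
* `se_subsampling()` computes the metric on `n_repeats` subsamples of size
  `M` drawn without replacement and rescales the standard deviation by
  `sqrt(M/n) / sqrt(1 - M/n)`. The second factor is the finite-population
  correction: subsamples of a fixed sample fluctuate around the
  full-sample statistic with variance deflated by `1 - M/n`, and omitting
  the factor understates the SE by `sqrt(2)` at the default `M = n/2`.
  With the correction, the subsampling and closed-form AUC SEs agree to a
  few percent on simulated binary tasks. Defaults: `M = n/2`,
  `n_repeats = 200`.
* `se_auc_analytic()` is the Hanley–McNeil closed form with the
  exponential-approximation moments `Q1 = A/(2-A)`, `Q2 = 2A^2/(1+A)`.
* `mean_pairwise_r2()` averages squared Pearson correlations over all
  unordered SNP pairs, pairwise-complete over missing calls; monomorphic
  SNPs contribute 0 with a warning.

## The simulator

`simulate_genotypes()` draws each SNP's allele frequency uniformly from
`maf_range` and genotypes from Hardy–Weinberg proportions via two
thresholded latent Gaussian haplotypes. Within an LD block the haplotype
latents share a block factor with correlation `ld_rho`, giving a
controllable, block-constant LD structure; `ld_block_size = 1` gives
independent SNPs. The default `maf_range = (0.005, 0.5)` covers the
common-variant spectrum above a 0.5% MAF filter, the standard
preprocessing cutoff for genotyped biobank panels.

`simulate_phenotype()` builds three components — linear (`n_linear` SNPs
with standard normal effects), epistatic (`n_epistatic_pairs` indicator
events `beta * 1{g_a = v_a} * 1{g_b = v_b}` with standard normal `beta`,
the genotype combination drawn uniformly from the nine joint values and
redrawn while its Hardy–Weinberg frequency is below 0.5%), and standard
normal noise — standardizes each to unit sample variance, and combines
them as `y = sqrt(w_l) y_l + sqrt(w_ep) y_ep + sqrt(w_eps) y_eps`. The
square-root scaling makes the weights *variance shares*: the total
variance of linear effects is `1 - w_ep - w_eps` exactly as the weights
are varied. Covariate effects, when configured, enter the linear component
(linear and squared single-covariate terms) or the interaction component
(gene–covariate indicator terms) before standardization. Binary phenotypes
threshold the liability at the configured prevalence quantile.

What the simulator does *not* emulate: realistic human LD maps and
recombination structure, rare-variant site-frequency spectra, population
structure and relatedness, dominance coding, and haplotype-phase effects.
Passing recovery tests on these simulations therefore demonstrates that
the algorithms work as specified under controlled conditions — epistatic
events on independent common-ish SNPs are considerably easier to localize
than interactions embedded in real LD, where importance spreads across
correlated neighbours and exact-SNP recall drops. Recovery fractions
measured here are accordingly upper ends of what real genotype data would
show, and the package reports them as its own measured values under its
own stated conditions.

## Problem sizes used in the shipped studies

The reference simulation design is 100,000 samples and 1,000 SNPs with 100
linear SNPs and 50 epistatic pairs, noise share 0.2 — the scale at which
the acceptance script measures epistatic-SNP detection (median over three
seeds, ~10 minutes on one core). The test suite exercises the same design
at 20,000 samples and the remaining properties at 1,000–20,000 samples and
10–1,000 SNPs, sizes chosen so the full suite completes in minutes while
keeping every statistical check comfortably powered.

## Degenerate inputs and numerical conventions

* MAF filtering is inclusive (`>= cutoff`); all-missing SNPs are dropped.
* `select_top_snps()` breaks importance ties by genome order and admits
  zero-importance SNPs only to pad an under-full selection, with a
  warning. Monomorphic SNPs get GWAS p-value 1 and are never selected
  before polymorphic ones.
* Split sizes are rounded fractions with the remainder assigned to the
  test split; empty splits at `n >= 3` are an error, and stratified
  splitting is available for binary phenotypes (plain random is the
  default).
* PCA covariates are fitted on the training split only — centering,
  scaling and loadings all come from training samples, and held-out
  samples are projected onto those loadings — so no information leaks
  across splits. Zero-variance SNPs are excluded from the decomposition.
* Component standardization in the simulator uses the sample standard
  deviation; a zero-variance component (e.g. `w_ep = 0` with no pairs) is
  left at zero rather than divided by zero.
* All stochastic operations take explicit seeds and restore the caller's
  RNG state.
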