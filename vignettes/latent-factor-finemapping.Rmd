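---
title: "Latent-factor GWAS and zero-correlation multi-trait fine-mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent-factor GWAS and zero-correlation multi-trait fine-mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(latentfm)
```

## The problem

High-dimensional quantitative phenotypes — a complete blood count, an NMR
metabolomics panel — consist of dozens to hundreds of correlated traits.
Univariate GWAS of each trait ignores the shared biology: a variant acting on
an upstream process shifts many traits a little, reaching genome-wide
significance in none. `latentfm` works with the *latent factors* underlying
the traits instead. Factors are fewer, capture shared variance-generating
mechanisms, and — after varimax rotation — are mutually uncorrelated, which
is exactly the condition that lets any number of them be fine-mapped jointly.

The package covers the full path: estimate the factor model, derive GWAS
summary statistics for the factors (from individual-level data *or* from
observed-trait summary statistics alone), fine-map each factor's signals, and
sharpen the per-factor posteriors by borrowing strength across factors that
share causal variants.

## The factor model

With $P$ traits on $N$ individuals, the trait matrix is modelled as
$$Y = M + L F + \varepsilon,$$
where $L$ is the $P \times K$ loading matrix, $F$ the $K \times N$ factor
scores, and $\varepsilon$ independent noise with variances $\Psi$ (the
uniquenesses).

* **Number of factors.** `parallel_analysis()` implements Horn's method: the
  observed correlation matrix's eigenvalues are compared with the mean
  eigenvalues of `n_sims` simulated standard-normal datasets of the same
  dimension; $K$ is the length of the leading run of observed eigenvalues
  exceeding the simulated means. The comparison rule (mean, not an upper
  quantile) and `n_sims = 20` are deliberate defaults, exposed as parameters;
  with thousands of observations the simulated eigenvalue curve is tight and
  the quantile choice is immaterial.
* **Loadings.** `fit_ml_factors()` minimises the maximum-likelihood
  discrepancy $\log|\Sigma| + \mathrm{tr}(S\Sigma^{-1}) - \log|S| - P$ with
  $\Sigma = LL^\top + \Psi$, profiling the loadings out of the problem: given
  $\Psi$, the optimal $L$ comes from the top-$K$ eigenpairs of
  $\Psi^{-1/2} S \Psi^{-1/2}$. Optimisation is quasi-Newton on
  log-uniquenesses with a floor of 0.005 (containing Heywood cases), started
  from the squared-multiple-correlation proxy $1 - 1/\mathrm{diag}(S^{-1})$.
  Kept eigenvalues that fall below 1 contribute to the discrepancy like
  discarded ones; this removes a flat direction at the no-common-variance
  boundary, and excess eigenvalues below $10^{-7}$ are snapped to zero there.
  The test suite cross-checks uniquenesses and communalities against
  `stats::factanal()`.
* **Rotation.** `rotate_varimax()` implements Kaiser's pairwise
  planar-rotation algorithm for the varimax criterion with row normalisation
  on by default. We author this rather than call `stats::varimax()` because
  the latter's simultaneous fixed-point iteration can stall at the identity
  rotation for perfectly simple structures under normalisation — the exact
  configuration our recovery tests (and well-separated real loadings)
  produce. Columns are then sign-fixed (dominant loading positive) and
  ordered by decreasing sum of squared loadings, making the output
  deterministic up to the inherent rotation invariance.
* **Scores and contributions.** `factor_scores()` evaluates the
  least-squares scores $\hat F = (L^\top L)^{-1} L^\top (Y - \bar Y)$ and
  requires complete data; `factor_contributions()` rescales squared loadings
  row-wise, $C_{ij} = L_{ij}^2 / \sum_k L_{ik}^2$, the share of trait $i$'s
  factor-explained variance attributable to factor $j$.

When trait measurements are missing, the trait correlation matrix is
estimated from pairwise-complete observations (not EM imputation), and the
effective `n_obs` supplied to `parallel_analysis()`/`fit_ml_factors()` should
be the median pairwise-complete count; results are empirically robust to
this choice.

## Latent-factor GWAS from summary statistics

Because $\hat F$ is a fixed linear map of $Y$, per-variant least-squares
effects transform exactly the same way:
$$\hat\beta^* = (L^\top L)^{-1} L^\top \hat\beta,$$
so a latent-factor GWAS needs only the observed-trait effect estimates — no
individual-level data. `latent_sumstats()` implements this identity together
with the delta-method covariance
$$\mathrm{Var}(\hat\beta^*) = (L^\top L)^{-1} L^\top \mathrm{Var}(\hat\beta)
L (L^\top L)^{-1}, \qquad
[\mathrm{Var}(\hat\beta)]_{ij} = \mathrm{Cov}(Y_i, Y_j)\, s_i s_j,$$
with $s_i$ the trait-level standard errors. Three choices deserve note:

* The $Z$ statistic is $\hat\beta^*_j / \sqrt{[\mathrm{Var}(\hat\beta^*)]_{jj}}$
  — the only dimensionally coherent form — with normal-approximation
  p-values (the large-$n$ GWAS convention).
* $\mathrm{Var}(\hat\beta)$ uses the *marginal* trait covariance. This is an
  approximation (the exact off-diagonal terms involve residual covariances);
  it makes betas exact but standard errors only approximate, which is why the
  headline equivalence test requires betas to $10^{-10}$ but standard errors
  only to 2% relative. Under the global null the approximation is exact, and
  the calibration suite confirms mean $Z^2 = 1$ and correct type-I error.
* `harmonise()` first places every trait's effects on a common effect allele
  (swapped alleles negate beta and flip the frequency), keeps only variants
  present in *all* tables, and applies `min_maf = 0.005` and
  `min_info = 0.4` filters in every table. Strand-ambiguous variants are
  kept by default (single-cohort setting) with a flag to drop them.

The individual-level route (`factor_scores()` + `gwas_ols()`) and the
summary-statistics route are tested against each other; their agreement is
the package's central contract. `gwas_ols()` is a plain per-variant
regression with intercept and pairwise-complete individuals — a deliberately
unstructured stand-in for mixed-model GWAS, adequate for the simulator's
homogeneous cohorts; population structure is out of scope.

## Single-factor fine-mapping

`enumerate_models()` scores every causal configuration up to size `cmax`
with a conjugate multivariate-normal Bayes factor computed from z-scores and
the LD matrix $R$: with per-SNP prior variance $W$ on standardised effects,
$z_\gamma \sim N(0, R_\gamma + nW R_\gamma R_\gamma)$ under the model, giving
$$\log BF = \tfrac12\big(\log|R_\gamma| - \log|A_\gamma|\big) +
\tfrac12\big(z_\gamma^\top R_\gamma^{-1} z_\gamma -
z_\gamma^\top A_\gamma^{-1} z_\gamma\big), \qquad
A_\gamma = R_\gamma + nW R_\gamma R_\gamma.$$
Defaults: $W = 0.04^2$ (the FINEMAP-convention scale), per-SNP Bernoulli
prior $1/p$ (one expected causal variant per region). Sizes 1–3 are scored
by vectorised closed forms (validated against the generic eigen path and an
independent density-ratio oracle); larger sizes fall back to the generic
path. Variants in perfect LD are collapsed to one representative before
enumeration and re-expanded into credible sets. Near-singular LD submatrices
receive a $10^{-6}$ ridge.

`dynamic_cmax()` grows the maximum model size from 1 while the posterior
mass on boundary-size models exceeds `growth_threshold = 0.05` — our
operationalisation of data-driven model-size selection. Two practical notes:

* An enumeration budget (`max_models = 1e5`) stops growth in wide, strongly
  correlated regions where exhaustive enumeration of the next size would be
  enormous; the `growth_guarded` flag records when the budget, not the mass
  rule, stopped growth. Stochastic-search engines for very large model
  spaces are a non-goal.
* Under a Bernoulli $1/p$ prior the null model holds only $\approx 37\%$
  prior mass and null-data Bayes factors have expectation 1, so in truly
  null regions the null model is *modal* but not overwhelming, and `cmax`
  typically grows a step or two before stopping. This is a property of the
  prior, not a defect; a sparser prior can be supplied via `snp_prior`.

`credible_set()` ranks variants by marginal posterior probability (ties by
position) and accumulates to the 99% level; `group_variants()`
single-linkage-clusters credible variants (MPP > 0.01) with $r^2 > 0.8$;
`best_guess_ld()` reproduces the hard-call LD pipeline (dosages mapped to
the nearest genotype within 0.2, variants under 80% resolvable calls
dropped, pairwise-complete Pearson correlations).

## Joint fine-mapping of uncorrelated factors

For uncorrelated traits the joint Bayes factor of a model combination
factorises into per-trait marginals, so sharing enters only through the
*prior*. For models $M_i$, $M_j$ of two traits the joint prior is
$p_i p_j \kappa^{1\{M_i \cap M_j \neq \emptyset\}} \tau_{ij}$: model pairs
sharing at least one causal variant are upweighted by $\kappa$, and
$$\tau = \frac{1}{1 - q + \kappa q}, \qquad
q(s_1, s_2) = 1 - \binom{p - s_1}{s_2}\Big/\binom{p}{s_2}$$
($q$ the probability that two uniformly drawn models of sizes $s_1, s_2$
overlap) restores the size-marginal prior exactly for every $\kappa$ — a
property the test suite verifies by exhaustive summation. The $\tau$ form is
reconstructed from that defining property rather than copied from any
existing implementation.

`flashfmzero()` then computes, for each focal trait $t$ and model $i$,
$$PP^{(t)}_{adj}(i) \propto PP_i^{(t)} \prod_{u \neq t}
\sum_j PP_j^{(u)} \,\kappa^{1\{M_i \cap M_j \neq \emptyset\}}\,
\tau(|M_i|, |M_j|),$$
normalised per trait. The product over partners is the generalisation to any
number of traits: because the factors are uncorrelated, each partner's
posterior enters through an independent pairwise sum. This is a documented
modelling assumption (the two-trait form is exact; the product form is the
natural factorisation under zero correlation) and the brute-force oracle in
the tests enumerates model pairs and triples under exactly this definition.
The partner sums are evaluated exactly via a size-marginal decomposition
plus inclusion–exclusion over shared-variant subsets, avoiding the
quadratic-in-models cost. The default $\kappa = 4$ is a package choice — a
moderate upweighting; conclusions should be checked across $\kappa$ (the
adjusted posterior of a genuinely shared model is provably non-decreasing in
$\kappa$, and $\kappa = 1$ recovers the unadjusted posteriors exactly).

`flashfmzero_finemap()` wires `dynamic_cmax()` per factor into
`flashfmzero()` and recomputes credible sets and variant groups from the
adjusted posteriors, emitting a per-factor summary table (CS99 sizes before
and after adjustment, top variant, MPPs).

## Region bookkeeping

`ld_clump()` is greedy smallest-p-first clumping at $r^2 > 0.6$ (tags are
absorbed via the lead in a single round, not transitively — the common
PLINK-style reading). `build_regions()` distance-clumps leads (smallest p
kept within 250 kb), flanks by ±250 kb, and merges overlapping intervals;
merging is checked against an interval-union oracle. `conditional_sumstats()`
residualises z-scores on lead variants through the LD matrix — the
summary-level analogue of joint regression, validated against
individual-level multiple regression to 2%. `clump_trait_crosstab()` builds
the shared-with-latent-factor contingency table by trait count and applies
the Cochran–Armitage trend test (via `stats::prop.trend.test`, verified
against the closed-form statistic).

## The synthetic cohort

All tests run on simulated data from `simulate_genotypes()` and
`simulate_factor_traits()`:

* Genotypes: two latent standard-normal haplotype processes per individual
  with AR(1) correlation $\rho$ along the variant axis, thresholded at the
  allele-frequency quantile and summed. This gives Hardy–Weinberg
  proportions, tunable LD decay, and full determinism per seed, with no
  external reference panel. INFO is 1 by construction;
  `add_dosage_jitter()` emulates imputation noise and recomputes INFO as
  $\mathrm{var}(dosage)/(2\,\mathrm{maf}(1-\mathrm{maf}))$.
* Traits: factors are sums of planted per-variant effects plus unit-variance
  Gaussian noise; traits are loading-weighted factor combinations plus
  independent noise. `add_missingness()` provides per-trait Bernoulli masks
  for pairwise-complete paths.

Canonical study conditions used by the validation suite, chosen once as
realistic for a well-powered biobank-scale signal: regions of $p = 50$
variants with AR(1) $\rho = 0.9$ (city-block LD), $n = 10{,}000$
individuals, a per-allele causal effect of 0.10 trait-SD at MAF 0.1–0.5
(marginal $z \approx 6$–8), three factors sharing one causal variant. The
equivalence and calibration suites use $n = 2{,}000$, $P = 8$–12 traits,
$K = 2$–3 factors, 300–500 variants, sized so the whole suite runs in
minutes on one CPU.

What the simulator does *not* emulate — and hence what passing tests do not
demonstrate about real data: population structure and relatedness (no
mixed-model correction is implemented), coalescent allele-frequency/LD joint
structure, imputation error correlated with MAF, strand issues across
cohorts, and selection-induced trait non-normality. The rank
inverse-normal transform (`rank_inverse_normal()`) is provided and tested,
but simulated traits are Gaussian by construction.

## Numerical choices and degenerate inputs

* LD matrices must be symmetric, unit-diagonal, PSD to $-10^{-8}$; perfect
  proxies are collapsed; near-singular blocks are ridged ($10^{-6}$) and
  flagged.
* Credible sets whose total MPP cannot reach the level return all variants
  with a warning (`attained = FALSE`).
* All-zero loading rows yield zero contribution rows with a warning;
  constant-dosage variants are skipped and logged; malformed summary-stat
  rows are rejected with line numbers.
* Ties: credible-set ranking breaks MPP ties by ascending position; varimax
  sign ties resolve positive; contribution trait ordering breaks ties by
  first factor index.
* Coordinates are 1-based inclusive everywhere except BED export.

## Known limitations

Mixed-model association, covariate adjustment, binary traits,
cross-trait LD-score-regression correlation estimation, oblique rotations,
stochastic-search fine-mapping for very large model spaces, functional
priors, and multi-ancestry analysis are all out of scope. The joint
adjustment assumes exactly uncorrelated inputs; applying it to correlated
traits violates the factorised-likelihood premise and is the caller's
responsibility to avoid.
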