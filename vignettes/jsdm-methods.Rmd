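---
title: "Methods: the multivariate probit JSDM and its workflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the multivariate probit JSDM and its workflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The model

`jsdmprobit` fits a joint species distribution model (JSDM) to a
site-by-taxon presence/absence matrix $y$ ($n$ sites, $T$ taxa) with a
site-by-covariate design $X$. Each taxon $j$ has a probit regression — its
abiotic niche — and the taxa are tied together by a residual correlation
matrix $R$:

$$
z_i \sim \mathrm{MVN}(x_i^\top B,\; R), \qquad
y_{ij} = \mathbf{1}(z_{ij} > 0),
$$

where $B$ is the covariates-by-taxa coefficient matrix and $R$ is symmetric,
unit-diagonal and positive definite. Marginally each taxon follows
$P(y_{ij}=1) = \Phi(x_i^\top \beta_j)$; jointly, the off-diagonals of $R$
absorb co-occurrence that the measured environment does not explain. Because
shared environmental responses are modelled explicitly, a non-zero residual
correlation is the model's proxy for a biotic association (e.g. predation
appearing as negative residual correlation between predator and prey taxa).
The probit link is what makes exact Gibbs sampling possible: conditional on
the sign constraints, the latent $z$ are truncated normals.

The boundary event $z = 0$ has probability zero; we deterministically count
it as absence ($y = 0 \iff z \le 0$) so runs are exactly reproducible.

## The four nested variants

Following the standard JSDM comparison design, four variants are supported
(`model_spec()`):

| variant            | niche covariates           | correlation matrix |
|--------------------|----------------------------|--------------------|
| `null`             | intercept + forced terms   | identity           |
| `community_only`   | intercept + forced terms   | estimated          |
| `environment_only` | + per-taxon selected terms | identity           |
| `full`             | + per-taxon selected terms | estimated          |

"Forced terms" are the survey-design dummies (dipping round, survey area),
included in every variant as fixed effects because a repeated-measures
survey with only a handful of rounds and areas cannot support a random-effect
variance. The null model therefore says: each taxon occurs with a constant
probability given round and area, and all spatial structure beyond that is
what the richer models try to explain.

# Priors

The prior specification is a design decision of this package, chosen to be
weakly informative and standard for this sampler family:

* coefficients: independent $\mathrm{Normal}(0, 10^2)$ — essentially flat on
  the probit scale, but proper, so taxa that are all-absent or all-present
  (quasi-separation) still yield a proper posterior. `jsdm_fit()` warns
  about such taxa instead of failing, because rare taxa are routine in
  survey data.
* correlation matrix: the marginally-uniform prior induced by parameter
  expansion — the expanded covariance is inverse-Wishart with identity
  scale and $T + 1$ degrees of freedom, which makes every off-diagonal of
  $R$ marginally uniform on $(-1, 1)$.

# The Gibbs sampler

One sweep updates, in order (`sample_latent()`, `sample_coefficients()`,
`sample_correlation()`):

1. **Latents.** Each $z_{ij}$ is drawn from its univariate full
   conditional: the conditional normal of $\mathrm{MVN}(x_i^\top B, R)$
   given the other entries of row $i$, truncated to $(0, \infty)$ if
   $y_{ij}=1$ and $(-\infty, 0]$ otherwise. Taxa are visited in index
   order; since rows are mutually independent given $(B, R)$, updating a
   whole column at once is the same conditioning as a literal per-site
   sweep and vectorises well. Truncated normals are drawn by inversion
   with tail guards.
2. **Coefficients.** Given $z$ and $R$ the model is a seemingly-unrelated
   regression, so the stacked included coefficients have a joint
   multivariate normal full conditional with precision blocks
   $(R^{-1})_{jk} X_j^\top X_k$ plus the prior precision. Structural zeros
   (covariates excluded from a taxon's niche model) are preserved exactly.
3. **Correlation** (estimated variants only). A parameter-expanded update:
   an unconstrained covariance is drawn from
   $\mathrm{IW}(T + 1 + n,\; I + E^\top E)$ with $E = Z - XB$, then rescaled
   to a correlation matrix; the matching per-taxon scales divide the latent
   and coefficient columns so the chain returns to the identified
   (unit-variance) scale. Identity-constrained variants skip this step, in
   which case the taxa are exactly independent probit regressions.

The sampler is written in C++ (RcppArmadillo) but consumes R's own random
number stream, so a fit is bit-reproducible from `mcmc_settings()$seed`;
chain $c$ uses stream `seed + c - 1`, making chains independent and the
whole run deterministic. Defaults are 2 chains of 30,000 iterations with
10,000 burn-in and thinning 10; the seed must always be given explicitly.
Split-chain potential-scale-reduction statistics are computed for every
scalar parameter and values above 1.1 produce a warning.

We verified the sampler's posterior externally during development against
an independent MCMC implementation of the expanded-covariance multivariate
probit model: posterior means and standard deviations of residual
correlations agreed to about 0.01 on matched data.

# Covariate selection

`forward_stepwise()` implements per-taxon forward selection by
maximum-likelihood probit regression: starting from intercept + forced
terms, each step adds the candidate giving the largest AIC decrease
($\mathrm{AIC} = -2\ell + 2k$), stopping when no candidate lowers AIC. Three
deliberate choices:

* any strictly positive decrease accepts a step (no $\Delta \ge 2$ rule);
* ties to machine precision go to the earliest candidate in the supplied
  ordering, so selection is fully deterministic;
* a candidate whose addition causes perfect separation (or a rank-deficient
  design) is skipped for that step with a warning rather than aborting —
  binary vegetation indicators plus rare taxa make separation likely.

Pure forward selection is used, never dropping previously accepted terms,
and backward/bidirectional search and other information criteria are out of
scope.

# Model comparison

## Likelihood evaluation

The joint likelihood of one site is an orthant probability of a
multivariate normal — the probability that $\mathrm{MVN}(x_i^\top B, R)$
matches the observed sign pattern. With $R = I$ it factorises into exact
univariate probit terms; otherwise `orthant_probability()` uses the GHK
sequential importance sampler (default $M = 5000$ replicates, antithetic
pairs, fixed seed, so every evaluation is deterministic and comparisons
across models share the same random inputs). Site probabilities are floored
at $10^{-300}$ before logging.

## Deviance and its decomposition

`jsdm_deviance()` returns $-2\sum_i \log P(y_i \mid x_i^\top B, R)$.
Per-taxon contributions (`per_taxon_deviance()`) are defined as
*conditional* deviances, $-2 \sum_i \log P(y_{ij} \mid y_{i,-j})$, so the
estimated correlations can inform per-taxon predictions; under $R = I$ this
reduces exactly to the taxon's marginal probit deviance and the per-taxon
values sum to the joint deviance. `proportion_explained()` reports
$1 - D_\text{model}/D_\text{null}$ at plug-in posterior means, per taxon
and community-wide; the community value is a ratio of summed deviances (not
a mean of ratios), weighting taxa by information content.

## DIC

`dic()` computes $\mathrm{DIC} = \bar D + p_D$ with
$p_D = \bar D - D(\bar\theta)$. The plug-in $\bar\theta$ uses the
element-wise posterior mean of $B$, and the posterior mean of the
correlation draws projected to the nearest correlation matrix (eigenvalues
clipped at $10^{-6}$, rescaled to unit diagonal), because a mean of
correlation matrices need not be one. The *integrated* (GHK) likelihood is
used rather than a likelihood conditional on latent variables; this choice
affects $p_D$ — conditioning on latents would count them as parameters —
and is the reading that makes DIC comparable across the identity and
estimated-correlation variants. Because GHK evaluation per draw is the
costly step, $\bar D$ is averaged over an evenly-spaced subsample of draws
(default 50) for correlated models; identity models use all draws with the
exact factorised likelihood. A DIC difference greater than 5 is treated as
an appreciable difference in explanatory power.

# Posterior summaries

* **Effect sizes** (`effect_sizes()`): continuous covariates are
  standardized (mean 0, sample sd 1) in `build_design()`, so coefficients
  are the effect of a one-standard-deviation change; 0/1 indicator
  covariates stay on their natural scale. The two kinds are flagged and
  should not be compared with each other. Point estimates are maximum a
  posteriori values: the mode of a Gaussian kernel density estimate
  (Silverman's rule-of-thumb bandwidth, 512-point grid over the draw
  range). Intervals are central 95% quantile intervals using linear
  interpolation between order statistics (R's default type-7 rule; the
  convention matters at a few hundred draws, so it is fixed and
  documented).
* **Bayesian p-values** (`bayesian_pvalue()`): the posterior probability
  that a quantity is zero or of opposite sign to its posterior mean, 0.5
  when the mean is exactly zero. Values below 0.05 play the role of
  significance at the 5% level.
* **Correlation networks** (`correlation_network()`): an edge for each
  unordered taxon pair whose Bayesian p-value is below the threshold
  (default 0.05), weighted by the posterior mean correlation. Lowering the
  threshold can only shrink the edge set.
* **Co-occurrence dendrograms** (`cooccurrence_dendrogram()`): pairwise
  dissimilarity $1 - r$ with $r$ the Pearson correlation of the binary
  occurrence columns (the phi coefficient) — 0 identical, 1 independent,
  2 complementary — clustered agglomeratively. Average linkage (UPGMA) is
  the default and configurable; the choice of linkage is a presentation
  decision and does not affect the dissimilarities. Export to Newick uses
  the merge heights as branch lengths.

# Spatial residual diagnostics

Raw residuals are $y_{ij} - \hat p_{ij}$ with $\hat p$ the posterior mean
of the *marginal* presence probability $\Phi(x_i^\top \beta_j)$ — the
simplest reading of "mean probability of presence"; a conditional
definition could be substituted but is not the default. Residual sets are
split by round × area (`split_residuals()`), screened per taxon with a
Moran's I test, and splits with $p < 0.05$ are inspected with a bootstrap
spline correlogram:

* **Moran's I** uses inverse-distance weights with zero diagonal and no
  row standardisation by default (k-nearest-neighbour binary weights, or
  any explicit weight matrix, as alternatives), with the normal
  approximation under the randomisation variance for the p-value.
* **Correlograms** bin pairwise products by distance, pass a cubic
  smoothing spline through the bin estimates, and bootstrap sites with
  replacement (default 199 replicates, seeded) for pointwise 95%
  percentile intervals. Bins with fewer than two pairs are dropped with a
  warning. Percentile intervals are not guaranteed to contain the point
  estimate at every grid point, though they almost always do in practice.
* **Coherence** is operationalised as at least three consecutive grid
  points whose intervals exclude zero — a declared, automatic version of
  what is otherwise a visual judgement.

# The synthetic-data generator

`simulate_covariates()`, `simulate_community()` and `make_study_fixture()`
generate survey-structured data from the model's own generative process, so
the whole pipeline is testable without any external download. The default
fixture mirrors the structure of a UK wetland larval dipping survey: 167
dip sites in 3 plots visited in 4 rounds (one row per visit), 16 taxa of
which 4 are labelled mosquitoes, 4 continuous water measurements (depth,
temperature, oxidation-reduction potential, salinity; correlated, with a
seasonal temperature trend, standardized) and 9 binary vegetation
indicators with site prevalences between 0.05 and 0.5 (indicators are
guaranteed non-constant so the design stays full rank). Coordinates are
uniform in per-plot rectangles, the largest 1700 m across. The truth uses
prevalences of roughly 0.1–0.4, effect sizes up to 1.5 on the standardized
scale, residual correlations of magnitude 0.15–0.5 — with ditch shrimp and
fish given negative correlations with two mosquito taxa, emulating a
predator signal — and non-zero round/area effects so the forced-term
machinery is always exercised. Everything regenerates bit-identically from
the recorded seed.

What the generator does *not* emulate: imperfect detection, observation
error, abundance, temporal autocorrelation across rounds beyond the fixed
round effects, and spatial autocorrelation in the residuals. Tests passing
on this generator therefore demonstrate correctness of the machinery under
the model's own assumptions, not robustness to their violation in real
field data.

# Problem sizes used by the test suite

The package's statistical claims are exercised at deliberately moderate
sizes: orthant-probability anchors at $M = 10^4$ GHK replicates;
identity-model oracle comparisons at 1000 rows; correlation recovery at
500 rows × 4 taxa (30 replicates) and at the reduced fixture scale of 200
rows × 6 taxa with 2 × 5000 iterations (100 replicates); DIC ordering at
500 and 300 rows (100 replicates each); stepwise recovery of a planted
1.5-sd covariate at 1000 rows (100 replicates); Moran size at 500 null
replicates.

# Known limitations

* The precision of residual-correlation estimates is limited by the binary
  data: at a few hundred rows with prevalences well below one half, the
  posterior standard deviation of an off-diagonal of $R$ is around 0.15,
  and point estimates cannot be systematically more accurate than that.
  Credible intervals remain calibrated (coverage near nominal); users of
  small surveys should lean on intervals and Bayesian p-values rather than
  point estimates of correlations.
* GHK is a consistent but noisy estimator of orthant probabilities;
  deviance comparisons across models use a common seed so the noise
  largely cancels, but very small deviance differences (a few units) are
  within its Monte-Carlo error at default settings.
* Logit-link JSDMs, abundance models, and phylogenetically or spatially
  structured random effects are out of scope; the spatial module
  *diagnoses* residual autocorrelation but the model cannot absorb it.
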