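---
title: "A shared-factor multilevel multinomial model for joint disease prevalence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A shared-factor multilevel multinomial model for joint disease prevalence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Obesity and diabetes are closely linked conditions whose joint prevalence
varies strongly across US counties and states. Separating *compositional*
variation (differences in the age, race and education make-up of area
populations) from *contextual* variation (area influences that persist
after individual risk factors are controlled) requires a model that treats
the two conditions jointly, respects the survey design, and carries an
explicit spatial structure at more than one geographic level. `jointprev`
implements such a model for a six-category outcome formed by crossing
diabetic status with weight class (obese, overweight, normal), with the
normal-weight non-diabetic class as the non-morbid reference.

## The model

For respondent $i$ with age group $a_i$ (12 groups), race $r_i$ (4 groups,
white non-Hispanic reference), education $e_i$ (4 groups, less than high
school reference), county $C_i$ and state $S_i$, the outcome
$y_i \in \{1, \dots, 6\}$ follows a multinomial logit

$$\Pr(y_i = j) = \pi_{ij} =
  \frac{e^{\varphi_{ij}}}{1 + \sum_{j'=1}^{5} e^{\varphi_{ij'}}},
  \qquad j = 1, \dots, 5,$$

with the reference category's predictor fixed at zero. The full linear
predictor is

$$\varphi_{ij} = \alpha_j + \beta_{j,r_i} + \gamma_{j,e_i} + \eta_{j,a_i}
  + \textstyle\sum_{k=1}^{5}\delta_{jk}\,x_{k,C_i}
  + \lambda_j v_{C_i} + \kappa_j u_{S_i},$$

where $x_{1..5,c}$ are county poverty (a proportion), log population
density, and binary indicators for counties in the top decile of black,
Hispanic and other-nonwhite population shares. The latent fields $v$
(county) and $u$ (state) are *shared factors*: a single spatially
structured effect per level enters every category through category-specific
loadings $\lambda_j$, $\kappa_j$. Identification uses corner constraints
($\beta_{j1} = \gamma_{j1} = 0$, $\lambda_1 = \kappa_1 = 1$), per-category
sum-to-zero age effects, and sum-to-zero centering of $v$ and $u$.

Three nested specifications form the incremental strategy: model 1 keeps
only age and the latent factors (the age-adjusted baseline), model 2 adds
the county covariates, model 3 adds race and education. Comparing the
marginal variance of $\lambda_j v_{C_i} + \kappa_j u_{S_i}$ across the
sequence measures how much apparent spatial variation is explained by
composition and by measured context.

Survey weights $w_i$ enter as a pseudo-likelihood,
$\log L_w = \sum_i w_i \sum_j d_{ij} \log \pi_{ij}$ with $d_{ij} =
1[y_i = j]$. By default the weights are rescaled to mean 1 before fitting
so that the information content of the pseudo-likelihood matches the actual
sample size and the prior/likelihood balance is honest; raw weights are an
option (`normalize_weights = FALSE`). Whether the original analysis
rescaled its weights is not documented; rescaling leaves all point
estimates essentially unchanged and only calibrates posterior spread.

## Priors

The spatial prior on each latent field is the intrinsic CAR with binary
adjacency: pairwise-difference kernel
$-\tfrac{1}{2\sigma^2}\sum_{c \sim c'}(x_c - x_{c'})^2$, a sum-to-zero
constraint per connected component, and isolated areas treated as free
Normal$(0, \sigma^2)$ effects. `icar_logpdf_kernel()` includes the full
normalising constant (half the log pseudo-determinant of the component
Laplacians and a $\sigma^2$ exponent equal to half the Laplacian rank), so
the density agrees exactly with the degenerate Gaussian obtained by
eigendecomposition — this is what the spectral tests check at `1e-8`.

Age effects follow, per category, a first-order random walk over the 12
age groups whose innovations are correlated *across* categories through a
$5 \times 5$ covariance $\Sigma_\eta$ with an inverse-Wishart$(J+2, I)$
prior: the five morbidity categories are expected to have similar (rising)
age gradients, and the cross-category correlation pools that information.
Fixed effects and free loadings get Normal$(0, 10^2)$; the conditional
standard deviations $\sigma_v$, $\sigma_u$ get half-Normal$(0,1)$, which is
better behaved near zero than a Gamma prior on the precision. All of these
choices are configurable; none is claimed to reproduce the original
analysis' unpublished prior text.

## Posterior computation

`run_mcmc()` is an adaptive Metropolis-within-Gibbs sampler over the
weighted pseudo-posterior. The data enter only through per-cell sufficient
statistics (unique age × race × education × county combinations with
per-category summed weights), which makes likelihood evaluation cheap and
exact. Update blocks per sweep:

* per category, two fixed-effect blocks — (intercept, county covariate
  effects) and (intercept, race, education) — with multivariate normal
  proposals; the shared intercept lets each block carry its own strong
  posterior correlations. Proposal shapes are seeded from the weighted
  multinomial MLE and its asymptotic covariance (`nnet::multinom` on the
  cell counts) and, for the covariate block, refined by Haario-style
  empirical-covariance adaptation during burn-in;
* per category, the age-effect row (two passes — these rows mix most
  slowly under the smoothing prior) with sum-to-zero-projected proposals,
  plus a scalar "tilt" move along the linear age trend, the smooth
  direction the random-walk prior leaves cheapest;
* a conjugate inverse-Wishart Gibbs draw for $\Sigma_\eta$;
* the latent fields by element-wise Metropolis over graph-colouring
  classes (areas of one colour are conditionally independent because the
  likelihood factorises by area and the ICAR prior couples only
  neighbours), under the ICAR full conditionals;
* three families of interweaving moves that traverse the posterior's soft
  ridges: a state-level exchange shifting a state's county effects against
  its state effect; a joint rescale $(x, \sigma^2) \to (cx, c^2\sigma^2)$
  of each field with its variance, which crosses the funnel between a
  field and its scale (for the state field this is the *only* update of
  $\sigma^2_u$ — a kernel-only update would be drawn into the degenerate
  $\sigma^2 \to 0$ corner when only a handful of states inform it); and a
  loading rescale $(x, \text{loadings}, \sigma^2) \to
  (cx, \text{loadings}/c, c^2\sigma^2)$ that moves along the factor scale
  ridge while touching the likelihood only through the reference loading;
* an exact likelihood-invariant shear between each county covariate effect
  and the county field, $v_c \to v_c - e\,x_{kc}$,
  $\delta_{jk} \to \delta_{jk} + \lambda_j e$, accepted on the prior ratio
  alone — this mixes the direction in which a flexible spatial field can
  absorb a covariate signal;
* loadings as two $(J-1)$-dimensional blocks with empirical-covariance
  proposals, and $\log \sigma^2_v$ by random walk against the ICAR kernel
  and half-Normal prior.

After every sweep the latent fields and age effects are re-centered with
the compensating intercept shift $\alpha_j \mathrel{+}= \lambda_j \bar v$
(etc.), which leaves every linear predictor — hence the likelihood —
exactly unchanged. Proposal scales adapt toward 20–50% acceptance in
windows during burn-in and are frozen afterwards. Chains start from the
MLE-centred dispersed values (chain 1 with modest noise, later chains
overdispersed threefold); convergence is monitored with the corrected
Brooks-Gelman-Rubin statistic (`gelman_rubin()`), whose floor for
identical chains is $\sqrt{(n-1)/n}$, and model fit with the DIC
(`compute_dic()`): average sampled deviance plus the effective parameter
count $p_D = \bar D - D(\bar\theta)$. A negative $p_D$ (possible when a
short run has not converged) is reported verbatim with a warning.

## The synthetic-data generator

`generate_dataset()` emulates the structure of a BRFSS-like male survey:
a near-square rook-adjacency county lattice partitioned into contiguous
column-strip states; county poverty from Beta(2, 10), log density from
Normal(4, 1.5), county race composition from a Dirichlet with the
top-decile indicators computed by the package's own rule; log-normal
county population sizes driving respondent allocation; respondent age,
race and education drawn independently of county; latent fields sampled
spectrally from the ICAR model; outcomes drawn from the exact model
probabilities; and inverse-stratum-probability survey weights in which
response propensity rises with age and is lower for minority strata, with
optional mean-one log-normal jitter.

The default true parameters are anchored to the magnitudes reported for
the 2007 US male survey analysis: intercepts at the logits of the overall
category shares (4.2, 3.1, 1.4, 22.4, 40.2 vs 28.8 percent), race and
education contrasts and county covariate effects at the published
posterior means, county loadings (1, 1.25, 1.27, 2.44, 1.65), state
loadings (1, 1.09, 0.45, 0.48, 0.30), $\sigma^2_v = 0.3$ (the magnitude of
the published marginal spatial variance) and $\sigma^2_u = 0.1$ (not
published; chosen so state effects are present but weaker than county
effects, as the loading pattern suggests), and smooth age profiles rising
with age for the diabetic categories only.

What the generator does *not* emulate: real county geography and
adjacency, telephone-frame sampling and raking, within-county correlation
of respondent race/education with county composition, item nonresponse,
and diabetes type differentiation. Passing tests therefore demonstrate
correctness of the machinery and recoverability under the stated
conditions, not agreement with the restricted real-survey estimates.

## Problem sizes used by the tests

The package's simulation study runs at a desk scale chosen to keep a full
replicate analysis in the minutes range on one core: 48 counties (8 × 6
grid) in 4 states with 6,000 respondents; five replicate datasets; model 3
fitted with one chain of 3,000 iterations (half burn-in) per replicate for
the calibration checks, matched model 1 fits for the DIC comparison, and
one two-chain fit of 8,000 iterations for the convergence criterion. The
analysis scripts under `analysis/` use the generator's full desk-scale
default (100 counties, 5 states, 20,000 respondents). At 48/4/6,000 the
fixed-effect credible intervals attain near-nominal coverage and the
posterior county field correlates with the generating field at about 0.87.

Two desk-scale caveats are worth recording. First, with only four states a
flexible county field can absorb most state-level variation (a per-state
constant is almost free under the county ICAR prior when states are
contiguous blocks), so the state variance often shrinks toward zero and
the state loadings $\kappa_{2..5}$ become prior-dominated — their wide
posteriors are genuine, not a sampler failure; with 49 real states the
state level is far better identified. Second, the convergence criterion is
evaluated on the *reported* parameters — those a report tabulates
(intercepts, race/education contrasts, county covariate effects, loadings
and variances). Random effects displayed only as posterior-mean summaries
(the per-area latent values, the age profiles, the innovation covariance)
are summarised but not gated: at desk scale the age profile of the
rarest category has near-empty young-age strata, so its tail is
prior-dominated and wide — wide posteriors there are genuine, and at the
real survey's size those strata are well populated.

## Post-processing definitions and open choices

* **Age-standardised county prevalence** (`standardized_prevalence()`):
  scores $w_{cj} = \exp(\alpha_j + \sum_k\delta_{jk}x_{kc} + \lambda_j v_c
  + \kappa_j u_{S_c})$ (covariate term only when the model includes it),
  $w_{c,6} = 1$, normalised per county. For a fitted model the default is
  the posterior mean of the per-draw prevalences — correct under the
  nonlinear transform — with prevalence-at-the-posterior-mean exposed as
  an alternative.
* **Composite latent effect** (`composite_effects()`):
  $t_{jc} = \lambda_j v_c + \kappa_j u_{S_c}$; for the jointly
  obese-diabetic category this is exactly $v_c + u_{S_c}$.
* **Marginal latent variance** (`marginal_latent_variance()`): the
  variance over respondents of $\lambda_{j(i)} v_{C_i} + \kappa_{j(i)}
  u_{S_i}$ at the observed category $j(i)$. The exact treatment of
  reference-category respondents is not documented in the source analysis;
  by default they contribute the category-share-weighted average of the
  five per-category composite effects, with exclusion
  (`reference = "drop"`) as the documented alternative. This quantity is
  an approximation to an under-specified target and is labelled as such.
* **Poverty decile profile** (`poverty_decile_profile()`): counties ranked
  by poverty, split into ten near-equal rank groups (remainder to the
  lowest deciles, ties broken by county index), mean composite effect per
  decile.
* **Cross-tabulations** (`crosstab_prevalence()`): percentage of
  (optionally weighted) subjects per category within education, race or
  state groups; direct age standardisation to the overall weighted age
  distribution when requested (the original analysis' exact
  standardisation scheme is unstated, so exact reproduction of its state
  table is not claimed). Printed-style rounding is half-up to one decimal.
* **Top-decile rule** (`top_decile_indicator()`): the threshold is the
  order statistic at position $\lceil 0.9n \rceil$ with strict exceedance,
  which flags exactly $\lfloor n/10 \rfloor$ counties for distinct values
  (311 of 3,110) and flags nothing when all values tie at the threshold.

## Numerical choices

Log-sum-exp throughout the probability computations, with a guarded fast
path for moderate predictors; support violations ($\sigma^2 \le 0$,
non-positive-definite $\Sigma_\eta$) return $-\infty$ rather than raising,
so Metropolis proposals are rejected cleanly; the ICAR pseudo-determinant
is precomputed per graph at construction ($O(n^3)$ eigendecomposition —
fine for the package's intended problem sizes, and needed only when graphs
are built); variance parameters are proposed on the log scale with the
Jacobian included; Monte Carlo standard errors use batch means with 50
batches; a singleton graph component sampled under per-component centering
is identically zero, while its log-density treats a free island value as
Normal$(0, \sigma^2)$ — the sampler draws island values only through that
density, never through `sample_icar()`.

## Limitations

The sampler is a pure-R random-walk scheme: adequate at desk scale, not
tuned for the 3,110-county national problem (a fit at that size would want
sparse-matrix ICAR updates and compiled likelihood code). DIC is reported
because it is the reference workflow's criterion; it shares the known
weaknesses of DIC for hierarchical models (focus-dependence, possible
negative $p_D$ before convergence). The pseudo-likelihood treatment of
survey weights yields design-consistent point estimates but its posterior
spread has no exact design-based calibration guarantee; mean-one weight
rescaling is the package's pragmatic default.
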