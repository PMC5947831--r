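---
title: "Niche models for assessing saltmarsh restoration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Niche models for assessing saltmarsh restoration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(marshniche)
library(dplyr)
```

## The question

Saltmarsh restored by breaching sea defences (managed realignment, MR) often
fails to develop the plant communities of natural reference marshes, even
after decades (accidental realignments, AR, restored by historic breaches).
Two explanations compete: the restored sites may simply not offer the right
*environmental conditions* — position in the tidal frame and sediment redox
potential are the two main controls on saltmarsh plant distribution — or
succession itself may run differently on bare, newly flooded sediment.

`marshniche` separates these hypotheses with species occurrence models.
Occurrence models for ten common saltmarsh species are trained on
natural-marsh quadrats only, then *transferred* to restored-marsh quadrats:
if environmental conditions were the whole story, observed occupancy should
match the transferred predictions. A second model that includes marsh age as
a covariate quantifies the residual age effect once the environment is
controlled for, and an observed-versus-expected analysis of each species'
mean position in the tidal frame tests for the signatures of altered
succession (pioneers sitting higher, upper-marsh species sitting lower, than
their natural-marsh niches predict).

## Environmental standardizations

Elevation (m above Ordnance Datum Newlyn) is standardized per site into
**relative tidal height**, `RTH = (elevation - MHWN) / (MHWS - MHWN)`, so 0
is mean high water neap and 1 mean high water spring and equal RTH implies
equal submergence duration. RTH below 0 or above 1 is real data — pioneer
species genuinely occur below MHWN — and is never clipped. Redox potential
measured against an Ag/AgCl reference is shifted by +204 mV onto the
standard hydrogen electrode scale. Quadrat rows lacking elevation or redox
are flagged (`complete_env`) and excluded from model fitting but kept in the
table.

## The occurrence model

For each species, presence/absence \(y_i\) in quadrat \(i\) is modelled via
a latent suitability function \(f\) with a Gaussian-process prior over the
quadrat-by-covariate matrix and a probit link,
\[
y_i \sim \mathrm{Bernoulli}\{\Phi(f(x_i))\},\qquad
f \sim \mathcal{GP}(m, k),
\]
with inference by the Laplace approximation: Newton iteration locates the
posterior mode of the latent field (tolerance \(10^{-8}\) on the penalized
log-likelihood, at most 100 iterations) and the curvature there supplies the
Gaussian approximation used for prediction, posterior sampling and the
marginal likelihood. Predictive probabilities use the closed form
\(\Phi(\mu_*/\sqrt{1+\sigma_*^2})\).

**Kernel.** Continuous covariates (RTH, redox) are standardized to zero
mean, unit variance *on the training data*; predictions reuse the training
scaling, which is what makes transfer to restored marshes well defined. They
enter a squared-exponential kernel with per-covariate lengthscales (default
1 standardized unit, signal variance 1, jitter \(10^{-6}\)). Categorical
covariates (region, and marsh age in the second model) multiply the kernel
by 1 for matching levels and \(\exp(-1/(2\ell_{cat}^2))\) otherwise
(default \(\ell_{cat}=1\), i.e. ~0.61), so levels share strength rather
than splitting the data. A level never seen in training matches nothing and
simply reverts toward the prior, with a message.

**Prior mean.** The latent prior mean is constant ("flat"). Its default is
`qnorm(prevalence)` of the training data, so far from the data the model
predicts the species' base rate rather than 0.5; `prior_mean_prob = 0.5`
gives the zero-mean alternative. Both readings of an "uninformative" latent
prior are defensible and both are exposed.

**Hyperparameters.** `gp_optimize()` tunes lengthscales and variance by
bounded L-BFGS-B on the Laplace log marginal likelihood and is guaranteed
never to return a worse spec than its start; fits default to the fixed
kernel (`optimize = FALSE`) because repeated refits (cross-validation,
subset fits in partitioning) are then exactly reproducible and directly
comparable. Either mode can be selected pipeline-wide.

## Derived analyses

**Cross-validation.** Discrimination is measured by AUC — implemented as the
Mann–Whitney concordance probability with ties counting ½, so it is exact —
over repeated simple random 75/25 splits (headline scale 1,000 runs).
Splits leaving a training or test part with only one class are redrawn and
counted, rather than stratified, to keep the protocol simple random. AUC
inflates for low-prevalence species, so prevalence is always reported
alongside.

**Transfer.** Per posterior draw (headline 1,000), occurrence probabilities
are averaged over the target class's quadrats; the across-draw median and
equal-tailed 95% interval summarize the mean suitability of the conditions
available in MR and AR marshes. Draws use the joint Gaussian over prediction
points up to 2,000 points (beyond that, marginals, logged): the joint is
more faithful for across-quadrat averages at modest size, the marginal
scales.

**Age effect at the latent optimum.** In the model with marsh age included,
each class's occurrence probability is evaluated at the (RTH, redox, region)
combination that maximizes the latent predictive mean, searched over the
*observed* covariate vectors with age substituted — not a free continuous
optimization — so "most favourable conditions" can never be extrapolated
outside sampled environmental space. The point summary is the posterior
mode. We estimate it by a kernel-density argmax on the probit scale of the
draws, mapped back through `pnorm`: a KDE directly on (0,1) needs boundary
correction, and whenever the latent predictive sd exceeds 1 the
probability-scale density truly diverges at 0 or 1, pinning a reflected-KDE
argmax to the boundary outside its own credible interval. The probit scale
is unbounded and near-Gaussian, so the argmax is stable and always interior.
Intervals are equal-tailed 2.5/97.5 percentiles of the draws.

**Hierarchical partitioning.** Predictor importance is decomposed by fitting
all \(2^k-1\) predictor subsets and averaging each predictor's marginal
goodness-of-fit gain over hierarchy levels (Chevan–Sutherland). Goodness of
fit is the in-sample log-likelihood gain of the latent-mode fit over the
prevalence-only null — a deviance-style measure under which the averaging
identity is exactly additive, so contributions sum to the full-model gain to
numerical precision. A subset whose fit fails is imputed at the null and
logged.

**Tidal position.** Observed position is the mean RTH of occupied quadrats
per class, with a type-7 (linearly interpolated) interquartile range.
Expected position asks where the species would sit if it filled the most
suitable quadrats: per posterior draw, the class's quadrats are ranked by
drawn probability, the top \(n\) taken (\(n\) = observed occupancy; ties
broken by quadrat order so the selection is deterministic), and their RTH
averaged; the across-draw mean and 95% percentile interval are reported.
Classes where a species never occurs give flagged, not invented, summaries.
Position differences among classes are tested by Kruskal–Wallis with
post-hoc pairwise two-sided Mann–Whitney–Wilcoxon tests,
Benjamini–Hochberg-adjusted across the pairs, summarized by a compact letter
display built by greedy clique cover of the non-significance graph.

**Environmental comparisons.** RTH and redox are compared across classes by
OLS with marsh age and region as factors (treatment coding, NAT and Essex
references — the contrasts of interest are restored-versus-natural), and the
redox–RTH relationship by `redox ~ rth * age_class + region`, whose
interaction contrasts measure the steepening (MR) or flattening (AR) of the
slope. Quadrats are pooled (no site random effect), matching the reported
fixed-effects analysis.

## The synthetic generator

Because the archived field data are an external download, every stage is
exercised against a generator that emulates the study design: 3 regions ×
{2 MR, 1 AR, 4 NAT} sites, at least 30 quadrats per site (defaults 48/83/42
put the class totals near the campaign's 290/249/506), RTH drawn uniformly
per class — MR over (−0.6, 1.1), AR/NAT over (−0.3, 1.4), encoding the
lower-lying MR platforms — and redox affine in RTH (intercept −60 mV; slopes
318/178/238 mV per RTH unit for MR/AR/NAT, i.e. the natural-marsh slope with
a steeper MR and flatter AR relationship) plus Gaussian noise, sd 150 mV
(chosen to reproduce a natural-marsh slope standard error near 14 mV at
n ≈ 500). Species presence comes from a *quadratic* latent surface on the
probit scale — a Gaussian bell over (RTH, redox) with region offsets and
age-class shifts — not from a GP draw: the ground truth (optimum, breadth,
shift) is then known exactly and parameter recovery is testable. The ten
default profiles order the species along the low-to-upper marsh gradient
with MR shifts depressing the mid-marsh suite.

The generator deliberately omits spatial autocorrelation within transects,
interspecific interactions, and any real successional dynamics. Passing the
recovery tests therefore shows the estimators work when their assumptions
hold; it does not validate the assumptions on field data.

A single master seed is split into named per-stage streams
(environment, occurrence, draws, each cross-validation), so any stage can be
reproduced in isolation and the full pipeline is bit-reproducible given its
configuration.

## Problem sizes and numerical choices

The test suite runs the generator at reduced but honest sizes: parameter
recovery at roughly 300 quadrats per age class (500 on natural marshes for
the niche-surface check), cross-validation properties at 50 runs, and the
end-to-end pipeline at 100 cross-validation runs and 200 posterior draws
over four species — the same code paths as the headline 1,000/1,000 scale,
which is one flag away. Monte-Carlo assertions use three standard errors.
The MCMC oracle used to validate the Laplace approximation in the tests is
an elliptical slice sampler over the exact latent posterior on designs of at
most eight quadrats.

Degenerate inputs are policy, not accidents: all-presence or all-absence
responses are errors; a species absent from a class yields flagged rows;
collinear observed conditions collapse the availability hull so off-line
grid cells are masked; tied probabilities in the top-\(n\) selection break
by quadrat order; rank-deficient linear models report aliased terms.

## A worked example

```{r example, eval = FALSE}
sv <- simulate_survey(sim_config(seed = 1))
nat <- filter(sv$survey, age_class == "NAT")

fit <- gp_fit(nat, "Pucc")
cross_validate(nat, "Pucc", n_runs = 100, seed = 1)$mean_auc
predict_transfer(fit, filter(sv$survey, age_class == "MR"),
                 n_draws = 200, seed = 1)

age_fit <- gp_fit(sv$survey, "Pucc",
                  c("rth", "redox", "region", "age_class"))
age_effect_at_optimum(age_fit, sv$survey, n_draws = 200, seed = 1)
autoplot(niche_surface(fit, nat))
```

## Limitations

The Laplace approximation understates skew in the latent posterior for
extreme prevalence; the oracle comparisons bound the error at 0.05 on small
designs but large-n behaviour rests on the approximation's usual asymptotics.
AUC under repeated random splits is an internal, not spatially blocked,
validation. Hierarchical partitioning refits \(2^k\) models and is meant for
the small predictor sets used here. The compact letter display is a greedy
cover and does not guarantee the minimum number of letters in pathological
significance graphs.
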