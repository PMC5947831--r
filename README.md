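# marshniche

Niche models for asking why restored saltmarshes differ from natural ones.

Saltmarsh restored by breaching sea defences (managed realignment, MR) and
older accidentally restored marshes (AR) often fail biological-equivalence
targets against natural reference marshes (NAT). Two mechanisms could be
responsible: the restored sites may not offer the right environmental
conditions — elevation in the tidal frame and sediment redox potential are
the dominant controls on saltmarsh plant distribution — or succession may
run differently where bare sediment is available across the whole tidal
frame. `marshniche` is for restoration ecologists who want to separate
those mechanisms from quadrat survey data.

## The model

For each species, presence/absence in a quadrat is modelled as

y_i ~ Bernoulli(Φ(f(x_i))),    f ~ GP(m, k),

a Gaussian-process classifier with probit link over the environmental
covariates (relative tidal height RTH, redox potential, region), fitted by
Laplace approximation and a flat (constant) latent prior mean. Around that
core the package provides:

- **Survey ingestion** — quadrat CSVs with site tidal datums;
  `RTH = (elevation − MHWN)/(MHWS − MHWN)`; Ag/AgCl → SHE redox
  standardization (+204 mV); validation with informative errors.
- **Synthetic surveys** (`simulate_survey()`) — the full study design with
  known ground truth (quadratic latent suitability surfaces), so every
  estimator is testable by parameter recovery.
- **Cross-validated discrimination** — repeated random 75/25 splits scored
  by an exact rank-based AUC.
- **Transfer prediction** — natural-marsh models applied to MR/AR quadrats,
  with 1,000-draw posterior uncertainty on the class-mean occurrence
  probability.
- **Age effects at the latent optimum** — models including marsh age,
  evaluated at each class's most favourable observed conditions (posterior
  mode + 95% credible interval).
- **Hierarchical partitioning** — independent contributions of RTH, redox,
  region and marsh age to model fit (exactly additive by construction).
- **Tidal-frame position** — observed versus model-expected mean RTH of
  occupied quadrats; Kruskal–Wallis and pairwise Mann–Whitney–Wilcoxon
  tests with Benjamini–Hochberg FDR control and compact letter displays.
- `run_pipeline()` to execute everything reproducibly from one seeded
  configuration, writing tidy CSV stage tables and a checksum manifest.

## A worked example

```r
library(marshniche)
library(dplyr)

sv  <- simulate_survey(sim_config(seed = 1))   # synthetic 21-site survey
nat <- filter(sv$survey, age_class == "NAT")

fit <- gp_fit(nat, "Pucc")                     # Puccinellia maritima
fit
#> Gaussian-process niche model (probit link, Laplace approximation)
#>   species: Pucc   n = 504   prevalence = 0.423
#>   covariates: rth, redox, region
#>   log marginal likelihood: -211.099   converged: TRUE (6 iter)

cross_validate(nat, "Pucc", n_runs = 100, seed = 1)$mean_auc
#> [1] 0.909

predict_transfer(fit, filter(sv$survey, age_class == "MR"),
                 n_draws = 200, seed = 1)
#>   species age_class n_quadrats median ci_lo ci_hi
#> 1 Pucc    MR               288  0.385 0.351 0.427

age_fit <- gp_fit(sv$survey, "Pucc", c("rth", "redox", "region", "age_class"))
age_effect_at_optimum(age_fit, sv$survey, n_draws = 200, seed = 1) |>
  select(species, age_class, mode, ci_lo, ci_hi)
#>   species age_class  mode ci_lo ci_hi
#> 1 Pucc    MR        0.737 0.597 0.918
#> 2 Pucc    AR        0.981 0.914 0.997
#> 3 Pucc    NAT       0.973 0.921 0.996
```

Reading: the model discriminates Puccinellia presences well out of sample
(mean AUC 0.909 at prevalence 0.42). The conditions available on the
simulated MR platforms would support it in ~39% of quadrats (transfer
median 0.385), yet at its most favourable conditions its occurrence
probability is still markedly lower on MRs (mode 0.74) than on natural
marshes (0.97) — an age effect beyond the environment, exactly the
generator's built-in MR suppression. `autoplot()` methods draw the niche
surfaces and the observed-versus-expected tidal-position figure.

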