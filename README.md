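# bartsdm

Probit Bayesian additive regression trees (BART) for species distribution
modelling, with a simulation harness that measures — rather than assumes —
predictive skill.

## The problem

Species distribution models (SDMs) relate occurrence records to
environmental covariates to predict presence probability across space and
time. Validating them on real data is circular: the true distribution is
unknown, absences are usually fabricated (pseudo-absences), and future
conditions have no observations at all. `bartsdm` addresses this with a
*virtual species*: a gridded world where the true probability of presence
is known at every cell and year, so any model's predictions can be scored
exactly — including under temporal extrapolation and contaminated
pseudo-absence labels.

The package provides, as first-class tested code:

* a **virtual-species simulator** — Matérn Gaussian field with AR(1)
  dynamics, deterministic bathymetry/temperature covariates, and Bernoulli
  occurrences via `logit π(s,t) = β₀ + f₁(t) + f₂(X₁(s)) + βX₂(s,t) + U(s,t)`,
  with "cosmopolitan" (diffuse) and "persistent" (concentrated) archetypes;
* a **from-scratch probit BART classifier** —
  `Φ⁻¹(πᵢ) = Σⱼ g(xᵢ; Tⱼ, Mⱼ)`, m = 200 trees, split prior
  `α(1+d)^−β` (α = 0.95, β = 2), leaf prior SD `3/(k√m)`, fixed N(0,1)
  probit error; Metropolis-within-Gibbs sampler in C++, with
  partial-dependence curves and permutation importance;
* **MaxEnt-style and GAM baselines** (penalized feature-expansion logistic
  via glmnet; binomial mgcv smooths) fitted to identical tables;
* an **evaluation harness** — Youden-cutoff confusion metrics, k-fold
  cross-validation, and replicate experiments over both absence regimes;
* a **habitat-projection pipeline** — historical-moment standardization,
  native-range vs suitable-habitat variants, yearly projections with
  posterior uncertainty, change maps, percentage-change summaries,
  richness stacking and functional-group ensembles.

## Worked example

Simulate the persistent archetype, draw 5 replicate samplings of 50
records (years 18–20 held out), fit BART and both baselines to each, and
score every grid cell-year against the simulated truth:

```r
library(bartsdm)

ex <- run_experiment("persistent", mode = "true",
                     models = c("bart", "maxent", "gam"),
                     R = 5, n = 50, holdout_years = c(18, 19, 20),
                     seed = 1)
ex$summary$overall
#>   model mean_accuracy
#>    bart     0.8962778
#>     gam     0.8892333
#>  maxent     0.8817556
```

Each row is the mean classification accuracy over all 900 grid cells × 20
years × 5 replicates, at each replicate's Youden cutoff: BART recovers the
persistent species' distribution at ~0.90 accuracy here, including three
purely extrapolated years. The per-year curves (`ex$summary$per_year`,
`plot_experiment(ex)`) show the replicate median with a 95% envelope.

A single fit looks like any classifier:

```r
w   <- simulate_scenario(scenario_config("persistent", seed = 7))
tab <- sample_true(w, n = 50, seed = 1, years = 1:17)
X   <- data.frame(bathymetry = 100 * log(tab$x * tab$y + 1),
                  temperature = sqrt(tab$y + 1) + 10 + 0.5 * (tab$year - 1),
                  year = tab$year)
fit <- bart_probit(X, tab$label)
fit
#> <bart_probit> 200 trees, 1000 retained draws, 50 obs, 3 covariates
#>   sigma_mu = 0.1061, MH acceptance 0.51
pred <- predict(fit, X)           # posterior mean + 2.5/97.5% quantiles
permutation_importance(fit)
#>      variable   raw importance
#> 1  bathymetry 0.272 0.81437126
#> 2 temperature 0.028 0.08383234
#> 3        year 0.034 0.10179641
```

Bathymetry dominates the importance ranking, as it should: the persistent
archetype is built around a strong positive depth association.
`partial_dependence(fit, "bathymetry")` returns the corresponding
functional-response curve with its posterior envelope.

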