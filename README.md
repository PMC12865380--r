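# longbart

Longitudinal soft Bayesian additive regression trees (BART) with a
grouped sparsity prior, Bayesian G-computation for an incremental
threshold intervention on a continuous exposure, and mortal-cohort
causal estimands.

## What problem this solves, and for whom

Prospective aging cohorts observe, at a handful of fixed waves and in
temporal order, survival `S`, response `R`, time-varying confounders
`X`, a continuous exposure `A` (e.g. systolic blood pressure, mm Hg),
and a continuous outcome `Y` (e.g. an episodic-memory composite,
0–76).  Death truncates the outcome; dropout hides it.  Analysts who
want the long-term effect of controlling the exposure — "shift blood
pressure downward whenever its natural value would exceed a threshold
τ" — face time-varying confounding, missingness, *and* the fact that
the intervention itself changes who is alive at the end of follow-up.

`longbart` estimates two contrasts between an incremental threshold
regime g\* and the natural course g0:

- **PCIE** (partly conditional intervention effect), a prognostic
  contrast among survivors under each regime separately:

  `PCIE = E[Y_T(g*) | S_T(g*)=1] − E[Y_T(g0) | S_T(g0)=1]`

- **SAIE** (survivors average intervention effect), the etiological
  contrast inside the always-survivor stratum, partially identified
  under *stochastic monotonicity* (sensitivity parameter λ ∈ [0,1])
  and a between-stratum mean difference Δ:

  `SAIE = PCIE + Δ {ψ* + λ(U − ψ*)} (1 − 1/U)`, `U = min{1, ψ*/ψ0}`,

  where `ψ^g` is the marginal probability of surviving to the final
  wave under regime g.

Estimation is Bayesian G-computation: every factor of the sequential
factorization (survival, response, each covariate, treatment, outcome,
per wave) is a **soft BART** model — smooth, probabilistically gated
regression trees — and pseudo-cohorts are simulated forward from the
posterior, with the intervention applied to the drawn natural value of
treatment.  Split-variable selection can use the **LDART** prior, a
longitudinal grouped Dirichlet prior that places increasing sparsity on
predictors measured further from the response (hyperprior schedule
`c_j = 1 − 0.5 (t−j)/(t−1)`), alongside plain DART and uniform
selection, in both soft and hard (indicator-split) trees.

## Worked example

Simulate a synthetic aging cohort (400 subjects, 4 waves; age cohorts
35–70, sBP as exposure, memory 0–76 as outcome, death/dementia as a
terminating event, monotone dropout), fit the sequential models with
the longitudinal prior, and contrast the natural course with a
τ = 130 mm Hg incremental threshold intervention whose shift prior is
Triangular(−44, −44, 0):

```r
library(longbart)

cohort <- generate_cohort(fixture_config(n = 400), seed = 1)
head(as.data.frame(cohort), 4)
#>   id t S R age    health      sbp   memory
#> 1  1 1 1 1  35  0.409402 109.2613 74.47737
#> 2  1 2 1 1  35  0.796540 133.0196 74.27690
#> 3  1 3 1 1  35 -0.190976 111.0967 57.12136
#> 4  1 4 1 1  35 -1.216590 116.5095 54.58429

fits <- fit_sequential(cohort, prior_mode = "ldart",
                       control = mcmc_control(n_warmup = 300,
                                              n_save = 200, thin = 2,
                                              seed = 1))

regime <- regime_spec("incremental_threshold", tau = 130,
                      shift_prior = triangular(-44, -44, 0))
g0 <- gcomp_estimates(fits, regime_spec("natural_course"),
                      nstar = 2000, draws = 1:100, seed = 2)
gs <- gcomp_estimates(fits, regime, nstar = 2000, draws = 1:100, seed = 2)

draws <- estimand_draws(g0, gs, sensitivity_spec(u_delta = 3.5), seed = 3)
summarize_draws(draws, c("survivor_mean_g0", "survivor_mean_gstar",
                         "psi_g0", "psi_gstar", "pcie", "saie"))
#>              estimand   mean  lower  upper
#> 1    survivor_mean_g0 51.578 50.801 52.582
#> 2 survivor_mean_gstar 52.041 51.012 53.305
#> 3              psi_g0  0.801  0.758  0.834
#> 4           psi_gstar  0.854  0.807  0.897
#> 5                pcie  0.464 -0.135  1.219
#> 6                saie  0.464 -0.135  1.219
```

Reading the output: under the natural course the expected final-wave
memory score among survivors is ≈ 51.6 with final-wave survival
ψ ≈ 0.80; under the intervention both rise (≈ 52.0 and ψ ≈ 0.85),
because lowering sBP both protects memory above the 130 mm Hg hinge and
lowers the terminating-event hazard in this generator.  The PCIE
posterior mean is ≈ 0.46 points with a 95% credible interval crossing
zero (the cohort is small).  The SAIE equals the PCIE here because the
intervention raises survival in every posterior draw (U = 1), making the
between-stratum adjustment vanish.  The generator truth for this
configuration (from `embedded_truth()`) is a PCIE of ≈ 0.4, inside the
interval.

The same machinery runs the simulation benchmark
(`scenario_config()`, `run_benchmark()`) comparing LDART with soft/hard
BART variants on bias, RMSE, and coverage, and command-line wrappers
live in `inst/scripts/` (`simulate-cohort.R`, `gcompute.R`,
`benchmark.R`).

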