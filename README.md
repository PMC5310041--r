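# mitedef

Bayesian analysis of host defence against parasitic water mites
(*Arrenurus* spp.) in the colour-polymorphic damselfly *Ischnura
elegans* — for evolutionary ecologists quantifying how discrete host
phenotypes (three heritable female morphs A, I, O, plus males M) differ
in **resistance**, **tolerance**, and the resulting **virulence** of
infection.

## The models

**Resistance** is a zero-altered (hurdle) Poisson mixed model for mite
counts. Individual *j* of phenotype *p* in population-year group *g* is
infected with probability

> logit(π) = ζ<sub>p</sub> + u<sub>g</sub> + e<sub>j</sub>,  u<sub>g</sub> ~ N(0, σ²<sub>g,logit</sub>), e<sub>j</sub> ~ N(0, 1)

and, if infected, carries a zero-truncated Poisson count with rate

> log(λ) = η<sub>p</sub> + v<sub>g</sub> + f<sub>j</sub>,  v<sub>g</sub> ~ N(0, σ²<sub>g,log</sub>), f<sub>j</sub> ~ N(0, σ²<sub>e,log</sub>).

Prevalence is reported as logit⁻¹(ζ<sub>p</sub>) and infection intensity
as the zero-truncated mean λ/(1 − e<sup>−λ</sup>) — the expected mite
count among carriers.

**Tolerance** is a random-slope Poisson mixed model for the 72-h egg
counts of mated A- and I-females:

> eggs ~ Poisson(exp(α<sub>m</sub> + (β<sub>m</sub> + u<sub>1g</sub>)·mites + u<sub>0g</sub> + ε)),  (u<sub>0g</sub>, u<sub>1g</sub>) ~ N₂(0, Σ<sub>u</sub>), ε ~ N(0, σ²<sub>ε</sub>)

so fecundity declines exponentially with mite load at a morph-specific
per-mite rate 1 − e<sup>β<sub>m</sub></sup>; a flatter slope means a
more tolerant morph.

**Virulence** combines both defence components per morph by posterior
resampling of the two independent fits:

> V<sub>m</sub> = 1 − b<sub>m</sub><sup>I<sub>m</sub></sup>,  b<sub>m</sub> = e<sup>β<sub>m</sub></sup>,

with I<sub>m</sub> the morph's infection intensity.

Both models are fitted by seeded, byte-reproducible MCMC (JAGS via
rjags, hierarchically centred), and all results come back as tibbles
with `tidy()`, `glance()` and `autoplot()` methods. A calibrated
synthetic-survey generator (`paper_mimic_config()`) reproduces the
statistical structure of the original decade-long field study — ~84%
uninfected individuals, strongly unequal phenotype frequencies,
over-dispersed counts, 40 population-year groups — so every inference
stage can be validated by parameter recovery without the (undeposited)
field data.

## Worked example

```r
library(mitedef)

cfg  <- paper_mimic_config()
fec  <- simulate_fecundity_survey(cfg)   # 4000 mated A/I females, 40 groups
fit  <- fit_tolerance(fec, schedule = mcmc_schedule(), seed = 1)

percent_decrease_per_mite(fit)
#> # A tibble: 2 x 4
#>   morph  mean conf.low conf.high
#>   <chr> <dbl>    <dbl>     <dbl>
#> 1 A      3.55     1.52      5.56
#> 2 I      9.27     6.98     11.4

intercept_contrast(fit)
#> # A tibble: 2 x 6
#>   term        mean conf.low conf.high pmcmc convention
#>   <chr>      <dbl>    <dbl>     <dbl> <dbl> <chr>
#> 1 difference 83.7     74.9      91.9  0.001 one_sided
#> 2 ratio       1.35     1.31      1.38 0.001 one_sided
```

The generating survey was simulated at per-mite fecundity decreases of
3.7% (morph A) and 8.3% (morph I) and a zero-parasite fecundity gap of
80 eggs (ratio 1.33); the fitted posteriors recover all four within
posterior uncertainty. The pMCMC of 0.001 is the chain's resolution
floor (1/1000 kept draws): every draw puts the I-intercept above the
A-intercept.

```r
res  <- simulate_resistance_survey(cfg)  # 20000 individuals, ~84% uninfected
rfit <- fit_resistance(res, schedule = mcmc_schedule(), seed = 2)

variance_partition(rfit, "logit")
#> # A tibble: 1 x 4
#>   process  mean conf.low conf.high
#>   <chr>   <dbl>    <dbl>     <dbl>
#> 1 logit   0.639    0.533     0.739

vir <- compute_virulence(fit, rfit, n_resample = 2000, seed = 3)
tidy(vir)
#> # A tibble: 2 x 4
#>   morph   mean conf.low conf.high
#>   <chr>  <dbl>    <dbl>     <dbl>
#> 1 A     0.0881   0.0381     0.138
#> 2 I     0.186    0.138      0.234
```

The population-by-year random effect accounts for about two-thirds of
the latent logit-scale variance in prevalence (generating share 65.6%),
and the virulence posteriors show the proportional fecundity loss each
morph would suffer at its own typical parasite burden.
`autoplot(fit)` draws the two fecundity reaction norms with credible
bands; `autoplot(rfit)` and `autoplot(vir)` plot prevalence/intensity
estimates and the virulence densities.

## Package tour

| Area | Functions |
| --- | --- |
| Survey data | `read_survey_csv()`, `write_survey_csv()`, `validate_survey()`, `summarize_survey()` |
| Simulation | `generator_config()`, `paper_mimic_config()`, `simulate_resistance_survey()`, `simulate_fecundity_survey()`, `rztpois()` |
| Resistance | `fit_resistance()`, `prevalence_estimates()`, `intensity_estimates()`, `zap_loglik()`, `ztpois_mean()` |
| Tolerance | `fit_tolerance()`, `percent_decrease_per_mite()`, `intercept_contrast()`, `predict_fecundity()`, `variance_partition()` |
| Posterior | `compute_virulence()`, `virulence_compare()`, `pmcmc_compare()`, `summarize_draws()`, `gelman_rubin()`, `autocorrelation()`, `effective_sample_size()` |
| Pipeline | `run_pipeline()`, `mcmc_schedule()`, `paper_mcmc_schedule()` |

See `vignettes/mite-defence-models.Rmd` for the full model description,
prior choices, generator calibration and limitations.
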