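# upwellsurv

Bayesian capture–mark–recapture survival analysis of intertidal mollusks
under contrasting upwelling regimes, with the environmental
characterization that frames it.

## What this package is for

Ecologists following tagged intertidal invertebrates (here *Chiton
granosus* and *Scurria zebrina* at Talcaruca, a semi-permanent upwelling
site, and Quintay, a seasonal one) need monthly apparent-survival
estimates from encounter histories in which **many months were never
searched**. `upwellsurv` provides:

* a data model for capture records, a monthly occasion calendar with
  per-(site, species) search masks, encounter-history construction, and
  m-array reduction;
* a marginalized Cormack–Jolly–Seber (CJS) likelihood with detection
  fixed at 0 in unsearched months, for five survival structures —
  $\phi(\cdot)$, $\phi(Po)$, $\phi(t)$, $\phi(L)$, $\phi(F)$ — always with
  time-varying detection $p(t)$;
* adaptive random-walk Metropolis posterior sampling (3 × 10,000
  iterations, burn-in 1,000 by default) with split-chain Gelman–Rubin
  diagnostics and effective sample sizes;
* derived quantities: annual survival $\phi^{12}$, fold differences,
  the Bayesian probability that one population out-survives another, and
  covariate-slope summaries with include-zero flags;
* a CO2SYS-style carbonate-system solver from pH and total alkalinity
  (Lueker/Weiss/Dickson/Millero/Mucci constants, total scale),
  Brown–Forsythe and Fligner–Killeen variance tests, and austral-season
  summaries of low-pH days;
* a synthetic-data generator reproducing the study design (26 monthly
  occasions, real search masks, recruitment following the observed
  capture pattern) so the entire pipeline runs with no field data.

The CJS model conditions on first capture: with $\chi_T = 1$ and
$\chi_t = (1-\phi_t) + \phi_t (1-p_{t+1})\,\chi_{t+1}$, a history
contributes
$\prod_{t=f}^{\ell-1} \phi_t\, p_{t+1}^{y_{t+1}} (1-p_{t+1})^{1-y_{t+1}}
\cdot \chi_\ell$. See `vignettes/upwellsurv-methods.Rmd` for the full
account of the model, priors, sampler, and design decisions.

## A worked example

```r
library(upwellsurv)

# the study design: 26 monthly occasions, Nov 2019 - Dec 2021
cal <- study_calendar()
capture_summary()$grand_total
#> [1] 783

# simulate a Talcaruca-like population and fit phi(.) p(t)
truth <- truth_config("talcaruca", "chiton_granosus",
                      n_individuals = 300, phi = 0.9, p = 0.4, seed = 1)
h   <- simulate_histories(truth)
fit <- sample_posterior(h, cjs_model_spec("phi_dot"),
                        config = mcmc_config(seed = 1))
max_split_rhat(fit)
#>      phi
#> 1.001085
mean(draws_of(fit, "phi"))
#> [1] 0.8920225
```

The maximum split R-hat across the 10 free parameters (monthly survival
plus one detection probability per searched occasion after the first) is
far below the 1.1 convergence criterion, and the posterior mean of monthly
survival recovers the simulated truth 0.9 to within 0.008. Annual-scale
comparisons follow from the monthly draws:

```r
mean(annual_survival(draws_of(fit, "phi")))
#> [1] 0.2559308
fold_difference(0.36, 0.15)   # annual contrast between two populations
#> [1] 2.4
```

Carbonate chemistry for one water sample:

```r
solve_from_ph_ta(water_sample(pH = 8.04, TA_umol_kg = 2273.8,
                              temperature_C = 13.2, salinity_psu = 33.53))
#> Carbonate system at pH(T) 8.040, TA 2273.8 umol/kg, 13.2 C, S 33.53:
#>   DIC 2081.2  HCO3 1923.7  CO3 141.3  CO2aq 16.1 umol/kg
#>   pCO2 404.5 uatm  Omega_ca 3.40  Omega_ar 2.17
```

An end-to-end run (simulate both sites, fit, derive annual survival,
compare populations, write CSVs and a JSON manifest) is one call to
`run_pipeline(pipeline_config(...))`; a thin command-line wrapper lives at
`inst/scripts/upwellsurv-pipeline.R`.

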