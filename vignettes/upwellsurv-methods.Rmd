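---
title: "Methods: Bayesian CJS survival under contrasting upwelling regimes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Bayesian CJS survival under contrasting upwelling regimes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Two intertidal mollusks, *Chiton granosus* and *Scurria zebrina*, were
followed by monthly capture–mark–recapture (CMR) at two Chilean sites with
contrasting upwelling regimes: Talcaruca, under semi-permanent upwelling,
and Quintay, under seasonal upwelling. The scientific question is whether
apparent survival differs between the regimes, and whether body length or
standard metabolic rate predicts survival. `upwellsurv` implements the full
chain from raw capture records to posterior comparisons, plus the
environmental characterization used to describe the two regimes (carbonate
chemistry from pH and total alkalinity, variance-heterogeneity tests, and
austral-season summaries of corrosive low-pH days).

Monthly searches ran from November 2019 to December 2021 (26 occasions),
but not every month was searched for every site and species. That
irregular effort is first-class in the data model: an `occasion_calendar`
carries a per-(site, species) `searched` mask, and every month without a
search has its detection probability fixed at exactly 0 in the model.

## The Cormack–Jolly–Seber model

Let $\phi_t$ be apparent monthly survival over the interval $(t, t+1)$
(confounding death with permanent emigration, which is expected to be
negligible for these sedentary grazers) and $p_t$ the probability of
detecting a live, present individual at occasion $t$. Conditioning on each
individual's first capture $f_i$, the contribution of a history with last
detection $\ell_i$ is

$$
L_i \;=\; \prod_{t=f_i}^{\ell_i-1}\phi_t\,
p_{t+1}^{y_{i,t+1}}(1-p_{t+1})^{1-y_{i,t+1}}
\;\times\; \chi_{\ell_i},
$$

where $\chi_t$, the probability of never being seen after $t$, satisfies
the backward recursion $\chi_T = 1$,
$\chi_t = (1-\phi_t) + \phi_t(1-p_{t+1})\chi_{t+1}$.

We marginalize the latent alive/dead state through this recursion rather
than sampling explicit alive indicators. The marginal likelihood is
mathematically identical to the state-space augmentation commonly used in
JAGS, but it is deterministic given the parameters, directly testable
against brute-force enumeration over death times (the test suite does this
for all histories with up to eight occasions after release), and much
cheaper at the scale of this study.

Five survival structures are supported, in classical CMR notation:

| structure | label | survival model |
|---|---|---|
| `phi_dot` | $\phi(\cdot)$ | constant |
| `phi_site` | $\phi(Po)$ | one constant per locality, sites fit jointly |
| `phi_time` | $\phi(t)$ | one parameter per monthly interval |
| `phi_length` | $\phi(L)$ | $\mathrm{logit}(\phi_i)=\alpha+\beta \tilde L_i$ |
| `phi_perf` | $\phi(F)$ | $\mathrm{logit}(\phi_i)=\alpha+\beta \tilde F_i$ |

Detection is always $p(t)$ — fully time-varying — because the irregular
search calendar makes any pooled detection parameter meaningless; months
with no search have $p$ pinned to 0 and **no parameter is created for
them**. Pinning $p=0$ across a gap is exactly equivalent to collapsing the
gap into a single interval whose survival is the product of the monthly
survivals (a unit test verifies the algebraic identity), which is also why
individual monthly survivals inside a gap are not separately identifiable
under `phi_time`: `survival_series()` flags those intervals, along with
the terminal interval where $\phi_{T-1}$ and $p_T$ only enter as a
product.

Several design points were genuinely open and were resolved as follows:

* The covariate models' intercept is not named in the classical notation;
  the package calls it $\alpha$.
* Under `phi_site` the two localities share nothing but the time grid:
  survival is site-indexed and detection is site-specific, because the two
  search calendars differ.
* Covariates are measured at first capture and drift over time, so
  covariate fits are meant to run on a restricted window
  (`restrict_window()`, default width 6 months) with covariates treated as
  time-constant; $\beta$ is reported per covariate standard deviation
  (standardization over the individuals entering the fit). Individuals
  with a missing covariate are excluded from covariate fits, with a
  message; no imputation is attempted.
* "Physiological performance" is operationalized as standard metabolic
  rate (mgO$_2$ h$^{-1}$ g$^{-1}$).
* Individuals first captured at the final occasion contribute a
  likelihood factor of 1 but stay in the data model.
* Tag loss (estimated below 5% in the field) is ignored; re-tagged
  individuals are assumed recorded under one identity.

For the time-structured models the sampler actually evaluates the m-array
(product-multinomial) form of the likelihood: the m-array is the
sufficient statistic, and with the multinomial coefficient omitted its
log-likelihood equals the individual-level sum *exactly*, not
asymptotically — the suite checks agreement to $10^{-10}$ on 500 simulated
histories. Covariate models keep the individual-level (vectorized)
evaluation, since per-individual survival breaks the m-array reduction.

## Priors, sampling, and diagnostics

"Uninformative" priors are concretized in the standard way for this model
class: Uniform(0, 1) on every probability parameter and Normal(0, 10) on
$\alpha$ and $\beta$. Sampling is component-wise adaptive random-walk
Metropolis on unconstrained scales (logit for probabilities, identity for
coefficients). A Uniform(0,1) prior sampled through the logit transform
contributes the standard-logistic log-density as its Jacobian.

Proposal scales adapt in batches of 50 iterations toward an acceptance
rate of 0.44 with the diminishing-adaptation step
$\delta_b = \min(0.05, b^{-1/2})$, and freeze at the end of burn-in, so
all retained draws come from a fixed Markov kernel with the correct
stationary distribution. Defaults mirror the study: 3 chains of 10,000
iterations, burn-in 1,000, no thinning (thinning only discards
information; none was specified for the original analysis). Chains start
from independent prior draws — over-dispersed relative to the posterior —
with per-chain sub-seeds drawn deterministically from the configured seed,
so runs are bit-reproducible. Initialization re-draws up to 100 times if
the starting log-posterior is not finite.

Convergence uses the split-chain Gelman–Rubin statistic (each chain halved;
$\hat R = \sqrt{((n-1)/n\,W + B/n)/W}$, defined as 1 when $W = 0$) with
the study's criterion $\hat R < 1.1$, plus effective sample sizes from the
standard autocorrelation-based estimator. Posterior summaries use type-7
(linear-interpolation) quantiles throughout.

The suite validates the sampler three ways: recovery of the Uniform prior
in a no-data limit; an exactly integrable two-parameter posterior (a
2-occasion design where the likelihood depends only on $q=\phi p$ and the
product of two uniforms has prior density $-\log q$, so posterior moments
follow from quadrature); and parameter recovery plus interval coverage on
synthetic data at the study's own scale.

## Derived quantities

* **Annual survival**: each monthly draw raised to the 12th power,
  regardless of calendar gaps — the model is parameterized monthly.
* **Probability of a difference**: posterior draws from the two
  independently fitted populations are paired by (chain, iteration) index
  and $P(A>B)$ is the fraction of strict exceedances (ties, a
  measure-zero event, count as "not greater"). Since the two posteriors
  are independent, any exhaustive pairing converges to the same value;
  index pairing is deterministic and cheap.
* **Fold difference**: ratio of (annual) survival means; consistency
  $\mathrm{fold}(a^{12}, b^{12}) = (a/b)^{12}$ is unit-tested.
* **Slope summaries**: mean, 95% credible interval, and a flag for
  intervals that include zero (the study's criterion for an inconclusive
  covariate effect).

## Carbonate chemistry

`solve_from_ph_ta()` solves the full carbonate system from pH and total
alkalinity at in-situ temperature and salinity, with the classic default
formulations: K1/K2 from Lueker et al. (2000), K0 from Weiss (1974), KB
from Dickson (1990), KW from Millero (1995), calcite/aragonite solubility
from Mucci (1983), borate from salinity after Uppström (1974); bisulfate
(Dickson 1990) and fluoride (Perez & Fraga 1987) enter the minor
alkalinity terms and pH-scale conversions. All constants are expressed on
the total hydrogen-ion scale; the formulations are nominally valid for
2–35 °C and 19–43 psu and are extrapolated with a warning outside that
envelope. Calcium is scaled conservatively from salinity
($0.01028 \cdot S/35$ mol/kg) and nutrients are assumed zero (they were
not measured).

The measurement protocol reports pH on the total scale, and the solver
treats input as total-scale by default; an `nbs` tag converts NBS
readings through the Takahashi activity-coefficient factor first, logging
the conversion. `ph_from_dic_ta()` inverts the alkalinity balance by
bracketed root-finding on pH ∈ (6, 9.5) and serves as the round-trip
oracle: the suite requires closure to $10^{-8}$ in pH and agreement
within 1% between two algebraically different solution routes for pCO$_2$
across the study's envelope (pH 7.5–8.3, TA 2100–2400 µmol/kg, 8–18 °C,
S 32–35). Constants are checked against the formulations' published
check values at 25 °C, S = 35. The printed site-mean table of the field
study is internally inconsistent (the lower-pH, lower-TA site shows
higher carbonate and lower pCO$_2$), as expected when means of per-sample
solutions are tabulated; the package therefore treats per-sample solution
as the supported workflow and does not target those printed means.

## Variance tests and seasons

"Levene's test" is implemented as the Brown–Forsythe (median-centered)
variant — the robust default in modern software — with the mean-centered
original behind `center = "mean"`; it is an ordinary one-way ANOVA on
absolute deviations, delegated to `lm`/`anova`. The Fligner–Killeen test
wraps `stats::fligner.test()`. Both are invariant to per-group location
shifts and group relabeling (tested; for the rank-based statistic the
invariance is exact in exact arithmetic and holds to ~10⁻⁴ under large
shifts in floating point). Austral seasons follow the southern-hemisphere
convention (spring Sep–Nov, summer Dec–Feb, autumn Mar–May, winter
Jun–Aug); `low_ph_season_summary()` counts days whose daily minimum pH
falls below the threshold (default 7.3) and reports per-season counts and
percentages to one decimal.

## What the synthetic generator does and does not emulate

`simulate_histories()` draws each individual's entry occasion from
recruitment weights (defaulting to the observed monthly capture counts of
the chosen population, so entries mimic the real pattern), propagates a
latent alive state with the configured monthly survival, and emits
detections with $p_t$ only on searched occasions. Covariate truths draw a
normal covariate once at entry and map it through the logit link. The
generator's defaults are the study's conditions: the 26-month calendar
with the real search masks, monthly survival in the 0.85–0.95 range, and
moderate detection (0.4–0.5).

It deliberately does **not** model: individual heterogeneity in detection,
density dependence, tag loss, transience, or within-month tide/microhabitat
structure. Passing recovery tests on this generator therefore shows the
estimator is correct under the model's own assumptions — it cannot show
robustness to the ways real data violate them.

`simulate_environment()` produces daily SST (annual sinusoid + AR(1)
noise) and pH (baseline minus a seasonally modulated upwelling-event
process). The `semipermanent_site` profile has larger thermal variability
and rare low-pH days; the `seasonal_site` profile concentrates sub-7.3
days in austral spring. These are caricatures sufficient to exercise the
variance tests and the seasonal summary, not oceanographic simulations.

## Problem sizes and numerical choices

The test suite runs the heavy experiments at the scale that makes them
statistically meaningful while staying desk-sized: single-fit convergence
and recovery checks use N = 300 individuals at the study's full MCMC
settings (3 × 10,000); the 20-replicate coverage experiment uses 2 chains
of 2,500 per replicate, which is ample for this unimodal, fast-mixing
posterior; the covariate-slope recovery uses N = 400 on a 6-occasion
window. Likelihood correctness is tested exactly (enumeration to
$10^{-12}$, m-array equivalence to $10^{-10}$), so the stochastic
tolerances apply only to genuinely stochastic quantities.

Degenerate inputs fail loudly and early: histories with detections in
unsearched months are rejected when built (this is the signature of a
calendar/effort mismatch); designs with no searched occasion after the
first are rejected as unidentifiable; infeasible water samples (carbonate
alkalinity non-positive after the borate/water correction) are errors,
not NaNs.

## Known limitations

* Apparent survival confounds mortality with permanent emigration; no
  multi-state or tag-loss machinery is provided.
* The component-wise random-walk sampler is adequate for the ≤ ~35
  parameters of these designs but would mix poorly for much larger
  time-varying models; no Hamiltonian sampler is included.
* No information-criterion model ranking is provided; structures are
  compared through their posteriors, as in the original analysis.
* The capture-summary medians are computed from the monthly count table;
  they are what the table implies, and no attempt is made to reproduce
  alternative summaries that cannot be derived from it.
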