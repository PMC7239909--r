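---
title: "Apparent survival with partially known sex: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Apparent survival with partially known sex: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

cjsmix estimates *apparent survival* — the probability of surviving **and**
remaining in a study area — from bird-ringing (mark-recapture) data in which
the sex of a majority of individuals may be unknown. This vignette explains
the model family, the priors, the numerical choices, and what the synthetic
data generator does and does not emulate.

## The state-space CJS model

Detections are aggregated onto an occasion grid (calendar years, or 4-month
seasons: winter December–March, breeding April–July, summer August–November).
For individual $i$ and occasion $t$, the observation $y_{it}$ indicates a
capture during occasion $t$, and a latent state $z_{it}$ indicates that the
bird is alive and present:

$$y_{it} \sim \mathrm{Bernoulli}(z_{it}\, p_{it}), \qquad
  z_{it} \sim \mathrm{Bernoulli}(z_{i,t-1}\, \Phi_{it}),$$

conditioning on the first capture ($z_{if_i} = 1$). $\Phi_{it}$ is apparent
survival over the interval from occasion $t-1$ to $t$; permanent emigration
and death are confounded, which is why the estimate is "apparent". The
interval indexed $t$ carries the weather covariates of the window in which
it starts: the survival interval from year $t$ to year $t+1$ uses the summer
(June–September) covariates of year $t$ and the winter covariates of
November $t$ – March $t+1$, the only assignment in which both fall
unambiguously inside one summer-to-summer interval.

### Marginalization

The latent states are never sampled. For a history with first capture $f$
and last detection $l$, the marginal likelihood is the product of survival
and detection terms up to $l$ times the probability of never being seen
afterwards,

$$\chi_t = (1 - \Phi_{t+1}) + \Phi_{t+1}(1 - p_{t+1})\,\chi_{t+1},
  \qquad \chi_T = 1,$$

evaluated in log space. `cjs_loglik()` implements this recursion; the test
suite verifies it against brute-force enumeration over every latent
alive/left path for all histories up to five occasions, and checks that the
probabilities of all possible histories sum to one.

### Unknown sex as a finite mixture

Survival and recapture are sex-specific, but sex identification in the
field depends on age, method and year, so unknown-sex individuals are *not*
missing at random and cannot simply be dropped (that would overestimate
survival, since long-lived birds have more chances to be sexed). Each
unknown-sex individual $i$ therefore contributes a two-component mixture

$$L_i = q_i\, L_i^{\mathrm{male}} + (1 - q_i)\, L_i^{\mathrm{female}},
  \qquad q_i \sim \mathrm{Beta}(1, 1),$$

with one free weight per individual, kept explicit rather than pooled. The
$q_i$ posteriors are expected to stay near-uniform (the data rarely say
much about an individual's sex); the inference tests assert this as a
diagnostic.

As a complement, every model can be refitted to a *reduced* dataset
containing only individuals of known sex, with all captures before the
first sex-ascertained capture discarded and individuals not adult at that
capture excluded (`build_reduced_dataset()`). Comparing full and reduced
fits brackets the possible selection effects of either choice.

## The model family

All annual variants share the recapture model $p_{it} = b0_{t,\mathrm{sex}[i]}$
(one free probability per year and sex, uniform prior; age is not a
recapture predictor because every bird is at least one year old when it can
first be recaptured). Apparent survival varies:

| variant | survival structure |
|---|---|
| `m1` | constant per class (first-year, adult M, adult F), probability scale |
| `m2a` | class intercepts + sex-specific year random effects $\gamma_{s,t} \sim N(0, \sigma_s)$ |
| `m2b` | as `m2a`, with separate adult intercepts for the first vs later intervals after first capture |
| `m3a` | class intercepts + linear effects of standardized summer and winter temperature |
| `m3b` | as `m3a` with intercepts *and* slopes split by first/later interval |
| `m23b` | transience intercepts, slopes shared between first/later, year random effects |
| `m4` | as `m3a` plus summer and winter precipitation |
| `seasonal` | 4-month survival per class × season, probability scale |

The first/later split addresses *transients* — birds that permanently leave
after the occasion of first capture, depressing apparent survival in the
first interval. The indicator applies only to birds first captured as
adults; a bird ringed as nestling or first-year has a single first-year
survival class and becomes adult after one year (on the seasonal grid, at
the start of the first breeding window after first capture).

Priors follow a single scheme: Normal(0, 1.5) for logit-scale survival
intercepts, Normal(0, 3) for slopes, Uniform(0, 1) for probability-scale
parameters, and Uniform(0, 5) for random-effect SDs (the SD is not a
probability; the uniform upper bound of 5 is far above any plausible
among-year SD on the logit scale and acts as a weakly informative guard;
results are insensitive to halving it). The seasonal variant places a
Beta(3.6, 1.2) prior directly on each 4-month survival: its median 0.79
(95% mass 0.33–0.99) corresponds to an annual survival of
$0.79^3 \approx 0.49$, so estimates that deviate from the prior median
reflect information in the data rather than prior shrinkage toward 0.5 in
data-poor seasons. The seasonal recapture model is
$\mathrm{logit}(p_{it}) = b0_{\mathrm{season}[t],\mathrm{sex}[i]} + \gamma_{\mathrm{year}[t]}$
with Normal(0, 1.5) intercepts.

The among-year SD $\sigma_s$ is sex-specific (one SD per sex), matching the
reporting of separate male and female among-year variances.

### Covariate standardization

Whether weather covariates are centred and scaled is a genuine design
choice: slope magnitudes depend on it. The default standardizes each
covariate across study years (slopes are per-SD effects, and "survival at
average weather" is the inverse-logit of the intercept); a flag on
`cjs_model_spec()` keeps raw °C/mm instead. The standardization constants
are stored so the transformation is invertible.

## Fitting and diagnostics

`fit_cjs()` samples the marginalized posterior with JAGS. The marginal
likelihood of each history is computed inside the model (the same
detection-term/χ expression as above) and attached through a
zero-inflation device, so the sampler only ever sees continuous
parameters: no latent alive state and no discrete sex indicator is sampled —
the sex mixture enters as an analytic weighted sum. Because conditional (slice/Gibbs) updates have no divergent-transition
failure mode, the recorded divergence count of a fit is identically zero;
the other three gate criteria do the work. Year random effects use the
centred parameterization, which mixes well under conditional updates (the
non-centred form is an HMC-specific remedy).

Defaults mirror the fitting protocol the model family was designed around:
4 chains of 2000 iterations, second half retained, plus 1000 adaptation
iterations. `check_convergence()` enforces, for every monitored parameter:

* no divergent transitions,
* effective sample size above 1000,
* Monte Carlo standard error below 10% of the posterior SD
  (MCSE/SD $= 1/\sqrt{\mathrm{ESS}}$),
* split R-hat below 1.01.

Year-effect chains under conditional updates are more autocorrelated than
under HMC, so for the random-effect and slope variants the package's
recovery experiments lengthen and thin the chains (e.g. 37 000 iterations
thinned by 36, still about 1000 retained draws per chain and a few minutes
of runtime) to clear the ESS gate honestly rather than loosening it.

Initialization is random in a small ball: logit intercepts in [−1, 1],
slopes in [−0.5, 0.5], probabilities in [0.2, 0.6] (coupled with [0.3, 0.7]
mixture weights), avoiding plateaus at survival 0 or 1. All chain RNGs
derive deterministically from one integer seed.

Numerical safety: all recursions run in log space; `log1p(-p)` is used for
non-detection terms; a recapture probability of exactly 1 with a
zero-detection interval correctly yields probability zero (−∞ on the log
scale) rather than NaN.

## Posterior predictive checking

`ppc_check()` simulates replicate capture histories for each individual in
the data — conditioning on the observed first capture, so the number of
individuals is fixed and the statistics are comparable — using a distinct
posterior draw per replicate; unknown-sex individuals have their sex drawn
from that draw's $q_i$. Two statistics are compared between replicates and
observation: the number of individuals captured exactly once (sensitive to
unmodelled transience) and the number captured at least three times
(sensitive to survival bias and recapture heterogeneity), split by
sex-known/sex-unknown for full-dataset fits. The reported tail probability
is one-sided with ties counted half (0.5 in the degenerate all-ties case);
a two-sided version ($2\min(P_\le, P_\ge)$, capped at 1) is also returned,
and `adequate` flags an observed value inside the central 95% predictive
interval. On synthetic data the package's acceptance suite shows both that
the intervals are calibrated (a fresh replicate falls inside the central
95% band about 95% of the time) and that checking transient-rich data
under a no-transience model inflates the single-capture discrepancy
relative to the transience-aware model.

## The synthetic-data generator

`sim_config()` / `simulate_population()` emulate the structure of a
15-year, ~671-individual alpine ringing study; `snowfinch_synthetic_study()`
freezes one such dataset (also shipped as plain CSV under `inst/extdata/`,
regenerable bit-identically from its seed). The generator's default
conditions are the study-like ones: a strongly summer-biased capture
calendar (monthly first-capture weights), entry age classes of roughly
15% nestlings / 45% other first-years / 40% adults, resident adult
survival near 0.52 (M) and 0.64 (F) with residency 0.54/0.59 (transients
permanently emigrate after the first interval, so first-interval apparent
survival is residency × survival — an exact mixture the CJS likelihood
represents as a multiplicative first-interval effect), first-year survival
0.11, sex-specific among-year logit SDs 0.43 (M) and 1.41 (F), a female
summer-temperature slope of −0.85 per SD against 0.05 for males, and
per-year recapture probabilities drawn from 0.1–0.8. Sex identification is
deliberately *not* missing at random: the per-capture identification
probability rises with age (0.02 nestling, 0.20 first-year, 0.75 adult)
and drifts across years (×0.6 to ×1.3), landing the unknown-sex share near
60%.

Daily two-station weather is generated as a shared seasonal sinusoid plus
a shared AR(1) anomaly plus station noise, making daily minimum and
maximum temperature correlate near 0.9, with zero-inflated precipitation
suppressed on warm days so that warm summers tend to be dry (a negative
summer temperature–precipitation correlation across years).

What the generator does **not** emulate: capture-effort variation within
occasions (effort is not modelled, as it could not be standardised in the
field), individual heterogeneity in recapture probability beyond
year/season/sex, trap response, gradual (rather than immediate) dispersal
of transients, spatial structure, and density dependence. Tests passing on
synthetic data therefore demonstrate the correctness and calibration of
the machinery under the stated model, not robustness to these real-data
pathologies — the full/reduced dataset comparison and the predictive
checks are the tools the package offers for probing them on real data.

## Problem sizes used in the automated experiments

The recovery and calibration experiments are sized for a desk machine:
constant-survival recovery at 300 individuals × 15 years (4 × 2000
iterations), transience recovery at 500 individuals (85% adults, recapture
0.5 — chosen by a power analysis: at 300 individuals and recapture 0.4 the
realized number of established-adult re-releases is so small that some
datasets carry no transience signal at all), and slope recovery at 600
individuals. The transience hypothesis is evaluated pooled across sexes,
since the simulated gap is sex-invariant. Posterior-predictive calibration
scores 20 fresh replicates against the interval of 400 reference
replicates from the same fit.

## Conventions and limitations

* Posterior summaries are medians with equal-tailed 2.5%/97.5% quantiles
  ("95% compatibility interval"), type-7 quantile interpolation; at low
  draw counts the interpolation convention affects the second decimal.
* Derived quantities (products of seasonal survivals, cumulative
  proportions, survival-vs-covariate curves) are always computed per draw
  and then summarised — never transforms of summaries.
* Occasions and intervals are 1-based internally and in reports; interval
  `t` is the transition from occasion `t − 1` to `t`.
* Individuals first captured at the final occasion are retained in data
  summaries and predictive replicates but contribute nothing to the
  likelihood.
* Whether total recapture counts refer to capture events or
  individual-occasion detections is ambiguous in general; the dataset
  summary reports occasion-level recaptures (`n_recapture_occasions`),
  and the raw records retain every capture event.
* The package fits no multi-state or spatial extensions and no
  individual covariates, and performs no information-criterion model
  selection: models are compared by predictive checks only.
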