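---
title: "Modelling incidence, prevalence and misclassification in GP registry data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling incidence, prevalence and misclassification in GP registry data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dismodgp)
```

## The problem

General-practice (GP) registration networks are a primary source of
morbidity statistics for chronic disease: with universal registration and
the GP as gatekeeper, the registered population approximates the general
population outside long-term care. Yet networks disagree substantially on
incidence and prevalence of the same diseases in the same country. A key
mechanism is how a registry separates *new* (incident) from *existing*
(prevalent) cases. Disease-episode registries keep a chronic diagnosis open
indefinitely, so point prevalence is read directly off the record. Care-episode
registries only see a disease when the patient contacts the GP for it; a
long-diagnosed patient who happens to contact only in the index year looks
incident, and one who does not contact at all inside the observation window
is invisible. `dismodgp` implements a pipeline that (i) derives observed
rates from aggregated registry counts, (ii) audits their mutual consistency
with an illness-death projection, (iii) fits a joint
incidence–prevalence–mortality ("DisMod") model with an explicit
misclassification fraction, and (iv) pools networks by random-effects
meta-analysis — plus a patient-level synthetic registry generator so every
stage is testable without confidential data.

## Observed rates

Within each network × disease × sex × age-band stratum the registry supplies
person-years $N$, the registered population on 1 January $n$, point-prevalent
cases $P$, incident cases $I$, and deaths $D$ and institutionalizations $U$
among the diseased. Incidence density is new cases per person-year *free of
disease*:

$$\hat i = \frac{I}{N - P - \tfrac12 I + \tfrac12 (D + U)}.$$

The half-period terms are standard person-time bookkeeping: an incident case
spends on average half the year disease-free before onset, and a diseased
person who dies or is institutionalized mid-year hands back half a year that
the subtraction of $P$ removed in full. Point prevalence is $P / n$ for
disease-episode registries and $(\text{seen in window} - I)/n$ for
care-episode registries, where "seen in window" counts patients with any
disease-coded contact in the index year or the lookback years before it.
When $n$ is not supplied it is imputed as $\mathrm{round}(N)$, i.e. a stable
population. Rates are exchanged per person-year and presented per 1,000
(half-up rounding: one decimal for incidence, whole numbers for prevalence).

Direct standardization weights stratum rates by a fixed standard population;
the package ships the 2013 European Standard Population in 5-year bands,
split equally by sex, as its default. Five-year bands are the canonical
exchange granularity — registry aggregation rarely offers finer — while all
internal computation runs on a single-year age grid 0–99 with band rates
applied uniformly within a band.

## The illness-death projection

For chronic disease without remission, prevalence must be explainable by
inflow (incidence) and outflow (mortality and institutionalization of the
diseased). `project_cohort()` pushes a hypothetical cohort of newborns
through the annual forward recursion

$$S(a+1) = S(a)\,\bigl(1 - i(a) - m(a)\bigr), \qquad
  C(a+1) = C(a)\,\bigl(1 - m(a) - f(a) - r(a)\bigr) + S(a)\,i(a),$$

with $S$ the disease-free and $C$ the diseased occupancy, $i$ incidence, $m$
general mortality, $f$ excess mortality of the diseased and $r$
institutionalization, all as annual probabilities taken from the
start-of-year state. Projected prevalence is $p(a) = C/(S+C)$;
`consistency_report()` tabulates projected minus observed prevalence per
stratum. Two modelling assumptions are inherited wherever the projection is
used: rates are stationary over time (no cohort trends), and people entering
or leaving the registered population resemble those who stay.

A numerical subtlety worth stating precisely: in this discrete scheme,
mortality that acts *equally* on both states does **not** cancel from
prevalence exactly, because the incident inflow $S\,i$ is not thinned by $m$
while the alive mass is. With $f = r = 0$ and constant $m$, the trajectory
equals the zero-mortality one with incidence inflated to $i/(1-m)$ — an
exact identity the test suite pins at $10^{-12}$. Exact cancellation holds
only in the continuous-time limit; the difference is $O(i\,m\,a)$. The
forward recursion above is the package's normative definition, chosen for
its transparency and exact mass conservation
($S + C + \text{dead} + \text{institutionalized} = 1$ at every age).

## The joint model with misclassification

The DisMod fit treats, per sex and age band,

* the incident count as Poisson with mean
  $E[I] = \mathrm{PY}_\text{free}\, i + \kappa\, n\, p_\text{mod}$,
* the prevalent count as binomial with $n$ trials and success probability
  $(1-\kappa)\, p_\text{mod}$,

where $p_\text{mod}$ is the prevalence projected from the candidate
incidence schedule and the *fixed* outflow schedules, and
$\mathrm{PY}_\text{free} = N (1 - p_\text{mod})$. The single parameter
$\kappa \in [0, 1)$ is the fraction of truly prevalent cases recorded as
incident; the reverse misclassification is assumed rare and ignored. κ is
constant over age within sex, reflecting that registries report one
misclassification behaviour per disease and population, not an age profile.

Log-incidence is a polynomial in age (default cubic, configurable degree
1–4), centered and scaled as $x = (a-50)/50$ so coefficients are
well-conditioned; implied rates are clipped to $[10^{-10}, 0.5]$. Outflow
($m$, $f$, $r$) is a fixed input rather than estimated, because registry
death counts are typically under-registered — the package's life-table check
(`life_expectancy()`, period life table with half-year convention, capped at
age 99 with terminal death) makes that under-registration visible as
implausibly high life expectancies. Misestimated outflow propagates into the
projection: too little outflow means too much projected prevalence.

Maximization is by BFGS over the coefficients and $\mathrm{logit}\,\kappa$,
started from a Poisson regression of observed incident counts that ignores
misclassification, with κ starting at 0.05; tolerance $10^{-8}$ on the
log-likelihood, at most 500 iterations. The covariance is the inverse of a
central-difference Hessian (relative step $10^{-4}$). When κ̂ falls below
$10^{-4}$ it is pinned to zero, the remaining parameters are refit and the
boundary flag is set; no κ interval is reported there, since Wald intervals
are invalid on the boundary. One consequence users should expect: when the
*true* κ is zero, about half of noisy datasets still yield a small positive
κ̂ — that is a property of maximum likelihood at a parameter-space boundary,
not a defect of the data.

Confidence intervals for standardized rates are parametric-bootstrap
percentiles: 1,000 multivariate-normal parameter draws around the estimate
(on the internal scale, so κ draws respect $[0,1)$), each rebuilt into an
incidence schedule, projected, and directly standardized; the 2.5th/97.5th
percentiles bound the interval and the SD of the log rates feeds the
meta-analysis. Percentile rather than normal-theory intervals are used
because the draw-to-rate map is nonlinear. Counts are assumed independent
across strata and between the incidence and prevalence likelihood terms;
the same individuals in fact contribute to both, so intervals are, if
anything, slightly narrow — a documented limitation.

## Pooling

Network-specific standardized rates are pooled on the log scale by
DerSimonian–Laird random-effects meta-analysis (`dl_meta()`): moment
estimator for the between-network variance τ², normal-quantile 95% CI, no
small-sample adjustment — matching the long-standing default of the standard
meta-analytic tooling. Networks whose fit did not converge are excluded from
pooling, with a log message. A single network passes through unchanged.

## What the synthetic generator emulates — and what it does not

`simulate_truth()` realizes the same illness-death process the projection
assumes, patient by patient and year by year: onset with $i(a)$ competing
with death $m(a)$ while healthy; death $m(a)+f(a)$ competing with
institutionalization $r(a)$ while diseased; new onsets face diseased outflow
from the next year. The generator is deliberately a stochastic realization
of the projection recursion, so model-vs-generator agreement is exact in
expectation. Observation is layered on separately: each alive post-onset
patient-year has a disease-coded GP contact with probability ρ
(independently; the onset year always has one, since a diagnosis implies a
visit), and extraction reproduces both registration mechanisms. For a
long-standing prevalent case under an $L$-year lookback, the probability of
being misclassified as incident is $\kappa = \rho(1-\rho)^L$ and of being
missed entirely is $(1-\rho)^{L+1}$ — `implied_misclassification()`.

Presets span the clinically motivated contrast: a diabetes-like disease
(guideline-driven contact, ρ = 0.95), COPD-like (ρ = 0.7), heart-failure-like
(disease-episode registration), and knee-osteoarthritis-like (ρ = 0.3, the
low-contact extreme), with Gompertz-type general mortality (intercept −10.3
females / −10.0 males, slope 0.095 per year of age, giving life expectancies
near 83/80), disease-specific excess-mortality multipliers (0.5, 0.8, 1.5,
0.05 of $m$) and institutionalization 0.4 · $m$ capped at 0.25. ρ values are
illustrative — no survey of per-disease contact frequencies exists to
calibrate them — and the five-network bundle echoes a realistic national
size mix (14,000–270,000 person-years, mixed registration types).

Not emulated: within-patient correlation of care-seeking (contacts are
independent Bernoulli), practice-level clustering, migration (the population
is closed; mid-year exits contribute half a person-year), secular trends in
incidence or survival, and diagnostic coding error. A green end-to-end test
therefore establishes internal consistency of the estimator chain under its
own assumptions, not robustness to those real-world features.

One consequence is worth spelling out because it is quantitatively large.
In a care-based registry with low contact probability, the extracted data
are distorted twice: seen-only-in-index-year prevalent cases are
*misclassified* (fraction $\rho(1-\rho)^L$ of long-standing cases), and
never-seen cases are *missing* (fraction $(1-\rho)^{L+1}$). The fitted model
has only κ to absorb both, so κ̂ systematically exceeds the analytic
misclassification fraction — for the knee-osteoarthritis preset
(ρ = 0.3, L = 2), κ̂ ≈ 0.19–0.22 against an analytic 0.147. This is the
correct behaviour of the estimator on such data: a large κ̂ is as much a
missing-case alarm as a misclassification measurement, and should be read
that way. Dropping the lookback entirely (L = 0) collapses observed
prevalence to near zero and drives κ̂ toward its upper limit, which is why
1-year extracts from care-based registries are unusable for chronic disease.

## Numerical and degenerate-input choices

* Age grid 0–99; band rates constant within bands; life table capped at 99
  with terminal death (documented truncation, error $<10^{-3}$ years for
  realistic schedules).
* `validate_table()` is total — violations are returned as data, never
  thrown — while constructors and readers throw on invalid input.
* Standard-population weights renormalize with a message when they sum to a
  positive value other than one; negative weights are errors.
* Draws producing non-finite standardized rates are dropped with a message;
  more than 10% dropped is an error.
* An extinct cohort band reports missing prevalence; the pipeline treats
  empty strata (zero registered patients) as zero-rate strata for
  standardization.
* Percentile intervals are widened, if necessary, to contain the ML point
  estimate, preserving `ci_lo ≤ value ≤ ci_hi` in pathological draws.
* All entry points that consume randomness require an explicit seed; there
  is no hidden RNG state, and identical seeds give byte-identical pipeline
  outputs.

## Known limitations

Binomial/Poisson independence is an approximation (see above). The fixed
outflow is a single schedule applied to all networks, so differential death
under-registration between networks biases network comparisons. κ is
age-constant; in reality contact behaviour varies with age. The
equal-mortality cancellation familiar from continuous-time illness-death
theory holds only to first order in the discrete scheme. And the model
cannot distinguish misclassified from missing prevalent cases — by design it
flags the sum.
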