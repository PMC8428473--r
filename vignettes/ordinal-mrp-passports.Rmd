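---
title: "Ordinal MRP and net-shift impact statistics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ordinal MRP and net-shift impact statistics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ordmrp)
```

## The estimation problem

Surveys that ask *"would a vaccine passport make you more or less inclined
to vaccinate?"* cannot be read off raw marginals for two reasons. First,
online panels are not population-representative, so respondent-level
predictions must be reweighted to census counts of socio-demographic
strata — multilevel regression and poststratification (MRP). Second, the
answer is confounded with what the respondent already intended to do: a
person who will "definitely" vaccinate and says passports make them *more*
inclined changes no decision, and a person who will "definitely not" cannot
be pushed lower. The package therefore estimates the population *joint*
distribution of baseline vaccination intent `Z` (4-level ordinal) and
change in inclination `Y` (5-level ordinal, 3 = neutral), and summarises it
with statistics that count only *decision-relevant* shifts.

Respondents who already hold both vaccine doses have no future vaccination
decision and are excluded from every fit (`exclude_fully_vaccinated()`).

## The model

Each outcome is modelled with a cumulative-logit (proportional-odds)
multilevel regression. For outcome level $c$ of $C$, ordered cutpoints
$\kappa_1 < \dots < \kappa_{C-1}$ and linear predictor $\eta$,

$$P(\text{outcome} \le c) = \mathrm{logit}^{-1}(\kappa_c - \eta), \qquad
  \eta = \sum_f \beta_{f[\ell]} \;+\; \gamma_Z z \;+\; u_{r,\,p}.$$

* $\beta_{f[\ell]}$ — national fixed effects, one per non-baseline level
  $\ell$ of each socio-demographic factor $f$ (region, sex, age group,
  education, work status, religious affiliation, ethnicity, primary
  language; treatment coding with the documented baselines).
* $\gamma_Z$ — present only in the change-in-inclination model, the slope
  on baseline intent entered as numeric 1–4. A single slope (rather than a
  categorical expansion) is used because one intent odds ratio is the
  interpretable quantity; the proportional-odds family already reports one
  odds ratio per covariate.
* $u_{r,p}$ — region-level random deviations of the non-region
  coefficients, $u_{r,p} \sim \mathcal N(0, \sigma_f^2)$ with one standard
  deviation per factor. These carry the sub-national variation around the
  national effects.

The single function `cell_probabilities()` evaluates this law everywhere —
in the synthetic-data generator, the likelihood, prediction and
poststratification — so the data-generating process and the fitted family
agree by construction (and a test asserts the pointwise equality).

### Priors and parameterisation

Fixed effects and $\gamma_Z$ have $\mathcal N(0, 2.5^2)$ priors; cutpoints
are the sorted transform of iid $\mathcal N(0, 5^2)$; random-effect SDs are
half-$\mathcal N(0,1)$. These are the weakly-informative defaults standard
for MRP-scale logistic models: effects of $|\beta| > 5$ on the log-odds
scale are not credible for survey covariates.

Two reparameterisations matter for sampling and are exactly undone when
draws are extracted, so all reported parameters are on the natural scale:

1. **Design centring.** Fixed-effect columns are centred at their
   pattern-weighted means. Cutpoints and coefficients are strongly
   correlated in the raw parameterisation (split-$\widehat R \approx 1.3$
   at default draw counts in our experiments); centring removes most of
   it. The cutpoint prior is therefore placed on the centred scale, the
   same convention brms uses for its intercept.
2. **Hierarchical centring of the region blocks.** Region coefficients are
   sampled directly as $v_{r,p} \sim \mathcal N(\beta_p, \sigma_f^2)$ and
   the deviation $u_{r,p} = v_{r,p} - \beta_p$ recovered afterwards. The
   naive "fixed effect + zero-mean deviation" form mixes poorly under
   one-at-a-time Gibbs updates because $\beta_p$ and the mean of the
   deviations trade off freely.

### Likelihood aggregation

All covariates are categorical (intent enters linearly but takes four
values), so the likelihood is exactly the product over *covariate
patterns* of multinomial cell counts. Records are aggregated to the
pattern table before JAGS sees them, which makes the per-iteration cost
independent of the number of respondents: a 5,000-respondent fit runs in
about a second instead of a minute, with draw-for-draw identical
posteriors (verified against the per-record likelihood during
development). This is an exact refactor, not an approximation.

### Sampling and diagnostics

Sampling is Gibbs via JAGS (rjags), the standard engine for this model
class, with deterministic per-chain RNG seeds derived from the `seed`
argument — identical settings reproduce identical draws. Defaults are 4
chains × 500 warm-up × 1,000 kept draws; production analyses should scale
to a few thousand per chain. `ordmrp` reports split-$\widehat R$ (each
chain halved) and effective sample size for every sampled parameter; the
pipeline warns when any $\widehat R \ge 1.01$. The regression effects and
$\gamma_Z$ converge quickly; the random-effect SDs are the slowest
parameters — with few regions they are weakly identified, and
$\widehat R \approx 1.03$ for $\sigma_f$ at default draws on a 3-region
toy cross is expected behaviour rather than an error. Poststratified
quantities, which average over strata and draws, are far less sensitive
to this than the SDs themselves.

## Poststratification and the joint distribution

With fitted intent model $P_d(Z \mid s)$ and intent-conditioned change
model $P_d(Y \mid z, s)$ (draws $d$ paired by index), the population joint
distribution over the census strata $s$ with weights $P(S{=}s)$ is the
chain-rule composition

$$P_d(Y'{=}j, Z'{=}k) \;=\; \sum_{s} P_d(Y'{=}j \mid Z'{=}k, s)\,
  P_d(Z'{=}k \mid s)\, P(S{=}s),$$

evaluated with the change model *at* each intent level $k$. (The
alternative reading — additionally marginalising the intent predictive
inside the change term — does not produce a coherent joint distribution
and is not implemented.) Every per-draw $5\times4$ matrix of percentages
sums to 100 by construction; tests assert it to $10^{-8}$ and check the
composition against a brute-force triple loop. Index-pairing the draws of
the two models preserves joint posterior uncertainty without storing a
cross-product; the two fits use different seeds, so their draws are
independent given the data, which matches the factorised posterior of two
separately-parameterised models.

The canonical UK cross — 12 regions × 2 sexes × 7 age groups × 3 education
levels × 7 work statuses × 7 religions × 5 ethnicities × 3 languages —
enumerates 370,440 strata (`enumerate_strata(uk_schemes())`). Strata with
zero census count keep their row (weight 0) so stratum ids are stable
across inputs.

## Net-shift impact statistics

For intent group $k$, with joint percentages $P(Y'{=}j, Z'{=}k)$,

$$U_k = (1-\delta_{k4}) \sum_{j>3} P(Y'{=}j, Z'{=}k)
      \;-\; (1-\delta_{k1}) \sum_{j<3} P(Y'{=}j, Z'{=}k),$$

where $\delta$ is the Kronecker delta: upward shifts are discounted for
the "definitely accept" group ($k{=}4$) and downward shifts for
"definitely not" ($k{=}1$), because neither can change its decision in
that direction. Consequently $U_1 \ge 0$ and $U_4 \le 0$ always. The total
$S = \sum_k U_k$ is the net population-wide decision-relevant change, and
$\Delta S = S_{\text{DOM}} - S_{\text{INT}}$ contrasts the domestic and
international passport scenarios on index-paired draws. Applied to the
bundled published panels, these formulas reproduce every published point
estimate to within the ±0.02 rounding slack of the 2-decimal printed
cells (`net_shift_from_panels()`).

Intervals are 95% highest-posterior-density, computed as the shortest
contiguous window over the sorted draws (Chen–Shao); ties break to the
lowest start index, so results are deterministic. A published convention
reads "the 95% HPD of the odds ratio excludes zero" for significance; the
only coherent reading — the log-odds-ratio interval excluding zero,
i.e. the OR interval excluding 1 — is what `summary.ordmrp()` flags.

## Attitude items

The seven agreement items (5-level) reuse the same machinery as
unconditional outcomes; `agreement_share()` reports the poststratified
top-two-box share. "Prefer not to say" responses default to complete-case
removal, with `apply_pnts_policy(..., "neutral")` recoding them to the
scale midpoint as the sensitivity variant. "Agree" is defined as the
top-two box; published shares do not state the collapse rule, and top-two
is the conventional reading of a 5-point agreement scale.

## The synthetic-data generator

Real survey microdata and census records are access-controlled, so the
generator stands in for both, with known ground truth so that recovery is
testable end to end:

* **Census**: stratum counts from a symmetric Dirichlet–multinomial over
  the full enumeration; concentration 5 and total 100,000 by default —
  heavy-tailed stratum sizes without empty-cell pathologies.
* **Respondents**: stratum sampled by census weight; intent from the
  cumulative-logit law with $\eta_z(s)$; both change outcomes from
  $\eta_y(s) + \gamma_Z z$; dose status independent with a 12% two-dose
  share (1,984 of 16,527 deposited records); attitude items share
  $\eta_z(s)$ with a 3% refusal rate.
* **Defaults emulate the study conditions**: intent cutpoints
  $(-3.05, -2.25, -1.31)$ put the baseline intent margins near
  (4.5, 5.1, 11.7, 78.7)%; $\gamma_Z = \log 3.11$ matches the published
  intent odds ratio; change cutpoints $(1.17, 1.79, 4.57, 5.26)$ place the
  "definitely accept" group's change distribution near its published
  shape; fixed effects are drawn with SD 0.2 (odds ratios mostly
  0.7–1.4, the published socio-demographic range) and region deviations
  with SD 0.15.

What the generator does **not** emulate: real UK census marginals and
their correlation structure, panel nonresponse, quota sampling, and any
misspecification of the proportional-odds assumption. Tests passing on
synthetic data therefore demonstrate that the inference machinery is
correct *when the model family holds*; they do not validate the
substantive published estimates, which require the deposited survey and
census microdata.

## Validation design

* **Worked example**: the published joint-distribution panels ship with
  the package; the net-shift formulas must reproduce all published point
  estimates within rounding (±0.02).
* **Oracle equivalence**: the joint composition, net shifts and HPD
  intervals are each checked against independent brute-force
  implementations (triple loops, exhaustive window scans) on batches of
  at least 100 random small instances.
* **Parameter recovery**: 20 replicates at the study-condition defaults
  (reduced cross of 3 regions × sex × 3 age groups × 2 education levels,
  n = 5,000, census total 50,000) must cover the true $\gamma_Z$ with the
  95% interval in at least 17; observed 18/20 with both misses at an
  interval boundary, consistent with nominal coverage.
* **Simulation-based calibration**: 100 replicates of a tiny
  intercept-only model with cutpoints drawn from the prior; the posterior
  ranks of the truths must be uniform (chi-square, $\alpha = 0.01$).
  This catches prior/likelihood mismatches that point recovery misses —
  and during development it caught a real defect in which intercept-only
  likelihoods never reached the sampler.
* **Determinism**: identical configuration and seed produce byte-identical
  impact reports.

Problem sizes in the suite (reduced crosses, 1,000–5,000 respondents,
hundreds to ~1,000 kept draws per fit) are chosen so the whole validation
runs in minutes on one core while leaving every inferential conclusion
unchanged at larger scale; production runs simply raise `warmup`/`draws`
and use the full scheme.

## Numerical notes and limitations

* `cell_probabilities()` computes cells as differences of logistic CDFs;
  cutpoints must be strictly increasing (enforced), and extreme linear
  predictors degrade gracefully to one-hot cells.
* `hpd()` requires at least two finite draws; single-draw summaries
  degenerate to the point value internally.
* Factor levels absent from the data are retained with prior-driven
  posteriors and a warning — required for poststratifying strata never
  observed in the sample.
* Missing baseline intent is a load error by design: the questionnaire
  offers no refusal option for intent, so any missingness signals an
  upstream coding problem the user must resolve explicitly.
* The proportional-odds assumption (one $\eta$ shifting all cutpoints) is
  untested within the package; with strong non-proportionality the
  reported odds ratios average over levels.
* Poststratification corrects only for the modelled socio-demographics;
  selection on unmodelled variables (e.g. internet access within ages)
  passes through.
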