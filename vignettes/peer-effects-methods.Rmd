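---
title: "Peer networks and new-drug adoption: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Peer networks and new-drug adoption: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rxpeer)
```

## The scientific problem

When a new drug reaches the market, some physicians adopt it quickly and
others not at all. Because physicians are embedded in professional networks
— they share patients, practice in the same groups and hospitals, and
trained together — part of that variation is plausibly *peer influence*: a
physician is more likely to adopt when the colleagues she interacts with
have adopted. Quantifying that influence matters for anyone who wants to
steer diffusion (payers, health systems, quality-improvement programs),
because an intervention delivered to a well-connected physician propagates.

Estimating peer effects from observational prescribing data runs into three
classic obstacles:

* **simultaneity** (the reflection problem): each physician influences the
  same peers who influence her, so regressing adoption on peer adoption is
  circular;
* **homophily**: physicians choose peers similar to themselves;
* **shared context**: unobserved factors (a local formulary change, a
  detailing campaign) move whole groups of peers together.

This package implements, end to end, the instrumental-variables strategy
used in the peer-effects literature for exactly this setting, together with
a synthetic-cohort generator whose ground truth makes every stage testable.

## The four peer networks

From claims-like record tables the package builds four undirected networks
over the physician roster:

* **P — patient sharing**: two physicians are linked when they billed
  claims for common patients; the link's raw weight is the number of unique
  shared patients pooled across payers. `build_patient_sharing_network()`
  keeps pairs with at least `min_shared` pooled patients. The default is
  `min_shared = 1`: the influence weights already discount thin links, and
  the claims-validation literature's 9–10-patient cutoff remains available
  as an option.
* **G — medical group** and **H — hospital**: co-membership projections of
  the physician-organization bipartite graph. Sharing several organizations
  still gives a single unit-weight edge: within-organization peers are
  treated as having equal influence.
* **T — training**: same medical school, or same residency program, within
  ±1 graduation year (`year_window` configurable).

Influence enters through row normalization (`row_normalize()`): the matrix
`W` gives row `i` the weights physician `i` places on each peer, summing to
1 (or 0 for isolates). For P the weights are shared-patient proportions;
for G/H/T they are equal shares. `W` is generally asymmetric even though
the raw networks are undirected: a peripheral physician may assign a hub
most of her attention while receiving almost none back.

Physicians without peers in a network are kept as isolated nodes; their
peer measures are zero-imputed and a no-peer indicator enters the model, so
the design matrix stays full rank and the cohort lines up across networks.

## Adoption and peer measures

Adoption is a single binary per physician: writing at least the *median*
number of new-drug prescriptions among physicians who prescribed the drug
at least once in its first five quarters (15 months) on the market. The
lower median is used for even support sizes so the threshold is an integer
actually attained. Robustness rules (`>=1`, `>=15`) are available in
`classify_adopters()`.

Per network, `peer_adoption_rate()` computes the influence-weighted
fraction of adopting peers `ybar_i = sum_j W[i,j] y_j`. Peer specialist
share and peer high-volume share (high volume = class prescribing at or
above the cohort median) are computed with the same weights, as are the
peer means of exogenous characteristics that serve as instruments. Using
the patient-sharing weights for the P-network instrument means mirrors the
adoption-rate weighting; this is an internal-consistency choice the source
data would not force.

## The estimation model

The linear probability model of adoption is

y_i = β0 + x_i'β1 + γ_P ybar_Pi + γ_G ybar_Gi + γ_H ybar_Hi + γ_T ybar_Ti
      + λ'cbar_i + δ'vbar_i + (no-peer indicators) + ε_i

with `x_i` the physician's own covariates (sex, graduation-year cohort,
specialty, metro status, payer mix, patient-age mix, region indicators,
high-volume flag). The four `ybar` columns are endogenous. Peer *specialty*
and *volume* composition plausibly affect adoption directly (a PCP
surrounded by specialists can refer instead of adopting), so those enter as
controls and are refused as instruments (`peer_mean_instruments()` enforces
the exclusion). The instruments are peer means of characteristics with no
plausible direct effect: sex, graduation cohort, metro, payer mix, patient
age mix — per network, giving 24 instruments for 4 endogenous columns.

`fit_2sls()` runs both stages explicitly: each `ybar` on all instruments
plus all included exogenous columns, then the outcome on fitted rates.
Standard errors use the proper 2SLS residual (observed, not fitted,
endogenous values) with an HC1 sandwich — the convention of the
econometric software this field uses. `fit_ols()` provides the naive
benchmark.

A linear probability model is used, rather than a logit, because it makes
2SLS straightforward; `compare_lpm_logit()` quantifies the cost by
summarizing the per-physician difference in fitted probabilities between
the two (on synthetic cohorts the median difference is well under a
percentage point).

## Diagnostics

* **First-stage F** (`weak_instrument_diagnostics()`): per endogenous
  column, the joint test of the excluded instruments; the robust Wald form
  is the headline number, the classical form is kept for the textbook
  identity with Cragg–Donald. Networks failing F > 10 are flagged and
  their γ estimates marked unreliable. On synthetic defaults the
  patient-sharing and hospital networks pass while the medical-group and
  training networks fail — small peer groups simply do not average enough
  signal — which reproduces the qualitative pattern reported for real
  cohorts.
* **Cragg–Donald minimum eigenvalue**: joint weak-instrument statistic for
  a designated subset of endogenous columns (typically P and H together).
  With a single endogenous column it equals the classical first-stage F,
  an identity the tests verify numerically.
* **Overidentification** (`overidentification_test()`): the "no
  confounding" null. Three forms: the classical Sargan `n R²`, a
  heteroskedasticity-robust two-step GMM J, and a *network-aware* J whose
  weight matrix adds the first-order cross terms `e_i e_j z_i z_j'` over
  peer pairs.

The third form exists because of a property of linear-in-means estimation
worth stating explicitly. The observed peer rate `ybar = W y` carries the
Bernoulli deviations of peers, and those same deviations sit in every
peer's residual through the `-γ W (y - p)` term; residuals of connected
physicians are therefore *negatively* correlated by construction. Because
the instruments are network-smooth (peer means vary at the community and
organization level), the Sargan and plain-robust statistics project the
residual onto exactly the directions where these negative covariances bite,
and both tests become conservative — in null simulations at n = 2000 their
rejection rate at α = 0.05 is around 0.01–0.02 rather than 0.05. The
network-aware weight restores the cross terms the plain weight ignores,
bringing the null rejection rate back toward its nominal level. The
correction is not free: against contamination that is itself
network-structured, the edge-aware variance absorbs part of the violation
and the network form loses power relative to the Sargan. The package
reports the robust J by default, the pipeline additionally computes the
network form when the networks are at hand, and the classical Sargan is
retained for comparability — a practitioner should read a Sargan
non-rejection in this model class as weaker evidence than its nominal level
suggests.

A second, related finding from the synthetic studies: an invalid instrument
whose violation is *routed through the structural error* (a shock shared by
peers that also drives the instrument) is largely absorbed into the peer
effect estimate rather than detected — the equilibrium feedback makes such
a violation look like genuine peer influence, biasing γ̂_P upward while
leaving the overidentification statistic nearly central. Only violations
with a component outside the peer-adoption channel (a *direct* effect of
peer characteristics on own adoption — precisely the concern that excludes
specialty and volume from the instrument set) produce reliable rejections.
The generator's contaminated-instrument dial therefore builds both
features: a promotional-exposure characteristic that loads on the
community shock *and* directly shifts a physician's own adoption through
peers' exposure. This is what the power simulations exercise.

## The social multiplier

The expected number of additional adopters induced by one physician's
adoption, counting all direct and indirect paths with attenuation γ per
step:

m_i = Σ_{t≥1} γ^t [1' W^t]_i

a Bonacich-type power centrality of the weighted, directed influence graph.
Two conventions need fixing because subscript notation alone does not fix
them:

* **walk direction**: adoption by `i` mechanically raises each peer `j`'s
  peer rate by `W[j, i]` — the weight *j places on i*. So the first-order
  term is the `i`-th *column* sum of γW, and `m' = 1' γW (I − γW)^{-1}`.
  This is the only convention under which the verbal definition ("others
  expected to adopt following adoption by i") matches the algebra.
* **which W**: the row-normalized influence matrix, not raw shared-patient
  counts. With row-stochastic W and |γ| < 1 the series converges for every
  graph; with raw counts it generally would not. It is also the same W that
  defines the model whose γ̂ is plugged in.

`multiplier_series()` sums the power series with a geometric-tail residual
bound; `multiplier_closed_form()` solves one sparse linear system; they
agree to 1e-8 on random matrices and both are exposed because the series is
the definition while the closed form is the computation. γ defaults to the
estimated patient-sharing peer effect.

`decile_targeting()` ranks physicians by patient-sharing degree and, in
parallel, by prescribing volume, and compares mean multipliers by decile —
the synthetic analogue of asking whether a payer should target the
best-connected or the busiest prescribers. On heavy-tailed-degree cohorts
with volume independent of degree, degree targeting dominates.

## The synthetic-data generator

The generator (`simulate_cohort()`) emulates the *structure* of a
claims-based physician cohort, not any real population:

* **geography in two levels**: 8 regions (the location covariate entered in
  the model) subdivided into practice communities of ~40 physicians.
  Patients are drawn mostly within a community, so the patient-sharing
  network is locally dense; communities are the natural home of shared
  unobservables.
* **organizations**: medical groups are small (≈10 members,
  region-stratified), hospitals large (≈185 staff), matching the peer-count
  regime of observed affiliation data. Hospitals draw only half their staff
  from the home region; fully region-locked hospitals would overlap the
  patient-sharing network far above the low (<20%) edge-overlap regime
  observed in real cohorts, which the defaults reproduce.
* **covariates**: independent draws with configurable marginals; payer and
  patient-age mixes carry a community-level component (local patient
  populations differ), which is what gives peer-mean instruments genuine
  first-stage signal. A lognormal patient-draw propensity (`sharing_skew`)
  controls degree heavy-tailedness.
* **outcomes**: the equilibrium propensity solves
  `p = clip(β0 + Xβ + Σ_k γ_k W_k p + u, 0.01, 0.99)`, with `u` =
  idiosyncratic noise (sd 0.05) plus a community-level shock — the
  peer-correlated confounder (sd 0.05 by default). Realized adoption is an
  independent Bernoulli draw from `p`. The Bernoulli deviations act as
  measurement error in observed peer rates that is uncorrelated with the
  instruments, so 2SLS remains consistent while naive OLS is biased both
  down (attenuation) and up (the community shock); at the default scales
  OLS lands far from the truth while 2SLS recovers it. A larger
  `confounder_sd` (0.15) makes OLS overshoot the true γ_P — but it also
  makes the community shock dominate the very directions the instruments
  span, and 2SLS inherits a many-instrument bias; the default keeps the
  confounder a perturbation rather than the dominant signal, which is the
  regime in which the instrumental-variables design is honest.
* **prescribing counts**: adopters draw `7 + geometric` new-drug totals,
  non-adopters 0 (80%) or `1..6`, spread over quarters with a mild ramp;
  class-level counts scale with the volume covariate and are at least one
  per quarter, so the minimal-prescribing filter retains the cohort at
  defaults. This construction makes the median rule recover the simulated
  truth exactly — the classifier is testable against ground truth.

What the generator does **not** emulate: real geography or payer rules,
correlated covariates, time-varying adoption hazards, strategic network
formation (homophily on unobservables), or patient-level clinical detail.
Passing tests on synthetic cohorts demonstrate that the estimators recover
a known structural process under the stated assumptions — not that any
particular real-world estimate is correct.

## Numerical choices

* The structural fixed point is solved by iterating the clipped map — a
  contraction with rate `Σ_k |γ_k|` because clipping is 1-Lipschitz —
  with periodic Aitken extrapolation of the dominant geometric mode;
  convergence is certified on the plain map at sup-norm 1e-10, and
  uniqueness is tested from random starts.
* The intercept β0 is calibrated to the target adoption rate by a secant
  search (each evaluation is a full equilibrium solve; an analytic initial
  guess `mean propensity ≈ (β0 + mean(Xβ+u)) / (1 − Σγ)` puts the search
  within a few steps of the root). Tolerance 0.001 on the mean propensity.
* Probabilities are clipped to [0.01, 0.99] to keep the linear model
  interior and the contraction well defined.
* The multiplier series truncates when the term's 1-norm falls below
  1e-12, with the geometric tail bound reported.
* Decile ties are broken by stable physician-id order; decile sizes differ
  by at most one.
* All randomness flows from a single integer seed; each generator stage
  reseeds at a fixed offset so stages are individually reproducible.

## Problem sizes in the test suite

The simulation studies in the test suite use the cohort sizes the methods
are designed around: parameter recovery at n = 4000 across 100 generated
cohorts; the no-peer-effect null at n = 2000 across 100 cohorts; test size
for the overidentification statistic from 500 outcome redraws on one fixed
n = 2000 cohort (the cohort structure is a design, the outcomes are the
randomness); power from 60 redraws at n = 4000 under the
contaminated-instrument dial. Algebraic identities are checked at machine
tolerance on instances of 30–150 observations against independent
matrix-algebra oracles.

## Known limitations

* Estimates for networks with weak first stages (medical group, training)
  are reported but flagged; their γ̂ should not be interpreted.
* The hospital-network estimate carries a subtler caveat: with ~185-member
  staffs, a cohort of a few thousand physicians contains only a dozen or
  two hospitals, and both `ybar_H` and its instruments are hospital-level
  aggregates. γ̂_H is then effectively identified from that handful of
  cluster observations while the (unclustered) HC1 standard errors count
  individual physicians — in null simulations the nominal 95% interval for
  γ̂_H covers zero only about half the time, where the other three networks
  are near nominal. Hospital-network peer effects estimated this way should
  be read qualitatively, not by their printed standard errors.
* The Sargan and plain-robust overidentification tests are conservative
  under this model's residual dependence (see above); the network-aware J
  corrects this but relies on the observed networks capturing the
  dependence structure.
* Confounders that operate through the peer-adoption channel itself are
  partially absorbed into γ̂ and cannot be fully diagnosed from within the
  model — a caution that applies equally to real-data applications.
* The linear probability model is an approximation; fitted probabilities
  outside [0,1] are possible in principle, and `compare_lpm_logit()` should
  accompany any substantive run.
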