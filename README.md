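# rxpeer

Peer networks and physician adoption of new drugs.

## What this package is for

When a new drug reaches the market, a physician's decision to adopt it is
shaped by the colleagues she interacts with — the physicians she shares
patients with, practices alongside in groups and hospitals, and trained
with. `rxpeer` implements a complete analysis of that peer influence for
researchers working with claims-like prescribing data (and for
methodologists studying the estimators themselves):

1. **Network construction** — four physician peer networks from record
   tables: patient-sharing **P** (weighted by pooled unique shared
   patients), medical-group **G** and hospital **H** co-affiliation
   projections, and training **T** (same school or residency within ±1
   graduation year).
2. **Adoption measurement** — the median rule (adopter = at least the
   median number of new-drug prescriptions among prescribers in the first
   15 months), peer adoption rates per network with influence weights,
   no-peer indicators, peer specialist / high-volume shares, and peer-mean
   instrument columns.
3. **Peer-effect estimation** — the linear probability model

   `y_i = β0 + x_i'β + γ_P ȳ_Pi + γ_G ȳ_Gi + γ_H ȳ_Hi + γ_T ȳ_Ti + λ'c̄_i + δ'v̄_i + ε_i`

   by naive OLS and by two-stage least squares with peer means of exogenous
   characteristics as instruments, HC1-robust standard errors, per-network
   first-stage F statistics (relevance bar F > 10), the Cragg–Donald
   minimum-eigenvalue statistic, Sargan / robust-J / network-aware-J
   overidentification tests, and an LPM-vs-logit fitted-probability
   comparison.
4. **Social multiplier** — the Bonacich-type power-series centrality
   `m' = 1'γW(I − γW)^{-1}` giving each physician's expected induced
   adoptions through all network paths, plus a decile targeting comparison
   (network degree vs prescribing volume).
5. **Synthetic cohorts** — a generator with a known linear-in-means
   structural adoption process (configurable true peer effects, a
   community-level peer-correlated confounder, calibrated adoption rates),
   so every stage is testable against ground truth.

The real study design this mirrors used proprietary prescribing and
affiliation data; here the synthetic generator stands in for those sources
and the emphasis is on verifiable methodology: parameter recovery,
diagnostic calibration, and exact agreement with independent oracles.

## Worked example

The `analysis/` directory holds the five-stage workflow; each stage is a
thin script over package functions and writes its tables under `results/`:

```sh
Rscript analysis/01_simulate.R     # synthetic cohort -> results/cohort/
Rscript analysis/02_networks.R     # four networks + overlap
Rscript analysis/03_measures.R     # median rule + peer measures
Rscript analysis/04_estimate.R     # OLS vs 2SLS + diagnostics
Rscript analysis/05_multiplier.R   # social multiplier + targeting
```

With the default configuration (4,000 physicians, true γ_P = 0.6,
γ_H = 0.3, γ_G = γ_T = 0, community confounder on, seed 1) the run prints:

```
realized adoption rate: 0.252 (target 0.25)
median threshold: 7 prescriptions
max off-diagonal network overlap: 0.094

OLS  peer effects:  ybar_P 0.296 (SE 0.049)   <- biased (attenuation + confounding)
2SLS peer effects:  ybar_P 0.957 (SE 0.180)   <- this seed sits high; the
                                                 100-seed mean is 0.61
first-stage F:  P 11.2 (reliable)  G 3.7  H 102.7 (reliable)  T 4.2
Cragg-Donald (P, H jointly): 14.0
overidentification (robust J): p = 0.681

top degree decile mean multiplier 49.4 vs top volume decile 23.6 (ratio 2.09)
```

Reading it: the median rule classifies 25.2% of the cohort as adopters at
a threshold of 7 prescriptions, exactly reproducing the generator's truth.
OLS lands far from the true γ_P = 0.6; 2SLS recovers it on average across
seeds (single seeds scatter with the reported robust SE, and this seed's
γ̂_P of 0.96 is a reminder that the multiplier, which feeds on γ̂/(1−γ̂),
inherits that sampling noise). Instruments are strong for the
patient-sharing and hospital networks and weak for medical-group and
training networks — those γ estimates are flagged unreliable. Targeting
the best-connected decile of physicians is projected to induce about twice
as many adoptions as targeting the busiest prescribers.

Equivalently, in R: `run_pipeline(sim_config(n_physicians = 4000, seed = 1))`.

## Layout

```
R/                  package code: generator, networks, measures, estimation,
                    multiplier, pipeline
analysis/           numbered workflow scripts (thin drivers over R/)
scripts/acceptance.R
tests/testthat/     unit, property and acceptance suites
vignettes/peer-effects-methods.Rmd   the methods vignette
```
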