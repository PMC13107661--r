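---
title: "Multimorbidity patterns from chronic disease networks: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimorbidity patterns from chronic disease networks: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morbnet)
```

## The problem

In an aging closed cohort, chronic diseases accumulate and co-occur
non-randomly. morbnet implements a population-level workflow for
discovering *multimorbidity patterns* — groups of chronic diseases that
cluster in a conditional-independence network — and for quantifying their
impact on mortality, unplanned hospitalization and length of hospital
stay, stratified by sex and age group (50–59, 60–69, 70–79, 80+) at three
follow-up waves (2011, 2016, 2019).

Administrative health records of this kind are not publicly available, so
the package ships a synthetic-cohort generator that reproduces the
statistical structure the analysis assumes. Every stage of the pipeline is
validated against that generator or against exact small-problem oracles.

## The disease network model

Let $x \in \{0,1\}^p$ be the cumulative diagnosis indicators of one person
at one wave. The working model is the pairwise binary Markov random field
(Ising model)

$$P(x) \propto \exp\Big(\sum_j h_j x_j + \tfrac12 \sum_{j \ne k}
\theta_{jk} x_j x_k\Big),$$

whose zero pattern encodes conditional independence: $\theta_{jk} = 0$
means diseases $j$ and $k$ are unassociated once all other diseases are
held fixed. With all variables binary, this is the binary special case of
the mixed graphical model, and the standard estimator is *nodewise
neighborhood selection*: each disease is regressed on all the others by an
$\ell_1$-penalized logistic regression (`fit_nodewise()`).

Choices that matter:

* **Penalty selection.** Each node's lambda is chosen by the extended BIC
  with $\gamma = 0.25$ over a 50-value log-spaced path
  ($\lambda_{\min} = 0.01\,\lambda_{\max}$). EBIC is the standard
  convention for sparse graph selection at these sample sizes; 10-fold CV
  is available via `rule = "cv"` for users who prefer denser estimates.
* **No standardization.** All predictors are 0/1 indicators on a common
  scale; standardizing would re-weight the penalty by prevalence.
* **Aggregation.** The two directed coefficients per pair are combined by
  the AND rule (edge kept only if both regressions select it) with the
  mean as the weight; sign-conflicting pairs are zeroed
  (`aggregate_network()`). This is the conservative convention for
  neighborhood selection. The reported weights are aggregated logistic
  coefficients (conditional log-odds-ratio scale); they approximate the
  strength of pairwise conditional association but are not partial
  correlations in the Gaussian sense.
* **Intercepts** are always included and never penalized.

One network is estimated per sex × age group × wave from the survivors
still under observation at that wave — 24 networks in the default design.
Diseases that are constant inside a cell are dropped from that cell's
network (the global prevalence filter makes this rare).

## Patterns as modularity-selected communities

Multimorbidity patterns are *hard* communities of the estimated network:
each disease belongs to exactly one pattern. Rather than fixing one
clustering algorithm, `run_algorithm_bank()` applies seven standard
algorithms (edge-betweenness, fast-greedy, Louvain, walktrap, spinglass,
exact modularity optimization, label propagation) and
`select_partition()` keeps the partition with the highest Newman weighted
modularity. Exact ties are broken by a fixed priority order (optimal >
louvain > walktrap > fast-greedy > spinglass > edge-betweenness >
label-propagation), so selection is deterministic.

Numerical choices:

* **Negative weights.** The community algorithms assume nonnegative
  weights, so detection and modularity use $|w|$. This discards the sign
  of (rare) negative conditional associations and is a documented
  limitation.
* **Stochastic algorithms** (spinglass, Louvain, label propagation) run
  under fixed seeds; label propagation additionally takes a consensus
  over 25 restarts (two diseases are clustered together when they
  co-occur in a majority of runs), because single runs are unstable on
  weak graphs.
* **"Optimal"** is exact integer-programming modularity maximization and
  is gated at 35 nodes; exhaustive enumeration
  (`brute_force_partition()`, used as an oracle in the tests) is gated at
  13.
* **Spinglass** requires a connected graph and runs per connected
  component. The other algorithms see the full graph: running modularity
  maximizers per component is wrong, because an isolated dense block has
  modularity 0 on its own and would be split artificially.
* **Algorithm selection scope.** The bank is run once on a designated
  reference network (female 60–69 at wave 2011 by default) and the
  winning algorithm is then applied to all 24 networks, which keeps the
  24 partitions methodologically comparable; this is configurable.

Communities are turned into named patterns by anchor diseases
(`label_patterns()`): heart failure anchors the cardiovascular pattern,
dementia the neuropsychiatric, COPD the respiratory-digestive and
diabetes the metabolic-pain pattern; anchor-free communities are labeled
`other-k`.

## Scoring diseases and assigning persons to patterns

Each disease receives a score = strength centrality (sum of $|w|$ over
incident edges) + in-degree of a Bayesian network learned on the same
data (`learn_dag()`, hill climbing with the discrete BIC score, tabu list
of the last 100 moves, random restarts, parent cap 4). The in-degree
proxies how much a disease is "downstream" of others. In-degree is the
raw parent count, not a weighted version — the score is meant as a simple
interpretable sum.

A multimorbid person is assigned exactly one pattern per wave
(`assign_pattern()`):

1. all their diseases in one pattern → that pattern;
2. otherwise the pattern holding most of their diseases;
3. ties → the pattern where *their own* diseases have the largest summed
   score (the person-centric reading of "most substantial");
4. residual ties → lexicographically smallest label, for determinism.

The cascade is a total deterministic function of (disease set, partition,
scores); each stage is pinned by a constructed fixture in the tests.

## Gatekeepers and strong dyads

Betweenness centrality identifies *gatekeeper* diseases — those on many
shortest paths between other diseases. Shortest paths use edge length
$1/|w|$ (stronger association = shorter), the standard transform for
association networks; betweenness gives fractional credit to tied
shortest paths, and closeness is the inverse mean distance to reachable
diseases only. The top 5 gatekeepers (ties broken by strength, then
code) each contribute their 5 strongest incident dyads; the pooled list
is deduplicated, so "25 strongest dyads" is an upper bound when
gatekeepers share an edge. A person is *exposed* when both members of at
least one dyad are diagnosed at baseline (2011), mirroring an
early-detection design. Dyad strengths come from the baseline-wave
network.

## Outcome models

Mortality is modeled on counting-process data: follow-up is split at the
wave boundaries (5 and 8 years after baseline) and the assigned pattern
and cumulative disease count update at each wave
(`build_counting_process()`). `fit_cox()` fits the proportional-hazards
model with Efron tie handling; reference levels are the cardiovascular
pattern, no/primary education and cities. `compare_models_aic()` contrasts
a disease-count-only model with a pattern-only model (both controlling
education and urbanity) by AIC on identical rows; the disease-count
covariate is time-updated per wave (a fixed lifetime count is a
configurable alternative).

The baseline-exposure analyses (`fit_exposure_glms()`) are three GLMs per
stratum: logistic regression on death during follow-up (odds ratio),
negative-binomial regression on unplanned hospitalization counts
(incidence-rate ratio; quasi-Poisson available — the overdispersion
mechanism is a configuration choice), and a linear model on
$\log(\text{length of stay} + 1)$ (multiplicative change $e^\beta$). The
$+1$ accommodates the many persons never hospitalized, whose stay is 0
days; as a consequence the multiplier is exactly unit-free only for
stays well above one day, which the tests respect by checking invariance
on hospitalized persons.

All outcome models are fit within sex × age-group strata (or with
stratified baselines). This matters: the baseline death hazard rises
steeply with age, and a pooled fit would let any covariate correlated
with age — notably the disease count — absorb the age effect.

## The synthetic cohort generator

`simulate_cohort()` emulates the features of a regional administrative
cohort that the analysis relies on, per sex × age-group stratum:

* **Baseline diseases** are drawn from a planted-block Ising model: 33
  diseases in four blocks (cardiovascular, neuropsychiatric,
  respiratory-digestive, metabolic-pain) plus two bridge diseases; each
  block has a hub connected to all members, other within-block pairs are
  present with probability 0.5 at coupling 0.8, bridges couple at 0.5
  (couplings strong enough that the nodewise estimator sees signal at
  5,000 persons per stratum; low-prevalence diseases in the youngest
  strata still yield sparse networks, which is the realistic small-n
  behavior).
  Three diseases have baseline prevalence below 1%, so the pooled
  prevalence filter reduces 33 to 30 diseases, and persons with fewer
  than two lifetime diseases are excluded
  (`apply_inclusion_filter()`).
* **Gibbs sampling** uses parallel chains, 500 burn-in sweeps and
  thinning 10 — conservative for p ≤ 33 — with node intercepts calibrated
  by a mean-field identity (optionally refined stochastically) so that
  marginal prevalences hit their targets.
* **Age and sex gradients** are additive log-odds shifts (0.1, 0.55,
  0.95, 1.25 across age groups); together with the wave incidence model
  (discrete-time logistic hazard per disease, 5-year base probability =
  0.22 × prevalence, +0.3 log-odds per already-affected network
  neighbor) they are calibrated so that median lifetime disease counts
  among included persons are within one disease of 3, 4, 5 and 6 across
  the four age groups. Diagnoses never remit.
* **Education and urbanity** follow per-stratum census multinomials
  (education improves in younger cohorts; suburban residence dominates).
* **Outcomes.** Survival is piecewise-exponential proportional hazards
  on the planted pattern (wave-updated), disease count, education,
  urbanity and planted-dyad exposure, with administrative censoring at 8
  years and exponential out-migration (rate 0.012/year); baseline yearly
  hazards 0.006–0.075 give 8-year death fractions from ~5% (50–59) to
  ~73% (80+). Hospitalization counts are negative-binomial (dispersion
  0.8), total stay is log-normal given at least one admission and 0
  otherwise (matching zero medians in younger strata). Wave matrices are
  truncated at death, so diagnoses stop accruing when observation ends.
* **A direct logistic mortality mechanism** (`mortality_model =
  "logistic"`) exists for planting an odds ratio that the baseline
  logistic analysis should recover exactly. For such recovery
  experiments the inclusion filter is applied *before* outcomes are
  simulated; filtering afterwards selects on death (early deaths accrue
  fewer diagnoses and are dropped differentially) and visibly biases the
  exposure odds ratio upwards — the tests document the clean design.

What the generator does **not** emulate: ICD coding and linkage noise,
cohort entry after baseline, time-varying education/urbanity, seasonal or
calendar-time effects, and any dependence between diseases beyond
pairwise couplings. Passing tests therefore show that the estimators
recover the structure of this generating process at realistic sizes, not
that real administrative data satisfy the model.

## Problem sizes and validation design

The validation suite uses planted-structure fixtures at sizes chosen to
keep a full run on one CPU comfortable while leaving the estimators
non-trivial headroom: structure recovery on p = 30, n = 20,000,
within-block couplings 0.8 (edge-set F1 ≥ 0.80 over 10 seeds); partition
recovery ARI ≥ 0.9 in ≥ 90% of 20 seeds with exactly four communities;
betweenness and exact-modularity equivalence against brute-force oracles
on graphs of ≤ 15 and ≤ 12 nodes; gatekeeper persistence across waves on
hub-dominated blocks (sparser, with a bridge anchoring every block — a
bridge anchoring only two blocks leaves the other blocks' cross-traffic
to false-positive edges and makes the top-5 unstable); outcome-parameter
recovery at n = 50,000 (log-HR ± 0.1, ratio-scale parameters ± 10%); and
a default end-to-end run with 5,000 persons per stratum producing the
full 24-network, 8-table output shape deterministically.

Determinism is end-to-end: a single seed is expanded into fixed per-stage
substreams (`child_seed()`), so reruns are byte-identical except for the
wall-clock timings in `log.txt`; the run manifest itself is deterministic
and records file checksums.

## Known limitations

* Edge weights are aggregated penalized logistic coefficients; their
  absolute scale depends on prevalence and penalty and should be read
  comparatively, not as correlations.
* Community detection on $|w|$ ignores association signs.
* The DAG is a score-based point estimate used only for the in-degree
  component of the assignment score; edge directions carry no causal
  claim.
* The exposure analyses condition on baseline exposure only; no
  time-varying exposure or mediation is modeled.
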