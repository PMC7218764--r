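---
title: "A Markov cohort model for RHD screening cost-utility analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Markov cohort model for RHD screening cost-utility analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhdcea)
```

## The decision problem

Latent rheumatic heart disease (RHD) — echocardiographic borderline or
definite valve lesions in children without symptoms — progresses over years
toward clinical valve disease, surgery and premature death. Secondary
prophylaxis (regular benzathine penicillin G) substantially slows that
progression, but only diagnosed children receive it; under standard care
most children surface only once symptomatic. One-time echocardiographic
screening of a school cohort buys earlier diagnosis. This package prices
that purchase: discounted lifetime-horizon (30-year) costs and
disability-adjusted life years (DALYs) for a screened versus an unscreened
cohort, combined into an incremental cost-effectiveness ratio (ICER) and net
monetary benefit (NMB).

## Model structure and assumptions

The engine (`run_cohort()`) is a standard closed-cohort state-transition
model: occupancy row-vector times a row-stochastic annual matrix, once per
cycle. It is state-space-agnostic; the canonical bundle uses 15 states.
Published summaries of this model count 13 states while the accompanying
cost table enumerates 15 rows; we follow the cost table, because every
state that accrues cost must exist in the model, and document the
discrepancy here rather than hiding it. The 15 states are: No RHD;
undiagnosed/diagnosed asymptomatic borderline; untreated/treated
asymptomatic definite; untreated/treated mild clinical; untreated/treated
severe clinical; three resolved-after-treatment states; Surgery;
Post-Surgery; Death.

Structural assumptions, each a deliberate choice:

* **Cycle length one year, cycle-constant matrix.** The engine accepts any
  matrix per run; age dependence can be layered by re-running with per-cycle
  matrices, but the base model is homogeneous.
* **No half-cycle correction.** Costs and utilities accrue for the state
  occupied at the *end* of each cycle, discounted by `(1+r)^-t`. The
  convention is exposed (`accrual = "begin"`) because the literature is
  split; switching moves every discounted total by at most one year of
  discounting and cancels almost entirely in the increments.
* **Surgery is a tunnel.** Its self-transition is forced to zero and its
  outgoing probabilities must fully allocate (post-surgery vs operative
  death); `assemble_matrix()` errors rather than silently padding.
* **Death is absorbing**, enforced on assembly regardless of input.
* **Screening acts once, at cycle 0.** Detected borderline children move to
  the diagnosed-borderline state (costed follow-up, a small "disutility of
  knowing" weight); detected definite cases move straight to the treated
  state. False positives pay a one-time confirmatory work-up and remain
  disease-free. Re-screening rounds are out of scope.
* **Prophylaxis as progression reduction.** Treated-state progression edges
  (treated-definite to clinical/surgery, treated-mild to severe) are scaled
  by `1 - effect` (default 0.50 each), the freed mass returning to the
  self-loop. Both strategies share the resulting matrix: the whole screening
  benefit flows through the cycle-0 reallocation, which is exactly the
  "earlier detection means more children under appropriate care" mechanism.
  Adherence is not modelled separately; `effect_*` is the effective,
  adherence-weighted reduction.

## Outcomes

DALYs are YLD + YLL. YLD is occupancy times per-state disability weight,
discounted like costs. YLL values each cycle's *new* entrants to the death
state (valid because death is absorbing) by the life-table remaining life
expectancy at the attained age. Two conventions are implemented:

* `yll_mode = "stream"` (default): the expectancy `L` becomes `ceiling(L)`
  year-sized terms starting the year after death, the last pro-rated, each
  discounted to time zero — the convention that makes a death at 40 with
  `L = 35` worth far less than 35 undiscounted years, as in standard
  burden-of-disease accounting with discounting.
* `yll_mode = "lump"`: `L` taken undiscounted at the death cycle, kept as a
  sensitivity switch because source descriptions of such models are often
  silent on the point.

No age-weighting is applied. QALYs are deliberately unsupported: the model
family this implements used DALY weights because no QALY estimates exist for
latent RHD states.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `cohort_size` | 1,000 | children | published cohort constant |
| `n_cycles` | 30 | years | ages 11–41; adult natural history too uncertain for lifetime |
| `discount_rate` | 0.03 | per year | WHO recommendation; swept 0–0.05 |
| `threshold` | 25,949.85 | USD/DALY | 3x GDP per capita (2015) |
| `cost_per_scan` | 6.60 | USD | handheld-echo screening program estimate |
| `sensitivity_definite` | 0.90 | — | baseline unpublished; midpoint of the 0.80–1.00 sweep |
| `sensitivity_borderline` | 0.65 | — | baseline unpublished; midpoint of the 0.50–0.80 sweep |
| `specificity` | 0.95 | — | synthetic; swept 0.90–0.99 |
| `false_positive_followup_cost` | 30 | USD | synthetic: confirmatory echo + consultation scale |
| `effect_definite`, `effect_mild` | 0.50 | fraction | prophylaxis progression reduction |
| `shared_cost_variance` | (0.3 x 4,120.51)^2 | USD^2 | see below |

Per-state annual costs (2017 USD) are the published table values: $25.84
diagnosed borderline, $93.93 treated asymptomatic definite, $337.47 treated
mild clinical, $854.00 treated severe/resolved-severe/post-surgery,
$4,120.51 surgery, zero for all undiagnosed/untreated states and death.

**Shared cost variance.** The source analysis assumed every state cost's
variance equals the surgery-state variance, the only one observable in the
administrative data — but never printed it. The bundle therefore sets it to
a 30% coefficient of variation on the surgery cost, typical of
administrative cost data, as a single overridable config key. A consequence
worth knowing: applying surgery's *absolute* variance to a $25.84 state
gives an extremely skewed gamma (shape << 1); the sampler handles it, but
PSA cost draws for cheap states are near-zero most of the time with rare
large values. That is what the stated assumption implies, so we implement it
rather than quietly substituting per-state CVs.

## Uncertainty machinery

* **Distributions.** Costs: gamma parameterised by mean/variance
  (`shape = m^2/v`, `rate = m/v`). DALY weights: triangular between the 95%
  uncertainty-interval bounds with the point estimate as mode (inverse-CDF
  sampler, written here since base R has none). Probabilities: beta by
  mean/effective-sample-size (bundled default `n = 100`). Point descriptors
  and zero-variance gammas degenerate exactly, so an all-point PSA equals
  the deterministic run bit for bit — a tested invariant.
* **Row repair.** Outgoing probabilities of a state are sampled
  independently, then the row is renormalized only if the sampled
  off-diagonal mass exceeds 1 (tunnel rows always renormalize to exactly 1,
  having no self-loop). Joint (Dirichlet) sampling would preserve negative
  correlation between competing exits but requires a concentration
  parameter the inputs do not provide; independent-then-repair is the
  minimal-assumption choice and is confined to `sample_params()`.
* **Rejection.** An iteration whose sampled matrix still fails validation is
  redrawn, at most 100 times, with a running count reported in the result;
  on well-formed bundles the count is zero.
* **CEAC.** Acceptance at threshold lambda is the fraction of iterations
  with `lambda * dE - dC > 0`; the default grid is 0 to twice the bundle
  threshold in 200 steps.
* **Tornado.** Every parameter with usable bounds is swept one-at-a-time:
  transitions and costs over their descriptors' central 95% intervals
  (transition upper endpoints capped so the source row stays
  sub-stochastic), DALY weights over their uncertainty intervals, screening
  accuracies over their configured sweep endpoints, prophylaxis effects
  down to zero, and the discount rate 0–5% always. Sweeping a tunnel-row
  transition rebalances its sibling destinations proportionally. Rows sort
  by absolute ICER spread. Dominance makes a raw ICER sign-unstable, so
  spreads should be read alongside the reported endpoint ICERs.

## The synthetic bundles

The study's supplementary transition tables are not redistributable, so the
packaged bundle and the generator supply *structurally* faithful stand-ins,
clearly marked `synthetic` in their file names:

* `paper_fixture()` — published costs and cohort constants verbatim;
  transition probabilities at the midpoints of the generator's documented
  per-edge ranges; synthetic GBD-tier DALY weights (mild clinical 0.041,
  severe 0.179, post-surgery 0.049, borderline "knowing" disutility 0.012);
  a linear-decline life table (remaining expectancy `71.5 - 0.8 * age`,
  floored at 2.5 years, emulating a socioeconomically disadvantaged urban
  population); initial latent prevalence 4.2% split 3:1
  borderline:definite. The 4.2% is the published screening-program
  prevalence; the 3:1 split is a typical screening-series ratio, chosen
  once and documented as synthetic.
* `generate_bundle(generator_config(seed))` — same topology, probabilities
  drawn uniformly from the per-edge ranges, with scale knobs
  (`progression_scale`, `mortality_scale`, `cost_scale`) for stress tests.
  The generator's job is that every pipeline stage runs and every invariant
  holds on arbitrary seeds; it makes no claim of numeric fidelity to any
  study, and deliberately so — calibrating it to reproduce published outputs
  would turn a structural test harness into circular evidence.
* `generate_toy_bundle()` — a 3-state healthy/sick/dead model whose
  discounted costs and DALYs have closed geometric-series forms,
  `sum_t p^t (1+r)^-t`, used as independent oracles for the accrual code.

What passing tests on these bundles show: the engine, accounting,
reallocation and uncertainty machinery are correct to stated tolerances
(1e-9 for traces and closed forms, exactness for degenerate PSA). What they
do not show: that the packaged numbers reproduce any published totals —
that requires the external transition tables via the overlay hook. The
model diagram itself (the allowed-edge list) is our transcription from the
state roles and the progression/care/mortality structure the source
narrates; it permits regression edges, care-seeking from symptomatic
untreated states, surgery from definite disease onward, and death from
every state.

## Numerical choices and degenerate inputs

* Row-stochasticity tolerance 1e-9 on input matrices; trace mass
  conservation holds to 1e-9 over 30 cycles and is asserted in tests.
* Monetary values are read at 2-decimal precision and kept as doubles
  internally; bundle serialization writes 17 significant digits so
  load-save-load is the identity (a tested invariant, byte-for-byte on
  re-save).
* Life-table lookups interpolate linearly and *error* outside the table —
  silent extrapolation of expectancy is how YLL bugs hide.
* A state with no economics row fails fast if occupied; death must carry
  zero cost and zero weight (mortality flows through YLL only).
* `prevalence_by_ageband()` divides by alive occupancy per cycle and then
  averages over cycles, matching prevalence-among-the-living comparisons;
  an empty age band is an error, not zero.
* ICER conventions: `delta_effect > 0, delta_cost > 0` gives the ratio;
  cheaper-and-better is labelled `dominant`, costlier-and-worse `dominated`;
  `delta_effect = 0` yields an `NA` ICER with an `equal_effect` label. NMB
  is always reported and is the safer decision statistic under dominance.

## Limitations

* The packaged natural-history magnitudes are placeholders: deterministic
  totals, the ICER's sign, PSA acceptance probabilities and tornado
  orderings on the packaged bundle characterise the *pipeline*, not the
  published analysis, until real transition tables are substituted.
* Cohort proportions only — no individual-level heterogeneity, no memory
  beyond the single surgery tunnel.
* One-time screening of a single age cohort; program administration costs
  and repeated screening rounds are out of scope.
* Costs enter already expressed in 2017 USD; currency conversion and
  inflation indexing are upstream of this package.
* The adherence pathway is collapsed into the effective prophylaxis
  reductions; settings with very poor adherence need those inputs lowered
  rather than a structural switch.
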