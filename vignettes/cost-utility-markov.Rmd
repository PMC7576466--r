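---
title: "Methods: a three-state Markov cost-utility model for integrated domiciliary care"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a three-state Markov cost-utility model for integrated domiciliary care}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(markovcea)
```

## The decision problem

Telehealth-enhanced integrated domiciliary care adds monitoring technology,
shared care plans and third-sector involvement to usual coordinated health
and social care for older multimorbid patients. Whether the extra programme
cost buys enough health to be worth paying for is a cost-utility question:
we need lifetime quality-adjusted life years (QALYs) and costs per arm, and
their ratio of increments against a willingness-to-pay (WTP) threshold.

The package answers it with a deterministic three-state Markov cohort
model — the workhorse of decision-analytic modelling when patient-level
longitudinal data are short (months) but the decision horizon is a
lifetime. The three states are *baseline disease stage* (the patient
remains at or above the functional level observed at enrolment),
*deteriorated disease stage* (functional decline on the Barthel index of
activities of daily living) and *dead*.

## Model mechanics and conventions

Each cycle is one year. Within a cycle, for each sex separately:

1. **Death competes first.** The annual death probability is the period
   life-table value $q_x$ for the cohort's current age and sex, scaled by a
   state-specific relative risk on the hazard scale,
   $p = 1 - (1-q_x)^{rr}$. The hazard-scale form guarantees a valid
   probability for any $rr > 0$; at the default $rr = 1.005$ it differs
   from naive multiplication by less than $10^{-4}$.
2. **Survivors transition.** From baseline, worsen with the per-cycle
   incidence $i$; from deteriorated, return to baseline with the recovery
   $r$. This ordering (death first, then disease transitions among
   survivors) is the standard cohort-model convention and is stated
   explicitly because it changes results.
3. **Rewards accrue on end-of-cycle occupancy**, discounted by
   $(1+\rho)^{-t}$: state utility for QALYs, annual state cost plus the
   recurring programme cost (weighted by alive occupancy) for costs. The
   one-off programme cost is charged undiscounted at entry. A half-cycle
   correction (mean of start- and end-of-cycle occupancy) is available via
   `econ_config(half_cycle_correction = TRUE)` but **off** by default: web
   tools in this space do not document their convention, and the flag lets
   users bracket the ambiguity.

The two sexes are simulated on their own life-table columns and mixed by
the cohort's female fraction. Ages beyond the table clamp to its terminal
row, whose $q_x$ is forced to 1 on load so the oldest age is absorbing.

Key tunable parameters (all per [`markov_arm()`] / [`econ_config()`]):

| parameter | unit | default | why |
|---|---|---|---|
| discount rates (effects, costs) | /year | 0.03, 0.03 | health-technology-assessment practice in southern Europe |
| horizon | cycles | 40 | covers the remaining lifespan of an older cohort |
| entry age / sex mix | years, fraction | 84, 0.65 female | pooled profile of the evaluated cohort |
| incidence, recovery | /cycle | 0.34/0.66 vs 0.36/0.64 | observed worsened fractions and their complements |
| utilities (B, D) | — | 0.56/0.30 vs 0.45/0.33 | Barthel-proxy utilities after follow-up |
| mortality relative risks | — | 1.005 both states | near-population mortality of the target group |
| WTP | EUR/QALY | 15,000 | threshold used in the sensitivity analyses |

### Analytic guard rails

With zero incidence and a constant per-cycle survival $s$, discounted
life-years have the closed form
$\sum_{t=1}^{T}(sv)^t = sv\,(1-(sv)^T)/(1-sv)$, $v = 1/(1+\rho)$, exposed as
`closed_form_dly()`; the engine must (and does, in the test suite) match it
to $10^{-10}$, and must equal an independently written transition-matrix
loop on randomized parameter sets to the same tolerance. The $sv \to 1$
degenerate case returns the horizon as the limit. Occupancy is conserved to
$10^{-12}$ per cycle by construction, and death is absorbing.

## The life table

A real national period life table (columns `age`, `sex`, `qx`) can be
supplied as delimited text via `read_life_table()`. Because such tables
cannot be redistributed here, the package ships a **synthetic** Gompertz
table (`gompertz_life_table()`, also as the plain-text fixture
`inst/extdata/gompertz_life_table_synthetic.tsv`): hazard
$h(x) = a\,e^{bx}$ with $b = 0.10$/year and levels $a$ calibrated so the
annual death probability at age 84 is ≈0.05 for women and ≈0.08 for men —
loosely representative of southern-European period mortality at advanced
ages. The Gompertz law is the standard parametric description of adult
mortality; its parameters were fixed once, from that calibration target,
and are documented in the fixture itself.

## From patient data to model inputs

`classify_transition()` marks a patient *worsened* when the follow-up score
drops **strictly** more than a threshold (`final − baseline < −threshold`);
the default threshold 0 counts any Barthel decline. The strict inequality
is a declared tie-break: how the original classification handled exact-
threshold declines is not public, so the boundary rule is explicit and
configurable. Incidence is the worsened fraction; recovery is estimated as
its complement, which makes the two sum to one exactly (the engine also
accepts independent values). The observed 8-month fraction is used directly
as the annual per-cycle probability by default — matching how the published
inputs were tabulated — with an optional constant-rate annualization
$p_{ann} = 1-(1-p_{obs})^{12/m}$ available but off by default.

Utilities come from a pluggable Barthel→utility proxy: affine
$u = a + b\,\mathrm{Barthel}$ clipped to $[0,1]$ (default $u =
\mathrm{Barthel}/100$), or *direct* mode passing externally published
per-state utilities through unchanged — the pass-through path uses direct
mode. The original regression mapping behind the published utilities is not
printed anywhere public, so it is deliberately out of scope; the mapping
interface is the extension point.

## Costing

Resource use is monetized linearly: contact duration × hourly wage
(physician €29.23, nurse €20.79, social-care worker €18.19; specialists at
the physician wage and other health providers at the nurse wage, since no
separate wages exist; volunteers unmonetized), bed-days × €733.56, citizen
time × €6.07 (2016 minimum-wage equivalent). All costs are homogenized to
per patient-year by `× 12 / followup_months`.

Contact durations are not recorded in routine data, so defaults ship as
explicit assumptions keyed by setting: home visit 0.75 h, out-of-home
0.33 h, telephone 0.17 h, writing 0.08 h, other 0.33 h. Per-record
durations override them.

The **health-care perspective** covers contacts and hospitalizations. The
**societal perspective** adds, for intervention patients, platform-usage
time (default 48 h per patient-year — roughly an hour a week, an assumption
since usage logs are not public) and, for comparator patients, the travel
burden of attended out-of-home contacts (default 0.5 h citizen time and €0
out-of-pocket per contact): the telehealth service avoids those journeys,
so they are charged to the comparator.

Per-state cost inputs are stratum means of annualized per-patient totals
over the worsened / stable-or-improved classification. When no
patient-level data exist, the packaged per-state cost block is passed
through directly — that is the reference mode of `run_pipeline()`.

## The synthetic cohort generator

`generate_cohort()` emulates the structure the analysis needs, with
defaults transcribed from the evaluated programme's summary tables:

- **Demographics**: Gaussian age (floored at the 65-year eligibility age),
  Bernoulli sex; arm means 85.5/82.8 years (SDs recovered from reported
  interquartile ranges via IQR/1.349), 74%/57% female.
- **Comorbidities**: independent Bernoulli flags at the observed
  prevalences, scored with standard Charlson weights.
- **Scores**: Gaussian baselines and Gaussian follow-up changes, clipped
  and rounded to each instrument's grid (Barthel multiples of 5 in [0,100];
  IADL integers in [0,8]; GDS integers in [0,15]). Change SDs are recovered
  from the reported 95% CIs of the mean changes. Gaussianity is the minimal
  assumption given that only means and CIs are public, and it is isolated
  in the configuration.
- **Contacts**: Poisson counts at the annual rate scaled by
  `followup_months/12`, with professional type, setting and
  planned/unplanned drawn independently from the observed marginal mixes.
  Only marginals are public, so the joint mix is their product — a known
  simplification.
- **Hospitalization**: Bernoulli any-admission, a 1-plus-Poisson admission
  count calibrated so the unconditional mean matches the observed
  admissions per patient, and lognormal length of stay by moment matching
  (the observed SDs exceed the means, ruling out a Gaussian; stays are
  non-negative and right-skewed).

Randomness is split per patient: one seeded stream draws a sub-seed per
patient, so enlarging an arm appends patients without perturbing earlier
ones, and identical configurations are bit-identical.

What the generator does **not** emulate: intra-patient correlation between
instruments, correlation between comorbidity burden and resource use,
temporal patterns within follow-up, and dropout (follow-up completeness was
never reported; the generator has none by default). Passing distributional
tests on synthetic cohorts therefore demonstrates estimator correctness,
not real-data validity.

## Sensitivity analysis

`one_way_sweep()` multiplies one or more target parameters by $(1+\delta)$
over a relative grid — by default 21 points spanning ±5% in 0.5% steps —
and reruns both arms per point; perturbed values are clipped to the
parameter's invariant range (utilities to $[0,1]$). The published analyses
describe a "0 to 5%" change without a sign, so the package sweeps the
symmetric ±5% range and judges the **maximum** ICER over the whole grid —
the stricter reading. The zero-perturbation point reproduces the base case
identically (a regression guard). The two first-class sweep families are
the intervention's baseline-stage utility and the per-state health-care
costs of both arms jointly.

A probabilistic sensitivity analysis (`psa()`, also `simulate()` on the
fitted model) is provided as a clearly-labelled extension beyond the
deterministic sweeps: beta distributions for probabilities and utilities,
gamma for costs, moment-matched around the base case with a default 10%
relative SD, seeded and reproducible; out-of-range draws are resampled up
to 100 times and then clipped, with the capped count reported.

## Numerical and design choices, and known limitations

- **Problem sizes.** Distributional-recovery tests use 5,000–10,000
  patients per arm (3-standard-error bands against clipped-normal /
  binomial / Poisson oracles computed in closed form); engine-equivalence
  tests use 100 randomized parameter sets at $10^{-10}$; the PSA
  self-consistency check uses 2 × 2,000 draws. These sizes give the
  property tests sharp expected behaviour while keeping the default suite
  quick on a laptop.
- **Entry profile.** The model enters everyone in the baseline stage at a
  single age with a fixed sex mix (defaults: age 84, 65% female, the pooled
  cohort profile). The web tool originally used for the published analysis
  does not document its entry profile, cycle-correction convention or
  life-table vintage, and the incremental results are sensitive to the
  implied discounted life expectancy: at entry age 84 the model yields
  ≈6.7 discounted life-years per arm, and correspondingly smaller absolute
  increments than an entry profile a decade younger would give. The entry
  profile is deliberately config-exposed rather than tuned.
- **Cost anomaly pass-through.** In the packaged inputs the intervention's
  deteriorated-stage cost is *lower* than its baseline-stage cost; no
  public rationale exists, so the values are passed through, not
  rationalized.
- **Currency.** Everything is 2016 euros; dollar conversions are
  presentation-only and never computed. Reports round euros to 2 decimals
  and QALYs to 3; machine-readable outputs keep full precision.
- The package models cohorts, not individuals: no microsimulation, no more
  than three states, and no time-varying transition probabilities beyond
  age-dependent mortality.
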