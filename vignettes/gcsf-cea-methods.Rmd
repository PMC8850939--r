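---
title: "Methods: two-model cost-effectiveness analysis of G-CSF prophylaxis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-model cost-effectiveness analysis of G-CSF prophylaxis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gcsfcea)
```

# The decision problem

Primary prophylaxis with granulocyte colony-stimulating factors (G-CSFs)
reduces the incidence of chemotherapy-induced febrile neutropenia (FN).
Two products compete in Chinese practice: a pegylated, long-acting form
given once per chemotherapy cycle (PEG-rhG-CSF, ¥3,315.74/cycle) and a
short-acting form given as a daily course (rhG-CSF, ¥734.34 per 6-day
course). The long-acting product costs roughly 4.5 times more per cycle
but is associated with fewer FN episodes in real-world use. `gcsfcea`
models whether that trade-off is worth paying for, from the Chinese
healthcare-system perspective, in women with stage II–IV breast cancer
receiving four cycles of TC chemotherapy (docetaxel 75 mg/m² +
cyclophosphamide 600 mg/m², every 21 days), with all costs in 2019 CNY.

Two linked Markov cohort models carry the analysis:

1. **Chemotherapy model** — a 12-week model over four 3-week cycles. Each
   cycle a patient on treatment develops FN with probability `p_fn`
   (0.0116 PEG vs 0.0404 rhG per cycle); given FN, an infection follows
   with probability `p_inf_fn` (0.0547 vs 0.547); FN and infection are
   fatal within the cycle with probability 0.034 each, as competing
   within-cycle outcomes; survivors resume chemotherapy. Costs: drugs
   (vial-rounded TC doses), G-CSF, mean per-cycle hospitalization
   (¥14,811.10), plus per-event costs of ¥25,000 for an FN admission and
   ¥50,000 more for an infection. Utilities: 0.70 on chemotherapy, 0.33
   during FN/infection. No discounting at this horizon.
2. **Post-chemotherapy model** — a 35-year annual-cycle survival model.
   FN history raises the probability of having received a reduced
   relative dose intensity (RDI < 85%): 0.500 with an FN history (the
   real-world estimate) versus 0.247 without (age < 65; RR 1.380 at
   ≥ 65). An RDI < 85% worsens survival through a hazard ratio of 1.730
   on breast-cancer-specific mortality. Utilities are 0.86 in years 1–5
   and 0.96 after year 5, discounted at 5%/year; the model carries no
   costs. The 35-year horizon covers a cohort entering at age 45 to near
   the ~80-year Chinese life expectancy.

The models are linked by each arm's course-level FN probability
`1 − (1 − p_fn)⁴`, which sets the RDI split at entry to the survival
model: RDI status is decided by the completed course, so it is fixed at
model-2 entry and never switches.

# Engine conventions

Both models run on a generic discrete-time engine (`run_cohort()`), with
an independent microsimulation oracle (`run_microsim()`) used to validate
it in the test suite.

**Reward timing.** State costs and utilities accrue on the cycle-*start*
occupancy (no half-cycle correction; `half_cycle = TRUE` switches to
averaging the cycle's start and end occupancy). Discounting indexes
cycles from 0: cycle *t* is discounted by $(1+r)^{-t\,\ell}$ with $\ell$
the cycle length in years. A consequence of cycle-start accrual in the
chemotherapy model is that the utility decrement of an FN episode
registers one row after the event transition, and the final cycle's FN
disutility sliver is not accrued; event *costs* and event *counts* are
exact regardless, because they attach to transitions.

**Events as state entries.** Per-event costs (FN admission, infection
treatment) are charged per *entry* into an event state, not per cycle of
occupancy, because they are priced per patient-episode. To make every
episode an observable entry — including a second FN episode in the
immediately following cycle — the FN and infection states are
parity-duplicated (`FNa`/`FNb`, `InfA`/`InfB`): consecutive episodes
alternate copies, so no event ever hides in a self-transition. Fatal
episodes pass through one-cycle tunnel states (`DeadFN`, `DeadInf`)
before absorption in `Dead`, making deaths countable entries too. The
per-1000 event counts are 1000 × the cumulative entries into the
corresponding state groups, and the test suite verifies them to 1e-12
against an exhaustive enumeration of the event tree.

**Hazard-scale hazard ratio.** The survival HR for RDI < 85% is applied
as $q \mapsto 1-(1-q)^{1.73}$ to the annual breast-cancer-specific death
probability. Multiplying probabilities directly would not respect
$q \le 1$ and misreads a hazard-scale quantity.

**Validation tolerances.** Transition rows must sum to 1 within 1e-12
and occupancy rows within 1e-9; absorbing states must self-transition
with probability 1. Discounting closed forms (35-year annuities at
3/5/7%) are verified to 1e-9.

# Choices where the published description is open

Several inputs cannot be taken off the page and required a modelling
decision; each is a documented switch with the stated default.

* **Per-cycle FN reading** (`fn_input_mode = "per_cycle"`). The FN
  baselines are labelled as holding *across* chemotherapy cycles; a
  Markov model needs per-cycle transitions. The default treats them as
  constant per-cycle probabilities; `"per_course"` converts a
  whole-course reading through an even hazard split
  $p_{cycle} = 1-(1-p_{course})^{1/4}$. Neither reading reproduces the
  published per-1000 event counts (which exceed the FN counts for
  infections despite infection being conditioned on FN); the package
  reports its own internally consistent counts.
* **The tenfold infection-risk asymmetry** (0.0547 vs 0.547) is used
  verbatim by default; `equalize_infection_risk = TRUE` sets both arms
  to the rhG value in case the gap is a typesetting artifact.
* **RDI risk with FN history** (`rdi_mode = "measured"`). The directly
  measured 0.500 is the default; `"odds"` instead applies the literature
  odds ratio 1.58 to the no-FN baseline (giving ≈ 0.341).
* **Vial rounding.** Drug costs are per vial (20 mg docetaxel, 0.2 g
  cyclophosphamide), so doses are computed from a default body surface
  area of 1.6 m² and rounded *up* to whole vials: 6 + 5 vials per cycle.
* **Whether "risk of death if infection" replaces or adds to FN death**
  is unstated; it is implemented as the competing (instead-of) outcome.
* **A missing beta parameter.** The PSA distribution for the
  FN-stratum RDI risk prints only β = 191; α = 191 (mean 0.5, matching
  the point estimate) is adopted.
* **Hospitalization-cost interpretation.** The cohort cost moments are
  treated as per single hospitalization, following the wording "total
  costs per hospitalization".

# The synthetic cohort generator

The generator (`generate_cohort()`) emulates the *marginal* statistical
structure of the five-hospital retrospective cohort: 926 PEG / 898 rhG
patients; length of stay 10.47 ± 7.47 vs 8.95 ± 7.88 days; cost per
hospitalization ¥17,079 ± 3,084 vs ¥14,086 ± 335; age 48.80 ± 9.56 vs
48.75 ± 9.96; surgery rates 52.9% vs 40%. Continuous fields are
zero-truncated normals (age truncated at 18, the adult-only inclusion
bound) whose *underlying* parameters are solved so the truncated
distribution carries the profile's mean and SD — at a length of stay of
10.47 ± 7.47 days the naive truncation bias exceeds a full day, so this
correction matters. The implausibly tight printed rhG cost SD (¥335) is
accepted verbatim but is an ordinary profile field.

Quantities the source does not print were fixed once at values realistic
for a Henan tertiary-hospital breast-cancer cohort: insurance mix 60%
urban/rural resident, 30% urban employee, 10% self-pay ("most were urban
and rural residents" is the only published signal); concomitant-disease
counts 0–3+ with probabilities 0.45/0.30/0.17/0.08. The per-course FN
indicator uses `1 − (1 − p_cycle)⁴` from the decision model's own FN
baselines, tying the cohort to the model.

Covariates are independent by default, which makes propensity-score
matching a no-op; `confounded = TRUE` shifts the PEG arm's mean age by
+5 years and tilts its employee-insurance share by +0.15 so the matching
stage has genuine imbalance to correct. What the generator does **not**
emulate: hospital-level clustering across the five sites, covariate
correlations (age × insurance × comorbidity), non-normal cost tails, or
outcome-covariate dependence beyond the arm-level FN rates. Passing
tests therefore show that the pipeline's machinery is correct on data
with this marginal structure — not that the published cohort's joint
distribution is recovered.

Matching itself is greedy 1:1 nearest-neighbour on the propensity score
without replacement, processing treated patients in descending score
order, ties to the lexicographically smallest control id; the optional
caliper is the conventional 0.2 × SD of the logit of the score. The
published matched count (852 pairs) and mean scores (0.52/0.49) are
data-dependent quantities of the original cohort and are echoed for
orientation only; on the synthetic confounded cohort the pipeline
typically retains ~765 of 898 possible pairs under the default caliper.

# The synthetic life table

Registry mortality tables are not published, so the survival model ships
with a synthetic stand-in (`make_life_table()`): Gompertz all-cause
hazard with slope 0.085/yr, level calibrated by `uniroot` so life
expectancy at birth is 80 years; breast-cancer-specific annual excess
mortality of 0.008/0.018/0.034 for stages II/III/IV, mixed equally
(blended 0.02/yr), constant for the first five post-chemotherapy years
and halving every five years thereafter. The absolute per-arm QALY
totals depend on this stand-in and are therefore *not* comparable to the
published per-arm values; every test and reported property (orderings,
monotonicities, closed-form bounds) is chosen to be robust to it. A real
table drops in via `read_life_table_csv()`.

# Sensitivity analysis

**One-way DSA.** Each parameter is varied ±15% of its base value
(probabilities and utilities capped at 1), the survival-model discount
rate is swept 3–7%, and the horizon 25–45 years — the discount and
horizon scenarios are tornado rows like any other. Outcomes are the
chemotherapy-phase incremental cost and the incremental QALYs at a
chosen horizon; entries sort by swing with alphabetical tie-breaks.

**PSA.** 1000 Monte-Carlo draws by default. Probabilities and utilities
are beta; costs and RR/OR/HR gamma. Published shape pairs are used where
they exist — Beta(289, 881), Beta(191, 191), Beta(40, 6), Beta(367, 15)
— and all other distributions are moment-matched with SE = 15% of the
mean, mirroring the DSA convention, because that is the only variance
signal available. Parameters are sampled in fixed alphabetical order so
a seed fully determines the cloud. The CEAC reports
$P(\lambda\,\Delta QALY - \Delta cost > 0)$ over the willingness-to-pay
grid; at 1000 draws its Monte-Carlo error is ±1.5 percentage points, so
bands, not points, are the right reading. The default cloud judges
draws on the combined (chemotherapy + 35-year) QALY horizon with the
chemotherapy-phase cost difference, the survival phase being costless.

# Problem sizes and numerical checks in the test suite

The suite exercises: moment recovery on 10⁴-per-arm cohorts (4 SE);
engine-vs-microsimulation agreement at 10⁵ patients within 4 SE over 20
random 4-state models; exhaustive event-tree enumeration to 1e-12;
35-year annuity closed forms to 1e-9; QALY monotonicity in the discount
rate (3/5/7%); balance improvement on the full-size confounded cohort in
≥ 90% of 50 seeds; published beta means within 1% at 10⁵ draws; a
bitwise base-case check for degenerate (all-fixed) PSA; and a 1000-draw
CEAC. These sizes keep each property statistically sharp while the whole
suite runs in a few minutes on one core.

# Known limitations

* Absolute totals (per-arm cost and QALYs, per-1000 event counts, the
  CEAC level) are *internally consistent* model outputs; the published
  headline totals cannot be decomposed from the published unit inputs,
  and the registry mortality behind the published survival totals is not
  available, so only the incremental arithmetic of the published
  strategy rows and the direction/ordering properties are asserted.
* The cohort generator's independence assumptions (above) limit what the
  matching stage can demonstrate beyond mechanics and balance recovery.
* The survival model has no recurrence/metastasis structure and no
  post-chemotherapy costs, matching the source analysis' scope.
* Semi-Markov features (time-in-state effects) and covariate-dependent
  transitions beyond the RDI split are out of scope.
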