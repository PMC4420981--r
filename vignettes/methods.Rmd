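---
title: "Modelling the health impacts of lower-emission diets: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the health impacts of lower-emission diets: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dietshift)
library(dplyr)
```

# The modelling problem

How much would population health improve if the average national diet were
modified to meet nutritional recommendations while cutting its
greenhouse-gas (GHG) footprint — and how radical would those modifications
have to be? `dietshift` answers this in two stages:

1. **Diet optimisation.** Starting from the current average diet (per sex),
   find the closest acceptable diet that satisfies a nutrient constraint
   set and, optionally, reduces diet-wide GHG emissions by at least a
   target fraction.
2. **Health impact modelling.** Translate the resulting changes in fruit,
   vegetable, red-meat and processed-meat intake into cause-specific
   mortality changes through log-linear relative risks with disease
   time-lag curves, and project them through sex-specific life tables to
   cumulative years of life lost (YLL) averted over 20 and 30 years and the
   change in life expectancy at birth.

# Stage 1: the diet optimiser

## Objective

For baseline consumption $c_i$ (g/day) of food group $i$, the optimiser
minimises the welfare-weighted sum of squared percentage deviations

$$\min_x \; \sum_i w_i \left( 100\,\frac{x_i - c_i}{c_i} \right)^2 ,$$

with weights $w_i = s_i / |e_i|$ (expenditure share over the magnitude of
the own-price elasticity), normalised to mean 1. The weights encode a
simple welfare intuition: foods that absorb a large share of spending and
respond weakly to price are the ones people are least willing to change, so
deviations there are penalised most. The functional form is a package
choice — share and price responsiveness are the inputs the welfare argument
names, and $s/|e|$ is the simplest form monotone in both; `optimise_diet()`
accepts any other positive weight vector via `weights =`.

Whether percentage deviations are expressed on the 0–100 or 0–1 scale only
rescales the objective by $10^4$; it does not move the minimiser. We use
the 0–100 scale, so the "deviation index" reported in sweeps is in squared
percentage points.

## Constraints

* **Nutrient bounds** — lower/upper bounds per nutrient, either absolute
  (e.g. fibre $\ge$ 25 g/day) or as a share of total energy (e.g.
  saturated fat $\le$ 10%E). The shipped default set (`who_constraints()`)
  is inspired by WHO-style population intake goals: total fat ≤ 30%E,
  saturated fat ≤ 10%E, free sugars ≤ 10%E, fibre ≥ 25 g/day, sodium ≤
  2000 mg/day, fruit + vegetables ≥ 400 g/day. It is an editable default
  (YAML round-trip via `read_constraints()`/`write_constraints()`), not an
  authoritative transcription of any guideline.
* **Energy equality** — total kcal/day held at its baseline value, so the
  optimiser cannot "improve" nutrition by eating less overall.
* **Liquid-proportion equality** — the liquid-flagged share of diet *mass*
  held at baseline. Mass is the chosen measure because the flag marks
  beverages, whose consumption is most naturally conserved in grams; the
  constraint is linear in the diet.
* **GHG inequality** — $\sum_i g_i x_i \le (1 - r) \sum_i g_i c_i$ for a
  target fraction $r$. An inequality, not an equality: the cheapest
  nutritionally compliant diet may overshoot the target, and the achieved
  reduction is reported separately. With no target the constraint is
  absent and the *incidental* reduction of the nutrition-only optimum is
  reported.
* **Non-negativity** — $x_i \ge 0$ as a bound; groups may hit zero (and do
  at tight targets: red and processed meat are eliminated first).

## Solver

With linear constraints and a diagonal quadratic objective the problem is
convex. It is solved in percentage-deviation coordinates
$z_i = 100 (x_i - c_i)/c_i$ (perfect conditioning of the quadratic) by an
augmented-Lagrangian method over `stats::optim(method = "L-BFGS-B")` with
analytic gradients; constraint rows are normalised to unit Euclidean norm
so feasibility tolerances compare across units (kcal, mg, kgCO2e). The
solver is run from 8 deterministic starts (the baseline plus fixed
elementwise perturbations) and the best feasible solution is kept; on this
convex problem all starts agree to tolerance, which the test suite asserts.
Defaults: feasibility tolerance `1e-9` on normalised rows, post-solve
verification at `1e-6` relative on every constraint; failure to verify
raises an error naming the most violated constraint, never a silent
partial answer.

The solver is also validated against dense grid search with iterative
refinement on two- and three-food problems, agreeing within 0.5% per
coordinate.

# Stage 2: the health impact model

## Exposure-response

Each pathway links one exposure (fruit, vegetables, red meat, processed
meat) to one mortality cause through a relative risk per reference
increment (g/day). Scaling is log-linear: a change $\Delta$ gives
$RR^{\Delta/\text{inc}}$, so effects compose multiplicatively over
increments, and pathways affecting the same disease multiply together. The
packaged table (`generate_erf_table()`, `inst/extdata/published_erfs.csv`)
holds 17 published meta-analytic pathways (Dauchet et al., Pan et al.,
Micha et al., WCRF) covering coronary heart disease, stroke, type 2
diabetes and five cancers; pathways keep their source increments (80 g and
100 g fruit rows are not re-normalised to a common increment). Central
estimates drive the main analysis — CIs enter only the sensitivity runs,
where the "low-impact" bound is the CI bound nearest 1 on the log scale
and the "high-impact" bound the farther one, for protective and harmful
risks alike. No truncation is applied to extrapolations beyond the
reference increment; the log-linear form is used as-is.

## Time lags

Risk changes phase in following rescaled normal CDFs: cardiometabolic
outcomes (CHD, stroke, type 2 diabetes) reach full effect at 10 years with
no onset delay; cancers have a 10-year onset delay and reach full effect at
30 years. The CDF parameters on the active interval — mean 5 y, sd 2 y
(cardiometabolic); mean 20 y, sd 3.3 y (cancer) — are package defaults
chosen to satisfy those endpoint conditions with a symmetric s-shape on
each interval, and are configurable in `lag_function()`. The curves are
rescaled so the weight is exactly 0 at onset and exactly 1 at full effect.
Between those endpoints the lag interpolates *linearly on the rate scale*:
$M_d(t) = 1 + f_d(t)\,(v_d - 1)$. The geometric alternative
$v_d^{f_d(t)}$ differs only in the third decimal for risks of this size;
the rate-scale convention matches standard life-table impact-assessment
practice.

## Life tables

Sex-specific single-year-of-age life tables use the survival transform
$s = (2 - m)/(2 + m)$ with half-interval person-years (deaths mid-interval
on average). Two consequences worth knowing:

* For a constant hazard the implied life expectancy is exactly $1/m$,
  independent of the time step — the closed-form anchor the tests use.
* The modified all-cause hazard
  $m'(a,t) = m(a) + \sum_d m_d(a)\,f_d(t)\,(v_d - 1)$ can in principle go
  negative only if the cause-specific rates exceed the all-cause rate;
  with valid inputs ($\sum_d m_d \le m$) it cannot, but the engine clips
  at zero with a warning rather than failing silently.

**YLL** is computed on a *closed* population (no future births): the
population is projected annually under baseline and scenario hazards
(lag weights evaluated at mid-year), and YLL averted at horizon $H$ is the
cumulative difference in person-years lived. **Life expectancy at birth**
uses a birth-cohort projection instead: the cohort experiences the lagged
scenario hazards as it ages (time since adoption equals age) and the
open-ended top age interval is closed geometrically at the final rate.
Diets are adopted instantly and underlying mortality rates are held
constant — deliberate simplifications that isolate the dietary effect.

Per-disease YLL rows are attributed by switching on one disease's
multiplier at a time; because hazards interact slightly, these sum to the
joint total only approximately (within 5% on the default fixture, asserted
in tests). The joint-run total is the headline number.

# The synthetic inputs

No survey microdata, life-cycle inventory or national mortality file ships
with the package; `synth_config()` + the three generators produce inputs
with the statistical structure the analysis assumes, so the whole pipeline
is testable offline.

* **Food table** (42 groups/sex): a fixed catalogue of named groups with
  order-of-magnitude-realistic consumption, per-gram composition, GHG
  intensity (with low/central/high variants at roughly 0.6–0.8× and
  1.25–1.55× central), price-based expenditure shares and elasticities in
  (−2, −0.05), given a small seeded log-normal jitter. Magnitudes were
  chosen once for realism: male energy ≈ 2,500 kcal/day, diet footprint
  ≈ 4.8 kgCO2e/day with ruminant meat the most intensive group and
  vegetables cheaper than fruit in emissions, fruit ≈ 137 (men) / 145
  (women) g/day, and a baseline that breaches the default fat, saturated
  fat, free-sugar, fibre, sodium and fruit-and-vegetable constraints — so
  the optimiser has realistic work to do and the optimised diets shift
  from fruit towards vegetables as emission targets tighten.
* **Population table**: Gompertz–Makeham all-cause mortality with an
  infant bump, sex-specific levels (period life expectancies near 78/82
  years), a closing rate of 1 at age 100; cause-specific rates are smooth
  age-dependent fractions of the all-cause rate, guaranteeing
  $\sum_d m_d \le m$ by construction; populations are the stationary
  population of the same schedule scaled to ~32 million per sex.
* **ERF table**: the packaged published pathways by default, or a random
  structurally valid table for stress tests.

What the generators do **not** emulate: dietary survey measurement error
and under-reporting, covariance between nutrient composition and price,
cohort trends in mortality, migration, and future births. A green test
suite on these fixtures therefore demonstrates correctness of the
machinery and its qualitative behaviour (feasibility, monotonicity,
direction and rough scale of effects), not quantitative fidelity to any
real national analysis.

# The scenario sweep

```{r sweep, eval = FALSE}
cfg <- synth_config(seed = 1)
food <- generate_food_table(cfg)
pop <- generate_population_table(cfg)
erfs <- generate_erf_table(cfg)

sw <- run_sweep(food, who_constraints(), erfs, pop)
tidy(sw)
autoplot(sw)
```

`run_sweep()` runs targets none, 10–60% end to end; per-target failures are
recorded in the summary, never dropped. Population totals sum the two
sexes; the population achieved reduction is the equal-weighted mean of the
per-sex reductions. The per-target "deviation index" is the optimiser
objective at the solution — on the default fixture it stays relatively
flat to 40% and then grows steeply, the acceptability pattern the sweep is
designed to expose. `run_parameter_sensitivity()` brackets the 20%-target
impacts with the low/high GHG variants combined with the near/far RR
bounds; `run_structural_sensitivity()` reruns the sweep counting only
fruit or only vegetable effects (a guard against double counting, since
the independence of fruit and vegetable effects is uncertain; lung cancer,
a fruit-only pathway, vanishes entirely in the vegetables-only variant).

## Problem sizes and runtime

The default configuration — 42 food groups × 2 sexes, ages 0–100, 8
diseases, 7 targets, 8 solver starts — runs the full sweep in well under a
minute; these sizes match the structure the analysis is designed around
and are comfortable on a single core.

# Known limitations

* Mortality only; no morbidity, so total health benefits are understated.
* Saturated-fat pathways to heart disease are deliberately excluded
  (confounded with the modelled meat pathways).
* Baseline mortality is frozen at current rates; real secular declines
  would change absolute YLL.
* The welfare weighting is a reduced form — no demand system, no price or
  income feedbacks, no individual-level heterogeneity around the average
  diet.
* A single CO2e metric aggregates gases with different time profiles;
  alternative climate metrics would reweight food groups.
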