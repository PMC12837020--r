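---
title: "Methods: a prevalence-based cost-of-illness model for diabetic eye disease"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a prevalence-based cost-of-illness model for diabetic eye disease}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coivis)
```

## Scope and perspective

`coivis` implements a deterministic, prevalence-based cost-of-illness
model: all existing cases of diabetes-related visual impairment and
blindness in one year are costed from a societal perspective. There is
no discounting and no multi-year projection — the horizon is a single
year — and uncertainty is handled exclusively by one-way deterministic
sensitivity analysis, not by probabilistic simulation. The model is an
accounting identity over a declarative parameter file; given the same
configuration it always produces the same numbers.

## The population cascade

Severity is graded on the Scottish system: retinopathy R1 (mild
non-proliferative) through R4 (proliferative), maculopathy M1 and M2,
with R4 and M2 treated as sight-threatening, plus a separately counted
blind population. The cascade is:

1. adults ≥ 35 years × diabetic prevalence → diabetic adults;
2. diabetic adults × blindness prevalence → blind;
3. diabetic adults × any-retinopathy, any-maculopathy, and combined
   (retinopathy and/or maculopathy) prevalences → the three overlap
   counts;
4. correction factor `CF = combined / (retinopathy + maculopathy)`,
   a fraction in (0, 1] that removes double-counting of patients with
   both conditions;
5. per-grade counts `p_g × diabetic adults × CF` for the six R/M grades.

Counts remain fractional persons throughout; rounding only happens in
printed reports. The correction factor deliberately does **not** apply
to the blind population, which is counted through its own prevalence.
In the bundled national configuration the six grade prevalences
partition the parent prevalences exactly (R1+R2+R3+R4 = any
retinopathy; M1+M2 = any maculopathy), but the model does not impose
that identity: each grade prevalence is an independent input.

A degenerate cascade (no retinopathy and no maculopathy) defines
`CF = 1`, so zero-prevalence configurations remain valid and cost zero.

## Direct medical costs

Each grade carries a *treatment protocol*: a list of lines
`(item, frequency, multiplicity)` priced against a unit-cost registry.
Frequencies are annualized as events/year: every *n* weeks → 52/*n*
(so the 4-weekly anti-VEGF schedule contributes 13 injections/year, not
12 — the schedule is stated in weeks and a year has 52 of them), every
*n* months → 12/*n*, a one-off at diagnosis → 1 within the one-year
horizon, and `per_year` carries an explicit count. `multiplicity`
(default 1) is the explicit knob for per-eye versus per-patient dosing;
the bundled configuration uses 1 throughout because bilaterality rates
are not part of its source data.

Design choices a reader should know about, all config-overridable:

* **Injection administration.** The intravitreal-injection facility fee
  is charged alongside each anti-VEGF *and* each triamcinolone
  administration, in addition to drug acquisition.
* **Monitoring cadence.** The R grades carry their test bundle (OCT,
  ophthalmologist visit, fundoscopy, visual field + dilating drops,
  visual acuity, fluorescein angiography) every 3 months,
  post-vitrectomy; M1/M2 carry OCT quarterly, the visit bundle monthly,
  and angiography once at diagnosis. Laser photocoagulation follows the
  grade's bundle cadence: quarterly for R3/R4, monthly for M2.
* **Vitrectomy** is part of the R1/R2 protocol only, taken literally
  from the clinical pathway the configuration encodes; consequently the
  cataract-after-vitrectomy adverse event applies to R1/R2 only.

*Adverse events* are costed as expectations — probability × annual cost
of the management bundle — never simulated; in a deterministic model
the expected value is the only coherent choice. The endophthalmitis
bundle defaults to intravitreal-strength vancomycin 500 mg +
ceftazidime 1 g + aqueous/vitreous sampling + 3 hospitalization days;
retinal detachment to vitrectomy + 3 hospitalization days; cataract
surgery to phacoemulsification + intraocular lens + the standard
pre-operative workup items. These bundles are explicit configuration so
that a user with local itemizations can replace them. Several registry
items (e.g. the non-intravitreal antibiotic strengths, IOP measurement,
gonioscopy) are intentionally present but unused by the default
protocols; they are available to overrides and serve as natural
zero-influence controls in the sensitivity analysis.

*Supportive care* follows severity flags: visual aids (3,000 SAR/year)
for R1, R2, M1 and R3; psychological support and a home-care nurse
(37,000 SAR/year) for R4, M2 and the blind. The psychologist-visit
frequency is not fixed by the source material; the default is monthly
(12 × 345 SAR), set once under `supportive_settings`.

The same money is partitioned two ways — six components (medication,
surgery/resources, adverse events, psychological, visual aids, home
nurse) and per grade — and the engine guarantees the partition identity.

## Indirect costs

The human capital method values lost production as
`persons × employment rate × absent days × daily wage`. Absenteeism is
14/21/28 days per year for mild/moderate/severe impairment and 261 days
for sight-threatening disease; the 80% employment rate attenuates all
patient losses, including the sight-threatening tier, for internal
consistency (the alternative — exempting the 261-day tier from the
employment rate — has no support in the source assumptions and would
value non-workers' absence). Caregivers of moderate (10 days) and
severe (28 days) patients are costed at full employment, since no
caregiver employment rate is part of the model.

Two wage tiers are used. Severe, sight-threatening and blind
individuals use the stated salary of SAR 4,000/month over 22 working
days/month (≈ 181.82 SAR/day). Mild/moderate patients and all
caregivers use a general daily wage that the source material defines
only as GDP-derived; the bundled default is **437 SAR/day**, an
estimate obtained as GDP (≈ SAR 4.155 × 10¹² for 2022) divided by
population (≈ 36.0 million) and by 264 working days/year. It is a
config scalar (`productivity.daily_wage_general_sar`), flagged here as
an estimate.

Government disability pensions are transfers counted for
pension-flagged grades (R4, M2, blind). No published annual pension
amount accompanies the model's other inputs; the bundled default of
**SAR 48,000/year** (4,000/month) is consistent with published Saudi
disability-benefit levels and with the pension aggregate the national
configuration is meant to represent. It is a required config scalar
with no universal default.

The blind population's default profile is supportive care + pension
only (absenteeism 0): the blind count is not part of the treated R/M
cascade, and attributing treatment protocols or absenteeism to it would
double-count the sight-threatening grades.

## Aggregation and currency

Totals are exact sums of the component breakdowns; direct + indirect
shares are stored at full precision and printed at 0 decimals.
Conversion to international dollars divides by the PPP rate
(SAR 1.85 / I$ in the bundled configuration; `derive_ppp_rate()`
recovers the rate from printed SAR/I$ pairs as the median of the
ratios, robust to rounding of individual pairs). The GDP share divides
the grand total by the configured GDP (default SAR 10 × 10¹²). When the
total is zero, shares are reported as 0 with a `degenerate` flag rather
than NaN.

## One-way sensitivity analysis

Every numeric scalar leaf of the configuration — prevalences, unit
costs, probabilities, frequencies, day counts, wages, rates — is
perturbed multiplicatively by ±20% (the `fraction` argument), the whole
pipeline is recomputed from the cascade down with no cached
intermediates, and parameters are ranked by the output span
`|high − low|`, ties broken alphabetically. Fractions and probabilities
clamp at 1 with a recorded flag rather than erroring; other leaves are
unbounded. The default scope is *all* eligible leaves; a configuration
can restrict it with an `owsa:` block (`include`/`exclude` path lists),
since which inputs belong in a given sensitivity analysis is an
analytical choice, not a property of the model.

Structure dictates the broad shape of the ranking: parameters that
scale the entire cascade linearly (adult population, diabetic
prevalence) produce a span of exactly 0.4 × the grade-driven total and
therefore bound from above any parameter that acts through a subset of
grades, while the any-retinopathy and any-maculopathy prevalences act
*only* through the correction factor's denominator — increasing them
shrinks every corrected grade. The combined prevalence scales all
corrected grades through the numerator. The acceptance suite records
where each of these lands on the bundled configuration.

## Synthetic scenarios and the oracle

`generate_scenario()` emits seeded, structurally valid configurations:
grade prevalences drawn to sum below 1 and defining the parent
prevalences, the combined prevalence drawn inside
`[max(ret, mac), ret + mac]` so the correction factor is always valid,
log-uniform unit costs around a chosen scale, protocols mixing all four
frequency kinds, adverse-event probabilities in [0, 0.5], and
productivity days in [0, 300]. A private RNG stream is seeded per call
and the global RNG state is restored, so scenarios are reproducible and
non-invasive. Degenerate cases (no items, zero prevalence, single
grade) are constructible on demand.

`oracle_total()` recomputes a configuration's total burden by a
deliberately naive enumeration — nested loops with inline arithmetic,
no code shared with the engines — and the test suite requires pipeline
and oracle to agree within 1e-9 relative across 100 seeded scenarios.
Scenarios emulate the model's *structure* (cascade, protocols, costing
rules), not national magnitudes or epidemiological realism: a passing
suite demonstrates the arithmetic is right, not that any particular
configuration reflects a real population.

## Numerical choices

* Money is held in SAR doubles at full precision; magnitudes up to
  ~10¹² are far inside exact double range. Rounding to 2 decimals
  happens only in CSV reports.
* YAML serialization writes 15 significant digits, making a
  load/write/load cycle value-identical for the bundled configuration;
  JSON round-trips at full precision.
* An unquoted YAML key `n` resolves to boolean `FALSE` under YAML 1.1;
  the loader accepts both the quoted and the misparsed form of the
  frequency interval.
* Problem sizes in the checks are small by construction (a 7-grade
  cascade, ≤ a few hundred sensitivity paths, 100 synthetic scenarios),
  so the full suite runs in seconds.

## Limitations

* Per-patient multiplicity (bilateral treatment), local visit-frequency
  variation, transportation and rehabilitation aids are outside the
  bundled configuration; the first two are expressible through the
  schema, the last two are not modelled.
* The general daily wage and the annual pension are estimates supplied
  as configuration, not published unit costs.
* Prevalence uncertainty is explored only through ±20% one-way
  perturbation; no probabilistic sensitivity analysis is provided.
* The friction-cost alternative to the human capital method is not
  implemented.
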