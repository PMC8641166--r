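---
title: "Methods: a patient-level real-world cost model for AF anticoagulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a patient-level real-world cost model for AF anticoagulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(afcost)
```

## What the model computes

`afcost` estimates the annual atrial-fibrillation-related cost of warfarin
versus DOAC therapy per patient, from two payer perspectives, over a fixed
365-day window (1 June 2017 – 31 May 2018). The patient side of a
patient-day sums four components — INR-monitoring time cost, direct therapy
cost (daily drug price plus ceiling-capped customer fees), travel time
cost, and travel cost — and the healthcare side sums visit and ward
accounting costs, the society drug share, society-paid travel
reimbursements and a fixed €31 per INR monitoring. Annual group averages
are arithmetic means over all of an arm's patients, zero-activity patients
included.

The assumptions baked in:

* **Time is money only for monitoring and travel.** Other contact time
  (waiting at a ward, the visit itself) is not valued, and neither is time
  spent hospitalised — hospitalisation is complication-driven, not part of
  performing the therapy.
* **A step-function value of time.** Working-age patients (< 65) lose the
  full postal-area hourly wage; retired patients (≥ 65) lose 35% of it. The
  main-text convention (65 counts as retired) wins over the price-list
  table's ambiguous "(age <= 65)" print; `wage_age_threshold` is a config
  override.
* **Routing is time-optimal on an undirected road network.** Per-edge speed
  is `min(speed limit, mode cap)` — walking 4 km/h, bus 30 km/h, motor
  vehicles at the limit. No one-way streets, congestion or timetables.
* **INR monitorings route to the *closest* laboratory** (recorded lab
  addresses are unreliable); other contacts route to their recorded
  facility. "Closest" is measured in car-profile fastest time, because time
  is the model's routing criterion; ties break on the lowest facility id.

## Fixed parameters

`cost_parameters()` carries the 2017–2018 Finnish price level: `t_m = 0.5 h`
per INR monitoring; parking/service penalty `t_a = 0.083 h` per car/taxi
leg; car €0.43/km; taxi €5.9 + €1.59/km; bus fares €2.00/3.80/5.00; patient
fees €20.6 (primary physician visit; €11.4 selects the nurse tariff),
€41.2 (specialised and emergency visits), €48.9/ward-day; €31 per INR
monitoring to the payer; payment ceiling €683/year; daily drug prices
€0.08/€0.05 (warfarin, patient/society) and €0.95/€1.76 (DOAC, the
apixaban-like point of the €0.95–1.00 / €1.76–1.87 ranges). The
patient/society drug split is cross-checked against the reimbursement rates
(basic 40% for warfarin, lower special 65% for DOACs) with a 0.02
tolerance; deviations warn rather than fail, since printed daily prices are
themselves rounded.

Values the source did not fix, chosen once and documented here:

* **Bus fare band thresholds** (0–15 km → €2.00, 15–40 → €3.80, > 40 →
  €5.00): only the three fares are given; the cut-points are regional-fare
  plausible.
* **Home INR measurements**: €12 home-care fee to the patient
  (ceiling-eligible) and €45 extra home-care visit cost to the payer, on
  top of the €31 test cost. Both are config fields; the source states only
  that such fees exist.
* **Phone consultations**: free for the patient, standard-price cost to the
  payer (generator default €15), never generating a journey.
* **Ceiling scope**: only healthcare customer fees count toward €683 —
  drugs and travel have their own reimbursement channels.

## The dimensional fix in the time-cost equation

The printed car/taxi time-cost equation reads `p_a c_t t_j + t_a`, which
adds hours to euros. Since `t_a` is explicitly a *time* ("parking time for
car or service time for taxi"), the package implements
`p_a · c_h · (t_j + t_a)` per leg — dimensionally consistent and the only
reading under which the penalty has the stated meaning. Each leg of a
roundtrip carries its own penalty.

## Travel modes and the daily trip limiter

`assign_travel_mode()` is a total, deterministic rule cascade:
reimbursement-recorded mode ≻ taxi at age ≥ 90 ≻ walking (≤ 1.25 km under
80; ≤ 0.25 km at 80–89) ≻ bus (> 1.25 km, bus-accessible destination, stop
within 0.25 km, age < 80) ≻ car. Ambulance is never inferred — it exists
only where an urgent visit carries an ambulance reimbursement record.
Patients aged 80–89 beyond 0.25 km drive: the bus rule requires age < 80.
Bus journeys add the stop-access distance walked at 4 km/h to the leg's
travel time (the source says stop access is "considered" without detail).

`daily_trip_plan()` caps each patient-day at two roundtrips (four one-way
legs). Readings where the published combination table is silent:

* A **one-day ward stay** is both a first and a last ward day: entry + exit
  one-way legs.
* Outpatient/INR contacts on a ward-transition day add a roundtrip only at
  a *different* care level; same-level visits are chained into the ward
  legs. INR during any inpatient involvement never generates a trip —
  but still accrues the monitoring time cost and the €31 payer cost, since
  published monitoring counts include in-hospital measurements.
* An INR + specialised-visit day is one roundtrip (hospitals have
  laboratories); INR at two distinct locations on one day is two.
* Two-roundtrip days route each destination independently from home;
  intra-day facility-to-facility chaining is not modelled.

## The synthetic world

The generators emulate the published cohort: arms of 3171/829 patients,
ages 76.0 ± 9.2 / 72.7 ± 9.8, ~47% women, postal-area income ≈ €12/h,
INR counts 17.5 ± 9.9 / 0.1 ± 0.9 per year, sparse primary/specialised
visits and ward days, complication probabilities matching the published
event counts, distance-to-laboratory 5.5 ± 7.6 km, ~72%/69% urban, and
reimbursement records covering ~5% of eligible contacts (taxi-dominant,
ambulance for urgent episodes).

Distributional forms are implementation choices, flagged as such:

* **Counts are negative binomial**, parameterised directly by the published
  (mean, SD) pairs — every published utilisation SD exceeds its mean (e.g.
  0.7 ± 1.5), so Poisson is untenable; under-dispersed configs fall back to
  Poisson. INR dates are evenly spaced with jitter (routine monitoring);
  other visit dates are uniform.
* **Geography is radial-spoke town clusters**: satellite nodes sit on
  spokes at radial distances drawn as stratified *conditional-mean* strata
  of the lognormal matched to 5.5 ± 7.6 km (midpoint quantiles would bias
  the heavy-tailed mean low by ~4%), so network distance to the
  cluster-centre laboratory equals the drawn radius. Patients draw a target
  distance from the same lognormal and take the node that matches it;
  the urban flag couples to the short-distance end of the same draw.
  Cluster centres join by a minimum-spanning-tree of trunk roads; speed
  limits grow with edge length (40 km/h streets to 100 km/h trunks).
* **All randomness flows from one seed** through named child streams per
  generator, so adding a generator never perturbs another's output, and a
  fixed (config, seed) pair is bit-reproducible.

What the synthetic world does **not** reproduce, and hence what a green
test does not establish: real contact-date clustering (synthetic visit
dates are independent, so same-day chaining is rarer and post-limiter
travel counts run *higher* than the published 13.2/year — the limiter's cap
is exercised, its real-world savings magnitude is not); the real road
network and the resulting travel-cost levels; accounting-cost heterogeneity
beyond a lognormal around plausible unit costs (chosen so rate × unit cost
matches the published per-arm component scale, e.g. 0.2 visits × €65 ≈
€12.7/year); and the published healthcare totals, whose component cells do
not quite sum in the source (the model therefore reports an explicit
`other_society` residual so its own tables are internally additive).

## Numerical and reporting choices

* Money is computed in double precision and rounded only at print (one
  decimal, matching the published table style); additivity identities
  (`c_p = c_m + c_a + c_t + c_d`, annual = Σ daily) are exact, not
  tolerance-based.
* The payment ceiling is order-dependent; fees process per patient in date
  order and out-of-order stateful calls error.
* Confidence intervals are `mean ± 1.96 · sd/√s`; the cost-difference
  p-value defaults to an unequal-variance normal z-test (the source says
  only "based on normal distributions"); a Welch t-test is config-exposed
  (`p_method = "t"`). Degenerate components print SD 0.0.
* Prescription continuity tolerates a configurable gap (default 0 days)
  between intervals; switching therapies mid-span excludes the patient,
  while *overlapping* prescriptions of both drug classes raise a
  data-integrity error instead of guessing.
* Episode linkage for the stroke/haemorrhage ward+urgent filter groups
  same-patient, same-diagnosis contacts whose dates lie within one day.

## Known limitations

Annual warfarin drug cells published elsewhere (€27.0/€18.0) are not 365 ×
the daily prices (€29.2/€18.25); the engine uses the configured daily
prices and leaves that discrepancy alone. All-cause (non-AF) fees do not
accrue toward the ceiling. Warfarin dosing is price-averaged. The two-arm
comparison is unadjusted — no regression on age or geography, by design.
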