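---
title: "Simulating land clearing under cascade-rule caps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating land clearing under cascade-rule caps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cascadr)
```

## The model

`cascadr` models a catchment as a purely tabular landscape: atomic land
units, each a unique combination of property, sub-catchment, vegetation
type and suitability index, carrying an area in hectares and three flags
(buffered, protected, existing-cleared). No geometry is retained — the
cascade rules operate on areas and shared membership, never on adjacency —
so the tabular form is exact, not an approximation.

Clearing proceeds property by property. Each replicate run:

1. orders all properties by the scenario rule (uniform shuffle;
   non-aboriginal before aboriginal sorted by size, descending or
   ascending; or descending area-weighted mean suitability);
2. draws each property's *total* cleared-fraction target from
   U(0.30, 0.70) — a property whose existing clearing already meets its
   draw clears nothing new;
3. clears the property's clearable units (not buffered, not protected, not
   already cleared, suitability > 0) in strictly decreasing suitability,
   taking from each unit the minimum of its area, the remaining target,
   and the cap headrooms `max(0, cap × baseline − cleared)` of the unit's
   property (cap 0.70 of total property area), sub-catchment (0.40 of
   sub-catchment area), vegetation type (0.30 of *pre-clearing* extent)
   and, depending on the overshoot mode, the catchment (0.20);
4. stops the run at the catchment cap, or after every property when the
   caps are disabled.

Existing clearing counts toward every accumulator and every denominator.
That single choice produces grandfathering for free: a sub-catchment that
starts 60% cleared has negative headroom, receives nothing, and reports the
same percentage in every scenario, while its existing clearing still
consumes part of the catchment allowance.

### Assumptions inherited from the policy setting

* Owners clear most-suitable land first (profit maximisation); partial
  clearing of a unit is allowed where a target or cap intervenes, so caps
  are met exactly rather than quantised to unit boundaries.
* The property cap's denominator is the *whole* property, including
  buffered, protected and unsuitable land (the policy states a flat 70%
  with no qualifier).
* Vegetation-type caps are measured against pre-clearing extents. Since
  fine-scale (98-type) mapping has no pre-clearing product, existing
  clearing known at the 15-group level is allocated to types
  proportionally to type extent (`allocate_group_clearing()`), i.e.
  clearing is assumed uniform across the types of a group.
* Government land behaves as "non-aboriginal" wherever orderings or
  summaries distinguish only two tenures.
* Ad-hoc buffer-zone exemption approvals are not modelled; buffers are
  absolute.

### Overshoot at the catchment cap

Two readings of "stop at 20%" are supported. In
`complete_last_property` mode (default) the catchment headroom is *not*
part of the per-unit minimum; the run stops after the first property whose
clearing crosses the cap, so totals land slightly above 20% — matching how
a permit-by-permit process overshoots, and how reported totals (20.2–20.7%)
behave. In `truncate` mode the catchment headroom enters the per-unit
minimum and the final clearing event is cut exactly at the cap; this is the
mode used for strict-bound verification, where the total is exactly 20%
whenever clearable land suffices.

Within a property, the cap check is per unit (headroom recomputed before
each take). Formulating it this way subsumes both "check before" and
"check after" readings of the clearing algorithm: a unit with zero headroom
is skipped and processing continues with the next-most-suitable unit.

## Randomness and reproducibility

All stochasticity flows from integer seeds. Per-run ordering uses a stream
seeded by `(seed, run_index, "order")`; each property's target draw uses
`(seed, run_index, prop_id, "target")`. Draws therefore do not depend on
how the iteration is refactored or where a run stopped, and any single run
is reproducible in isolation. Sub-seeds are reduced modulo a prime below
2^31 so they remain valid R integers.

## The synthetic landscape

The real inputs (cadastre, vegetation site mapping, land-suitability
mapping) are government GIS layers that are not redistributable, so the
package generates landscapes with the published statistical structure. The
defaults are the stated world, not tuning knobs:

| Quantity | Default | Basis |
|---|---|---|
| Catchment area | 5.2 Mha | catchment extent |
| Protected fraction | 0.13 | national parks + indigenous protected areas |
| Tenure of available land | 10/30/60 gov/aboriginal/private | published split |
| Properties | 473, 100–400,000 ha | cadastre membership count; size range |
| Sub-catchments | 16 | hydrological subdivisions |
| Vegetation | 98 types in 15 groups | vegetation site mapping |
| Existing clearing | 5.4% of catchment; per-property 1–100%, mean 25% | reported levels |
| Suitability | 0–400; catchment mean ≈ 178 | suitability index statistics |

Three defaults are the package's own choices where no figure is published,
made once and documented rather than revisited:

* **Buffered fraction 0.08** of the catchment. Buffers are mapped but no
  area statistic is printed. 8% makes unprotected, unbuffered, suitable
  land come to ≈ 49.4% of the catchment
  (0.87 × 0.908 × 0.625), which is exactly the published clearable
  complement (44% potential + 5.4% existing).
* **Unsuitable fraction 0.375** of unprotected, unbuffered land has
  suitability 0, with suitable land scored by a Beta law with mean 285 —
  jointly chosen so the area-weighted catchment mean is ≈ 178 and the
  clearable complement above holds.
* **Property-size law**: log-normal (σ_log = 1.6) truncated to
  [100, 400,000] ha. The stated 15,000 ha mean is used to shape the law,
  but 473 properties tiling 5.2 Mha *force* a mean of ~11,000 ha
  (5.2e6/473); draws are rescaled above the 100 ha floor to tile the
  catchment exactly, because area conservation is a hard invariant of the
  data model. The realized ~11,000 ha mean matches the published
  whole-population (private-property) average of ~10,500 ha; the 15,000 ha
  figure describes the guideline-subject subset. `audit_landscape()`
  therefore audits mean size against the budget-consistent target
  `area/n`.

Structure the generator does reproduce: heavy-tailed sizes (a handful of
>100,000 ha stations), properties straddling up to two sub-catchments,
Dirichlet sub-catchment areas with a wide spread, whole-property reserves,
tenure quotas filled largest-first, every vegetation type present, and
per-property cleared fractions on [0.01, 1] averaging 0.25 — which implies
a few properties start above the 70% property cap and several vegetation
types above 30%, exercising grandfathering in realistic ways.

What it deliberately does not reproduce: the actual map (no spatial
autocorrelation in suitability or vegetation — the algorithm never uses
adjacency), the exact per-sub-catchment composition of the real catchment,
and any correlation between tenure and land quality. A green test on a
synthetic landscape therefore establishes that the *mechanism* (caps,
grandfathering, ordering effects, conservation of area) is correct, not
that any specific real-world percentage is predicted.

## Numerical choices

* Areas are double-precision hectares; every conservation and cap
  comparison uses relative tolerance 1e-6; clearing events smaller than
  1e-9 of a property are suppressed.
* Suitability is integer 0–400 and units are keyed on exact values; ties
  within a property break by ascending vegetation type then unit id, so
  event streams are fully deterministic.
* Ordering ties (equal size or equal mean suitability) break by ascending
  property id.
* The across-type SD of percentage cleared uses the population divisor
  (n), switchable to the sample divisor; with 98 types the difference is
  ~0.5%.
* "Average size of properties with clearing" is computed per run and then
  averaged across runs (run-then-average), matching per-scenario averaging
  of replicates; runs in which no property cleared are dropped from that
  average.
* Spearman correlations use average ranks for ties; a constant vector's
  correlation is reported as `NA` rather than 0.

## Degenerate inputs

A property whose units are all buffered or unsuitable is ordered and
drawn like any other but contributes no events. Vegetation types with zero
pre-clearing extent are excluded from percentage tables with a warning. An
infeasible generator configuration (e.g. minimum property sizes exceeding
the catchment) fails at construction, not generation.

## A small worked check

The `capbound` fixture encodes the grandfathering story in 5,000 ha: its
first sub-catchment starts 60% cleared (over the 40% cap) and must appear
unchanged in every scenario, while the second remains open.

```{r capbound}
cb <- generate_fixture("capbound")
res <- run_scenario(cb, cap_policy(overshoot_mode = "truncate"),
                    scenario_spec("random", n_runs = 5, seed = 1))
percent_cleared_by_subcatchment(res, cb)
```

## Known limitations

* No temporal dynamics: the simulation is an end-state allocation, not a
  rate model; "order" stands in for time.
* No behavioural or economic model beyond the suitability ordering and the
  uniform target band; assessment costs enter only through the
  size-ordered scenarios' rationale.
* Equity findings on synthetic landscapes depend on the assumed
  independence of tenure and land quality; with real data that correlation
  may dominate.
* The unconstrained scenario retains buffers and reserves; it measures cap
  removal, not complete deregulation.
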