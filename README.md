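# cascadr

Stochastic simulation of land clearing under nested "cascade rule" caps, as
applied in the Daly River catchment (Northern Territory, Australia).

## The problem

The Daly catchment (~5.2 Mha of largely intact tropical savanna) is under
pressure for agricultural development. Its clearing guidelines control
conversion through a hierarchy of percentage caps on the cleared fraction of
nested features, plus prohibited riparian buffer zones:

| Feature          | Cap |
|------------------|-----|
| Stream / wetland / rainforest / river buffers | clearing prohibited |
| Property         | 70% |
| Sub-catchment    | 40% |
| Vegetation type  | 30% |
| Whole catchment  | 20% |

Once a feature reaches its cap, no further clearing of that feature is
allowed; features already beyond a cap (e.g. a sub-catchment 60% cleared
before the rules existed) are *grandfathered* — they keep their clearing but
gain none. Because the caps are nested, the *order* in which properties take
up their clearing entitlements decides who gets to clear at all: a few large
early movers can exhaust a sub-catchment's or the catchment's allowance and
lock everyone else out. That makes cap policies an equity question as much
as a conservation one — particularly between aboriginal land (about a
quarter of the available area, with no short-term development plans) and
private pastoral land.

`cascadr` simulates this process for conservation planners and policy
analysts. Each replicate run orders properties by a scenario rule (random;
non-aboriginal largest first; non-aboriginal smallest first; or directed by
land suitability), draws each property's clearing target from
U(30%, 70%), and clears that property's land units in order of decreasing
suitability index (a 0–400 score summing percentage suitability for four
land uses) under a cap ledger, until targets, caps or clearable land run
out. An unconstrained variant disables the percentage caps (buffers and
reserves still apply) to quantify what the guidelines prevent.

Because the underlying cadastre and vegetation GIS layers are not public,
the package includes a seeded synthetic-landscape generator that reproduces
the catchment's published statistical structure (~473 properties of
100–400,000 ha, 16 sub-catchments, 98 vegetation types in 15 groups, 13%
protected, 5.4% already cleared, mean suitability ~178), and small
hand-specified fixtures for exact oracle tests.

## Worked example

```r
library(cascadr)

L <- generate_landscape(generator_config(seed = 1))
L
#> <landscape>
#>   catchment area : 5200000 ha
#>   units          : 5986
#>   properties     : 473
#>   sub-catchments : 16
#>   veg types      : 98 in 15 groups
#>   existing cleared: 5.40%

res <- run_scenario(L, cap_policy(overshoot_mode = "truncate"),
                    scenario_spec("random", n_runs = 20, seed = 1))
res
#> <scenario_result> ordering=random, constrained, 20 runs
#>   mean new clearing: 759200 ha; mean total cleared: 20.00%

as.data.frame(round(summarize_properties(res, L), 1))
#>   avg_n_properties_with_clearing avg_size_of_clearing_properties_ha
#> 1                          210.9                            10373.8
#>   avg_total_new_cleared_ha avg_cleared_aboriginal_ha
#> 1                   759200                  232064.5
#>   avg_cleared_nonaboriginal_ha avg_selected_property_suitability
#> 1                     527135.5                             174.9
```

On average ~211 properties share 759,200 ha of new clearing before the
catchment reaches its 20% cap (5.4% existing + 14.6% new); under random
ordering aboriginal properties capture ~31% of the new clearing, close to
their share of available land. Per-feature outcomes:

```r
head(percent_cleared_by_subcatchment(res, L), 5)
#>   sc_id current_pct avg_pct
#> 1 SC01        2.52    21.5
#> 2 SC02        0.612    6.59
#> 3 SC03        2.06    19.8
#> 4 SC04       31.9     36.3
#> 5 SC05        5.95    22.5

vegtype_summary(percent_cleared_by_vegtype(res, L))
#>   n_types mean_pct sd_pct
#> 1      98     19.9   6.85

single_property_share(400000, 5200000)
#>   pct_of_catchment pct_of_catchment_cap
#> 1             5.38                 26.9
```

The last line is the policy's built-in inequity in one number: the largest
property alone, clearing its 70%, would use ~5% of the catchment — over a
quarter of the entire 20% catchment allowance.

Scenario results compose with the tidyverse: `tidy(res)` gives per-run
totals, `glance(res)` scenario averages, `autoplot(res)` the distribution of
cleared fractions, and `spearman_matrix()` compares per-vegetation-type
outcomes between scenarios. `cmd_generate()` / `cmd_simulate()` /
`cmd_report()` (or `inst/cli/cascadr.R`) run the same pipeline against CSV
directories with reproducibility manifests.

## Acceptance script

`scripts/acceptance.R` regenerates the default landscape, executes 100
constrained random-order replicates with the catchment-cap stop in truncate
mode, and writes the extreme realized cleared fractions (catchment,
property, sub-catchment) and the minimum of 10,000 property-target draws to
JSON — the quantities that verify the simulator never breaches the caps or
the target band:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
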