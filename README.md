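# coldroute

Single-day delivery route optimization for cold-chain and ambient health
products.

In many low- and middle-income health systems, delivery routes from a
distribution warehouse to health facilities are drawn by hand and adjusted
at the last minute to whatever vehicles and roads are usable that day.
Vaccines are most at risk of temperature excursions while in transit, so a
good route is not just a short one: it also avoids rough roads and
unreliable vehicles. `coldroute` is a decision-support tool for the
logisticians who plan these distributions, for routine operations and for
emergencies (floods, cyclones, outbreaks) when depots move, facilities drop
out, and roads become impassable.

## The model

Given facilities with a demand table (units per product), products
aggregated into two temperature categories (cold chain / ambient), a fleet
of vehicles with separate cold and ambient capacities in liters, and a
symmetric distance matrix paired with qualitative road conditions, the
optimizer builds depot-to-depot routes minimizing

```
W_t * (total transit time / T_ref)  +  W_p * (total risk / P_ref)
```

where the user enters only the integer transit-time weight `W_t` in 0..10
and the risk weight is always `W_p = 10 - W_t`. Each leg's travel time is
`distance / speed(road class)` and its spoilage risk is
`distance * (road_risk(class) + vehicle_risk(condition))`; speeds and risk
factors per class/condition are configurable
(`default_road_profile()`, `read_road_profile()`). `T_ref` and `P_ref` are
the totals of a deterministic pure-time greedy reference solution, so the
two objectives are on comparable scales: weights 5/5 weigh both equally.

Hard constraints: every route fits the daily time window (at most 24 h),
starts and ends at the depot, uses only accessible roads, respects vehicle
cold/ambient capacity, every facility with demand is visited exactly once,
demand is always met, and available vehicles are used as evenly as possible
(route counts differ by at most one; extra routes run on consecutive days).
Facility storage capacity is deliberately a warning, not a constraint.

The solver constructs routes with a recalculated two-index priority rule
(which vehicle opens the next route; which facility to add next) and then
improves the incumbent with an anytime depth-first branch-and-bound under a
time budget (default 120 s). With `branching_width = "all"` and no budget
the search is exhaustive and certified; a brute-force oracle
(`enumerate_optimal()`) cross-checks it on small instances.

## Worked example

The package bundles a small eight-facility input workbook (CSV bundle; an
`.xlsx` workbook with the same seven sheets is read identically):

```r
library(coldroute)
instance <- read_instance(system.file("extdata", "cyclone", package = "coldroute"))
validate_instance(instance)
#> <validation_report> 0 error(s), 0 warning(s)
solution <- solve_routes(instance, solver_config(time_budget_seconds = 5))
solution
#> <route_solution> 2 route(s)
#>   Landcruiser_3PL (day 1): Province A -> Center C -> Center G -> Center F -> Center H -> Center E -> Center D -> Province A  [6.78 h, risk 183.0, 343.9 km]
#>   New Vehicle (day 1): Province A -> Center B -> Province A  [1.62 h, risk 164.4, 82.2 km]
#>   totals: 8.40 h transit, risk 347.4, 426.1 km, fuel 107.64, per diem 120.00
#>   objective score: 4.9395
```

Both vehicles are used (one route each); the Good-condition Landcruiser
takes the long tour. Transit is in hours including per-stop service time,
risk is the dimensionless spoilage exposure summed over legs, and fuel/per
diem are the route running costs. `write_solution(solution, "out")` writes
the two output sheets: `Routes.csv` (one row per stop with departure clock
times and capacity utilization) and `Health products.csv` (named product
quantities per facility, disaggregated from the two optimization
categories).

An emergency is a declarative transform of the same inputs:

```r
scenario <- read_scenario(system.file("extdata", "cyclone_scenario.yaml", package = "coldroute"))
emergency <- apply_emergency(instance, scenario)   # depot -> Center B, three
solve_routes(emergency, solver_config(time_budget_seconds = 5))  # facilities zeroed, road B-E blocked
#> <route_solution> 1 route(s)
#>   Landcruiser_3PL (day 1): Center B -> Center H -> Center E -> Center G -> Center F -> Center B  [6.63 h, risk 275.5, 340.5 km]
#>   totals: 6.63 h transit, risk 275.5, 340.5 km, fuel 88.87, per diem 60.00
#>   objective score: 8.8813
```

Note the route reaches Center E through Center H and leaves through
Center G: the blocked Center B - Center E road is never used.

The same workflow is available from the shell:

```sh
Rscript inst/cli/coldroute validate my_inputs/
Rscript inst/cli/coldroute solve my_inputs/ -o routes_out --weight-time 7
Rscript inst/cli/coldroute generate -o synthetic/ --seed 7 --facilities 12
Rscript inst/cli/coldroute emergency my_inputs/ --scenario cyclone.yaml -o adjusted/
```

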