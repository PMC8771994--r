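---
title: "Cold-chain route optimization: model, algorithm and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cold-chain route optimization: model, algorithm and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A distribution warehouse must deliver health products to a set of health
facilities in a single day. Products fall into two temperature categories:
cold-chain items (vaccines, typically kept at 2-8 °C) and ambient items
(syringes, medicines). Vehicles have separate cold and ambient transport
capacities in liters, and differ in mechanical condition; roads differ in
surface quality and may be entirely impassable. Transit time matters
(vehicles are shared resources, and time in transit is time at risk), but
so does *where* that time is spent: a vaccine carrier stuck on a flooded
dirt road in an unreliable vehicle is the classic way doses lose potency.
The optimizer therefore balances two objectives rather than minimizing
distance alone.

## Model

Let a route be an ordered list of facilities, implicitly starting and
ending at the depot. For a leg of length $d$ km on road class $c$ driven
by a vehicle in condition $v$:

* travel time $= d / \mathrm{speed}(c)$ hours,
* spoilage risk $= d \cdot (\rho_{\mathrm{road}}(c) + \rho_{\mathrm{veh}}(v))$.

Risk is additive per kilometer: exposure grows linearly with the distance
covered under bad conditions. Whether road and vehicle penalties should
add or multiply is genuinely open; we add, because it keeps the two
contributions separately interpretable and either factor alone should be
able to create risk. Both maps are configurable; the defaults are

| road class | speed (km/h) | risk / km | | vehicle | risk / km |
|---|---|---|---|---|---|
| Fully paved | 80 | 0 | | Good | 0 |
| Partially paved | 60 | 1 | | Fair | 1 |
| Dirt road (Good Quality) | 40 | 2 | | Poor | 2 |
| Dirt road (Rough) | 25 | 4 | | | |

"Not accessible" has no profile entry: such legs can never appear on a
route. The qualitative vocabularies are fixed; only their numeric
conversion is tunable (`read_road_profile()`).

A route's transit time is the sum of its leg times plus
`service_hours_per_stop` per delivery (default 0; the synthetic generator
uses 0.25 h, a realistic unloading stop). The objective is

$$\min\; W_t \frac{\sum \text{transit}}{T_{\mathrm{ref}}} +
        (10 - W_t) \frac{\sum \text{risk}}{P_{\mathrm{ref}}},$$

with $W_t \in \{0,\dots,10\}$ entered by the user and the risk weight
always derived. $T_{\mathrm{ref}}, P_{\mathrm{ref}}$ are the transit and
risk totals of a deterministic reference solution -- the greedy
construction run with raw leg time as its index -- so that the integer
weights act on comparable scales; a zero reference total is replaced by 1.
Normalization is instance-intrinsic and deterministic, which makes scores
comparable across runs of the same instance but not across instances.

Constraints (all hard): daily window (return time minus start time, at
most 24 h); depot round trips; demand met exactly, each facility with
positive demand visited exactly once; zero-demand facilities and the depot
are never visited (zeroing demand is also how emergency workflows drop a
facility); per-category vehicle capacity; accessibility of every
consecutive leg, with no pass-through travel (a leg exists only between
consecutive delivery stops); and even fleet use -- route counts of
available vehicles differ by at most one. Facility *storage* capacity is
deliberately a warning, not a constraint: facilities routinely store
beyond their nominal space, so the tool warns and proceeds.

Evenness deserves a note. "As evenly as possible" could be read as a soft
preference; we implement the strictest reading (hard, spread at most one)
in both the solver and the oracle, because it makes the contract testable
and matches the operational intent of keeping all crews active. The
alternative -- a soft penalty -- would need an arbitrary weight with no
data to calibrate it.

Multiple routes assigned to one vehicle run on consecutive days (`day` is
the ordinal of the route on its vehicle), each independently bounded by
the daily window. Whether a second route could instead depart later the
same day is not knowable from the workflow the tool supports; consecutive
days is the conservative choice and is what the output sheet reports.

Costs (fuel = km x L/km x price; per diem = rate x crew, charged once per
route since each route is one crew-day) are reported, never optimized.

## Search algorithm

Construction uses two priority indices, recalculated at every step:

* **vehicle index** (which vehicle opens the next route): lexicographic
  key (routes already assigned ascending, total capacity descending,
  condition Good < Fair < Poor, name). Because every new route goes to a
  vehicle currently holding the minimum count, counts can never spread
  beyond one -- evenness holds by construction.
* **facility index** (which facility to add next): the normalized marginal
  objective of the candidate leg,
  $W_t\,\Delta t/T_{\mathrm{ref}} + W_p\,\Delta p/P_{\mathrm{ref}}$, with a
  hard feasibility filter: the leg must be accessible, the candidate's
  aggregated load must fit the remaining capacity, and the elapsed time
  plus leg, service and the *shortest-path* return to the depot (over the
  accessible graph, by travel time) must fit the window. The shortest-path
  bound, rather than the direct return leg, lets routes pass through
  facilities that cannot themselves close a route; closing additionally
  requires the direct depot leg to be accessible.

The greedy solution is the first depth-first leaf of the search ordered by
these indices: extend with the argmin-index facility until nothing is
feasible, close the route, open the next. If a choice dead-ends (a route
that can neither continue nor return), depth-first backtracking silently
tries the next-best index choice, so greedy construction finds a feasible
solution whenever the search space contains one.

The same depth-first search then continues as an anytime branch-and-bound:
at each node it branches on the `branching_width` best extensions (default
3) plus "close route" as a genuine alternative -- so the search explores
route-count trade-offs, not just orderings -- and prunes nodes whose
partial score plus an admissible bound cannot beat the incumbent. The
bound sums, over unvisited facilities, the cheapest normalized cost of any
accessible entering leg (using the best available vehicle condition), plus
shortest-path time and risk bounds for returning the open route. The
incumbent is always feasible, never worsens, and is returned when the time
budget (default 120 s, checked between node expansions) expires.

With `branching_width = "all"` and an unlimited budget the search is
exhaustive. In that mode, opening a route branches over *all* vehicles
currently tied at the minimum route count rather than only the single
best-keyed one: any final assignment with counts within one of each other
is reachable by some min-count-only construction order, so this branching
is exactly what makes the exhaustive search complete with respect to the
brute-force oracle while still enforcing evenness. The heuristic mode
keeps the single lowest-keyed vehicle, which is the deterministic
index-rule behavior.

Determinism: there is no randomness anywhere in the solver; all ties break
lexicographically (index value, then facility id; vehicles by the static
key). Identical instance and configuration give identical solutions and
byte-identical output workbooks.

## Numerical choices

* Internal time is decimal hours; clock I/O is 24-h `HH:MM`, rounded
  half-up to whole minutes on output only.
* Feasibility comparisons (window, capacity) carry an absolute slack of
  1e-9 to absorb float summation; pruning and incumbent updates use
  1e-12 so equal-score optima are not lost.
* Blank workbook cells are *errors with cell coordinates*, never imputed:
  a tool that silently fails on incomplete data costs its users hours, so
  validation reports every blank and never throws
  (`validate_instance()` is total).
* The distance and road-condition matrices must be symmetric and are
  enforced as such at read time; asymmetric travel times are out of scope.
* Degenerate inputs: an empty visit set returns an empty solution (header
  -only output sheets); a zero reference total normalizes to 1; a facility
  whose load exceeds every vehicle, or whose shortest possible round trip
  exceeds the window, or with no accessible road is reported as infeasible
  before any search.

## The exact oracle

`enumerate_optimal()` enumerates set partitions of the visit set, all
evenness-respecting assignments of blocks to vehicles, and stop orders
within blocks (best order per block and vehicle memoized by bitmask), with
window pruning via the same shortest-path bound. It is limited to 8 visit
facilities and 3 vehicles, shares none of the branch-and-bound machinery,
and exists to certify the solver: on every tested instance the exhaustive
search must reproduce its optimum exactly.

## What the generator emulates -- and what it does not

`generate_instance()` draws facilities uniformly in a square (default
60 km side), with road distance = beeline x 1.3, a standard road-wiggle
heuristic. Road classes are drawn from a mix (default 35/30/20/15 over
the four passable classes) and facility-facility legs are blocked with
probability 0.05; legs touching the depot stay passable, modeling a
warehouse sited on an arterial road. Demands are Poisson (mean 20 units
per product); the catalogue always contains at least one cold and one
ambient product; vehicle capacities are sized to 1.3-2.2 times the largest
single-facility load, as a real fleet would be. Together these choices
make every generated instance solvable by construction (each facility
admits a singleton round trip within the 08:00-18:00 window), which is
what lets the test suite fuzz hundreds of instances without filtering.

The generator does **not** emulate real geography (no clustering along
roads, no shared highways), heterogeneous crew sizes, demand correlated
with population, or instances that are infeasible in interesting ways.
Passing tests therefore certify the *optimizer's contract* -- feasibility,
optimality on small instances, determinism, evenness, conservation of
delivered quantities -- on plausible inputs; they are not evidence about
any particular real road network. Real inputs enter through the workbook
reader, which is exercised separately against hand-built fixtures.

Test and verification sizes are chosen to keep the whole suite fast while
covering the claims: oracle comparisons use up to 6 visit facilities and
2 vehicles (100 instances in the suite); feasibility fuzzing uses up to
12 facilities and 3 vehicles (500 instances); the anytime check uses a
20-facility instance with a 30 s budget, a scaled-down stand-in for the
recommended 50-facility / 2-minute operating envelope.

## Limitations

* Single-day routes only: every route must fit the daily window. A 24 h
  window can stand in for, say, three 8 h working days, but true
  multi-day tours (overnight cold storage, accommodation) are out of
  scope.
* The exhaustive mode and the oracle are for small instances; beyond
  roughly 8 facilities certification is impractical and the anytime
  heuristic is the intended mode.
* No map integration: distances are user-supplied (the hardest input to
  assemble in practice) and outputs are tabular, not drawn on a map.
* Fuel consumption lives on the vehicle sheet (per-vehicle L/km); if a
  deployment models fuel price per route or region instead, the profile
  and parameters would need extending.
* XLSX workbooks are read natively; all writing uses the CSV bundle,
  which any spreadsheet application opens directly.
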