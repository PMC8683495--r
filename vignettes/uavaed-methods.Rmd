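---
title: "Methods: simulating drone AED delivery for OHCA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating drone AED delivery for OHCA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uavaed)
```

## Overview

`uavaed` models a city-wide drone AED delivery program for out-of-hospital
cardiac arrest and compares it against the ground-EMS baseline. The pipeline
has six stages: synthetic data generation, the cohort exclusion cascade,
risk mapping, station allocation, dispatch simulation, and outcome
statistics. Every stage is seeded and deterministic, so any run is exactly
reproducible from its configuration.

This vignette explains the model behind each stage, the parameters that
matter, the numerical choices, and what the synthetic data can and cannot
tell you about real registries.

## The synthetic city, weather and cohort

No public OHCA registry with case coordinates, no hourly weather archive
and no building-height raster ships with the package; the generator
(`synth_config()`, `generate_city()`, `generate_weather()`,
`generate_cohort()`) produces data with the statistical structure the
downstream stages assume.

**Terrain.** Elevation is a sum of a few seeded 2-D Gaussian hills (default
4, up to 60 m). This is the simplest smooth field that creates non-trivial
corridor maxima for the topographic pathway; no claim of geomorphological
realism is made. Buildings are rectangular footprints (default 25 per km²)
with log-normal heights (median 15 m, log-sd 0.7), typical of a mixed
mid-rise district. Candidate drone stations are placed on building-free
cells, mirroring the use of fire stations — open, operable ground — as
siting candidates.

**Weather.** Hours are grouped into 6-hour persistence blocks; each block
draws its regimes independently with the configured probabilities, and
hourly values are drawn conditional on the regime. The default marginals
are the frequencies observed in the motivating four-year metropolitan
registry period: rain 9.6% of hours, snow 5.3%, sub-zero temperature
16.0%, sight distance under 1 km 10.7%, wind at or above 10 m/s
essentially never (10⁻⁴). Calm hours carry exactly zero wind and 20 km
visibility: the series exists to drive the dispatch gates, not to be a
meteorological model, and this convention makes the all-clear configuration
(`all probabilities 0`) uniformly flyable by construction. Autocorrelation
beyond block persistence, diurnal temperature cycles and seasonality are
deliberately absent.

**EMS timeline.** Each interval — call→recognition (median 2.4, IQR
1.6–3.4 min), call→ambulance-departure (1, 0–1), call→scene-arrival (6,
4–7) and scene-arrival→AED-attach (2, 1–4) — is drawn from a log-normal
matched in closed form to its reported median and IQR: the log-mean is the
log median and the log-sd is `log(q75/q25) / (2·z₀.₇₅)`. This pins the
median and the quartile *ratio*; it cannot pin both quartiles separately,
because the reported quartiles are mildly left-skewed while any log-normal
is right-skewed. We accept that mismatch (the parameter-recovery test
asserts the median and the log-IQR) rather than adopt a heavier
three-parameter family: the simulation consumes only the intervals'
location and spread. A reported lower quartile of zero (possible in
registry data rounded to whole minutes) falls back to matching the upper
quartile only. Departure is clamped to precede scene arrival so the
timeline ordering invariant holds record-wise.

**Locations and covariates.** Case locations come from a Gaussian mixture
(default 3 clusters, sd = extent/8, clamped to the extent) so the
occurrence heat-map has structure. Utstein covariates are independent
Bernoulli/categorical draws at the registry frequencies (male 63.7%,
witnessed 43.0%, public location 22.6%, shockable rhythm 15.0%, EMS
defibrillation 21.3%). The bystander-CPR rate is not published alongside
the others; the default 0.45 is typical of contemporaneous metropolitan
registries. Covariates are carried for realism and future stratification
but do not enter the dispatch model.

**Exclusions.** Records acquire cascade-tripping features either missing
completely at random at configured rates, or — for reproducing printed
cohort margins exactly — via `exclusion_counts`, which assigns exact,
disjoint counts in cascade order. The cascade itself
(`apply_exclusions()`) removes, in order: age < 8 years (the paediatric
dose-attenuator boundary; the threshold is an argument because eligibility
wordings vary), arrest during ambulance transport, missing AED-attach
time, missing recognition time — counting each record under the first rule
it trips, the convention under which cascades are reported.

## Risk map

The siting objective is a 50 m lattice whose score is the 1:1 sum of two
layers, each min–max normalized to [0, 1] before summing:

* **Occurrence layer** — quartic (biweight) kernel density of case
  locations with a 300 m radius, evaluated at cell centres. The quartic
  kernel is the common GIS heat-map default; only the radius is a modelling
  commitment.
* **Response-time layer** — inverse distance weighting (power 2) of
  per-case EMS response times, using all sample points (no neighbour
  cut-off). IDW is exact at sample points (a cell centre within
  `cell_size/100` of a sample takes its value) and bounded by the sample
  range. Longer response time contributes higher risk, with no inversion.

Normalizing before the 1:1 sum is a design choice: the two layers carry
different units (events vs minutes), and equal weighting is only meaningful
on a common scale. Users can reweight via `combine_risk(weights =)`.

## Station allocation

`ga_select()` maximizes covered risk mass over k-subsets of the candidate
stations, where a cell is covered when its centre lies within 3 km of at
least one selected station (cell-centre membership is unambiguous and
resolution-consistent; overlapping discs count once). The genetic algorithm
uses k-subset chromosomes, tournament selection (size 3), uniform crossover
with repair to cardinality k, per-gene swap mutation (rate 0.1), elitism,
and a stagnation stop (40 generations without improvement, cap 200,
population 50). These hyper-parameters are conventional defaults, exposed
in `ga_params()`; the test suite requires the GA to match exhaustive
enumeration on all instances with C(n,k) ≤ 5,000. `sweep_k()` runs an
ascending series of k, injecting each solution into the next initial
population; with elitism this guarantees coverage non-decreasing in k. The
monotone sweep is an engineering guarantee of this implementation, not an
empirical claim.

## Flight simulation

Two pathway models share the 50 km/h cruise ceiling of the small
multi-rotor airframe class the simulation targets:

* **Euclidean** (`euclidean_flight_time()`): distance over speed, reported
  in minutes to two decimals — the granularity at which such timelines are
  communicated.
* **Topographic** (`plan_topographic_path()` + `block_path_time()`): climb
  vertically from the station to one clearance (default 10 m, one block)
  above the tallest obstacle — terrain plus building height — in the
  corridor to the scene; cruise the Euclidean ground distance; descend
  vertically to the scene. The corridor is scanned at ±5 m around the
  segment (cells whose centre is within halfwidth + cell_size/2, so cells
  merely clipped by the corridor edge count). Each leg is decomposed into
  10 m blocks annotated with entry/escape speeds and directions.

Block traversal times come from a lookup table keyed by (entry speed bin,
entry direction, escape speed bin, escape direction). The packaged table
holds the single available bench measurement (10 km/h down-entry, 10 km/h
right-escape: 3.25 s); all other keys use the analytic
constant-acceleration estimate `2·10 m / (v_in + v_out)` (speeds in m/s),
with a standing start-and-stop block (both speeds zero) modelled as two
half-blocks to and from the first speed bin (7.2 s). Users with a fuller
bench-measured table load it with `read_traversal_db()`.

The speed profile is a documented convention, since measured acceleration
data for the airframe are not available: each leg ramps from its entry
speed toward the 50 km/h cap in one 10 km/h bin per block and decelerates
symmetrically into its exit speed; the first climb block starts from
standstill, corners are taken at 10 km/h, and the final descent block ends
at zero. Under these defaults the topographic time always dominates the
Euclidean time for the same geometry — the property the pathway comparison
rests on — but its absolute value depends on the traversal table, so
topographic flight times should be read as regime-correct, not
bench-calibrated.

## Dispatch simulation

`simulate_program()` processes included cases in call-time order. The drone
is dispatched at arrest recognition (call time + recognition interval),
gated by the weather record of the hour the call was received:

| model | extreme weather | poor visibility |
|---|---|---|
| basic | blocks | blocks |
| control advanced | blocks | — |
| flight advanced | — | blocks |
| flight & control advanced | — | — |

Extreme weather is wind ≥ 10 m/s, any rain, any snow, or temperature
< 0 °C; poor visibility is nighttime (fixed 18:00/06:00 clock boundaries,
not sun position) or sight distance < 1 km. The wind threshold unit is
m/s by default — consistent with how such registries tabulate strong-wind
hours — and configurable for sensitivity analyses. Lightning is recorded
but gates only when `lightning_blocks = TRUE`, since it is not part of the
canonical gate list.

A launch also requires a station within the dispatch range (default 3 km,
matching the siting radius — this cap, together with one-drone-per-station
fleet contention, is what keeps dispatch rates below 100% even for the
unrestricted model in large sparse cities) holding a free drone; the
nearest eligible station by ground distance wins, ties broken by station
id. The drone is busy from dispatch until return (twice the flight time
plus a configurable turnaround, default 0). Station choice ignores
altitude differences.

## Outcomes and statistics

Per case, the program attach time is `min(drone, EMS)` when a drone was
dispatched and the EMS attach time otherwise — the first-arrival reading,
which is the only one consistent with a program improving median times at
sub-50% dispatch rates. Pre-arrival means the drone's AED strictly beat
the EMS one. Success is attach within 5 or 10 min of the call. Flight-time
medians are over dispatched cases; attach-time medians and success rates
are over the whole included cohort (configurable, since denominators are a
common ambiguity in program evaluations).

Paired times are compared with the Wilcoxon signed-rank test (the paired
analogue; zero differences dropped, exact p for small untied samples,
normal approximation with continuity correction otherwise; all-zero
differences give p = 1 by convention). Paired success proportions use the
McNemar construction: exact binomial on the discordant pairs when there
are fewer than 25 of them, chi-square with continuity correction
otherwise. `station_count_curves()` reruns the dispatch simulation per
allocation in a k-sweep and tabulates median call-to-attach per scenario,
with k = 0 reproducing the EMS-only median.

## Problem sizes and verification

The default configuration — a 1 km² city, 500 cases, 12 candidate
stations, a four-year hourly weather window — is the package's
demonstration scale: it exercises every stage (including fleet contention
and all four gates) while a full pipeline run completes in seconds. The
test suite verifies the generator's parameter recovery at n = 10,000
cases and the weather marginals over the full 35,064-hour window; GA
optimality is checked exhaustively up to C(14,7) = 3,432 subsets.

Passing tests on synthetic data show that the machinery is correct —
gates, cascades, pathway dominance, paired tests, determinism — not that
any particular city would see the same dispatch or pre-arrival rates. In a
1 km² demo city every case is within dispatch range, so absolute rates run
far higher than a several-hundred-km² metropolis would produce; the qualitative
orderings (Euclidean pre-arrival above topographic; permissive scenarios
above restricted ones; program never worse than baseline) are the
transferable results.

## Known limitations

* The spatial distribution of cases is a stand-in mixture; real OHCA
  clustering follows population, land use and deprivation, none of which
  are modelled.
* The traversal database ships with one measured entry; topographic flight
  times are regime-correct but not bench-calibrated.
* No mid-flight weather changes, aborts, battery limits, lateral obstacle
  avoidance, or multi-drone stations.
* Survival and neurological outcomes are out of scope; the endpoint is
  AED-attach time, a process measure.
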