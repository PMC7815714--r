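---
title: "Models and methods behind coastweb"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind coastweb}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(coastweb)
```

coastweb studies how a coastal benthic food web responds to two opposing
pressures: top-down biomass extraction by small-scale fisheries and bottom-up
change in the pelagic productivity that subsidises the benthos through its
plankton supply. It couples two complementary views of the same web: a
*static* network analysis of extinction cascades and a *dynamic* bioenergetic
simulation. This vignette documents the models, the numerical choices and the
limits of what the synthetic test webs can show.

## The food web object

A `food_web` is a node table (species, body mass, trophic category, harvested
flag, catch rank, plankton/fisheries markers) plus a directed
consumer-to-resource link table. Two special nodes may exist:

* a **plankton node** — a basal "trophic species" aggregating phyto- and
  zooplankton, consumed exclusively by specialist filter-feeders and
  replenished from outside the web;
* a **fisheries node** — artisanal fishing treated as one more consumer when
  the structure is analysed. It has resources (the harvested species) but no
  consumers, is never deleted in a removal sequence, can never go secondarily
  extinct, and is *not* a dynamic state variable: in the bioenergetic model
  harvesting enters only as a mortality term.

Basal status is derived, not stored: a node with no resources of its own is
basal. Cannibalistic self-links are legal but never count as a node's own
resource — a cannibal cannot sustain itself once everything else it eats is
gone — and they are excluded from trophic-level computations.

## Trophic levels

`swtl()` computes the short-weighted trophic level: the mean of the
shortest-chain trophic level (1 + length of the shortest food chain to a
basal node) and the prey-averaged trophic level ($T_i = 1 + \\,$mean of the
resource trophic levels, solved as a linear system). Basal nodes sit at
exactly 1. The short-weighted average is the standard compromise between the
two classical measures: shortest-chain alone understates omnivory,
prey-averaged alone is inflated by long rare chains. A web in which some
consumer has no directed path to a basal node has no defined trophic level
and is rejected.

## The static cascade

A primary removal deletes a node outright. The cascade rule is purely
bottom-up: a non-basal species is secondarily extinct once *all* of its
resources are extinct. Basal species (plankton included — its resources come
from outside the web) only die when directly removed. `cascade()` computes
the least fixed point of this rule with an incremental worklist; the test
suite checks it against an independent brute-force oracle that rescans the
full node set until stable.

Four deletion sequences probe robustness:

* **harvesting** — harvested species in descending order of landed catch
  (rank 1 first); the sequence stops when the harvested set is exhausted, so
  only extinction counts are recorded for it;
* **random** — uniform shuffles of all removable species, summarised over
  replicates with a percentile 95% confidence band;
* **most-connected** — highest degree first, degree recomputed on the
  surviving web after every removal, ties broken at random under the seed;
* **supporting-basal** — targets well-connected species that trophically
  support other well-connected species. The literature describing this
  sequence gives no closed formula, so the package scores each node as
  $\mathrm{deg}(i)\,(1 + \sum_{j \in \text{consumers}(i)} \mathrm{deg}(j))$,
  ranks basal nodes first at equal score, and recomputes after every removal.
  This operationalisation makes a heavily-consumed basal hub (such as the
  plankton node feeding the filter-feeder clique) the natural first target.

`run_static_sequence()` records, per step, cumulative primary and secondary
extinctions. The **R50** index is the fraction of species that had to be
primarily removed for total losses to reach half the web (threshold
$\lceil S/2 \rceil$); its bounds are $[1/S, 0.5]$. For odd $S$ the upper
boundary can exceed 0.5 by $1/(2S)$ — an artefact of the integer threshold —
so the bound-checking tests use even-sized webs. A sequence that ends before
half the web is gone (the harvesting sequence on a robust web) leaves R50
undefined (`NA`).

One accounting subtlety: in a sequential run a species that starved *before*
its own turn for primary removal stays counted as a secondary extinction.
This keeps the cumulative secondary count non-decreasing; a one-shot
`cascade()` call, by contrast, classifies everything in the removed set as
primary.

## The bioenergetic model

The dynamic layer is an allometric trophic network (ATN) model: a coupled
ODE system in which every rate scales with body mass as $M^{-1/4}$ and all
rates are normalised to the growth rate of the *reference producer* — the
producer with the smallest body mass, hence the fastest mass-specific
growth. One time unit is one day.

Producers ($i$) grow logistically under a single community-wide carrying
capacity and lose biomass to herbivory and fishing:

$$\frac{dB_i}{dt} = r_i B_i G_i(B)
  - \sum_j \frac{x_j\, y\, B_j\, F_{ji}(B)}{e_{ji}}
  - F_{\max,i} B_i,
  \qquad G_i(B) = 1 - \frac{\sum_{j \in \text{prod}} c_{ij} B_j}{K}.$$

Consumers assimilate a fraction of what they ingest, respire a maintenance
fraction of their metabolic rate, and lose biomass to predation and fishing:

$$\frac{dB_i}{dt} = f_a\, x_i B_i \sum_j y\, F_{ij}(B)
  - f_m\, x_i B_i
  - \sum_j \frac{x_j\, y\, B_j\, F_{ji}(B)}{e_{ji}}
  - F_{\max,i} B_i.$$

Consumption follows a Hill-type functional response with optional
intraspecific interference:

$$F_{ij}(B) = \frac{\omega_{ij} B_j^q}
  {B0_{ij}^q + d_i B_i B0_{ij} + \sum_{l} \omega_{il} B_l^q}.$$

The plankton node obeys the producer equation **plus a constant subsidy**
$s$ (biomass per day), the externally controlled inflow of pelagic
production captured by filter-feeders. With $s = 0$ and no fishing the
plankton equation reduces exactly to the plain producer equation — an
invariant the tests assert.

### Parameters and defaults

| symbol | meaning | default | notes |
|---|---|---|---|
| $r_i$ | producer growth rate | $(M_i/M_\mathrm{ref})^{-1/4}$ | 1 for the reference producer |
| $x_i$ | consumer metabolic rate | $(a_x/a_r)(M_i/M_\mathrm{ref})^{-1/4}$ | $a_r = 1$, $a_x = 0.314$ |
| $y$ | max consumption / metabolism | $a_y/a_x = 8$ | identical for every consumer |
| $q$ | Hill exponent | 1.2 | between type II and type III |
| $B0$ | half-saturation biomass | 0.5 | per link, overridable |
| $d_i$ | consumer interference | 0 | |
| $e_{ji}$ | assimilation efficiency | 0.45 herbivory / 0.85 carnivory | by resource type |
| $\omega_{ij}$ | preference | $1/(\text{diet size})$ | renormalised after overrides |
| $f_a$, $f_m$ | assimilated / maintenance fraction | 0.4 / 0.1 | |
| $K$ | shared producer capacity | 0.25 per producer | community-wide |
| $c_{ij}$ | producer competition | 1 (fully shared $K$) | matrix overridable |
| $s$ | plankton subsidy | 0.5 biomass day$^{-1}$ | comparable to plankton's own production |
| $F_{\max,i}$ | fishing mortality | 0 (non-harvested always 0) | calibrated, see below |

The allometric constants and the assimilation efficiencies are the standard
ATN literature values; preferences, interference and half-saturations are
uniform defaults because no empirical per-link table ships with the package
— all of them can be overridden per link. With fully shared capacity
($c_{ij} = 1$) producer competition is maximal: persistent fishing pressure
on one producer ultimately hands its share of $K$ to the others, which is
why harvested basal species are far more sensitive to fishing than harvested
consumers.

### Integration and extinction bookkeeping

`atn_integrate()` uses an adaptive solver (deSolve's `lsodar`, relative
tolerance 1e-8, absolute 1e-10) with a root function on the extinction
threshold: when a species' biomass crosses $10^{-6}$ the solver stops at the
crossing, the species is zeroed, logged, and excluded from all further
dynamics. Event detection matters: clamping at output steps instead would
make extinction times (and everything downstream) step-size dependent. An
extinct species can never re-grow — including the plankton node, whose
subsidy is switched off by its extinction.

`equilibrate()` integrates for 3650 days (ten years) and reports a
stationarity diagnostic — the maximum of $|dB/dt|/B$ over the survivors
against 1e-6 day$^{-1}$ — without enforcing it. Scenario machinery uses a
**spin-up of twice the perturbation window** (7300 days) for the unperturbed
baseline: competitive exclusion under a fully shared capacity has slow
tails, and a baseline that is still drifting would contaminate the
perturbation effects; with the longer spin-up the null scenario (no fishing,
no subsidy change) reproduces the baseline to a fraction of a percent.

### Calibrating fishing mortality

The fishing scenarios are defined by outcomes: mortalities $F_{\max}$ that
reduce every harvested species to 50%, 20% or 1% of its unfished baseline
biomass after ten years of fishing (the "-100%" scenario targets 1%
residual, not extinction — the biomass removed each day is biomass produced
a day earlier). `calibrate_fmax()` solves this coupled inverse problem
iteratively; every iteration runs one simulation with the whole current
mortality vector, so the per-species updates self-correct as the
co-mortalities move. Two-sided targets use damped per-species secant steps
on log-mortality against log-biomass (capped at one doubling per step, with
species already on target frozen so they stop perturbing the rest); the
one-sided 1%-residual target uses a per-species bracket search for the
smallest over-fishing mortality, discarding any bracket side contradicted
by a later evaluation. Targets are accepted at 1% relative tolerance, and
non-convergence within the iteration cap is an error naming the offending
species — or, with `on_fail = "best"`, the best iterate is returned with an
explicit `converged = FALSE` and the achieved reductions, which reporting
workflows quote instead of the nominal target. The escape hatch matters
because the inverse problem can be genuinely singular: producers under a
fully shared carrying capacity have no interior equilibrium when several
are fished at different per-capita pressures, so their ten-year biomasses
are knife-edge transients; on webs with many co-harvested producers an
exact simultaneous target may be unattainable. `run_factorial()` calibrates
ascending fishing levels with warm starts from the previous level, which
keeps the steep producer responses inside the solver's reach. Calibration
search runs may use slightly looser solver tolerances than the final
reported simulations; the returned mortalities are always re-evaluated by
the scenario run at full precision.

### Scenario protocol

A scenario cell (fishing level, subsidy change) is always run from the
common unperturbed baseline: perturbations are applied as step changes (the
calibrated $F_{\max}$ and/or $s' = s(1 + \delta/100)$) and the system is
integrated a further 3650 days. Changes are reported per species as
$[(B_\text{after}/B_\text{before}) - 1] \times 100$ and per trophic category
as the change of summed biomass, split by harvested status; extinct species
keep their zero biomass in the sums.

## The synthetic web generator

`generate_web()` provides study systems with the architecture of a
well-resolved rocky-intertidal web, so every stage of the pipeline is
testable without any external data. Topology starts from the classic niche
model at the requested size and connectance — chosen over cascade or random
graphs because it yields interval diets and pervasive omnivory, the
structural features behind food-web robustness. The draw is then edited:

* the lowest-niche 44% of dynamic nodes become primary producers;
* one producer becomes the plankton node; a clique of filter-feeders (15 of
  107 by default) is rewired to consume it exclusively, and nothing else
  consumes it;
* connectance is steered back to the target by adding/removing ordinary
  links, and every consumer is guaranteed a directed path to a basal node;
* categories come from the final diets (a diet at least 75% animal prey
  makes a carnivore; a carnivore with no consumers is a top predator);
* body masses grow log-normally with trophic level at the requested
  consumer-resource mass ratio (default 100, a typical marine value, with
  0.3 log-sd noise), which makes the smallest producer the allometric
  reference;
* a harvested set (22 of 107 by default) is sampled, stratified across
  categories in the proportions typical of artisanal landings (macroalgae
  and omnivores dominating), and given a random catch-rank permutation; a
  fisheries node consuming exactly the harvested set completes the web.

Model parameters use the defaults of the table above; initial biomasses put
total producer biomass near (below) $K$ and start consumers small, scaled by
seeded uniform noise in [0.5, 1.5].

### What the synthetic webs do and do not emulate

They reproduce the *structural* signatures: size, connectance, the
producer-heavy composition, the specialist filter-feeder clique (so removing
plankton statically starves exactly that clique), the omnivorous fisheries
node, masses increasing with trophic level. They do **not** carry the
empirical per-link parameterisation (preferences, half-saturations,
efficiencies, measured body masses in g/m²), so dynamic *magnitudes* — how
many consumers a subsidy collapse drags down, which categories flip sign in
a factorial cell — will differ from any particular empirical web. In
particular, with default parameters plankton retains enough intrinsic
production that specialist filter-feeders can survive a subsidy shut-off at
low density, whereas removing the plankton *node* kills them in both modes.
Passing tests therefore validate the machinery and its documented
invariants, not any site-specific prediction. A handful of generated
consumers typically fails to persist through the baseline equilibration;
scenario accounting is restricted to the community that actually persists,
and calibration to the harvested species among it.

## Problem sizes

The test suite exercises the cascade engine against its brute-force oracle
on 1000 random webs of up to 12 species, enumeration oracles on 4-species
webs, and the dynamic machinery on generated webs of 10–60 species; the full
factorial check runs a 30-species web over all 4 × 7 cells. The acceptance
script runs the complete pipeline at the default size (107 species, 1000
null and random-sequence replicates, one calibrated fishing level). These
sizes were chosen so each run completes in minutes on a single core while
remaining large enough for the structural statistics to be meaningful.

## Known limitations

* Facilitation, mutualism, direct consumer interference between species,
  prey switching and rewiring are outside the model, as are temperature
  dependence of rates, larval recruitment and spatial structure.
* The supporting-basal score is one defensible operationalisation of a
  verbally described ranking; alternatives (e.g. pure consumer-degree sums)
  would reorder ties.
* R50's upper bound is exact only for even S (see above).
* Calibration solves a genuinely ill-conditioned inverse problem when
  several co-harvested producers share a carrying capacity; the solver is
  built to self-correct, but extreme targets on pathological webs can still
  fail, and they fail loudly.
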