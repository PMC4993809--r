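---
title: "The virtual-farm model: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The virtual-farm model: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cherryfarm)
```

## The model in one paragraph

`cherryfarm` is an individual-based, Markov-like stochastic simulator of
female European cherry fruit flies (*Rhagoletis cerasi*) on a spatially
explicit sweet cherry farm.  The farm is a rectangular grid of 10 x 10 m
sectors, each carrying a cover type (host cherry, non-host tree, open
ground), a cultivar reference, canopy cover, optionally a Rebel monitoring
trap, and an initial pupae load.  Every simulated day, each female — in a
fixed event order — may emerge from the soil, die of senescence, natural
enemies, weather or pesticide, explore or relocate, oviposit into suitable
fruit, or be trapped.  All decisions are Bernoulli/normal draws conditioned
on her age and on the current state of the sector she occupies.  Because
the species is univoltine, the within-season population can only decline;
the quantity that links seasons is the overwintering pupal pool produced by
larvae that complete their in-fruit development.

## Demography

**Spring emergence** is staggered over a 35–50 day window with 70–90% of
individuals emerging during the peak 14 days.  The expected shape is a
day-binned truncated normal centred mid-window; its spread is solved
numerically so that the best consecutive 14 days carry exactly the target
mass (for a 0.80 target, sigma is about 5.46 days, the central ±7 days of
a normal).  Realized daily counts are one multinomial draw, so the sector
total is conserved exactly.

**Intrinsic mortality** follows a Gompertz daily hazard
$h(t) = \min(1, a e^{bt})$ with the hazard forced to 1 at the 95-day
maximum lifespan.  One target (a 59-day mean lifespan under optimal
conditions) cannot identify two parameters, so the family is closed by
requiring the unforced hazard to reach 1 exactly at the cap
($a = e^{-95b}$); a one-dimensional bisection on $b$ then matches the mean
of the truncated process to 59 days within $10^{-6}$.  The calibrated
values are $a \approx 3.23\times10^{-4}$, $b \approx 0.0846$.

**Fecundity** is zero before the 5-day maturation onset and then follows a
gamma-kernel bell $c\,(t-5)^{\alpha} e^{-(t-5)/\beta}$ with $\alpha = 2$,
$\beta = 12$, normalized so the mean curve sums to the 365-egg lifetime
potential over ages 1–95 (no source states the horizon of that total; we
integrate to the maximum lifespan and expose the horizon as the curve's
normalization range).  The peak (8.4 eggs/day at age 29) sits
inside the most damaging "mature" age band and below the 10 eggs/day cap;
if a user-supplied shape violates the cap, $\beta$ is widened until it
holds.  Individual daily egg loads are Normal(mean, mean/3) truncated to
[0, 10] and rounded — the literature gives a range and an age-dependent
mean but no individual SD, so mean/3 places ±3 SD across the range.

**Other constants**: 3%/day extrinsic mortality from resident natural
enemies; 92% combined mortality from egg to next-spring adult (applied at
season end, not simulated through winter); a 1:1 sex ratio applied by
simulating females only and halving recruits when building next-season
emergence maps; 20–23 days of in-fruit development, fixed per farm-season
by a linear map anchored at (22.1 °C, 20 d) and (19.1 °C, 23 d) rather
than a daily degree-day accumulation, since only "adjusted to the locally
prevailing temperatures" is documented.

## Host phenology and attractiveness

Each cultivar's fruit suitability window (FSW) runs from the recorded hue
change (green to yellowish-green) to the last harvest; when no hue date is
recorded it is estimated backwards from harvest as 31% (early/medium) or
44% (late/very-late) of the flowering-to-harvest span.  Daily fruit
attractiveness is an asymmetric bell over the FSW: a sine rise to exactly
1.0 at one third of the window, then a monotone power decline to 0.2 at
harvest (only the shape constraints are documented; the two half-curves
and the 0.2 terminal value are this package's choices).  The post-peak
decline also stands in for the loss of attraction of dark, fully ripened
fruit, which is why flies drift from an earlier cultivar back to a later
one near its harvest without any dedicated rule.  Sector attractiveness is
the canopy cover (linear factor — size/structure "play a role" but no
formula is documented) times max(0.30, fruit attractiveness) for hosts,
a configurable 0.10 baseline for non-host trees (attractive chemical
cues), and 0 for open ground, modulated downward by the niche rules below.

## Movement

Local exploration covers one sector (100 m², the source of the grid
resolution) and is therefore implicit: a non-migrating fly stays put.
With an age-dependent daily propensity a female attempts a micro-migration
of 30–300 m: the distance is Normal around an age-dependent mean (SD = 0.4
x mean, clamped to the range), and the destination is drawn from the
sectors whose centres lie within ±5 m (half a sector) of that distance,
with probability proportional to attractiveness plus a 0.01 floor.

Two moderating effects represent the influence of canopy macro-structure
on relocation patterns.  First, a candidate's weight is multiplied by
`gap_penalty^k`, where `k` is the expected number of open (canopy-free)
sectors the straight path crosses; the penalty is age dependent — 0.03 for
young females (tightly canopy-bound), 0.9 for old ones (committed long
errands over open ground).  Second, the home sector competes in the
destination choice with its own attractiveness, so a migration attempt
whose ring offers nothing better than home is abandoned.  Without these
two rules the model cannot keep young flies concentrated where they were
released while still letting old flies reach distant plots — the contrast
at the heart of the mark-recapture validation.

Where the candidate ring extends beyond the farm, the out-of-grid arc
competes with weight (mean candidate weight x outside ring fraction x
in/out balance); selecting it emigrates the fly and — under the default
balanced landscape — queues an immigrant of an age drawn from the current
live age distribution at a uniformly chosen border host sector, keeping
emigration and immigration near 1:1.

The propensity and distance defaults (0.95/0.95/0.65 per day and 32/42/150
m at ages ≤10/22/≥30, SD factor 0.4) are the package's calibration against
the three-cohort mark-recapture experiment; they are deliberately not
literature values, which do not exist at this granularity.  The calibrated
picture is of frequent short tree-to-tree hops within contiguous canopy,
with the hop length, the willingness to cross open ground, and (via trap
responsiveness) the catchability all shifting with age.

## Niche modulation

Oviposition propensity and destination attractiveness are both multiplied
by $(1 - I^2)(1 - (d/K)^2)$ (floored at 0), with $I$ the sector's infested
fruit fraction, $d$ its live females and $K = 20$ the density capacity;
the quadratic keeps the impact minor at low-to-moderate exploitation
(≥ 0.91 at $I = 0.3$).  The complementary leave multiplier
$1 + I^2 + (d/K)^2$ raises the migration propensity out of exploited or
crowded sectors.

## Traps, pesticides, natural enemies, harvest

A Rebel trap is effective only within its own sector: the daily capture
probability is 0.05 x 0.99^(days deployed) x responsiveness(age), with
responsiveness 0.8 at emergence, 1.0 over the 12–22 day reproductive peak
and a 0.4 floor from 4 weeks of age.  Because exposure requires residence,
local out-trapping (declining catches at constant population) emerges
without a dedicated rule.

Pesticide applications carry separate adult and larval daily-risk profiles
over days since application, combined across overlapping applications as
complements.  The systemic (acetamiprid-like) default: larval risk 0.9/day
for 14 days, declining through 0.6/day at day 21 and halving every 7 days
after; adult knockdown 0.8 on the application day with a 2-day half-life.
The short adult half-life matters: a longer tail suppresses the treated
plot's late emergence for weeks and eliminates the post-treatment
resurgence the model is meant to expose.  A pure knockdown mode kills all
adults on the application day only; a bait-spot mode kills 50% on that
day.  All profiles are overridable per application.  Natural-enemy
mortality (3%/day) drops to zero in a treated zone on the application day
and recovers linearly over 21 days, twice as fast at the zone border
(recovery speed 1 + 1/distance-to-nearest-untreated-sector).

Harvest picks each fruit independently with the event's accuracy (usual
practice 0.8).  In-fruit occupants of picked fruit die — unless deposited
within the last 4 days, in which case the injury is still concealed: the
egg counts toward fecundity but neither toward the assessment nor the next
generation.  Occupants of fruit left on the tree complete development into
the overwinter pool.  Infestation is assessed on a random sample
(min(100, yield)) of harvested fruit, counting visibly damaged plus
occupied non-concealed fruit.  An egg or young larva killed within 5 days
of deposition heals the fruit, which becomes available for oviposition
again on day 5; later deaths leave the fruit permanently damaged.

## The daily event order

Emergence and queued immigration; intrinsic mortality; natural-enemy risk;
weather mortality; activity gating and movement; adult pesticide risk at
the end-of-day sector; oviposition; trap capture; fruit-state update;
harvest events; ledger check; age increment.  The order is a design choice
(nothing in the biology fixes it); trapping after oviposition lets a fly
both infest and be caught the same day.  A fate ledger (emerged +
immigrated = alive + each terminal fate) is verified every day and any
imbalance aborts the run.  Seeds: a master seed and a replicate index give
a deterministic per-replicate stream, so every replicate is bit-identical
on rerun and reproducible in isolation.

## Weather

A day permits explorative activity iff there is no rain, the average
temperature exceeds 13 °C, mid-day wind is below 12 m/s and radiation
exceeds 100 W/m²; mating additionally needs 15 °C and oviposition 16 °C.
Severe weather adds mortality: severity scores 0.5 for rain > 10 mm, 0.5
for wind > 8 m/s plus 1.0 when combined, risk = 0.10 x score x (1 − 0.7 x
canopy cover), capped at 0.10/day.  The thresholds and weights are
declared defaults (no quantitative source exists), all in configuration.

## Validation statistics

`chisq_gof_mc()` computes the Pearson statistic against expected
proportions with a Monte-Carlo p-value (multinomial tables under the
null), add-one corrected so it is never exactly zero — the appropriate
small-count correction; zero expected cells are merged into the smallest
neighbour.  `control_chart()` builds per-point mean ± 3 SD limits from
replicate simulations (sample SD, n−1), flags observations outside the
limits and same-sign runs of length ≥ 7; ties carry sign zero and break
runs, and a zero-SD point counts as inside only on exact equality (the
degenerate limit of the band).  `replicate_homogeneity()` is the standard
r x c chi-square across replicate count tables with the same Monte-Carlo
correction.  Because trap catches within one replicate share that
replicate's population trajectory, finely binned tables are overdispersed
relative to the multinomial null; homogeneity checks therefore default to
coarser (biweekly) pooling, a choice the data layout leaves open.

## Synthetic data

The generators produce everything the simulator consumes, so no external
data are required.  `generate_weather()` draws a seasonal temperature ramp
with noise, rain days and rarer storm days; `benign_weather()` is the
controlled all-gates-open series used in the mark-recapture experiment.
`generate_synthetic_farm()` lays out rectangular host/non-host plots with
negative-binomial initial pupae.  `build_jki_markrecapture_layout()`
realizes the published description of the mark-recapture farm — five
zones of fruiting cherries at the stated distances (zone 2 behind a ~20 m
open band; zone 3 with its closest edge ~90 m and centre ~147 m away
behind a plot of apple trees; zone 4, the largest, ~191 m; two wild
cherries at ~238 m) with 3/4/12/19 Rebel traps (the published counts sum
to 38 before zone 5, so the wild cherries carry none) — while inventing
the shapes the description leaves open.  `build_demo_farm()` is the fixed
two-plot stage for the IPM scenario experiments (treated plot mixing a
medium and a late cultivar; untreated plot mixing a medium and a very late
one).

What the synthetic fixtures do not emulate: real weather series, the true
farm geometries (only their stated distances and trap counts), between-year
population feedback, and absolute population scale — initial pupae maps
are arbitrary, so simulated trap totals and infestation levels are
comparable between scenarios, not with any particular farm's absolute
records.  Passing tests therefore demonstrate internal consistency and
the reproduction of published relative patterns, not site-specific
prediction skill.

## Problem sizes

The shipped experiments are desk-scale by design: the mark-recapture
validation runs 200 replicates of 3 x 300 females over 15 days on a 30 x
30 grid (about a minute); the scenario experiments use the two-plot demo
farm (16 x 22 sectors, ~1000 females, 80-day seasons, 5 replicate seeds
per scenario); demographic checks integrate 96-day survival curves exactly
and simulate 100,000-fly cohorts where a Monte-Carlo cross-check is
wanted.

## Known limitations

* One movement decision per day; transit exposure to traps or pesticides
  between sectors is not modelled (end-of-day residence only; documented
  choice, the alternative being an open question).
* No males, mating dynamics or sperm limitation (females assumed mated).
* No multivoltine cycling, no diapause-termination model: emergence timing
  is an input, not predicted from winter temperature.
* The calibrated mobility constants are tied to the destination-choice
  rule and its ring discretization; they are not field-measurable
  distances.
* The 14-day cohort's simulated recapture distribution puts more weight on
  the adjacent zone and less on the farthest one than the field pattern;
  the release-zone share and overall rates match, but the full spatial
  histogram for that cohort is only approximate.
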