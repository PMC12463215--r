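---
title: "Simulating latitudinal diversity gradients: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating latitudinal diversity gradients: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(ldgsim)
```

This vignette is the package's own account of its model: the assumptions
behind each stage, the parameters that matter, the numerical choices made
where the design was genuinely open, and what the synthetic worlds do and do
not capture about real paleo-landscapes.

## The question and the approach

The latitudinal diversity gradient (LDG) — richness declining from tropics
to poles — could arise from many combinations of ecological, evolutionary
and geographic mechanisms. The package takes the mechanistic route: build a
minimal but explicit world, let a clade diversify on it under a small set of
behavior rules, and ask which features of the gradient emerge and how they
respond to the forcing. Four scenarios separate the candidate roles of
terrain ("physiographic diversity", Φ): M0 uses climate and geography only;
M1s lets high-Φ cells act as barriers to gene flow (speciation); M1d makes
Φ contrasts costly to cross (dispersal); M1e adds Φ to the resource base of
the carrying capacity (ecology).

## Synthetic worlds

`generate_world()` replaces external paleo-reconstructions with a generator
whose statistical structure carries the features the engine responds to:

- **Continents** are smoothed Gaussian elevation blobs advected by
  per-continent drift velocities; a fragmentation event splits every blob.
  The default of six continents is Earth-like and, on coarse grids, keeps
  several distinct landmasses rather than one merged supercontinent — the
  drift/fragmentation structure is what the allopatric machinery responds
  to. Sea level is set per step as the area-weighted height quantile holding
  the target land fraction (default 0.3).
- **Hemispheric asymmetry**: `hemisphere_asymmetry` shifts the continent
  count north (`round(n(1+a)/2)` north); at the default 0.5, roughly three
  quarters of the land sits in the northern hemisphere, emulating the
  enduring northern land excess of the last 150 Myr.
- **Sea-level cycles** (amplitude 0.15 of the land fraction, period 25 Myr)
  emulate epicontinental transgression/regression cycles; they periodically
  flood lowlands, fragmenting and reconnecting ranges.
- **Climate**: temperature is a monotone zonal profile from `equator_T`
  (28 °C) to `pole_T` (−25 °C) with exponent 1.5, plus a polar-amplified
  greenhouse–icehouse cycle (4 °C equatorial amplitude, 80 Myr period,
  scaled by `0.5 + |lat|/90`). There is deliberately no elevational lapse
  term, so zonal-mean monotonicity in |lat| holds by construction and is
  asserted in tests. Precipitation peaks in the tropics
  (2 m/yr) and decays poleward (0.3 m/yr) with smooth multiplicative noise.
- **Pseudo-K-Pg shock**: at `kpg_time` the temperature drops by
  `severity × (equator_T − pole_T)` and precipitation by the factor
  `1 − severity` for 2 steps, recovering linearly over 5. This is a purely
  climatic stand-in for a mass-extinction boundary — no impact or volcanism
  mechanics.
- **Discharge** is steepest-descent single-flow accumulation of
  precipitation times cell area; pits retain their flux (a lake proxy,
  without evaporation). Cell areas use the exact spherical band area
  (∝ cos lat).

What the generator does **not** emulate: real plate reconstructions,
orographic rainfall, elevational temperature structure, seasonality, and
coastline geometry at sub-cell scales. Tests passing on these worlds show
the machinery behaves as specified under the stated statistical structure —
not that any specific empirical reconstruction would yield the same maps.

## Physiography

The topographic position index is computed on two Chebyshev annuli (ring of
radius 1 cell; ring of radii 2–3 cells). The classical definition uses
sub-degree annuli on a fine source grid; at the working resolutions here the
two rings are the closest available analogue, and each standardized layer
(`100(TPI − mean)/sd` over land) is averaged into a single layer before
classification so that the diversity index always has exactly three
categorical inputs. TPI classes are deciles of the slice's land distribution
(no published fixed thresholds exist); slope and water-flux classes use the
fixed hierarchical thresholds, with inclusive lower bounds.

For Φ we compute the Shannon index of each layer separately over the
neighborhood (radius 1 by default, coastline-clipped) and normalize by the
log of that layer's own class count before averaging. The alternative —
pooling all three layers into one index normalized by ln 3 — can exceed 1
and was rejected for that reason; with the per-variable normalization
Φ ∈ [0,1] is guaranteed, with 0 iff all layers are locally constant.

## Engine design notes

- **Normalization**: temperature converts to trait units at 100 °C per
  unit, anchoring the evolutionary step σ = 0.005 to exactly 0.5 °C per
  step. Precipitation is normalized by its series-wide land maximum for the
  niche match, and by slice maxima (as are H and Φ) inside the carrying
  capacity.
- **Trait evolution**: the printed stochastic update for the thermal
  optimum is not usable as written; it is implemented as a bounded directed
  step — a half-normal increment toward the cluster-local mean temperature
  that never overshoots. Expected step size is σ√(2/π) ≈ 0.4 °C.
- **Isolation clustering** uses the kernel scale Ψ as the reachability
  radius — it is the only length scale the parameterization supplies. On
  grids coarser than the 2° reference, Ψ (for both dispersal and
  clustering) is scaled by `lon_res/2` so reach per cell spacing is
  preserved; the factor is 1 on a 2° grid.
- **Barriers (M1s)**: cells above the 0.75 land quantile of Φ block
  *transit*: shortest paths may start or end on a barrier cell via its
  direct edges but never pass through one. (Severing barrier cells
  entirely would permanently isolate summit populations from their own
  neighbors and produce runaway fission.)
- **Divergence ledger**: tracked per cluster pair, +1 per isolated step,
  −1 on re-union (floored at zero, retained as a within-cluster residual
  that re-splitting clusters inherit); a cluster speciates when its
  divergence from every other cluster reaches τ, and the cluster with the
  largest total abundance always remains the parent. Speciation uses the
  first integer crossing of the continuous threshold.
- **Establishment**: dispersal produces candidates only; a colonizer
  receives abundance through reapportionment (site total reset to Ks, split
  by suitability, entries below 0.01 dropped one-at-a-time from the
  weakest, ties dropping the later index).
- **Initialization**: one ancestral species on the habitable cell of the
  largest landmass nearest the equator, with optima set to local
  conditions. The first 25 steps are excluded from analysis outputs
  (spin-up).
- **Determinism**: one RNG stream per simulation seeded from the
  simulation seed; the pipeline derives child seeds as
  `(master·1000 + scenario·100 + draw) mod 2³¹−1`, so ensemble members are
  order-independent.

## LDG quantification

`fit_tanh()` fits `α(lat) = α_min + Δα tanh(θ(|lat| − lat₀))` per
hemisphere by bounded Levenberg–Marquardt with four multi-starts (slope
sign × lat₀ quartiles) and canonicalizes to θ > 0 (the curve is invariant
under flipping both signs). Because "slope" and "width" of a tanh are not
unique summaries, both conventions are reported: raw θ and the maximum
gradient |θ·Δα| for slope; the midpoint lat₀ and the transition width 2/|θ|
for width. Flat profiles return a degenerate, flagged fit rather than a
spurious θ.

The simplified Köppen rules are evaluated with precedence A→B→C→D→E, which
resolves their overlapping printed definitions (e.g. MAT 8 °C, MAP 0.7 m/yr
satisfies C, D and E; precedence yields C). The arid rule compares MAP in
cm/yr against κ = 2·MAT — the classic Köppen convention; the function's
interface stays in m/yr throughout.

## Scaled-down study conditions

All shipped experiments run on small worlds so that the full test suite and
the analysis scripts complete on one CPU in minutes; the mechanisms, not
the problem sizes, are the subject. The stochastic emergence checks use 20
independent end-to-end replicates: replicate *s* generates a tiny world
(18×9 cells, 60 steps) with seed *s*, takes Sobol draw *s* (after the
origin point) and runs scenario M1e with seed 1000+*s*. Under these
conditions a tropical richness peak (mean post-spin-up richness at
|lat|<15° exceeding |lat|>60°) emerges in 18 of 20 replicates.

Two regimes of the parameter space behave very differently: when the
kernel scale falls below the cell spacing, every occupied cell is its own
isolation cluster and the clade turns over explosively (thousands of
species, abundant extinction); above it, a handful of wide-ranging species
persist with few or no extinctions over 60 Myr. Global extinction therefore
concentrates in a minority of draws at this scale, and per-replicate
extinction counts are zero in most replicates — pooled across replicates the
northern hemisphere accumulates more extinction events than the southern
(consistent with its land excess), but a per-replicate majority does not
hold under these conditions. The demo world (36×18, 10° cells) sits closer
to the reference regime.

## Known limitations

- The cost graph is 8-neighbor with great-circle edge lengths; long sea
  crossings are chains of doubled-cost edges, not explicit ocean routing.
- Trait state is one thermal optimum per cluster (precipitation optima are
  fixed at founding); no intraspecific variance.
- No biotic interactions (competition beyond abundance reapportionment,
  mutualism, predation) — deliberately, as the scenarios isolate abiotic
  forcing.
- The niche widths ω ∈ [0.05, 0.25] correspond to 5–25 °C under the 100 °C
  normalization; published niche-width anchors in degrees Celsius imply a
  different, unstated normalization and are not reproduced.
- CSV is the only landscape interchange format; values round-trip to
  ≤ 1e-5 relative error.
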