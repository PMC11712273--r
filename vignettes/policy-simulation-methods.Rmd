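---
title: "Methods: simulating sharing, sparing and three-compartment conservation policies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating sharing, sparing and three-compartment conservation policies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sparesim)
```

`sparesim` compares three agri-environmental conservation strategies on
a gridded landscape, each under three spatial allocation rules and two
conservation habitats, against a common no-policy baseline. This
vignette is the package's own account of the model: its assumptions,
the parameters that matter, the numerical choices, and what the
synthetic landscapes do and do not establish about real data.

## The decision problem

The decision unit is a grid cell (nominally 2 km square). Land is
divisible: any fraction of a cell's farmland can be converted, so every
allocation problem here is a *continuous* knapsack and the greedy rules
are exactly optimal for their linear objectives — a property the test
suite checks against an independent vertex-enumeration oracle rather
than assumes.

* **Sharing** converts a fixed total area $T$ of farmland to the
  conservation habitat, with no yield change. Output falls, so imports
  must rise: the policy leaks.
* **Sparing** applies a proportional yield uplift $g$ to all retained
  farmland and converts land until annual output returns exactly to the
  baseline. The converted areas $c_i$ solve
  $\sum_i y_i c_i = \frac{g}{1+g} \sum_i y_i A_i$.
  Under the equal rule this has the closed form of a uniform converted
  fraction $f = g/(1+g)$ of every cell.
* **Three-Compartment Sparing** starts from the sparing allocation and
  reassigns exactly one-third of the spared hectares to low-yield
  agriculture (productivity $\lambda$ times conventional), choosing the
  lowest-yield hectares first. Total spared area is unchanged, and food
  output gains a small surplus $\lambda$-proportional to the
  reassigned land.

The three allocation rules order cells by: nothing (equal division with
water-filling when a cell's farmland is smaller than its share), yield
(cost minimization — the lowest-opportunity-cost land first), or
biodiversity gain (per hectare under an area constraint; per unit of
forgone output, $G_i / y_i$, under output neutrality). The
output-constrained form of the biodiversity ranking is a deliberate
design choice: the binding resource under sparing is output, not land,
and ranking gain against the binding resource is what makes the greedy
walk optimal — ranking per hectare instead can make biodiversity
maximization *underperform* cost minimization. Ties always break by
ascending `cell_id`, so every allocation is deterministic.

## Occupancy model

Species respond linearly to the converted fractions of a cell, clipped
to the unit interval:

$$p_{s,i}(t) = \mathrm{clip}\!\left(p^0_{s,i} + \delta_{s,i,h}\, f^{hab}_i
 + \gamma_{s,i}\, f^{low}_i + \beta_s\, a(t),\; 0, 1\right)$$

The linear-in-fraction form is the simplest interpolation between the
two land-use states a species-distribution model would score (all
farmland vs all habitat); nothing in the package depends on it beyond
the occupancy module, so a saturating response could replace it without
touching the allocation code. Yield uplifts do not enter the occupancy
model: at the few-percent magnitudes considered they are assumed not to
affect in-field biodiversity.

**Gain in Occupancy** is the difference against the no-policy baseline,
summed over all cells and species, evaluated at each year's anomaly
over 2020–2060 (41 inclusive, unweighted years) and averaged. The
difference is taken against the climate-evolving baseline year by year,
not against the 2020 state: with linear responses the climate terms
cancel whenever clipping does not bind, so climate-insensitive species
contribute identically in every year (a tested property), while species
pushed to a clipping boundary contribute a genuine time-varying
difference. Per-cell sums of the same quantity give the
richness-change map, which sums back to the headline gain exactly.

## Economics

Food output in year $t$ values retained conventional farmland at
$y_i (1 + \kappa_i a(t))(1+g)$, low-yield land at $\lambda$ times that,
and habitat at zero. Two conventions are worth stating:

* The uplift is a **step** at the base year, not a ramp. The
  alternative (phasing $g$ in) would make sparing output-neutral only
  in aggregate; the step makes it neutral in every single year, which
  is the cleaner reading of "overall change in food output is zero"
  and is what the acceptance suite asserts.
* Discounting is end-of-year at rate 0.035 (the HM Treasury social
  discount rate), with the base-year flow undiscounted:
  $\mathrm{NPV} = \sum_t x_t (1.035)^{-(t-2020)}$.

Leakage is the one-sided import requirement $\max(0, -\Delta_t)$,
NPV-weighted. Opportunity cost is $-\mathrm{NPV}(\Delta)$ times a
configurable unit price (default 1; output is in abstract units because
calorific and monetary framings differ only by this constant here).

## The synthetic landscape generator

No real land-cover, farm-census or climate-projection data enter the
package; `generate_landscape()` emulates the *statistical* structure
such data would supply:

| parameter | default | meaning |
|---|---|---|
| `n_cols`, `n_rows` | 40 × 40 | grid size (1600 cells; desk-scale stand-in for a national grid of tens of thousands) |
| `n_species` | 100 | at-risk species count |
| `upland_fraction` | 0.3 | leftmost columns forming a contiguous low-yield upland block |
| `yield_meanlog`, `yield_sdlog` | log 1.5 / log 5, 0.4 / 0.3 | per-stratum log-normal yields; upland mean ≈ 0.31 of lowland |
| `smoothing_radius` | 2 | moving-average kernel on the log-yield noise (spatial autocorrelation) |
| `farmland_range` | 200–380 ha | per-cell farmland, uniform (a 2 km cell holds ≤ 400 ha) |
| `archetype_prop` | 0.3/0.3/0.2/0.2 | woodland, grassland, farmland specialists, generalists |
| `climate_slope` | 0.025 yr⁻¹ | linear anomaly, 0 in 2020, 1.0 by 2060 |
| `lowyield_factor` | 0.1 | λ, productivity of low-yield agriculture |

Choices that deserve justification:

* **Stratum means are pinned, not sampled.** After smoothing, yields in
  each stratum are rescaled so the stratum's arithmetic mean equals its
  log-normal target exactly. The upland-below-lowland ordering
  therefore holds for *every* seed by construction — no rejection
  sampling, no seed-dependent failures.
* **One climate-yield sensitivity per landscape.** The generator draws
  a single κ shared by all cells. Output-neutral sparing is solved at
  base-year yields; a uniform proportional climate response rescales
  both sides of the identity equally, so neutrality holds in every
  year. Cell-varying κ is fully supported for user-supplied landscapes,
  but then neutrality is exact only at the base year — a real-data
  caveat, not a property of the method.
* **Default responses are non-negative.** All archetypes have
  $\delta, \gamma \ge 0$; farmland specialists gain mainly from
  low-yield agriculture ($\gamma \in [0.15, 0.35]$), habitat
  specialists from their habitat ($\delta \in [0.25, 0.5]$), with
  per-cell multiplicative heterogeneity (×0.6–1.4). This makes gains
  monotone along every policy sweep, which is what the regression
  tests assert. Real species can lose from conversion; the monotonicity
  results are conditional on this generator, not general.
* **λ = 0.1.** The policy framing fixes only that low-yield
  agriculture produces *something*; any λ > 0 produces the qualitative
  three-compartment signature (small positive food surplus, zero
  leakage). 0.1 keeps the surplus an order of magnitude below sharing
  losses at comparable conserved area.
* **Species responses are independent of yield.** Biodiversity gain
  per hectare is uncorrelated with the stratum, so cost minimization
  concentrates in the uplands (it tracks yield) while biodiversity
  maximization spreads with the gain field — the mechanism behind the
  contrasting selection maps.

What the synthetic landscapes cannot show: real spatial covariance
between productivity and species' habitat suitability, non-linear or
interacting species responses, farm-level (integer) decision units,
agglomeration effects, and any calibration of absolute magnitudes.
Passing tests establish the *logic* of the policy comparisons — output
neutrality, dominance orderings, leakage signs, map structure — not
their empirical sizes on any real landscape.

## Numerical conventions

* Water-filling terminates when the residual is ≤ 1e-12 of the target;
  greedy walks place the final fractional cell by direct division, so
  area and output targets are met to ≈ 1e-9 relative (float
  accumulation), which is the tolerance the invariants are tested at.
* Occupancy clipping uses `pmin(1, pmax(0, ·))`; degenerate cells with
  zero farmland are excluded from rankings and contribute zero
  fractions.
* The uplift cap (default 0.05) and the sharing cap (total farmland)
  are validated at the policy boundary, not silently truncated.
* CSV round-trips serialize doubles with 17 significant digits, so
  `read_landscape(write_landscape(L))` is value-identical; the
  ESRI ASCII raster writes row 1 of the grid as the northernmost row
  with a 2000 m default cell size.
* Sweep grids: sharing sweeps run over fractions of total farmland
  (0–15% in 10 steps) because absolute national hectare targets have no
  meaning on a synthetic grid; sparing sweeps use uplifts 1–5%. Runs at
  1600 cells × 100 species × 41 years take roughly a second each, and
  the full 18-sweep factorial about a minute.

## Worked check

Every allocation on the four-cell toy fixture is hand-verifiable:

```{r toy}
T4 <- toy_landscape()
# 5% uplift removes 5/105 of 1500 = 71.43 output units; the cost-min
# rule takes it all from the yield-1 cell
al <- allocate_spared(T4, "cost_min", 0.05)
al$cells$habitat_ha
annual_food_output(T4, al, uplift = 0.05, year = 2020)  # back to 1500
gain_in_occupancy(T4, al)                               # 0.3 * 5/7
tc <- split_three_compartment(T4, al)
c(tc$habitat_area, tc$lowyield_area)                    # 2:1 split
delta_food_series(T4, tc, 0.05)$delta[1]                # small surplus
```

## Known limitations

Single conservation habitat per run (no mixed portfolios); no spatial
contiguity constraints; no re-ranking during greedy selection (exact
only because responses are linear in fractions — under a saturating
response the greedy walk would be a heuristic); leakage is reported in
food-output units, not converted to overseas biodiversity impact; and
the landscape generator, while seeded and reproducible, is a synthetic
stand-in whose parameters are chosen for structural realism rather than
calibrated to any country's data.
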