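---
title: "Mapping crystallization phase diagrams with phaseplan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping crystallization phase diagrams with phaseplan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phaseplan)
library(tibble)
```

## The problem and the model

Serial crystallography consumes thousands of uniform microcrystals, and
producing them is a phase-diagram problem: in the plane of precipitant
concentration $c$ versus protein concentration $P$, the solubility curve
$S(c)$ separates undersaturated solutions from supersaturated ones, and
the supersaturation ratio

$$\sigma(P, c) = P / S(c)$$

organizes everything above it. Crystals *grow* anywhere with $\sigma > 1$,
but *nucleate spontaneously* only beyond a kinetic threshold
$\sigma_{\mathrm{nuc}} > 1$. The band $1 \le \sigma < \sigma_{\mathrm{nuc}}$
is the metastable zone: the best place to grow well-ordered crystals, and
reachable only by adding seed stock. At still higher supersaturation,
growth becomes shower-like (dense microcrystal showers, threshold
$\sigma_{\mathrm{shower}}$) and finally amorphous precipitation
($\sigma_{\mathrm{prec}}$). Microbatch-under-oil drops do not equilibrate
by evaporation, so each well *is* a fixed point of this plane, and a plate
of drops is a direct sampling of the diagram.

`phaseplan` covers the full desk-side loop around such plates: designing
the sampling, computing robot dispense volumes, classifying paired
seeded/unseeded outcomes into zones, estimating the zone boundaries,
designing seed titrations, and scaling a chosen condition to batch
volumes. A parametric simulator closes the loop for testing.

## Mixture arithmetic and its assumptions

All composition arithmetic is linear, volume-additive mixing:
$c_{\mathrm{final}} = \sum_i c_i v_i / \sum_i v_i$. No excess-volume
correction, activity coefficients or buffer chemistry — the calculator a
dispensing robot actually implements. Three deliberate policies:

* **Units are never converted silently.** Each component carries its unit;
  mixing the same component declared in different units is an error. One
  explicit normalizer (`normalize_units()`, molar species to mM) runs at
  configuration load and nowhere else. Silent unit conversion is the
  classic bug in mixing code, so the conversion surface is one function.
* **pH is metadata, not a mixed quantity.** There is no pH-mixing model;
  a mixture's pH is carried through `mix()` only when every contributing
  part that declares a pH agrees on the value (parts without a declared pH,
  such as water, do not veto). Anything else would pretend to buffer
  chemistry the package does not do.
* **The cocktail co-dilutes as a unit.** The designated primary
  precipitant sets the cocktail channel volume; every other cocktail
  component (buffer, additives) scales with it. This matches how
  crystallization cocktails are dispensed. A consequence worth knowing:
  co-dilution arithmetic gives 58.45 mM HEPES for a 0.35-fraction of a
  1 M citrate / 167 mM HEPES cocktail, and published formulations
  sometimes round such values (e.g. to 60 mM); the package reports the
  arithmetic, not the rounding.

## Diagonal plate design

A plate is defined by its four **corner conditions** and interpolated
bilinearly: well $(r, j)$ maps to $(u, v) = (r/(R-1), j/(C-1))$ and blends
the corners with weights $(1-u)(1-v), (1-u)v, u(1-v), uv$ in both
coordinates. Bilinear interpolation is the minimal scheme that honors four
free corners and keeps every row and column affine in the well index —
which is what makes *diagonal sampling* work: corners are chosen so
gradients run roughly parallel to the expected solubility boundary,
concentrating wells where the zone transitions are. The corners need not
form a rectangle; that is the point. Rows index protein (A1 is the
high-protein, low-precipitant corner) and a `transpose` flag swaps the
convention.

Channel volumes per well follow the linear dispense rule
$v = V_d \cdot \mathrm{target}/\mathrm{stock}$, the diluent takes the
remainder, and a well is *feasible* iff
$P/P_{\mathrm{stock}} + c/C_{\mathrm{stock}} + f_{\mathrm{seed}} \le 1$
and every non-zero channel clears the robot's minimum dispense. Infeasible
wells are kept and flagged rather than dropped or raised as errors, so
coverage reports are honest about the unreachable corner of phase space.
Defaults mirror common dispensing hardware: 0.01 µl precision, 0.1 µl
minimum dispense, 2 µl drops. Rounding residuals go into the diluent
channel — preserving the drop volume exactly at the cost of at most one
precision step on an inert channel, rather than perturbing an active
concentration. Worklist rows are emitted in the fixed channel order
diluent, cocktail, seed, protein (largest first, reactive component last
into a pre-mixed drop); the true dispense order of commercial robots is
not published, so this is a package convention, configurable only by
editing the worklist.

Seeding enters the design in one of two modes, as in practice: premixed
into the cocktail channel (volumes unchanged) or as a separate fourth
channel occupying a fixed fraction of the drop (default 0.1 — drop-level
seed volumes are rarely published, and a fixed 10% channel keeps the
remaining arithmetic identical across wells).

## From outcomes to zones

Each well is scored `clear`, `crystals`, `shower` or `precipitate` in an
unseeded and/or a seeded arm. (`shower` and `crystals` are deliberately
distinct categories — crystal-density language matters downstream — but
identical for zone logic.) The classification truth table:

| unseeded | seeded | zone |
|---|---|---|
| crystals/shower | anything but clear | nucleation |
| crystals/shower | clear | inconsistent (flagged, never guessed) |
| precipitate | — | precipitation |
| clear | crystals/shower | metastable |
| clear | clear | undersaturated |
| clear | precipitate | precipitation |
| clear | missing | unknown |
| missing | anything | unknown |

Missing arms degrade gracefully: an unseeded-only plate still locates
nucleation and precipitation, but a clear drop alone cannot distinguish
undersaturated from metastable, so it is `unknown`, and zone fractions are
computed over classified (non-unknown) wells only.

## Frontier estimation

Zone boundaries are estimated as monotone non-increasing staircases:
protein threshold as a step function of precipitant, non-increasing
because precipitant lowers solubility. Candidate thresholds are the
mid-gaps between adjacent observed protein levels (plus infinite sentinels
for one-sided columns); among all monotone staircases the estimator
minimizes the number of misclassified wells, breaking ties by maximal
total margin (the mid-gap preference) and then toward the higher
staircase. The optimum is found by dynamic programming over precipitant
columns — the monotonicity constraint makes the problem a chain — and the
test-suite verifies it equals brute-force enumeration over every monotone
staircase on grids up to 8 × 8. Published phase-diagram figures typically
draw such boundaries by hand; the staircase estimator is this package's
explicit formalization, chosen over smooth fits because it makes the
misclassification count exact and the estimator assumption-free beyond
monotonicity.

Some landscapes genuinely break global monotonicity: competing salting-in
and salting-out effects can split the metastable zone into two disjoint
regions (one at high protein / low precipitant, one at low protein / high
precipitant). The estimator therefore runs per connected component of the
metastable wells (4-neighbor adjacency) and emits one frontier segment per
component rather than forcing a single curve through an inconsistent
landscape.

## The simulator: what it emulates and what it does not

Ground truth is the log-quadratic solubility family

$$\ln S(c) = \ln S_0 + \beta c - K c^2,$$

classical Cohn-style salting-out ($-Kc^2$) plus an optional linear
salting-in term ($\beta c \ge 0$): the simplest smooth family exhibiting
both the textbook single-band landscape and the dual-metastable landscape,
the latter realized as one *option* — the salting-in explanation for dual
metastability is a hypothesis in the field, not an established mechanism.
Outcomes follow the $\sigma$ thresholds deterministically; the single
stochastic knob is `p_nuc`, a linear ramp (in $\sigma$) for rare
spontaneous nucleation inside the metastable band, default 0 so that
round-trip tests are exact. Crystal counts, size distributions, nucleation
kinetics in time, Ostwald ripening and oil permeability are all outside
the model; `shower` is a categorical stand-in for density.

Passing round-trip tests therefore show that the classifier and frontier
estimator invert the simulator's generative logic exactly — they do not
show robustness to scoring noise, drop-to-drop heterogeneity, or
non-threshold nucleation behavior of real plates. Those limits are
inherent to any synthetic check.

Three frozen fixtures pin qualitative topologies observed in real systems
(`generate_fixture()`): `classic` (one contiguous band per zone, as for
robust model proteins), `dual_metastable` ($\beta > 0$, two metastable
components bridged by nucleation wells), and `nucleation_limited`
(exactly one spontaneous hit on the plate, rescued to a majority of
crystal-bearing wells by seeding — the situation where seed titration
earns its keep). For `nucleation_limited` the threshold
$\sigma_{\mathrm{nuc}}$ is placed midway between the grid's two highest
$\sigma$ values, which realizes "exactly one well nucleates" by
construction. Fixture grids are 8 × 12 to 12 × 12 — large enough for the
topology to be unambiguous, small enough that the whole loop runs in
milliseconds.

## Titration and scale-up conventions

Seed-stock titrations are constructed analytically as factor ladders
($\mathrm{step}^{0}, \mathrm{step}^{-1}, \dots$; eight decade levels reach
$10^{-7}$), crossed against a condition list so each row shares a dilution
and each column a condition. Seed "concentration" is unitless (fraction of
neat): absolute seed-particle densities are never quantified bench-side.
An optional pipetting plan gives transfer volumes for realizing the ladder
physically; the carryover scheme (transfer $V/\mathrm{step}$ into
$V(1-1/\mathrm{step})$ diluent) is a convention, since bench protocols
vary.

Batch recipes are ratio-based: volumes $v_i = V \cdot w_i / \sum w$, with
the largest part absorbing the floating-point residue so parts sum to the
total exactly. Final composition is volume-weighted mixing, hence
independent of total volume — the property that makes a validated 10 µl
PCR-tube trial transfer to a 500 µl batch. Reported volumes print to the
nearest µl at ≥ 100 µl and to 0.1 µl below (so a 1:1:1 split of 500 µl
reports as 167 µl), matching how such protocols are written up.
`retune_seed()` changes only the seed part's weight and logs the old and
new volumes; no kinetic model links seed load to final crystal size — that
mapping is empirical, which is exactly why the titration module exists.
Seed dilution (1:100, 1:200, …) is a property of the seed part's
*mixture*, orthogonal to its ratio *weight*; both knobs exist because both
are used in practice. Recipes take per-part source mixtures rather than
deriving everything from one cocktail, because published final
formulations sometimes hold one component fixed (e.g. citrate) while
another is diluted — only per-component sources can express that.

## Numerical choices

* Feasibility tolerance: $\max(10^{-9}, 10^{-5} V_d)$ µl of negative
  diluent is treated as zero, absorbing corner targets printed at 4–5
  significant figures that close the drop only approximately.
* `volume_for_target()` tolerates a $10^{-9}$ relative excess of target
  over stock before raising an infeasible-target error, so bilinear blends
  of corners exactly at the stock concentration do not fail on
  floating-point dust.
* Channel rounding snaps to the robot grid and then to 12 decimals, so a
  written CSV parses back to bit-identical doubles (determinism is tested
  byte-wise).
* Staircase tie-breaks are fully deterministic (margin, then the higher
  staircase), so estimator output is reproducible and comparable against
  enumeration.
* All simulator randomness flows from one integer seed through R's RNG,
  saved and restored around each simulation, so a simulation never
  perturbs the caller's RNG state.

## Problem sizes in the checks

The package's own test-suite and the acceptance script use: exhaustive
truth-table verification (25 cases); 200 random grids up to 8 × 8 for
estimator-vs-enumeration equality; 50 random models on grids up to
12 × 12 for exact zone recovery; 10 monotone models on ≥ 10 × 10 grids
for staircase-vs-$S(c)$ tracking within one grid spacing. These sizes
give full coverage of the discrete logic (the truth table and small-grid
staircase space are checked exhaustively) while keeping the whole suite
in seconds.

## Known limitations

* Outcomes are taken as scored; there is no image analysis, and scoring
  noise propagates directly into zone calls (an `inconsistent` flag is the
  only defense).
* The frontier estimator assumes monotone boundaries within each
  metastable component; landscapes that violate monotonicity *within* a
  component would be summarized by a staircase that minimizes
  misclassification but may not be meaningful.
* The simulator's threshold model has no time axis: incubation effects,
  slow nucleation and ripening are invisible.
* Mixing is ideal; strongly non-additive mixtures (high PEG, glycerol)
  will dispense slightly off-target in reality.
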