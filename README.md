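# phaseplan

Design and analysis of automated microbatch-under-oil crystallization
phase diagrams, for structural biologists preparing microcrystal samples —
in particular for serial crystallography (SX), where success hinges on
dense, uniform microcrystal suspensions rather than single large crystals.

Macromolecular crystallization is governed by the phase diagram in
(precipitant, protein) concentration space, partitioned by the solubility
curve S(c) into an undersaturated region (σ = P/S(c) < 1), a **metastable**
zone where crystals grow but nucleation is kinetically hindered
(1 ≤ σ < σ_nuc), a labile **nucleation** zone of spontaneous growth
(σ_nuc ≤ σ < σ_prec) and a **precipitation** region (σ ≥ σ_prec).
Microbatch-under-oil drops do not evaporate, so the composition at
nucleation is known and constant — ideal for mapping these boundaries
empirically. `phaseplan` provides the full desk-side toolchain around such
experiments:

* **Diagonal-sampling plate design.** Four user-defined corner conditions
  are bilinearly interpolated over an r × c grid, so concentration
  gradients run roughly parallel to the expected solubility boundary.
  Per-well four-channel dispense volumes (protein / cocktail / seed /
  diluent, `v = V_drop · target / stock`), robot-precision rounding,
  feasibility flags and protein-mass budgets come out as tidy tables plus
  worklist CSVs.
* **Zone classification.** Paired seeded/unseeded drop outcomes
  (clear / crystals / shower / precipitate) are classified by the two-arm
  truth table: spontaneous crystals ⇒ nucleation; crystals only upon
  seeding ⇒ metastable; both clear ⇒ undersaturated.
* **Monotone frontier estimation.** The solubility and nucleation
  boundaries are fitted as monotone non-increasing staircases minimizing
  misclassified wells (exact dynamic program, equal to exhaustive search),
  with per-component segments when the landscape splits into several
  metastable regions.
* **Seed titration and scale-up.** Serial-dilution ladders (neat to 1e-7),
  cross-matrix titration plates, and ratio-based batch recipes
  (e.g. 1:1:2 protein:precipitant:seed at 500 µl) with seed re-tuning.
* **A built-in simulator.** A log-quadratic solubility model
  `ln S(c) = ln S0 + βc − Kc²` (Cohn-style salting-out plus optional
  salting-in) with supersaturation thresholds generates deterministic
  ground-truth outcomes, so the whole design → observe → classify →
  estimate loop is testable without a laboratory.

## Worked example

```r
library(phaseplan)

stocks <- stock_set(
  protein_stock  = mixture(data.frame(component = "xylanase",       conc = 36, unit = "mg_per_ml")),
  cocktail_stock = mixture(data.frame(component = "sodium_formate", conc = 8,  unit = "M")))

grid <- grid_design(
  rows = 6, cols = 8, drop_volume_ul = 2,
  corners = corner_spec(protein     = c(20,  8,   8,   2),     # r0c0, r0cN, rNc0, rNcN
                        precipitant = c(1.6, 5.2, 3.2, 6.8)))

plate <- plan_plate(grid, stocks)
plate
#> <plate design> 6 x 8 wells, 2 ul drops (48 feasible)
#>   consumption: protein 25.31 ul (0.911 mg), cocktail 50.40 ul, seed 0.00 ul, diluent 20.29 ul
```

The consumption line is the experiment's budget: 25.3 µl of the 36 mg/ml
stock, i.e. 0.91 mg of protein for a full 48-well diagram. Each well's
channel volumes sum to the 2 µl drop exactly:

```r
dplyr::select(tidy(plate), well, protein_mg_ml, precipitant_conc, v_protein_ul, v_cocktail_ul)
#> # A tibble: 48 x 5
#>   well  protein_mg_ml precipitant_conc v_protein_ul v_cocktail_ul
#> 1 A1             20               1.6          1.11          0.4
#> 2 A2             18.3             2.11         1.02          0.53
#> ...
```

Score the plate (here: simulated observations from a known model; swap in
`read_observations()` for a scored real plate) and build the diagram:

```r
model <- phase_model(S0 = 24, K = 0.09, sigma_nuc = 2, sigma_shower = 4,
                     sigma_prec = 8, seed = 7)
obs <- simulate_plate(model, plate)
diagram <- build_phase_diagram(plate, obs)
diagram
#> <phase diagram> 48 wells (48 classified)
#>   undersaturated: 4 (8.3%)
#>   metastable: 22 (45.8%)
#>   nucleation: 22 (45.8%)

head(diagram$solubility_frontier, 2)
#> # A tibble: 2 x 3
#>   segment precipitant protein
#> 1       1        1.6     15.6
#> 2       1        1.92    15.6
```

Nearly half the diagram is metastable — accessible only with seeds, the
key information for choosing SX growth conditions. `autoplot(diagram)`
draws the diamond plot with the estimated staircase boundaries. Finally,
scale the chosen condition to a batch:

```r
rec <- make_recipe(tibble::tibble(
  role    = c("protein", "precipitant", "seed"),
  weight  = c(1, 1, 2),
  mixture = list(protein_stock, cocktail, dilute(seed_carrier, 1/100))),
  total_volume_ul = 500)
#> <batch recipe> 500 ul total, ratio 1:1:2
#>   protein      125 ul
#>   precipitant  125 ul
#>   seed         250 ul
```

A command-line interface wraps the same functions
(`inst/cli/phaseplan.R`): `phaseplan design|simulate|classify|titrate|
scaleup|fixture`, with `--seed` controlling all randomness.

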