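#' Define the stock set for a plate
#'
#' Bundles the four dispense channels of a microbatch-under-oil experiment:
#' protein stock, crystallization cocktail, seed stock (characterized by its
#' dilution relative to neat plus an optional chemical carrier) and diluent
#' (typically water). The cocktail is always co-diluted as a unit: its
#' designated primary precipitant sets the channel volume and every other
#' cocktail component (buffer, additives) scales with it.
#'
#' @param protein_stock [mixture()] holding one protein component in
#'   `mg_per_ml`.
#' @param cocktail_stock [mixture()] holding the crystallization cocktail.
#' @param protein Name of the protein component. Defaults to the single
#'   `mg_per_ml` component of `protein_stock`.
#' @param precipitant Name of the primary precipitant in `cocktail_stock`.
#'   Defaults to its highest-concentration component.
#' @param diluent [mixture()] used as diluent; defaults to [water()].
#' @param seed_carrier [mixture()] describing the chemical carrier of the
#'   seed stock (usually the mother-liquor condition the seeds came from).
#' @param seed_stock_dilution Dilution of the working seed stock relative to
#'   neat, in (0, 1].
#' @return Object of class `pp_stock_set`.
#' @examples
#' xyl <- stock_set(
#'   protein_stock = mixture(data.frame(
#'     component = "xylanase", conc = 36, unit = "mg_per_ml")),
#'   cocktail_stock = mixture(data.frame(
#'     component = "sodium_formate", conc = 8, unit = "M"))
#' )
#' @export
stock_set <- function(protein_stock, cocktail_stock,
                      protein = NULL, precipitant = NULL,
                      diluent = water(), seed_carrier = water(),
                      seed_stock_dilution = 1) {
  pp_assert(inherits(protein_stock, "pp_mixture") &&
              inherits(cocktail_stock, "pp_mixture") &&
              inherits(diluent, "pp_mixture") &&
              inherits(seed_carrier, "pp_mixture"),
            "stocks must be mixtures", "pp_invalid_input")
  if (is.null(protein)) {
    cand <- protein_stock$component[protein_stock$unit == "mg_per_ml"]
    pp_assert(length(cand) == 1,
              "`protein` must be given when the protein stock does not hold exactly one mg_per_ml component",
              "pp_invalid_input")
    protein <- cand
  }
  pp_assert(protein %in% protein_stock$component,
            sprintf("protein component '%s' not found in protein stock", protein),
            "pp_invalid_input")
  pp_assert(conc_of(protein_stock, protein) > 0,
            "protein stock concentration must be > 0", "pp_invalid_input")
  if (is.null(precipitant)) {
    pp_assert(nrow(cocktail_stock) > 0,
              "cocktail stock has no components; name a `precipitant`",
              "pp_invalid_input")
    precipitant <- cocktail_stock$component[which.max(cocktail_stock$conc)]
  }
  pp_assert(precipitant %in% cocktail_stock$component &&
              conc_of(cocktail_stock, precipitant) > 0,
            sprintf("primary precipitant '%s' must be in the cocktail with concentration > 0",
                    precipitant),
            "pp_invalid_input")
  pp_assert(is.numeric(seed_stock_dilution) && length(seed_stock_dilution) == 1 &&
              seed_stock_dilution > 0 && seed_stock_dilution <= 1,
            "`seed_stock_dilution` must be in (0, 1]", "pp_range_error")
  structure(
    list(protein_stock = protein_stock, cocktail_stock = cocktail_stock,
         protein = protein, precipitant = precipitant,
         diluent = diluent, seed_carrier = seed_carrier,
         seed_stock_dilution = as.numeric(seed_stock_dilution)),
    class = "pp_stock_set")
}

#' @export
print.pp_stock_set <- function(x, ...) {
  cat(sprintf("<stock set> protein '%s' at %g mg/ml; precipitant '%s' at %g %s; seed dilution %g\n",
              x$protein, conc_of(x$protein_stock, x$protein),
              x$precipitant, conc_of(x$cocktail_stock, x$precipitant),
              unit_of(x$cocktail_stock, x$precipitant),
              x$seed_stock_dilution))
  invisible(x)
}

protein_stock_conc <- function(stocks) conc_of(stocks$protein_stock, stocks$protein)
precipitant_stock_conc <- function(stocks) conc_of(stocks$cocktail_stock, stocks$precipitant)

#' Corner conditions of a diagonal-sampling grid
#'
#' The experimenter defines the plate by its four corner conditions; every
#' other well is interpolated. Corners need not form a rectangle in
#' (precipitant, protein) space -- that is the point of diagonal sampling:
#' choosing corners so that well-to-well gradients run roughly parallel to
#' the expected solubility boundary concentrates sampling where the zone
#' transitions occur.
#'
#' @param protein Length-4 numeric, protein targets (mg/ml) in layout order
#'   top-left, top-right, bottom-left, bottom-right, i.e. (row 0, col 0),
#'   (row 0, col N), (row N, col 0), (row N, col N).
#' @param precipitant Length-4 numeric, primary-precipitant targets in the
#'   cocktail stock's unit, same order.
#' @return Tibble of class `pp_corners` with columns `corner`, `protein`,
#'   `precipitant`.
#' @export
corner_spec <- function(protein, precipitant) {
  pp_assert(is.numeric(protein) && length(protein) == 4 && all(protein >= 0),
            "`protein` must be 4 non-negative numbers", "pp_invalid_input")
  pp_assert(is.numeric(precipitant) && length(precipitant) == 4 && all(precipitant >= 0),
            "`precipitant` must be 4 non-negative numbers", "pp_invalid_input")
  out <- tibble(corner = c("r0c0", "r0cN", "rNc0", "rNcN"),
                protein = as.numeric(protein),
                precipitant = as.numeric(precipitant))
  structure(out, class = c("pp_corners", class(out)))
}

#' Define a plate grid
#'
#' @param rows,cols Grid dimensions (each >= 2).
#' @param drop_volume_ul Final drop volume per well in microlitres (the
#'   experiments this package models used 2 ul drops).
#' @param corners A [corner_spec()].
#' @param seed_mode `"none"` (unseeded plate), `"premixed_in_cocktail"`
#'   (seed stock premixed into the cocktail channel; channel volumes are
#'   unchanged) or `"separate_channel"` (a fourth channel dispenses seed
#'   stock at a fixed fraction of the drop).
#' @param seed_fraction Fraction of the drop volume occupied by the seed
#'   channel when `seed_mode = "separate_channel"`; in \[0, 1).
#' @param robot_precision_ul Dispensing resolution of the robot; channel
#'   volumes are rounded to this grid with the residual pushed into the
#'   diluent channel so each well still sums exactly to `drop_volume_ul`.
#' @param min_dispense_ul Smallest dispensable non-zero volume; wells
#'   requiring a smaller non-zero channel are flagged infeasible.
#' @param transpose Swap the roles of rows and columns (rows then index
#'   precipitant instead of protein).
#' @param plate_capacity Maximum number of wells.
#' @return Object of class `pp_grid`.
#' @export
grid_design <- function(rows, cols, drop_volume_ul, corners,
                        seed_mode = c("none", "premixed_in_cocktail", "separate_channel"),
                        seed_fraction = 0.1,
                        robot_precision_ul = 0.01,
                        min_dispense_ul = 0.1,
                        transpose = FALSE,
                        plate_capacity = 384L) {
  seed_mode <- match.arg(seed_mode)
  pp_assert(rows >= 2 && cols >= 2, "grid needs rows >= 2 and cols >= 2", "pp_design_error")
  pp_assert(rows * cols <= plate_capacity,
            sprintf("%d wells exceed the plate capacity of %d", rows * cols, plate_capacity),
            "pp_design_error")
  pp_assert(is.numeric(drop_volume_ul) && drop_volume_ul > 0,
            "`drop_volume_ul` must be > 0", "pp_design_error")
  pp_assert(inherits(corners, "pp_corners"), "`corners` must be a corner_spec()", "pp_invalid_input")
  pp_assert(seed_fraction >= 0 && seed_fraction < 1,
            "`seed_fraction` must be in [0, 1)", "pp_range_error")
  pp_assert(robot_precision_ul > 0 && min_dispense_ul >= 0,
            "robot precision must be > 0 and min dispense >= 0", "pp_range_error")
  if (isTRUE(transpose)) {
    corners <- corner_spec(corners$protein[c(1, 3, 2, 4)],
                           corners$precipitant[c(1, 3, 2, 4)])
  }
  structure(
    list(rows = as.integer(rows), cols = as.integer(cols),
         drop_volume_ul = as.numeric(drop_volume_ul), corners = corners,
         seed_mode = seed_mode, seed_fraction = as.numeric(seed_fraction),
         robot_precision_ul = as.numeric(robot_precision_ul),
         min_dispense_ul = as.numeric(min_dispense_ul)),
    class = "pp_grid")
}

well_labels <- function(row, col) {
  # rows -> letters (A, B, ..., Z, AA, AB, ...), cols -> 1-based numbers
  letter <- function(r) {
    if (r < 26) LETTERS[r + 1] else paste0(LETTERS[r %/% 26], LETTERS[r %% 26 + 1])
  }
  paste0(vapply(row, letter, character(1)), col + 1L)
}

#' Bilinearly interpolate the four corner conditions over a grid
#'
#' Well (r, c) maps to normalized coordinates (u, v) = (r/(rows-1),
#' c/(cols-1)) and takes the bilinear blend of the four corners in both the
#' protein and the precipitant coordinate. Grid corners reproduce the input
#' corners exactly; along any single row or column both coordinates are
#' affine in the well index.
#'
#' @param corners A [corner_spec()].
#' @param rows,cols Grid dimensions (>= 2).
#' @return Tibble with columns `row`, `col` (0-based, row-major order),
#'   `protein`, `precipitant`.
#' @export
interpolate_corners <- function(corners, rows, cols) {
  pp_assert(inherits(corners, "pp_corners"), "`corners` must be a corner_spec()", "pp_invalid_input")
  pp_assert(rows >= 2 && cols >= 2, "grid needs rows >= 2 and cols >= 2", "pp_design_error")
  grid <- tidyr::expand_grid(row = 0:(rows - 1), col = 0:(cols - 1))
  u <- grid$row / (rows - 1)
  v <- grid$col / (cols - 1)
  blend <- function(x) {
    (1 - u) * (1 - v) * x[1] + (1 - u) * v * x[2] + u * (1 - v) * x[3] + u * v * x[4]
  }
  tibble(row = grid$row, col = grid$col,
         protein = blend(corners$protein),
         precipitant = blend(corners$precipitant))
}

# Feasibility slack: absorbs corner specifications printed at 4-5 significant
# figures whose channel volumes close the drop to within ~1e-5 ul.
feasibility_tol <- function(drop_volume_ul) max(1e-9, 1e-5 * drop_volume_ul)

#' Plan the channel volumes for one well
#'
#' Converts a (protein, precipitant) target into the four channel volumes
#' protein / cocktail / seed / diluent that realize it in a drop of the
#' grid's volume: `v_protein = V_d * P / P_stock`,
#' `v_cocktail = V_d * c / C_stock` (the whole cocktail is co-diluted, so
#' every cocktail component scales together), `v_seed = V_d * seed_fraction`
#' for a separate seed channel, and the diluent takes the remainder. Volumes
#' are exact (unrounded); [plan_plate()] applies robot-precision rounding.
#'
#' A target whose protein or precipitant exceeds its stock is an error; a
#' target whose channel volumes overfill the drop (negative diluent) is
#' *flagged* infeasible, not an error, so plate reports stay honest about
#' the unreachable corner of phase space.
#'
#' @param protein_mg_ml Target final protein concentration (mg/ml).
#' @param precipitant_conc Target final primary-precipitant concentration in
#'   the cocktail stock's unit.
#' @param stocks A [stock_set()].
#' @param grid A [grid_design()].
#' @return One-row tibble with the target, the four channel volumes and a
#'   `feasible` flag.
#' @examples
#' xyl <- stock_set(
#'   mixture(data.frame(component = "xylanase", conc = 36, unit = "mg_per_ml")),
#'   mixture(data.frame(component = "sodium_formate", conc = 8, unit = "M")))
#' grid <- grid_design(2, 2, 2, corner_spec(c(20, 20, 5, 5), c(1, 6, 1, 6)))
#' plan_well(15.95, 4.4556, xyl, grid)
#' @export
plan_well <- function(protein_mg_ml, precipitant_conc, stocks, grid) {
  pp_assert(inherits(stocks, "pp_stock_set"), "`stocks` must be a stock_set()", "pp_invalid_input")
  pp_assert(inherits(grid, "pp_grid"), "`grid` must be a grid_design()", "pp_invalid_input")
  pp_assert(all(protein_mg_ml >= 0) && all(precipitant_conc >= 0),
            "targets must be non-negative", "pp_invalid_input")
  V <- grid$drop_volume_ul
  v_p <- volume_for_target(protein_mg_ml, protein_stock_conc(stocks), V,
                           component = stocks$protein)
  v_c <- volume_for_target(precipitant_conc, precipitant_stock_conc(stocks), V,
                           component = stocks$precipitant)
  v_s <- if (grid$seed_mode == "separate_channel") {
    rep_len(V * grid$seed_fraction, length(v_p))
  } else {
    rep_len(0, length(v_p))
  }
  v_d <- V - (v_p + v_c + v_s)
  tol <- feasibility_tol(V)
  feasible <- v_d >= -tol
  v_d <- pmax(v_d, 0)
  # every non-zero channel must also be individually dispensable
  min_ok <- function(v) v == 0 | v >= grid$min_dispense_ul - 1e-12
  feasible <- feasible & min_ok(v_p) & min_ok(v_c) & min_ok(v_s) & min_ok(v_d)
  tibble(protein_mg_ml = as.numeric(protein_mg_ml),
         precipitant_conc = as.numeric(precipitant_conc),
         v_protein_ul = v_p, v_cocktail_ul = v_c,
         v_seed_ul = v_s, v_diluent_ul = v_d,
         feasible = feasible)
}

# snap to the robot's dispense grid; the final decimal rounding keeps the
# stored doubles identical to their CSV round-trip
round_to <- function(x, precision) round(round(x / precision) * precision, 12)

#' Plan a full plate
#'
#' Interpolates the grid's corner conditions over every well
#' ([interpolate_corners()]), computes the four channel volumes per well
#' ([plan_well()]), rounds them to the robot's precision (the rounding
#' residual is pushed into the diluent channel so each well sums exactly to
#' the drop volume), labels wells row-major (A1, A2, ...), and accumulates
#' per-channel consumption totals plus the protein mass budget
#' (`sum(v_protein) * P_stock / 1000` mg).
#'
#' Infeasible wells are retained and flagged -- never dropped -- but are
#' excluded from the consumption totals (they would not be dispensed).
#'
#' @param grid A [grid_design()].
#' @param stocks A [stock_set()].
#' @return Object of class `pp_plate`: see [tidy()][tidy.pp_plate] for the
#'   per-well table and [glance()][glance.pp_plate] for the totals.
#' @export
plan_plate <- function(grid, stocks) {
  targets <- interpolate_corners(grid$corners, grid$rows, grid$cols)
  plans <- plan_well(targets$protein, targets$precipitant, stocks, grid)
  prec <- grid$robot_precision_ul
  V <- grid$drop_volume_ul

  v_p <- round_to(plans$v_protein_ul, prec)
  v_c <- round_to(plans$v_cocktail_ul, prec)
  v_s <- round_to(plans$v_seed_ul, prec)
  v_d <- V - (v_p + v_c + v_s)
  v_d <- round_to(v_d, prec)
  # a rounded-up trio can overfill by a precision step or two: take the
  # deficit out of the largest active channel so the well still closes
  for (i in which(v_d < 0 & plans$feasible)) {
    deficit <- -v_d[i]
    ch <- which.max(c(v_p[i], v_c[i], v_s[i]))
    if (ch == 1) v_p[i] <- v_p[i] - deficit
    if (ch == 2) v_c[i] <- v_c[i] - deficit
    if (ch == 3) v_s[i] <- v_s[i] - deficit
    v_d[i] <- 0
  }
  v_d[v_d < 0 & !plans$feasible] <- 0

  wells <- tibble(
    well = well_labels(targets$row, targets$col),
    row = targets$row, col = targets$col,
    protein_mg_ml = plans$protein_mg_ml,
    precipitant_conc = plans$precipitant_conc,
    precipitant_unit = unit_of(stocks$cocktail_stock, stocks$precipitant),
    v_protein_ul = v_p, v_cocktail_ul = v_c,
    v_seed_ul = v_s, v_diluent_ul = v_d,
    feasible = plans$feasible)

  if (!any(wells$feasible)) {
    pp_abort(paste0(
      "no feasible well: every target overfills the drop. Feasible targets satisfy ",
      "P/P_stock + c/C_stock + seed_fraction <= 1 with P_stock = ",
      protein_stock_conc(stocks), " mg/ml and C_stock = ",
      precipitant_stock_conc(stocks), " ", unit_of(stocks$cocktail_stock, stocks$precipitant)),
      "pp_design_error")
  }
  new_plate(wells, grid, stocks)
}

new_plate <- function(wells, grid, stocks, subclass = character()) {
  feas <- wells[wells$feasible, , drop = FALSE]
  totals <- list(
    volume_ul = c(protein = sum(feas$v_protein_ul),
                  cocktail = sum(feas$v_cocktail_ul),
                  seed = sum(feas$v_seed_ul),
                  diluent = sum(feas$v_diluent_ul)),
    protein_mass_mg = sum(feas$v_protein_ul) * protein_stock_conc(stocks) / 1000)
  structure(list(wells = wells, grid = grid, stocks = stocks, totals = totals),
            class = c(subclass, "pp_plate"))
}

#' @export
print.pp_plate <- function(x, ...) {
  cat(sprintf("<plate design> %d x %d wells, %g ul drops (%d feasible)\n",
              x$grid$rows, x$grid$cols, x$grid$drop_volume_ul,
              sum(x$wells$feasible)))
  v <- x$totals$volume_ul
  cat(sprintf("  consumption: protein %.2f ul (%.3g mg), cocktail %.2f ul, seed %.2f ul, diluent %.2f ul\n",
              v[["protein"]], x$totals$protein_mass_mg, v[["cocktail"]],
              v[["seed"]], v[["diluent"]]))
  invisible(x)
}

#' @describeIn plan_plate Per-well tibble of a plate design.
#' @param x A `pp_plate`.
#' @param ... Unused.
#' @export
tidy.pp_plate <- function(x, ...) x$wells

#' @describeIn plan_plate One-row summary: well counts, per-channel
#'   consumption and protein mass.
#' @export
glance.pp_plate <- function(x, ...) {
  v <- x$totals$volume_ul
  tibble(n_wells = nrow(x$wells), n_feasible = sum(x$wells$feasible),
         drop_volume_ul = x$grid$drop_volume_ul,
         v_protein_ul = v[["protein"]], v_cocktail_ul = v[["cocktail"]],
         v_seed_ul = v[["seed"]], v_diluent_ul = v[["diluent"]],
         protein_mass_mg = x$totals$protein_mass_mg)
}

#' Export a robot worklist
#'
#' One row per (well, channel) dispense, for feasible wells only, in the
#' fixed channel order diluent, cocktail, seed, protein (largest first,
#' protein last so the reactive component enters a pre-mixed drop). Rows
#' with zero volume are omitted.
#'
#' @param plate A `pp_plate` from [plan_plate()] or [cross_matrix()].
#' @return Tibble with columns `well`, `channel`, `source_name`,
#'   `volume_ul`.
#' @export
export_worklist <- function(plate) {
  pp_assert(inherits(plate, "pp_plate"), "`plate` must be a pp_plate", "pp_invalid_input")
  wells <- plate$wells[plate$wells$feasible, , drop = FALSE]
  channels <- tibble(
    channel = c("diluent", "cocktail", "seed", "protein"),
    source_name = c("diluent", "cocktail", "seed_stock", "protein_stock"),
    colname = c("v_diluent_ul", "v_cocktail_ul", "v_seed_ul", "v_protein_ul"),
    ord = 1:4)
  out <- tidyr::expand_grid(well = wells$well, ord = channels$ord) |>
    left_join(channels, by = "ord") |>
    left_join(wells[, c("well", "v_protein_ul", "v_cocktail_ul", "v_seed_ul", "v_diluent_ul")],
              by = "well")
  out$volume_ul <- map2_dbl(seq_len(nrow(out)), out$colname,
                            function(i, cn) out[[cn]][i])
  out <- out[out$volume_ul > 0, c("well", "channel", "source_name", "volume_ul")]
  # preserve plate (row-major) well order, then channel order
  out[order(match(out$well, wells$well)), ]
}

#' Read and write plate maps and worklists
#'
#' Plate maps are plain CSV with columns `well`, `row`, `col`,
#' `protein_mg_ml`, `precipitant_conc`, `precipitant_unit`, `v_protein_ul`,
#' `v_cocktail_ul`, `v_seed_ul`, `v_diluent_ul`, `feasible`; worklists have
#' `well`, `channel`, `source_name`, `volume_ul`. [read_plate()] returns the
#' per-well tibble, which is what [build_phase_diagram()] and
#' [simulate_plate()] accept.
#'
#' @param plate A `pp_plate` (or its [tidy()] tibble for `write_plate`).
#' @param path File path.
#' @return `read_plate` and `read_worklist` return tibbles; the writers
#'   return `path` invisibly.
#' @export
write_plate <- function(plate, path) {
  wells <- if (inherits(plate, "pp_plate")) plate$wells else as_tibble(plate)
  readr::write_csv(wells, path)
  invisible(path)
}

#' @rdname write_plate
#' @export
read_plate <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    well = readr::col_character(),
    row = readr::col_integer(),
    col = readr::col_integer(),
    precipitant_unit = readr::col_character(),
    feasible = readr::col_logical(),
    .default = readr::col_double()))
}

#' @rdname write_plate
#' @export
write_worklist <- function(plate, path) {
  wl <- if (inherits(plate, "pp_plate")) export_worklist(plate) else as_tibble(plate)
  readr::write_csv(wl, path)
  invisible(path)
}

#' @rdname write_plate
#' @export
read_worklist <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    well = readr::col_character(),
    channel = readr::col_character(),
    source_name = readr::col_character(),
    volume_ul = readr::col_double()))
}

#' Reconstruct a well's drop composition from its channel volumes
#'
#' Re-mixes the planned channel volumes through [mix()]; useful to verify
#' that a plan reproduces its target within rounding tolerance.
#'
#' @param well One-row slice of a plate's well table.
#' @param stocks The plate's [stock_set()].
#' @return A [mixture()].
#' @export
well_composition <- function(well, stocks) {
  seed_mix <- mix_seed_stock(stocks)
  mix(bind_rows(
    part(stocks$protein_stock, well$v_protein_ul),
    part(stocks$cocktail_stock, well$v_cocktail_ul),
    part(seed_mix, well$v_seed_ul),
    part(stocks$diluent, well$v_diluent_ul)))
}

# working seed stock = carrier diluted to the stock-set's working dilution
mix_seed_stock <- function(stocks) {
  dilute(stocks$seed_carrier, stocks$seed_stock_dilution)
}
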