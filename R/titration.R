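#' Serial-dilution factor ladder
#'
#' Analytic construction of a serial dilution: `levels` factors starting at
#' neat (1) and descending by `1/step` each level. Eight decade levels give
#' the ladder 1, 1e-1, ..., 1e-7 used to titrate a seed stock from neat to
#' a 1e-7 dilution.
#'
#' @param levels Number of dilution levels (>= 1), including neat.
#' @param step Fold-dilution per level (> 1); 10 gives decades.
#' @return Numeric vector of factors, strictly decreasing, first element 1.
#' @examples
#' serial_dilution(8, 10)
#' @export
serial_dilution <- function(levels, step = 10) {
  pp_assert(is.numeric(levels) && length(levels) == 1 && levels >= 1 &&
              levels == as.integer(levels),
            "`levels` must be a whole number >= 1", "pp_range_error")
  pp_assert(is.numeric(step) && length(step) == 1 && step > 1,
            "`step` must be > 1", "pp_range_error")
  step^(-(0:(levels - 1)))
}

#' Pipetting plan for a physical serial dilution
#'
#' Transfer volumes realizing [serial_dilution()] factors bench-side: each
#' tube holds `tube_volume_ul` after mixing, made by carrying
#' `tube_volume_ul / step` from the previous tube into
#' `tube_volume_ul * (1 - 1/step)` of diluent.
#'
#' @inheritParams serial_dilution
#' @param tube_volume_ul Final volume per tube.
#' @return Tibble with columns `level`, `factor`, `transfer_ul`,
#'   `diluent_ul`.
#' @export
serial_dilution_plan <- function(levels, step = 10, tube_volume_ul = 100) {
  factors <- serial_dilution(levels, step)
  pp_assert(tube_volume_ul > 0, "`tube_volume_ul` must be > 0", "pp_range_error")
  tibble(level = seq_along(factors), factor = factors,
         transfer_ul = c(NA_real_, rep(tube_volume_ul / step, levels - 1)),
         diluent_ul = c(NA_real_, rep(tube_volume_ul * (1 - 1 / step), levels - 1)))
}

#' Cross-matrix seed-stock titration plate
#'
#' Crosses a seed-stock dilution ladder (rows) against a set of
#' crystallization conditions (columns): every (dilution, condition) pair
#' becomes one well. The seed channel volume is fixed
#' (`seed_fraction * drop_volume_ul`); the seed concentration in the drop
#' varies only through the row's dilution factor, so the ratio between
#' adjacent rows is exactly `1/step`. Condition arithmetic is delegated to
#' [plan_well()]. Duplicate conditions are allowed and flagged as
#' replicates.
#'
#' @param conditions Data frame with columns `protein_mg_ml` and
#'   `precipitant_conc`, one row per condition (plate column).
#' @param dilutions Numeric dilution factors, e.g. [serial_dilution()] output.
#' @param stocks A [stock_set()].
#' @param drop_volume_ul Drop volume per well.
#' @param seed_fraction Fraction of the drop taken by the seed channel.
#' @param robot_precision_ul,min_dispense_ul,plate_capacity See
#'   [grid_design()].
#' @return Object of class `pp_titration`/`pp_plate` whose well table
#'   carries extra columns `seed_dilution` (row factor) and `replicate`
#'   (occurrence index of the condition; > 1 marks a replicate).
#' @export
cross_matrix <- function(conditions, dilutions, stocks, drop_volume_ul,
                         seed_fraction = 0.1,
                         robot_precision_ul = 0.01, min_dispense_ul = 0.1,
                         plate_capacity = 384L) {
  pp_assert(is.data.frame(conditions) && nrow(conditions) > 0 &&
              all(c("protein_mg_ml", "precipitant_conc") %in% names(conditions)),
            "`conditions` must be a non-empty data frame with protein_mg_ml and precipitant_conc",
            "pp_invalid_input")
  pp_assert(is.numeric(dilutions) && length(dilutions) > 0 &&
              all(dilutions > 0 & dilutions <= 1),
            "`dilutions` must be factors in (0, 1]", "pp_range_error")
  n_rows <- length(dilutions)
  n_cols <- nrow(conditions)
  pp_assert(n_rows * n_cols <= plate_capacity,
            sprintf("%d x %d titration exceeds the plate capacity of %d",
                    n_rows, n_cols, plate_capacity),
            "pp_design_error")

  # a synthetic grid carries drop volume / precision / seed settings; its
  # corner values are placeholders (targets come from `conditions`)
  grid <- grid_design(max(n_rows, 2), max(n_cols, 2), drop_volume_ul,
                      corner_spec(rep(0, 4), rep(0, 4)),
                      seed_mode = "separate_channel",
                      seed_fraction = seed_fraction,
                      robot_precision_ul = robot_precision_ul,
                      min_dispense_ul = min_dispense_ul,
                      plate_capacity = plate_capacity)

  layout <- tidyr::expand_grid(row = 0:(n_rows - 1), col = 0:(n_cols - 1))
  cond_key <- paste(conditions$protein_mg_ml, conditions$precipitant_conc)
  replicate_idx <- ave(seq_len(n_cols), cond_key, FUN = seq_along)

  plans <- plan_well(conditions$protein_mg_ml[layout$col + 1],
                     conditions$precipitant_conc[layout$col + 1],
                     stocks, grid)
  prec <- robot_precision_ul
  v_p <- round_to(plans$v_protein_ul, prec)
  v_c <- round_to(plans$v_cocktail_ul, prec)
  v_s <- round_to(plans$v_seed_ul, prec)
  v_d <- round_to(drop_volume_ul - (v_p + v_c + v_s), prec)
  v_d[v_d < 0] <- 0

  wells <- tibble(
    well = well_labels(layout$row, layout$col),
    row = layout$row, col = layout$col,
    protein_mg_ml = plans$protein_mg_ml,
    precipitant_conc = plans$precipitant_conc,
    precipitant_unit = unit_of(stocks$cocktail_stock, stocks$precipitant),
    v_protein_ul = v_p, v_cocktail_ul = v_c, v_seed_ul = v_s, v_diluent_ul = v_d,
    feasible = plans$feasible,
    seed_dilution = dilutions[layout$row + 1],
    replicate = replicate_idx[layout$col + 1])
  if (!any(wells$feasible)) {
    pp_abort("no feasible well in the titration: conditions overfill the drop once the seed channel is reserved",
             "pp_design_error")
  }
  new_plate(wells, grid, stocks, subclass = "pp_titration")
}

#' @export
print.pp_titration <- function(x, ...) {
  cat(sprintf("<seed titration> %d dilution levels x %d conditions (%d wells)\n",
              length(unique(x$wells$seed_dilution)),
              length(unique(x$wells$col)), nrow(x$wells)))
  cat(sprintf("  dilution range: %g down to %g of neat\n",
              max(x$wells$seed_dilution), min(x$wells$seed_dilution)))
  invisible(x)
}
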