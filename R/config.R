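#' Load an experiment configuration
#'
#' Reads and validates a JSON experiment config into a `pp_config`
#' (a validated [stock_set()] + [grid_design()] + RNG seed). Every
#' validation failure names the offending JSON path; unknown keys are
#' warnings, not errors. Molar units are canonicalized to mM on load
#' ([normalize_units()]) and applied defaults are echoed to the log
#' (suppress with `quiet = TRUE`).
#'
#' Schema sketch:
#' ```
#' {
#'   "stocks": {
#'     "protein_stock":  {"components": {"xylanase": {"conc": 36, "unit": "mg_per_ml"}}},
#'     "cocktail_stock": {"components": {"sodium_formate": {"conc": 8, "unit": "M"}}},
#'     "precipitant": "sodium_formate",
#'     "seed_stock_dilution": 1, "seed_carrier": {...}, "diluent": {...}
#'   },
#'   "grid": {
#'     "rows": 8, "cols": 12, "drop_volume_ul": 2,
#'     "corners": {"protein": [20, 8, 10, 2], "precipitant": [1000, 5000, 3000, 7000]},
#'     "seed_mode": "none", "seed_fraction": 0.1,
#'     "robot_precision_ul": 0.01, "min_dispense_ul": 0.1
#'   },
#'   "seed": 1
#' }
#' ```
#'
#' @param path Path to the JSON file.
#' @param quiet Suppress the default-echo log messages.
#' @return Object of class `pp_config` with elements `stocks`, `grid`,
#'   `seed`.
#' @export
load_config <- function(path, quiet = FALSE) {
  pp_assert(file.exists(path), paste0("config file not found: ", path), "pp_config_error")
  x <- jsonlite::read_json(path)
  errors <- character(0)
  note <- function(msg) errors <<- c(errors, msg)

  known_top <- c("stocks", "grid", "seed")
  unknown <- setdiff(names(x), known_top)
  if (length(unknown) > 0) {
    warn(paste0("ignoring unknown config key(s): ", paste(unknown, collapse = ", ")),
         class = "pp_config_warning")
  }
  if (is.null(x$stocks)) note("stocks: missing")
  if (is.null(x$grid)) note("grid: missing")
  if (length(errors) > 0) {
    pp_abort(paste0("invalid config:\n", paste0("  - ", errors, collapse = "\n")),
             "pp_config_error")
  }

  known_stocks <- c("protein_stock", "cocktail_stock", "protein", "precipitant",
                    "seed_stock_dilution", "seed_carrier", "diluent")
  unknown <- setdiff(names(x$stocks), known_stocks)
  if (length(unknown) > 0) {
    warn(paste0("ignoring unknown stocks key(s): ",
                paste0("stocks.", unknown, collapse = ", ")),
         class = "pp_config_warning")
  }
  get_mix <- function(field, default = NULL) {
    raw <- x$stocks[[field]]
    if (is.null(raw)) return(default)
    tryCatch(normalize_units(mixture_from_json_list(raw, paste0("stocks.", field))),
             error = function(e) {
               note(paste0("stocks.", field, ": ", conditionMessage(e)))
               NULL
             })
  }
  protein_stock <- get_mix("protein_stock")
  cocktail_stock <- get_mix("cocktail_stock")
  if (is.null(protein_stock)) note("stocks.protein_stock: missing")
  if (is.null(cocktail_stock)) note("stocks.cocktail_stock: missing")
  diluent <- get_mix("diluent", water())
  seed_carrier <- get_mix("seed_carrier", water())

  g <- x$grid
  known_grid <- c("rows", "cols", "drop_volume_ul", "corners", "seed_mode",
                  "seed_fraction", "robot_precision_ul", "min_dispense_ul",
                  "transpose", "plate_capacity")
  unknown <- setdiff(names(g), known_grid)
  if (length(unknown) > 0) {
    warn(paste0("ignoring unknown grid key(s): ",
                paste0("grid.", unknown, collapse = ", ")),
         class = "pp_config_warning")
  }
  num <- function(field, default = NULL, where = "grid") {
    v <- g[[field]] %||% default
    if (is.null(v) || !is.numeric(unlist(v))) {
      note(paste0(where, ".", field, ": must be a number"))
      return(NULL)
    }
    unlist(v)
  }
  rows <- num("rows"); cols <- num("cols")
  drop <- num("drop_volume_ul")
  corners_raw <- g$corners
  corner_pro <- unlist(corners_raw$protein)
  corner_pre <- unlist(corners_raw$precipitant)
  if (length(corner_pro) != 4 || !is.numeric(corner_pro)) {
    note("grid.corners.protein: must be 4 numbers (r0c0, r0cN, rNc0, rNcN)")
  }
  if (length(corner_pre) != 4 || !is.numeric(corner_pre)) {
    note("grid.corners.precipitant: must be 4 numbers (r0c0, r0cN, rNc0, rNcN)")
  }
  defaults_used <- character(0)
  dflt <- function(field, default) {
    v <- g[[field]]
    if (is.null(v)) {
      defaults_used <<- c(defaults_used, sprintf("grid.%s = %s", field, format(default)))
      default
    } else {
      unlist(v)
    }
  }
  seed_mode <- dflt("seed_mode", "none")
  seed_fraction <- dflt("seed_fraction", 0.1)
  precision <- dflt("robot_precision_ul", 0.01)
  min_disp <- dflt("min_dispense_ul", 0.1)
  transpose <- isTRUE(unlist(g$transpose))
  capacity <- dflt("plate_capacity", 384L)
  rng_seed <- x$seed %||% 1L
  if (is.null(x$seed)) defaults_used <- c(defaults_used, "seed = 1")

  if (length(errors) > 0) {
    pp_abort(paste0("invalid config:\n", paste0("  - ", errors, collapse = "\n")),
             "pp_config_error")
  }

  stocks <- tryCatch(
    stock_set(protein_stock, cocktail_stock,
              protein = x$stocks[["protein"]],
              precipitant = x$stocks[["precipitant"]],
              diluent = diluent, seed_carrier = seed_carrier,
              seed_stock_dilution = x$stocks[["seed_stock_dilution"]] %||% 1),
    error = function(e) {
      pp_abort(paste0("invalid config:\n  - stocks: ", conditionMessage(e)),
               "pp_config_error")
    })

  # corner feasibility against the stocks, named per corner
  corner_names <- c("r0c0", "r0cN", "rNc0", "rNcN")
  for (i in 1:4) {
    if (corner_pro[i] > protein_stock_conc(stocks)) {
      note(sprintf("grid.corners.protein[%d] (%s): %g mg/ml exceeds the %g mg/ml protein stock",
                   i, corner_names[i], corner_pro[i], protein_stock_conc(stocks)))
    }
    if (corner_pre[i] > precipitant_stock_conc(stocks)) {
      note(sprintf("grid.corners.precipitant[%d] (%s): %g exceeds the %g %s cocktail stock",
                   i, corner_names[i], corner_pre[i], precipitant_stock_conc(stocks),
                   unit_of(stocks$cocktail_stock, stocks$precipitant)))
    }
  }
  if (length(errors) > 0) {
    pp_abort(paste0("invalid config:\n", paste0("  - ", errors, collapse = "\n")),
             "pp_config_error")
  }

  grid <- tryCatch(
    grid_design(rows, cols, drop, corner_spec(corner_pro, corner_pre),
                seed_mode = seed_mode, seed_fraction = seed_fraction,
                robot_precision_ul = precision, min_dispense_ul = min_disp,
                transpose = transpose, plate_capacity = capacity),
    error = function(e) {
      pp_abort(paste0("invalid config:\n  - grid: ", conditionMessage(e)),
               "pp_config_error")
    })

  if (!quiet && length(defaults_used) > 0) {
    message("config defaults applied: ", paste(defaults_used, collapse = "; "))
  }
  structure(list(stocks = stocks, grid = grid, seed = as.integer(rng_seed)),
            class = "pp_config")
}

#' Save an experiment configuration
#'
#' Inverse of [load_config()]: writing and re-loading a config is the
#' identity (concentrations are stored unit-normalized).
#'
#' @param config A `pp_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  pp_assert(inherits(config, "pp_config"), "`config` must be a pp_config", "pp_invalid_input")
  s <- config$stocks
  g <- config$grid
  out <- list(
    stocks = list(
      protein_stock = mixture_to_json_list(s$protein_stock),
      cocktail_stock = mixture_to_json_list(s$cocktail_stock),
      protein = s$protein,
      precipitant = s$precipitant,
      seed_stock_dilution = s$seed_stock_dilution,
      seed_carrier = mixture_to_json_list(s$seed_carrier),
      diluent = mixture_to_json_list(s$diluent)),
    grid = list(
      rows = g$rows, cols = g$cols, drop_volume_ul = g$drop_volume_ul,
      corners = list(protein = g$corners$protein,
                     precipitant = g$corners$precipitant),
      seed_mode = g$seed_mode, seed_fraction = g$seed_fraction,
      robot_precision_ul = g$robot_precision_ul,
      min_dispense_ul = g$min_dispense_ul),
    seed = config$seed)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @export
print.pp_config <- function(x, ...) {
  cat("<experiment config>\n")
  print(x$stocks)
  cat(sprintf("  grid: %d x %d, %g ul drops, seed mode '%s'\n",
              x$grid$rows, x$grid$cols, x$grid$drop_volume_ul, x$grid$seed_mode))
  invisible(x)
}
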