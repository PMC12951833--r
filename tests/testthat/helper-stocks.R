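# Shared stock sets and grids, built in code (no fixture files).

mk_mix <- function(...) {
  comps <- list(...)
  ph <- comps$pH
  comps$pH <- NULL
  if (length(comps) == 0) return(water())
  mixture(tibble::tibble(
    component = names(comps),
    conc = vapply(comps, function(x) x[[1]], numeric(1)),
    unit = vapply(comps, function(x) x[[2]], character(1))
  ), pH = ph)
}

xylanase_stocks <- function() {
  stock_set(
    mk_mix(xylanase = list(36, "mg_per_ml")),
    mk_mix(sodium_formate = list(8, "M")))
}

citrate_stocks <- function(protein_conc = 30) {
  stock_set(
    mk_mix(protein = list(protein_conc, "mg_per_ml")),
    mk_mix(sodium_citrate = list(1000, "mM"), HEPES = list(167, "mM"), pH = 7))
}

simple_grid <- function(rows = 4, cols = 4, drop = 2,
                        protein = c(20, 20, 5, 5),
                        precipitant = c(0.5, 6, 0.5, 6), ...) {
  grid_design(rows, cols, drop, corner_spec(protein, precipitant), ...)
}

# random rectangular plate-well table for simulator property tests
random_rect_wells <- function(rows, cols, protein_range, precipitant_range) {
  pr <- seq(protein_range[2], protein_range[1], length.out = rows)
  cc <- seq(precipitant_range[1], precipitant_range[2], length.out = cols)
  grid <- expand.grid(row = 0:(rows - 1), col = 0:(cols - 1))
  grid <- grid[order(grid$row, grid$col), ]
  tibble::tibble(
    well = paste0(LETTERS[grid$row + 1], grid$col + 1),
    row = grid$row, col = grid$col,
    protein_mg_ml = pr[grid$row + 1],
    precipitant_conc = cc[grid$col + 1],
    feasible = TRUE)
}

write_demo_config <- function(path, seed_mode = "none") {
  cfg <- list(
    stocks = list(
      protein_stock = list(components = list(
        xylanase = list(conc = 36, unit = "mg_per_ml"))),
      cocktail_stock = list(components = list(
        sodium_formate = list(conc = 8, unit = "M")))),
    grid = list(
      rows = 6, cols = 8, drop_volume_ul = 2,
      corners = list(protein = c(20, 8, 8, 2),
                     precipitant = c(1.6, 5.2, 3.2, 6.8)),
      seed_mode = seed_mode),
    seed = 7)
  # corners are in M here; the loader normalizes the cocktail to mM, so
  # express precipitant corners in the normalized unit
  cfg$grid$corners$precipitant <- cfg$grid$corners$precipitant * 1000
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
  path
}
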