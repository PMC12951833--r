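#' Deterministic demonstration fixtures
#'
#' Returns a matched (config, model) pair whose simulated, classified
#' diagram exhibits a named landscape topology:
#'
#' * `"classic"` -- a textbook landscape: one contiguous band per zone,
#'   ordered undersaturated, metastable, nucleation, precipitation along
#'   any path of increasing supersaturation (the behavior of robust model
#'   systems such as concanavalin A).
#' * `"dual_metastable"` -- competing salting-in (`beta > 0`) and
#'   salting-out terms split the metastable wells into at least two
#'   disjoint components, one at high protein / low precipitant and one at
#'   low protein / high precipitant.
#' * `"nucleation_limited"` -- a system where spontaneous nucleation is so
#'   rare that exactly one well of the unseeded plate yields a crystal,
#'   while seeding unlocks crystals in the majority of wells; the
#'   nucleation threshold is placed just below the grid's maximum
#'   supersaturation to realize this.
#'
#' All three are deterministic (`p_nuc = 0`).
#'
#' @param name One of `"classic"`, `"dual_metastable"`,
#'   `"nucleation_limited"`.
#' @return List with elements `config` (a `pp_config`) and `model`
#'   (a [phase_model()]).
#' @examples
#' fx <- generate_fixture("classic")
#' plate <- plan_plate(fx$config$grid, fx$config$stocks)
#' diagram <- build_phase_diagram(plate, simulate_plate(fx$model, plate))
#' @export
generate_fixture <- function(name) {
  pp_assert(is.character(name) && length(name) == 1, "`name` must be a string",
            "pp_usage_error")
  fixture_stocks <- function(protein_name = "model_protein",
                             protein_conc = 40,
                             precipitant_name = "sodium_citrate",
                             precipitant_conc = 2000) {
    stock_set(
      mixture(tibble(component = protein_name, conc = protein_conc,
                     unit = "mg_per_ml")),
      mixture(tibble(component = precipitant_name, conc = precipitant_conc,
                     unit = "mM")))
  }
  switch(
    name,
    classic = {
      stocks <- fixture_stocks()
      # diagonal sampling: protein falls as precipitant rises, so gradients
      # run roughly parallel to the falling solubility curve
      grid <- grid_design(
        rows = 10, cols = 10, drop_volume_ul = 2,
        corners = corner_spec(protein = c(36, 14, 12, 1),
                              precipitant = c(100, 1100, 500, 1500)),
        seed_mode = "premixed_in_cocktail", min_dispense_ul = 0)
      model <- phase_model(S0 = 30, K = 2.4e-6, beta = 0,
                           sigma_nuc = 2.2, sigma_shower = 4.5,
                           sigma_prec = 8, p_nuc = 0, seed = 101L)
      list(config = structure(list(stocks = stocks, grid = grid, seed = 101L),
                              class = "pp_config"),
           model = model)
    },
    dual_metastable = {
      stocks <- fixture_stocks(protein_conc = 100, precipitant_conc = 4000)
      grid <- grid_design(
        rows = 12, cols = 12, drop_volume_ul = 2,
        corners = corner_spec(protein = c(31, 2, 8, 0.8),
                              precipitant = c(100, 1400, 100, 1400)),
        seed_mode = "premixed_in_cocktail", min_dispense_ul = 0)
      model <- phase_model(S0 = 15, K = 1.3e-6, beta = 3e-4,
                           sigma_nuc = 1.5, sigma_shower = 6,
                           sigma_prec = 12, p_nuc = 0, seed = 202L)
      list(config = structure(list(stocks = stocks, grid = grid, seed = 202L),
                              class = "pp_config"),
           model = model)
    },
    nucleation_limited = {
      stocks <- fixture_stocks(protein_name = "xylanase_like", protein_conc = 36,
                               precipitant_name = "sodium_formate",
                               precipitant_conc = 8000)
      grid <- grid_design(
        rows = 8, cols = 12, drop_volume_ul = 2,
        corners = corner_spec(protein = c(26, 12, 14, 2),
                              precipitant = c(1800, 4600, 3200, 6400)),
        seed_mode = "premixed_in_cocktail", min_dispense_ul = 0)
      # place the nucleation threshold just below the grid's maximum
      # supersaturation: only the single hottest well nucleates unseeded
      base <- phase_model(S0 = 30, K = 6e-8, beta = 0,
                          sigma_nuc = 1.01, sigma_shower = 2, sigma_prec = 4,
                          p_nuc = 0, seed = 303L)
      targets <- interpolate_corners(grid$corners, grid$rows, grid$cols)
      sig <- sort(supersaturation(base, targets$protein, targets$precipitant),
                  decreasing = TRUE)
      nuc <- (sig[1] + sig[2]) / 2
      model <- phase_model(S0 = base$S0, K = base$K, beta = 0,
                           sigma_nuc = nuc,
                           sigma_shower = sig[1] * 1.5,
                           sigma_prec = sig[1] * 3,
                           p_nuc = 0, seed = 303L)
      list(config = structure(list(stocks = stocks, grid = grid, seed = 303L),
                              class = "pp_config"),
           model = model)
    },
    pp_abort(paste0("unknown fixture name: '", name,
                    "' (use classic, dual_metastable or nucleation_limited)"),
             "pp_usage_error"))
}
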