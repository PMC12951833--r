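#' Split a total volume by ratio weights
#'
#' Batch recipes are quoted as component ratios (e.g. a 1:1:2
#' protein:precipitant:seed mix); each part's volume is
#' `total * w_i / sum(w)`, with the largest part absorbing the floating
#' residue so the parts sum to the total exactly.
#'
#' @param weights Positive ratio weights, e.g. `c(1, 1, 2)`.
#' @param total_volume_ul Total batch volume (>= 0).
#' @return Numeric volumes, one per weight.
#' @examples
#' scale_by_ratio(c(1, 1, 2), 500)  # 125, 125, 250
#' scale_by_ratio(c(1, 1, 1), 500)  # 166.7 each (reported as 167 ul)
#' @export
scale_by_ratio <- function(weights, total_volume_ul) {
  pp_assert(is.numeric(weights) && length(weights) > 0 && all(weights > 0),
            "`weights` must be positive numbers", "pp_range_error")
  pp_assert(is.numeric(total_volume_ul) && length(total_volume_ul) == 1 &&
              total_volume_ul >= 0,
            "`total_volume_ul` must be a single number >= 0", "pp_range_error")
  v <- total_volume_ul * weights / sum(weights)
  imax <- which.max(v)
  v[imax] <- total_volume_ul - sum(v[-imax])
  v
}

#' Reporting convention for batch volumes
#'
#' Volumes of 100 ul and above print to the nearest integer microlitre
#' (166.67 reports as 167); smaller volumes print to 0.1 ul.
#'
#' @param volume_ul Numeric volumes.
#' @return `format_volume_ul` a character vector; `reported_volume_ul` the
#'   corresponding rounded numbers.
#' @export
format_volume_ul <- function(volume_ul) {
  ifelse(volume_ul >= 100, sprintf("%.0f", volume_ul), sprintf("%.1f", volume_ul))
}

#' @rdname format_volume_ul
#' @export
reported_volume_ul <- function(volume_ul) {
  ifelse(volume_ul >= 100, round(volume_ul), round(volume_ul, 1))
}

#' Assemble a batch scale-up recipe
#'
#' Translates a chosen phase-diagram condition into a batch recipe at an
#' arbitrary total volume: part volumes by [scale_by_ratio()], the final
#' composition by [mix()], and the protein mass from the final protein
#' concentration. Because the parts are fixed-ratio, the final composition
#' is independent of the total volume -- scaling a validated 10 ul PCR-tube
#' trial to a 500 ul batch leaves every final concentration unchanged.
#'
#' @param parts Data frame with columns `role` (one of `"protein"`,
#'   `"precipitant"` (or `"cocktail"`), `"seed"`, `"diluent"`), `weight`
#'   (positive ratio weight) and `mixture` (list-column of [mixture()]s:
#'   the stock dispensed for that part). Seed dilution (1:100, 1:200, ...)
#'   is a property of the seed part's mixture, set with [dilute()],
#'   orthogonal to its ratio weight.
#' @param total_volume_ul Total batch volume (> 0).
#' @return Object of class `pp_recipe`.
#' @examples
#' cocktail <- mixture(data.frame(
#'   component = c("sodium_citrate", "HEPES"),
#'   conc = c(600, 100.2), unit = c("mM", "mM")), pH = 7)
#' protein <- mixture(data.frame(
#'   component = "AtPdx1.3", conc = 12, unit = "mg_per_ml"))
#' rec <- make_recipe(
#'   tibble::tibble(role = c("protein", "precipitant", "seed"),
#'                  weight = c(1, 1, 1),
#'                  mixture = list(protein, cocktail, water())),
#'   total_volume_ul = 150)
#' rec$final_composition  # 4 mg/ml protein, 200 mM citrate, 33.4 mM HEPES
#' @export
make_recipe <- function(parts, total_volume_ul) {
  pp_assert(is.data.frame(parts) && nrow(parts) > 0 &&
              all(c("role", "weight", "mixture") %in% names(parts)),
            "`parts` needs columns role, weight, mixture", "pp_invalid_input")
  parts <- as_tibble(parts)
  roles <- c("protein", "precipitant", "cocktail", "seed", "diluent")
  pp_assert(all(parts$role %in% roles),
            paste0("part roles must be among: ", paste(roles, collapse = ", ")),
            "pp_invalid_input")
  pp_assert(all(map_lgl(parts$mixture, inherits, "pp_mixture")),
            "`parts$mixture` must hold mixtures", "pp_invalid_input")
  pp_assert(total_volume_ul > 0, "`total_volume_ul` must be > 0", "pp_range_error")
  parts$volume_ul <- scale_by_ratio(parts$weight, total_volume_ul)
  final <- mix(parts[, c("mixture", "volume_ul")])
  protein_mass <- sum(final$conc[final$unit == "mg_per_ml"]) * total_volume_ul / 1000
  structure(list(parts = parts, total_volume_ul = as.numeric(total_volume_ul),
                 final_composition = final, protein_mass_mg = protein_mass),
            class = "pp_recipe")
}

#' Re-tune the seed load of a batch recipe
#'
#' Replaces the seed part's ratio weight and recomputes every volume at the
#' same total. Raising the seed weight raises the number of growth
#' templates so the protein pool is depleted across more, smaller crystals;
#' the mapping from seed load to final crystal size is empirical, so this
#' is ratio arithmetic plus provenance: the old and new seed volumes are
#' reported in a message.
#'
#' @param recipe A `pp_recipe` containing a `"seed"` part.
#' @param new_seed_weight New positive ratio weight for the seed part.
#' @return A new `pp_recipe`.
#' @examples
#' \dontrun{
#' retune_seed(rec, 2)  # 1:1:1 at 500 ul -> 1:1:2: seed 167 -> 250 ul
#' }
#' @export
retune_seed <- function(recipe, new_seed_weight) {
  pp_assert(inherits(recipe, "pp_recipe"), "`recipe` must be a pp_recipe", "pp_invalid_input")
  i <- which(recipe$parts$role == "seed")
  pp_assert(length(i) == 1,
            "recipe has no (single) seed part to re-tune", "pp_usage_error")
  pp_assert(is.numeric(new_seed_weight) && new_seed_weight > 0,
            "`new_seed_weight` must be > 0", "pp_range_error")
  old_v <- recipe$parts$volume_ul[i]
  parts <- recipe$parts[, c("role", "weight", "mixture")]
  parts$weight[i] <- as.numeric(new_seed_weight)
  out <- make_recipe(parts, recipe$total_volume_ul)
  message(sprintf("seed volume %s -> %s ul at %g ul total",
                  format_volume_ul(old_v),
                  format_volume_ul(out$parts$volume_ul[i]),
                  recipe$total_volume_ul))
  out
}

#' @export
print.pp_recipe <- function(x, ...) {
  cat(sprintf("<batch recipe> %g ul total, ratio %s\n", x$total_volume_ul,
              paste(x$parts$weight, collapse = ":")))
  for (i in seq_len(nrow(x$parts))) {
    cat(sprintf("  %-12s %s ul\n", x$parts$role[i],
                format_volume_ul(x$parts$volume_ul[i])))
  }
  cat(sprintf("  protein mass: %.3g mg\n", x$protein_mass_mg))
  invisible(x)
}

#' @describeIn make_recipe Part table with volumes and their reported form.
#' @param x A `pp_recipe`.
#' @param ... Unused.
#' @export
tidy.pp_recipe <- function(x, ...) {
  out <- x$parts
  out$volume_reported <- format_volume_ul(out$volume_ul)
  out
}

#' @describeIn make_recipe One-row summary (total volume, protein mass,
#'   part count).
#' @export
glance.pp_recipe <- function(x, ...) {
  tibble(total_volume_ul = x$total_volume_ul,
         n_parts = nrow(x$parts),
         protein_mass_mg = x$protein_mass_mg)
}

#' Read and write recipe JSON
#'
#' Input schema mirrors [make_recipe()]'s arguments:
#' `{"total_volume_ul": 500, "parts": [{"role": "protein", "weight": 1,
#' "mixture": {"components": {...}}}, ...]}`. [write_recipe()] additionally
#' stores the computed volumes, final composition and protein mass.
#'
#' @param recipe A `pp_recipe`.
#' @param path File path.
#' @param total_volume_ul Optional override of the JSON's total volume.
#' @return `read_recipe` returns a `pp_recipe`; the writer returns `path`
#'   invisibly.
#' @export
write_recipe <- function(recipe, path) {
  out <- list(
    total_volume_ul = recipe$total_volume_ul,
    parts = map(seq_len(nrow(recipe$parts)), function(i) {
      list(role = recipe$parts$role[i],
           weight = recipe$parts$weight[i],
           volume_ul = recipe$parts$volume_ul[i],
           volume_reported = format_volume_ul(recipe$parts$volume_ul[i]),
           mixture = mixture_to_json_list(recipe$parts$mixture[[i]]))
    }),
    final_composition = mixture_to_json_list(recipe$final_composition),
    protein_mass_mg = recipe$protein_mass_mg)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_recipe
#' @export
read_recipe <- function(path, total_volume_ul = NULL) {
  x <- jsonlite::read_json(path)
  total <- total_volume_ul %||% x$total_volume_ul
  pp_assert(!is.null(total), "recipe JSON needs `total_volume_ul` (or pass one)",
            "pp_config_error")
  parts <- tibble(
    role = map_chr(x$parts, function(p) as.character(p$role)),
    weight = map_dbl(x$parts, function(p) as.numeric(p$weight)),
    mixture = map(x$parts, function(p) mixture_from_json_list(p$mixture, "parts.mixture")))
  make_recipe(parts, as.numeric(total))
}
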