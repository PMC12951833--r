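#' Supported concentration units
#'
#' Concentrations are declared per component and are never converted
#' implicitly: mixing two parts that declare the same component in different
#' units is an error. [normalize_units()] is the single explicit converter
#' (molar species are canonicalized to mM); it runs when a configuration
#' file is loaded and nowhere else.
#'
#' @format Character vector of unit codes.
#' @export
pp_units <- c("mg_per_ml", "M", "mM", "percent_w_v", "fraction")

#' Create a mixture
#'
#' A mixture is a tibble of named chemical components with concentrations,
#' plus an optional pH carried as metadata. It is the universal currency of
#' the package's mixing arithmetic: protein stocks, crystallization
#' cocktails, seed carriers, final drop compositions and batch recipes are
#' all mixtures. Protein concentrations are in mg/ml (`mg_per_ml`); salts
#' and buffers in `M` or `mM`; polymers such as PEG in `percent_w_v`.
#'
#' @param components Data frame with columns `component` (name), `conc`
#'   (non-negative concentration) and `unit` (one of [pp_units]). `NULL`
#'   gives the empty mixture (pure water / diluent).
#' @param pH Optional numeric pH. pH is metadata: it is never interpolated
#'   by [mix()], only carried through when all contributing parts that
#'   declare a pH agree.
#' @return A tibble of class `pp_mixture` with columns
#'   `component`, `conc`, `unit` and a `pH` attribute.
#' @examples
#' cocktail <- mixture(
#'   data.frame(
#'     component = c("sodium_citrate", "HEPES"),
#'     conc = c(1000, 167),
#'     unit = c("mM", "mM")
#'   ),
#'   pH = 7.0
#' )
#' dilute(cocktail, 0.6)
#' @export
mixture <- function(components = NULL, pH = NULL) {
  if (is.null(components)) {
    components <- tibble(component = character(), conc = double(), unit = character())
  }
  components <- as_tibble(components)
  missing_cols <- setdiff(c("component", "conc", "unit"), names(components))
  pp_assert(length(missing_cols) == 0,
            paste0("`components` must have columns component, conc, unit (missing: ",
                   paste(missing_cols, collapse = ", "), ")"),
            "pp_invalid_input")
  components <- components[, c("component", "conc", "unit")]
  components$component <- as.character(components$component)
  components$conc <- as.numeric(components$conc)
  components$unit <- as.character(components$unit)
  pp_assert(!anyNA(components$conc) && all(components$conc >= 0),
            "component concentrations must be non-negative numbers",
            "pp_invalid_input")
  bad_unit <- setdiff(unique(components$unit), pp_units)
  pp_assert(length(bad_unit) == 0,
            paste0("unknown unit(s): ", paste(bad_unit, collapse = ", ")),
            "pp_unit_error")
  pp_assert(!anyDuplicated(components$component),
            "component names within a mixture must be unique",
            "pp_invalid_input")
  if (!is.null(pH)) {
    pp_assert(is.numeric(pH) && length(pH) == 1 && is.finite(pH),
              "`pH` must be a single finite number", "pp_invalid_input")
    pH <- as.numeric(pH)
  }
  structure(components, class = c("pp_mixture", class(components)), pH = pH)
}

#' @rdname mixture
#' @export
water <- function() mixture()

#' @export
print.pp_mixture <- function(x, ...) {
  ph <- attr(x, "pH")
  cat("<mixture>", if (!is.null(ph)) paste0(" pH ", format(ph)), "\n", sep = "")
  if (nrow(x) == 0) {
    cat("  (no components: water/diluent)\n")
  } else {
    for (i in seq_len(nrow(x))) {
      cat(sprintf("  %s: %g %s\n", x$component[i], x$conc[i], x$unit[i]))
    }
  }
  invisible(x)
}

#' pH of a mixture
#' @param m A [mixture()].
#' @return The pH, or `NULL` when unset.
#' @export
mixture_pH <- function(m) attr(m, "pH")

#' Concentration of one component
#' @param m A [mixture()].
#' @param component Component name.
#' @return Concentration of `component` in `m`, 0 when absent.
#' @export
conc_of <- function(m, component) {
  i <- match(component, m$component)
  if (is.na(i)) 0 else m$conc[i]
}

unit_of <- function(m, component) {
  i <- match(component, m$component)
  if (is.na(i)) NA_character_ else m$unit[i]
}

#' Bundle a mixture with a dispensed volume
#'
#' Convenience constructor for the parts table consumed by [mix()].
#'
#' @param m A [mixture()].
#' @param volume_ul Volume in microlitres (>= 0).
#' @return One-row tibble with a `mixture` list-column and `volume_ul`.
#' @export
part <- function(m, volume_ul) {
  pp_assert(inherits(m, "pp_mixture"), "`m` must be a mixture", "pp_invalid_input")
  pp_assert(is.numeric(volume_ul) && length(volume_ul) == 1 &&
              is.finite(volume_ul) && volume_ul >= 0,
            "`volume_ul` must be a single non-negative number", "pp_invalid_input")
  tibble(mixture = list(m), volume_ul = as.numeric(volume_ul))
}

#' Mix volumetric parts into one mixture
#'
#' Volume-weighted mixing under the ideal (additive-volume) assumption:
#' each component's final concentration is sum(conc_i * v_i) / sum(v_i).
#' This is the linear arithmetic a liquid-handling robot realizes when it
#' co-dispenses stocks into one drop. pH is carried only when every part
#' that declares a pH agrees on its value; otherwise it is unset.
#'
#' @param parts Data frame with a `mixture` list-column and a `volume_ul`
#'   column, e.g. built by binding [part()] rows.
#' @return A [mixture()].
#' @examples
#' cocktail <- mixture(data.frame(
#'   component = c("sodium_citrate", "HEPES"),
#'   conc = c(1000, 167), unit = c("mM", "mM")
#' ), pH = 7)
#' # 0.6 volumes cocktail + 0.4 volumes water -> 600 mM citrate, 100.2 mM HEPES
#' mix(rbind(part(cocktail, 0.6), part(water(), 0.4)))
#' @export
mix <- function(parts) {
  pp_assert(is.data.frame(parts) && nrow(parts) > 0,
            "`parts` must be a non-empty data frame of (mixture, volume_ul)",
            "pp_invalid_input")
  parts <- as_tibble(parts)
  pp_assert(all(c("mixture", "volume_ul") %in% names(parts)),
            "`parts` needs columns `mixture` and `volume_ul`", "pp_invalid_input")
  pp_assert(all(map_lgl(parts$mixture, inherits, "pp_mixture")),
            "`parts$mixture` must contain mixtures", "pp_invalid_input")
  vols <- as.numeric(parts$volume_ul)
  pp_assert(!anyNA(vols) && all(vols >= 0),
            "part volumes must be non-negative", "pp_invalid_input")
  total <- sum(vols)
  pp_assert(total > 0, "total part volume must be > 0", "pp_invalid_input")

  tab <- purrr::map2(parts$mixture, vols, function(m, v) {
    tibble(component = m$component, conc = m$conc, unit = m$unit, volume_ul = v)
  })
  tab <- bind_rows(tab)
  if (nrow(tab) > 0) {
    clash <- tab |>
      group_by(.data$component) |>
      summarise(n_units = n_distinct(.data$unit), .groups = "drop") |>
      filter(.data$n_units > 1)
    pp_assert(nrow(clash) == 0,
              paste0("unit clash for component(s): ",
                     paste(clash$component, collapse = ", ")),
              "pp_unit_error")
  }
  out <- tab |>
    group_by(.data$component, .data$unit) |>
    summarise(conc = sum(.data$conc * .data$volume_ul) / total, .groups = "drop") |>
    arrange(.data$component)

  phs <- purrr::compact(map(parts$mixture, mixture_pH))
  ph <- if (length(phs) > 0 && length(unique(unlist(phs))) == 1) phs[[1]] else NULL
  mixture(out, pH = ph)
}

#' Dilute a mixture by a factor
#'
#' @param m A [mixture()].
#' @param factor Dilution factor in (0, 1]; 1 is the identity (neat).
#'   Seed-stock serial dilutions reach factors as small as 1e-7.
#' @return A [mixture()] with every concentration scaled by `factor`.
#' @export
dilute <- function(m, factor) {
  pp_assert(inherits(m, "pp_mixture"), "`m` must be a mixture", "pp_invalid_input")
  pp_assert(is.numeric(factor) && length(factor) == 1 && is.finite(factor) &&
              factor > 0 && factor <= 1,
            "`factor` must be in (0, 1]", "pp_range_error")
  out <- as_tibble(m)
  out$conc <- out$conc * factor
  mixture(out, pH = mixture_pH(m))
}

#' Stock volume needed to reach a target concentration
#'
#' The core linear dispense rule: to realize `target_conc` of a component in
#' a drop of `total_volume_ul` from a stock at `stock_conc`, dispense
#' `total_volume_ul * target_conc / stock_conc`.
#'
#' @param target_conc Target final concentration (same unit as `stock_conc`).
#' @param stock_conc Stock concentration (> 0).
#' @param total_volume_ul Final drop volume in microlitres.
#' @param component Component name used in error messages.
#' @return Volume in microlitres. Vectorized over its numeric arguments.
#' @examples
#' # 15.95 mg/ml from a 36 mg/ml stock in a 2 ul drop
#' volume_for_target(15.95, 36, 2)
#' @export
volume_for_target <- function(target_conc, stock_conc, total_volume_ul,
                              component = "component") {
  pp_assert(all(stock_conc > 0), "`stock_conc` must be > 0", "pp_range_error")
  pp_assert(all(target_conc >= 0), "`target_conc` must be >= 0", "pp_range_error")
  if (any(target_conc > stock_conc * (1 + 1e-9))) {
    pp_abort(sprintf(
      "target %s concentration (%g) exceeds its stock concentration: unreachable by dilution",
      component, max(target_conc)),
      "pp_infeasible_error")
  }
  total_volume_ul * target_conc / stock_conc
}

#' Canonicalize molar units to mM
#'
#' The single explicit unit converter: components declared in `M` are
#' rewritten in `mM` (concentration multiplied by 1000). All other units
#' pass through unchanged. Runs at configuration load; nothing else in the
#' package converts units.
#'
#' @param m A [mixture()].
#' @return A [mixture()] with molar components expressed in mM.
#' @export
normalize_units <- function(m) {
  pp_assert(inherits(m, "pp_mixture"), "`m` must be a mixture", "pp_invalid_input")
  out <- as_tibble(m)
  is_M <- out$unit == "M"
  out$conc[is_M] <- out$conc[is_M] * 1000
  out$unit[is_M] <- "mM"
  mixture(out, pH = mixture_pH(m))
}

mixture_to_json_list <- function(m) {
  comps <- list()
  for (i in seq_len(nrow(m))) {
    comps[[m$component[i]]] <- list(conc = m$conc[i], unit = m$unit[i])
  }
  out <- list(components = comps)
  if (!is.null(mixture_pH(m))) out$pH <- mixture_pH(m)
  out
}

mixture_from_json_list <- function(x, path = "mixture") {
  pp_assert(is.list(x), paste0(path, " must be an object"), "pp_config_error")
  comps <- x$components %||% list()
  if (length(comps) == 0) return(mixture(NULL, pH = x$pH %||% NULL))
  tab <- tibble(
    component = names(comps),
    conc = map_dbl(comps, function(ci) as.numeric(ci$conc %||% NA_real_)),
    unit = map_chr(comps, function(ci) as.character(ci$unit %||% NA_character_))
  )
  pp_assert(!anyNA(tab$conc) && !anyNA(tab$unit),
            paste0(path, ".components entries need `conc` and `unit`"),
            "pp_config_error")
  mixture(tab, pH = x$pH %||% NULL)
}
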