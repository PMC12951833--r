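zone_palette <- c(
  undersaturated = "grey70", metastable = "#c0392b", nucleation = "#2980b9",
  precipitation = "#7f6000", inconsistent = "#8e44ad", unknown = "grey95")

#' Plot a phase diagram
#'
#' Wells in (precipitant, protein) space colored by zone, mirroring the
#' field's convention (blue: spontaneous nucleation, red: seeded-only
#' metastable growth, grey: clear), with the estimated solubility and
#' nucleation frontiers drawn as staircases.
#'
#' @param object A `pp_phase_diagram`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pp_phase_diagram <- function(object, ...) {
  zones <- object$zones
  p <- ggplot2::ggplot(zones, ggplot2::aes(x = .data$precipitant_conc,
                                           y = .data$protein_mg_ml)) +
    ggplot2::geom_point(ggplot2::aes(fill = .data$zone), shape = 23, size = 4) +
    ggplot2::scale_fill_manual(values = zone_palette, drop = FALSE) +
    ggplot2::labs(x = "precipitant concentration", y = "protein (mg/ml)",
                  fill = "zone") +
    ggplot2::theme_minimal()
  add_frontier <- function(p, fr, color) {
    fr <- fr[is.finite(fr$protein), , drop = FALSE]
    if (is.null(fr) || nrow(fr) == 0) return(p)
    p + ggplot2::geom_step(
      data = fr,
      ggplot2::aes(x = .data$precipitant, y = .data$protein,
                   group = .data$segment),
      color = color, linewidth = 0.8, inherit.aes = FALSE)
  }
  p <- add_frontier(p, object$solubility_frontier, "#c0392b")
  add_frontier(p, object$nucleation_frontier, "#5b2c6f")
}

#' Plot a plate design
#'
#' The sampled conditions in phase space (diagonal grids appear as sheared
#' lattices), with infeasible wells hollow.
#'
#' @param object A `pp_plate`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pp_plate <- function(object, ...) {
  ggplot2::ggplot(object$wells,
                  ggplot2::aes(x = .data$precipitant_conc, y = .data$protein_mg_ml,
                               shape = .data$feasible)) +
    ggplot2::geom_point(size = 3, color = "#2c3e50") +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1)) +
    ggplot2::labs(x = "precipitant concentration", y = "protein (mg/ml)",
                  shape = "feasible") +
    ggplot2::theme_minimal()
}

#' Plot a phase model
#'
#' Solubility curve with the nucleation, shower and precipitation threshold
#' curves (`sigma_* x S(c)`); the band between the solubility curve and the
#' nucleation curve is the metastable zone.
#'
#' @param object A `pp_phase_model`.
#' @param precipitant_range Length-2 range of precipitant concentrations.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pp_phase_model <- function(object, precipitant_range = c(0, 1500), ...) {
  cc <- seq(precipitant_range[1], precipitant_range[2], length.out = 200)
  curves <- bind_rows(
    tibble(precipitant = cc, protein = solubility(object, cc), curve = "solubility"),
    tibble(precipitant = cc, protein = object$sigma_nuc * solubility(object, cc),
           curve = "nucleation"),
    tibble(precipitant = cc, protein = object$sigma_prec * solubility(object, cc),
           curve = "precipitation"))
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$precipitant, y = .data$protein,
                                       color = .data$curve)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "precipitant concentration", y = "protein (mg/ml)") +
    ggplot2::theme_minimal()
}
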