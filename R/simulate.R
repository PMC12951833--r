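#' Parametric phase-diagram model
#'
#' Ground truth for the built-in simulator. Solubility follows a
#' log-quadratic law, `ln S(c) = ln S0 + beta*c - K*c^2`: the `-K*c^2` term
#' is classical (Cohn-style) salting-out and the optional linear `beta*c`
#' term is salting-in, whose competition with salting-out can produce two
#' disjoint metastable regions. Outcomes are governed by the
#' supersaturation ratio `sigma = P / S(c)` against three thresholds:
#' crystals nucleate spontaneously above `sigma_nuc`, grow into dense
#' microcrystal showers above `sigma_shower`, and the protein crashes out
#' as precipitate above `sigma_prec`. Between the solubility curve
#' (`sigma = 1`) and `sigma_nuc` lies the metastable band where crystals
#' grow only when seeded.
#'
#' @param S0 Solubility at zero precipitant (mg/ml, > 0).
#' @param K Salting-out coefficient (> 0, per squared concentration unit).
#' @param beta Salting-in coefficient (>= 0, per concentration unit).
#' @param sigma_nuc Spontaneous-nucleation threshold (> 1).
#' @param sigma_shower Microcrystal-shower threshold
#'   (`sigma_nuc <= sigma_shower <= sigma_prec`).
#' @param sigma_prec Precipitation threshold.
#' @param p_nuc Peak probability of spontaneous nucleation inside the
#'   metastable band (0 = fully deterministic, the default). When > 0 the
#'   per-well probability ramps linearly in sigma from 0 at the solubility
#'   curve to `p_nuc` at `sigma_nuc`.
#' @param seed Integer RNG seed driving [simulate_plate()].
#' @return Object of class `pp_phase_model`.
#' @examples
#' m <- phase_model(S0 = 30, K = 3e-6, sigma_nuc = 2, sigma_shower = 4,
#'                  sigma_prec = 8)
#' solubility(m, c(0, 500, 1000))
#' @export
phase_model <- function(S0, K, beta = 0, sigma_nuc = 2, sigma_shower = 4,
                        sigma_prec = 8, p_nuc = 0, seed = 1L) {
  pp_assert(is.numeric(S0) && S0 > 0, "`S0` must be > 0", "pp_range_error")
  pp_assert(is.numeric(K) && K > 0, "`K` must be > 0", "pp_range_error")
  pp_assert(is.numeric(beta) && beta >= 0, "`beta` must be >= 0", "pp_range_error")
  pp_assert(sigma_nuc > 1, "`sigma_nuc` must be > 1", "pp_range_error")
  pp_assert(sigma_nuc <= sigma_shower && sigma_shower <= sigma_prec,
            "need sigma_nuc <= sigma_shower <= sigma_prec", "pp_range_error")
  pp_assert(p_nuc >= 0 && p_nuc <= 1, "`p_nuc` must be in [0, 1]", "pp_range_error")
  structure(list(S0 = as.numeric(S0), K = as.numeric(K), beta = as.numeric(beta),
                 sigma_nuc = as.numeric(sigma_nuc),
                 sigma_shower = as.numeric(sigma_shower),
                 sigma_prec = as.numeric(sigma_prec),
                 p_nuc = as.numeric(p_nuc), seed = as.integer(seed)),
            class = "pp_phase_model")
}

#' @export
print.pp_phase_model <- function(x, ...) {
  cat(sprintf("<phase model> ln S(c) = ln(%g) + %g c - %g c^2; sigma thresholds %g / %g / %g; p_nuc %g\n",
              x$S0, x$beta, x$K, x$sigma_nuc, x$sigma_shower, x$sigma_prec, x$p_nuc))
  invisible(x)
}

#' Model solubility curve
#'
#' @param model A [phase_model()].
#' @param precipitant_conc Precipitant concentration(s), >= 0.
#' @return Solubility in mg/ml. With `beta = 0` strictly decreasing in the
#'   precipitant; with `beta > 0` it peaks at `c* = beta / (2 K)`.
#' @export
solubility <- function(model, precipitant_conc) {
  pp_assert(all(precipitant_conc >= 0), "`precipitant_conc` must be >= 0", "pp_range_error")
  exp(log(model$S0) + model$beta * precipitant_conc - model$K * precipitant_conc^2)
}

#' Supersaturation ratio
#'
#' `sigma = P / S(c)`: 1 on the solubility curve, < 1 when undersaturated.
#'
#' @inheritParams solubility
#' @param protein_mg_ml Protein concentration(s), >= 0.
#' @return Numeric sigma, vectorized.
#' @export
supersaturation <- function(model, protein_mg_ml, precipitant_conc) {
  pp_assert(all(protein_mg_ml >= 0), "`protein_mg_ml` must be >= 0", "pp_range_error")
  protein_mg_ml / solubility(model, precipitant_conc)
}

#' Analytic zone of a condition under a model
#'
#' The noise-free ground truth the classifier should recover:
#' `sigma < 1` undersaturated; `1 <= sigma < sigma_nuc` metastable;
#' `sigma_nuc <= sigma < sigma_prec` nucleation (the shower band is part of
#' the labile/nucleation zone); `sigma >= sigma_prec` precipitation.
#'
#' @inheritParams supersaturation
#' @return Character vector of zones.
#' @export
zone_map <- function(model, protein_mg_ml, precipitant_conc) {
  sigma <- supersaturation(model, protein_mg_ml, precipitant_conc)
  dplyr::case_when(
    sigma < 1 ~ "undersaturated",
    sigma < model$sigma_nuc ~ "metastable",
    sigma < model$sigma_prec ~ "nucleation",
    TRUE ~ "precipitation")
}

#' Simulate the outcome of one drop
#'
#' Unseeded arm: undersaturated drops stay clear; inside the metastable
#' band they stay clear except for rare spontaneous nucleation (probability
#' ramping to `p_nuc`); above `sigma_nuc` crystals appear, turning into
#' showers above `sigma_shower` and precipitate above `sigma_prec`. Seeded
#' arm: seeds dissolve below the solubility curve (clear) and template
#' growth anywhere above it (crystals / shower / precipitate by the same
#' upper thresholds).
#'
#' @inheritParams supersaturation
#' @param seeded Logical: was seed stock added? Vectorized.
#' @param u Optional uniform deviates (for the stochastic metastable ramp);
#'   drawn from the session RNG when needed and omitted.
#' @return Character vector of outcomes ([pp_outcomes]).
#' @export
simulate_outcome <- function(model, protein_mg_ml, precipitant_conc, seeded,
                             u = NULL) {
  sigma <- supersaturation(model, protein_mg_ml, precipitant_conc)
  n <- length(sigma)
  seeded <- rep_len(as.logical(seeded), n)
  out <- character(n)
  out[sigma >= model$sigma_prec] <- "precipitate"
  out[sigma >= model$sigma_shower & sigma < model$sigma_prec] <- "shower"
  out[sigma < model$sigma_shower] <- "clear"
  # crystal band differs between the arms
  out[seeded & sigma >= 1 & sigma < model$sigma_shower] <- "crystals"
  band <- !seeded & sigma >= model$sigma_nuc & sigma < model$sigma_shower
  out[band] <- "crystals"
  meta <- !seeded & sigma >= 1 & sigma < model$sigma_nuc
  if (model$p_nuc > 0 && any(meta)) {
    if (is.null(u)) u <- runif(n)
    p <- model$p_nuc * (sigma - 1) / (model$sigma_nuc - 1)
    spont <- meta & u < p
    out[spont] <- "crystals"
  }
  out
}

#' Simulate seeded/unseeded observations for a plate
#'
#' Generates the observation table a scored plate would produce under the
#' model: one row per feasible well with the requested arms. Deterministic
#' given the model's `seed` (and fully deterministic when `p_nuc = 0`);
#' infeasible wells produce no observation.
#'
#' @param model A [phase_model()].
#' @param plate A `pp_plate` or plate-map tibble.
#' @param arms Which arms to observe: subset of
#'   `c("unseeded", "seeded")`.
#' @return Wide observation tibble (`well`, `protein_mg_ml`,
#'   `precipitant_conc`, `unseeded`, `seeded`) suitable for
#'   [build_phase_diagram()] and [write_observations()].
#' @export
simulate_plate <- function(model, plate, arms = c("unseeded", "seeded")) {
  pp_assert(inherits(model, "pp_phase_model"), "`model` must be a phase_model()",
            "pp_invalid_input")
  arms <- match.arg(arms, several.ok = TRUE)
  wells <- plate_wells(plate)
  wells <- wells[wells$feasible, , drop = FALSE]
  pp_assert(nrow(wells) > 0, "plate has no feasible wells to observe", "pp_invalid_input")
  with_local_seed(model$seed, {
    obs <- tibble(well = wells$well,
                  protein_mg_ml = wells$protein_mg_ml,
                  precipitant_conc = wells$precipitant_conc,
                  unseeded = NA_character_, seeded = NA_character_)
    if ("unseeded" %in% arms) {
      obs$unseeded <- simulate_outcome(model, wells$protein_mg_ml,
                                       wells$precipitant_conc, seeded = FALSE)
    }
    if ("seeded" %in% arms) {
      obs$seeded <- simulate_outcome(model, wells$protein_mg_ml,
                                     wells$precipitant_conc, seeded = TRUE)
    }
    obs
  })
}

#' Read and write phase-model JSON
#'
#' Schema: `{"S0": ..., "beta": ..., "K": ..., "sigma_nuc": ...,
#' "sigma_shower": ..., "sigma_prec": ..., "p_nuc": ..., "seed": ...}`.
#'
#' @param model A [phase_model()].
#' @param path File path.
#' @return `read_model` returns a [phase_model()]; the writer returns
#'   `path` invisibly.
#' @export
write_model <- function(model, path) {
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  phase_model(S0 = x$S0, K = x$K, beta = x$beta %||% 0,
              sigma_nuc = x$sigma_nuc %||% 2,
              sigma_shower = x$sigma_shower %||% x$sigma_prec %||% 4,
              sigma_prec = x$sigma_prec %||% 8,
              p_nuc = x$p_nuc %||% 0, seed = x$seed %||% 1L)
}
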