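#' Observation categories and phase-diagram zones
#'
#' Drop outcomes are scored into four categories: `clear`, `crystals`,
#' `shower` (a dense shower of microcrystals) and `precipitate`. `shower`
#' and `crystals` are identical for zone logic but the distinction is kept
#' for downstream crystal-density reporting. Zones are `undersaturated`,
#' `metastable`, `nucleation`, `precipitation`, plus `inconsistent`
#' (contradictory seeded/unseeded pair) and `unknown` (not classifiable
#' from the arms observed).
#'
#' @name outcomes
#' @format Character vectors of levels.
#' @export
pp_outcomes <- c("clear", "crystals", "shower", "precipitate")

#' @rdname outcomes
#' @export
pp_zones <- c("undersaturated", "metastable", "nucleation", "precipitation",
              "inconsistent", "unknown")

#' Classify a paired seeded/unseeded observation into a phase-diagram zone
#'
#' The two-arm truth table at the heart of seeded phase-diagram mapping:
#' spontaneous crystals without seeds place a condition in the nucleation
#' (labile) zone; crystals that appear *only* when seed stock is added mark
#' the metastable zone, where growth is favorable but nucleation is
#' kinetically hindered; precipitate in the unseeded arm (or in the seeded
#' arm of an otherwise clear drop) marks the precipitation zone; clear in
#' both arms is undersaturated. Unseeded crystals that vanish on seeding
#' are contradictory and flagged `inconsistent`, never guessed. A missing
#' unseeded arm degrades to `unknown`: an unseeded-only plate can still
#' locate nucleation and precipitation, but a clear drop alone cannot
#' distinguish undersaturated from metastable.
#'
#' @param unseeded,seeded Outcome categories ([pp_outcomes]) or `NA` for a
#'   missing arm. Vectorized.
#' @return Character vector of zones ([pp_zones]).
#' @examples
#' classify_pair("clear", "crystals")    # metastable
#' classify_pair("crystals", "crystals") # nucleation
#' classify_pair("crystals", "clear")    # inconsistent
#' @export
classify_pair <- function(unseeded, seeded) {
  n <- max(length(unseeded), length(seeded))
  u <- rep_len(as.character(unseeded), n)
  s <- rep_len(as.character(seeded), n)
  ok <- function(x) is.na(x) | x %in% pp_outcomes
  pp_assert(all(ok(u)) && all(ok(s)),
            paste0("outcomes must be NA or one of: ", paste(pp_outcomes, collapse = ", ")),
            "pp_invalid_input")
  grows <- function(x) !is.na(x) & x %in% c("crystals", "shower")
  zone <- rep("unknown", n)
  zone[grows(u)] <- "nucleation"
  zone[grows(u) & !is.na(s) & s == "clear"] <- "inconsistent"
  zone[!is.na(u) & u == "precipitate"] <- "precipitation"
  uc <- !is.na(u) & u == "clear"
  zone[uc & grows(s)] <- "metastable"
  zone[uc & !is.na(s) & s == "clear"] <- "undersaturated"
  zone[uc & !is.na(s) & s == "precipitate"] <- "precipitation"
  zone
}

# --- monotone staircase frontier estimation ---------------------------------

# Candidate thresholds: midpoints between adjacent observed protein levels,
# plus -Inf / +Inf for the degenerate all-above / all-below columns.
frontier_candidates <- function(protein) {
  p <- sort(unique(protein))
  mids <- if (length(p) >= 2) (p[-1] + p[-length(p)]) / 2 else numeric(0)
  c(-Inf, mids, Inf)
}

# Per-column cost of placing the boundary at threshold t: points labeled
# "below" must lie under t, "above" points over it. Margin (distance from
# the threshold to the nearest point in the column; 0 for the infinite
# sentinels) breaks ties toward mid-gap boundaries.
frontier_col_cost <- function(protein, side, tvals) {
  mis <- vapply(tvals, function(t) {
    sum(side == "below" & protein > t) + sum(side == "above" & protein < t)
  }, numeric(1))
  margin <- vapply(tvals, function(t) {
    if (!is.finite(t) || length(protein) == 0) 0 else min(abs(protein - t))
  }, numeric(1))
  list(mis = mis, margin = margin)
}

#' Estimate a monotone phase-boundary staircase
#'
#' Fits the boundary between two labeled sides of a phase diagram as a
#' monotone non-increasing step function: protein threshold as a function
#' of precipitant, non-increasing because higher precipitant lowers
#' solubility. Among all monotone staircases over the candidate thresholds
#' (mid-gaps between adjacent observed protein levels, plus infinite
#' sentinels) the estimator minimizes the number of misclassified points;
#' ties are broken by maximal total margin (preferring mid-gap boundaries
#' far from the data), then toward the higher staircase. The optimum is
#' found by dynamic programming over precipitant columns and equals
#' exhaustive search over all monotone staircases.
#'
#' @param points Data frame with columns `precipitant`, `protein` and
#'   `side` (`"below"` for points under the boundary, `"above"` for points
#'   over it).
#' @return Tibble with one row per distinct precipitant level: columns
#'   `precipitant` and `protein` (the threshold), non-increasing in
#'   `protein`; attribute `misclassified` counts points on the wrong side.
#'   One-sided input yields a degenerate staircase at +/-Inf with a
#'   warning.
#' @export
estimate_frontier <- function(points) {
  pp_assert(is.data.frame(points) &&
              all(c("precipitant", "protein", "side") %in% names(points)),
            "`points` needs columns precipitant, protein, side", "pp_invalid_input")
  points <- as_tibble(points)
  pp_assert(all(points$side %in% c("below", "above")),
            "`side` must be 'below' or 'above'", "pp_invalid_input")
  cols <- sort(unique(points$precipitant))
  pp_assert(length(cols) > 0, "`points` must be non-empty", "pp_invalid_input")

  if (!all(c("below", "above") %in% points$side)) {
    warn("one-sided frontier input: returning a degenerate staircase",
         class = "pp_one_sided")
    t_inf <- if (all(points$side == "below")) Inf else -Inf
    out <- tibble(precipitant = cols, protein = t_inf)
    attr(out, "misclassified") <- 0L
    return(out)
  }

  tvals <- frontier_candidates(points$protein)
  K <- length(tvals)
  n <- length(cols)
  costs <- map(cols, function(cc) {
    sel <- points$precipitant == cc
    frontier_col_cost(points$protein[sel], points$side[sel], tvals)
  })

  # DP over columns in increasing precipitant; thresholds non-increasing.
  # State: threshold index for the current column; value: (misclassified,
  # -total margin) accumulated, lexicographic.
  INF <- .Machine$integer.max
  mis <- matrix(0, n, K)
  mar <- matrix(0, n, K)
  choice <- matrix(NA_integer_, n, K)  # best previous index j' >= j
  mis[1, ] <- costs[[1]]$mis
  mar[1, ] <- costs[[1]]$margin
  if (n > 1) {
    for (i in 2:n) {
      # suffix-best over previous row: for each j, best j' >= j
      best_j <- K
      best_mis <- mis[i - 1, K]
      best_mar <- mar[i - 1, K]
      suf_j <- integer(K)
      suf_mis <- numeric(K)
      suf_mar <- numeric(K)
      suf_j[K] <- K; suf_mis[K] <- best_mis; suf_mar[K] <- best_mar
      for (j in (K - 1):1) {
        # strict improvement required, so ties keep the larger j'
        if (mis[i - 1, j] < best_mis ||
            (mis[i - 1, j] == best_mis && mar[i - 1, j] > best_mar)) {
          best_j <- j; best_mis <- mis[i - 1, j]; best_mar <- mar[i - 1, j]
        }
        suf_j[j] <- best_j; suf_mis[j] <- best_mis; suf_mar[j] <- best_mar
      }
      mis[i, ] <- suf_mis + costs[[i]]$mis
      mar[i, ] <- suf_mar + costs[[i]]$margin
      choice[i, ] <- suf_j
    }
  }
  # pick the final column's best state, ties toward larger threshold
  jbest <- K
  for (j in (K - 1):1) {
    if (K == 1) break
    if (mis[n, j] < mis[n, jbest] ||
        (mis[n, j] == mis[n, jbest] && mar[n, j] > mar[n, jbest])) {
      jbest <- j
    }
  }
  idx <- integer(n)
  idx[n] <- jbest
  if (n > 1) {
    for (i in n:2) idx[i - 1] <- choice[i, idx[i]]
  }
  out <- tibble(precipitant = cols, protein = tvals[idx])
  attr(out, "misclassified") <- as.integer(mis[n, jbest])
  out
}

# --- diagram assembly -------------------------------------------------------

plate_wells <- function(plate) {
  if (inherits(plate, "pp_plate")) plate$wells else as_tibble(plate)
}

obs_to_wide <- function(observations) {
  observations <- as_tibble(observations)
  if (all(c("arm", "outcome") %in% names(observations))) {
    pp_assert(all(observations$arm %in% c("unseeded", "seeded")),
              "`arm` must be 'unseeded' or 'seeded'", "pp_invalid_input")
    observations <- observations |>
      distinct(.data$well, .data$arm, .keep_all = TRUE) |>
      tidyr::pivot_wider(id_cols = "well", names_from = "arm",
                         values_from = "outcome")
  }
  for (arm in c("unseeded", "seeded")) {
    if (!arm %in% names(observations)) observations[[arm]] <- NA_character_
  }
  observations[, c("well", "unseeded", "seeded")]
}

#' Build a phase diagram from paired plate observations
#'
#' Joins observations to the plate's target concentrations, classifies each
#' well with [classify_pair()], computes zone fractions over classified
#' (non-`unknown`) wells, and estimates two monotone boundaries: the
#' solubility frontier (undersaturated below vs. everything supersaturated
#' above) and the nucleation frontier (undersaturated + metastable below
#' vs. nucleation + precipitation above). When the metastable wells form
#' several disjoint components -- the dual-metastable landscape produced by
#' competing salting-in and salting-out effects -- global monotonicity is
#' broken and both frontiers are estimated per component over the columns
#' that component spans, emitting one segment per component rather than
#' forcing a single curve.
#'
#' @param plate A `pp_plate` or a plate-map tibble (e.g. from
#'   [read_plate()]).
#' @param observations Either a wide tibble (`well`, `unseeded`, `seeded`)
#'   or the long observation format (`well`, `arm`, `outcome`), e.g. from
#'   [read_observations()] or [simulate_plate()].
#' @return Object of class `pp_phase_diagram` with elements `zones`
#'   (per-well tibble), `zone_fractions`, `solubility_frontier` and
#'   `nucleation_frontier` (tibbles with columns `segment`, `precipitant`,
#'   `protein`).
#' @export
build_phase_diagram <- function(plate, observations) {
  wells <- plate_wells(plate)
  obs <- obs_to_wide(observations)
  stray <- setdiff(obs$well, wells$well)
  if (length(stray) > 0) {
    pp_abort(paste0("observations reference wells absent from the plate: ",
                    paste(stray, collapse = ", ")),
             "pp_reconciliation_error")
  }
  zones <- wells |>
    select("well", "row", "col", "protein_mg_ml", "precipitant_conc",
           any_of("precipitant_unit")) |>
    left_join(obs, by = "well") |>
    mutate(zone = classify_pair(.data$unseeded, .data$seeded))

  classified <- zones$zone[zones$zone != "unknown"]
  fractions <- tibble(zone = setdiff(pp_zones, "unknown")) |>
    mutate(n = map_dbl(.data$zone, function(z) sum(classified == z)),
           fraction = if (length(classified) > 0) .data$n / length(classified) else NA_real_)

  diagram <- structure(
    list(zones = zones, zone_fractions = fractions,
         solubility_frontier = NULL, nucleation_frontier = NULL),
    class = "pp_phase_diagram")

  segs <- frontier_segments(zones)
  diagram$solubility_frontier <- estimate_frontier_segments(
    zones, below = "undersaturated",
    above = c("metastable", "nucleation", "precipitation"), segments = segs)
  diagram$nucleation_frontier <- estimate_frontier_segments(
    zones, below = c("undersaturated", "metastable"),
    above = c("nucleation", "precipitation"), segments = segs)
  diagram
}

# Column ranges over which to fit separate frontier segments: one global
# segment for <= 1 metastable component, else each component's column span.
frontier_segments <- function(zones) {
  comps <- zone_components(zones, "metastable")
  if (length(comps) <= 1) {
    return(list(range(zones$precipitant_conc)))
  }
  map(comps, function(idx) range(zones$precipitant_conc[idx]))
}

estimate_frontier_segments <- function(zones, below, above, segments) {
  pieces <- purrr::imap(segments, function(rng, k) {
    sel <- zones$precipitant_conc >= rng[1] & zones$precipitant_conc <= rng[2] &
      zones$zone %in% c(below, above)
    pts <- tibble(precipitant = zones$precipitant_conc[sel],
                  protein = zones$protein_mg_ml[sel],
                  side = ifelse(zones$zone[sel] %in% below, "below", "above"))
    if (nrow(pts) == 0 || !all(c("below", "above") %in% pts$side)) {
      return(tibble(segment = integer(0), precipitant = double(0), protein = double(0)))
    }
    st <- estimate_frontier(pts)
    tibble(segment = as.integer(k), precipitant = st$precipitant, protein = st$protein)
  })
  bind_rows(pieces)
}

# Connected components (4-neighbor adjacency on the row/col lattice) of the
# wells assigned to `zone`; returns a list of index vectors into `zones`.
zone_components <- function(zones, zone) {
  sel <- which(zones$zone == zone)
  if (length(sel) == 0) return(list())
  key <- paste(zones$row[sel], zones$col[sel])
  pos <- setNames(seq_along(sel), key)
  comp <- rep(NA_integer_, length(sel))
  nc <- 0L
  for (start in seq_along(sel)) {
    if (!is.na(comp[start])) next
    nc <- nc + 1L
    queue <- start
    comp[start] <- nc
    while (length(queue) > 0) {
      i <- queue[1]; queue <- queue[-1]
      r <- zones$row[sel[i]]; cl <- zones$col[sel[i]]
      for (nb in c(paste(r - 1, cl), paste(r + 1, cl),
                   paste(r, cl - 1), paste(r, cl + 1))) {
        j <- pos[nb]
        if (!is.na(j) && is.na(comp[j])) {
          comp[j] <- nc
          queue <- c(queue, j)
        }
      }
    }
  }
  map(seq_len(nc), function(k) sel[comp == k])
}

#' Count connected components of a zone
#'
#' 4-neighbor connectivity on the plate's row/column lattice. Two or more
#' metastable components signal a dual-metastable landscape.
#'
#' @param diagram A `pp_phase_diagram`.
#' @param zone Zone name ([pp_zones]).
#' @return Integer component count.
#' @export
count_zone_components <- function(diagram, zone = "metastable") {
  pp_assert(inherits(diagram, "pp_phase_diagram"),
            "`diagram` must be a pp_phase_diagram", "pp_invalid_input")
  length(zone_components(diagram$zones, zone))
}

#' @export
print.pp_phase_diagram <- function(x, ...) {
  cat(sprintf("<phase diagram> %d wells (%d classified)\n",
              nrow(x$zones), sum(x$zones$zone != "unknown")))
  f <- x$zone_fractions[x$zone_fractions$n > 0, ]
  for (i in seq_len(nrow(f))) {
    cat(sprintf("  %s: %d (%.1f%%)\n", f$zone[i], f$n[i], 100 * f$fraction[i]))
  }
  invisible(x)
}

#' @describeIn build_phase_diagram Per-well zone tibble.
#' @param x A `pp_phase_diagram`.
#' @param ... Unused.
#' @export
tidy.pp_phase_diagram <- function(x, ...) x$zones

#' @describeIn build_phase_diagram One-row summary with zone fractions and
#'   the metastable component count.
#' @export
glance.pp_phase_diagram <- function(x, ...) {
  f <- setNames(x$zone_fractions$fraction, paste0("frac_", x$zone_fractions$zone))
  bind_cols(tibble(n_wells = nrow(x$zones),
                   n_classified = sum(x$zones$zone != "unknown")),
            as_tibble(as.list(f)),
            tibble(n_metastable_components = count_zone_components(x, "metastable")))
}

#' Read and write observation tables
#'
#' Observations CSV: columns `well`, `arm` (`seeded`|`unseeded`),
#' `outcome` (`clear`|`crystals`|`shower`|`precipitate`).
#'
#' @param observations Wide (`well`, `unseeded`, `seeded`) or long
#'   observation tibble.
#' @param path File path.
#' @return `read_observations` returns the wide tibble; the writer returns
#'   `path` invisibly.
#' @export
write_observations <- function(observations, path) {
  wide <- obs_to_wide(observations)
  long <- wide |>
    tidyr::pivot_longer(c("unseeded", "seeded"),
                        names_to = "arm", values_to = "outcome") |>
    filter(!is.na(.data$outcome))
  readr::write_csv(long[, c("well", "arm", "outcome")], path)
  invisible(path)
}

#' @rdname write_observations
#' @export
read_observations <- function(path) {
  long <- readr::read_csv(path, col_types = readr::cols(
    well = readr::col_character(),
    arm = readr::col_character(),
    outcome = readr::col_character()))
  obs_to_wide(long)
}

#' Write estimated frontiers to JSON
#'
#' @param diagram A `pp_phase_diagram`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_frontiers <- function(diagram, path) {
  out <- list(
    solubility = as.list(diagram$solubility_frontier),
    nucleation = as.list(diagram$nucleation_frontier))
  jsonlite::write_json(out, path, auto_unbox = FALSE, digits = NA, pretty = TRUE)
  invisible(path)
}
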