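test_that("classify_pair matches the hand-written oracle on all 25 cases", {
  tab <- truth_table_oracle()
  expect_equal(nrow(tab), 25)
  got <- classify_pair(tab$unseeded, tab$seeded)
  expect_equal(got, tab$zone)
})

test_that("classify_pair rejects unknown outcome categories", {
  expect_error(classify_pair("sparkly", "clear"), class = "pp_invalid_input")
})

test_that("zone fractions sum to one and ignore unknown wells", {
  wells <- random_rect_wells(3, 4, c(2, 20), c(1, 6))
  obs <- tibble::tibble(
    well = wells$well,
    unseeded = rep(c("clear", "crystals", "clear", "precipitate"), 3),
    seeded = rep(c("crystals", "crystals", "clear", "precipitate"), 3))
  d <- build_phase_diagram(wells, obs)
  expect_equal(sum(d$zone_fractions$fraction), 1)
  expect_equal(d$zone_fractions$n[d$zone_fractions$zone == "metastable"], 3)

  # dropping one well's observations leaves every other numerator unchanged
  d2 <- build_phase_diagram(wells, obs[-1, ])
  expect_equal(sum(d2$zones$zone == "unknown"), 1)
  kept <- d$zone_fractions$zone != "metastable"
  expect_equal(d2$zone_fractions$n[kept], d$zone_fractions$n[kept])
})

test_that("observations for unknown wells are a reconciliation error", {
  wells <- random_rect_wells(2, 2, c(2, 20), c(1, 6))
  obs <- tibble::tibble(well = c("A1", "Z9"), unseeded = "clear",
                        seeded = "clear")
  expect_error(build_phase_diagram(wells, obs),
               regexp = "Z9", class = "pp_reconciliation_error")
})

test_that("an all-clear plate is fully undersaturated with empty frontiers", {
  wells <- random_rect_wells(3, 3, c(2, 20), c(1, 6))
  obs <- tibble::tibble(well = wells$well, unseeded = "clear", seeded = "clear")
  d <- build_phase_diagram(wells, obs)
  expect_equal(d$zone_fractions$fraction[d$zone_fractions$zone == "undersaturated"], 1)
  expect_equal(nrow(d$solubility_frontier), 0)
  expect_equal(nrow(d$nucleation_frontier), 0)
})

test_that("a perfectly separable constant boundary is found exactly", {
  pts <- expand.grid(protein = 1:4, precipitant = 1:4)
  pts$side <- ifelse(pts$protein <= 2, "below", "above")
  st <- estimate_frontier(pts)
  expect_equal(st$protein, rep(2.5, 4))
  expect_equal(attr(st, "misclassified"), 0L)
})

test_that("a single flipped label costs exactly one misclassification", {
  set.seed(31)
  for (rep in 1:10) {
    pts <- random_frontier_points(4, 4, flip = 0)
    i <- sample(nrow(pts), 1)
    pts$side[i] <- ifelse(pts$side[i] == "below", "above", "below")
    st <- estimate_frontier(pts)
    oracle <- oracle_frontier(pts)
    expect_equal(attr(st, "misclassified"), oracle$misclassified)
    expect_lte(attr(st, "misclassified"), 1L)
    expect_equal(st$protein, oracle$protein)
  }
})

test_that("the staircase estimator equals exhaustive search on random grids", {
  set.seed(32)
  for (rep in 1:60) {
    rows <- sample(2:8, 1)
    cols <- sample(2:8, 1)
    pts <- random_frontier_points(rows, cols, flip = runif(1, 0, 0.25))
    if (!all(c("below", "above") %in% pts$side)) next
    st <- estimate_frontier(pts)
    oracle <- oracle_frontier(pts)
    expect_equal(attr(st, "misclassified"), oracle$misclassified)
    expect_equal(st$protein, oracle$protein)
    expect_false(is.unsorted(rev(st$protein)))  # non-increasing
  }
})

test_that("one-sided input warns and returns a degenerate staircase", {
  pts <- data.frame(protein = 1:3, precipitant = 1, side = "below")
  expect_warning(st <- estimate_frontier(pts), class = "pp_one_sided")
  expect_equal(st$protein, Inf)
})

test_that("nucleation frontier sits at or above the solubility frontier", {
  fx <- generate_fixture("classic")
  plate <- plan_plate(fx$config$grid, fx$config$stocks)
  d <- build_phase_diagram(plate, simulate_plate(fx$model, plate))
  stopifnot(nrow(d$solubility_frontier) > 0, nrow(d$nucleation_frontier) > 0)
  joined <- merge(d$solubility_frontier, d$nucleation_frontier,
                  by = c("segment", "precipitant"),
                  suffixes = c("_sol", "_nuc"))
  expect_true(all(joined$protein_nuc >= joined$protein_sol))
})

test_that("dual-metastable landscapes yield multiple frontier segments", {
  fx <- generate_fixture("dual_metastable")
  plate <- plan_plate(fx$config$grid, fx$config$stocks)
  d <- build_phase_diagram(plate, simulate_plate(fx$model, plate))
  expect_gte(count_zone_components(d, "metastable"), 2)
  expect_gte(length(unique(d$solubility_frontier$segment)), 2)
})

test_that("observation tables round-trip through the long CSV format", {
  wells <- random_rect_wells(2, 3, c(2, 20), c(1, 6))
  obs <- tibble::tibble(well = wells$well,
                        unseeded = c("clear", "crystals", NA,
                                     "precipitate", "clear", "shower"),
                        seeded = c("crystals", "crystals", "clear",
                                   NA, "clear", "shower"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_observations(obs, path)
  back <- read_observations(path)
  expect_equal(as.data.frame(back[order(back$well), ]),
               as.data.frame(obs[order(obs$well), c("well", "unseeded", "seeded")]))
})
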