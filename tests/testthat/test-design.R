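test_that("corner interpolation is bilinear with exact corners", {
  corners <- corner_spec(c(20, 8, 10, 2), c(1, 6, 3, 8))
  g2 <- interpolate_corners(corners, 2, 2)
  expect_equal(g2$protein, corners$protein)
  expect_equal(g2$precipitant, corners$precipitant)

  g3 <- interpolate_corners(corners, 3, 3)
  center <- g3[g3$row == 1 & g3$col == 1, ]
  expect_equal(center$protein, mean(corners$protein))
  expect_equal(center$precipitant, mean(corners$precipitant))

  # equal protein across top and bottom edges -> identical protein ladder
  # in every column
  flat <- interpolate_corners(corner_spec(c(18, 18, 3, 3), c(1, 6, 2, 9)), 5, 7)
  ladders <- split(flat$protein, flat$col)
  for (l in ladders) expect_equal(l, ladders[[1]])

  expect_error(interpolate_corners(corners, 1, 4), class = "pp_design_error")
})

test_that("rows and columns are affine in the well index", {
  corners <- corner_spec(c(22.3, 7.1, 11.8, 0.9), c(0.7, 6.2, 2.9, 8.8))
  g <- interpolate_corners(corners, 7, 9)
  line_dev <- function(v) {
    idx <- seq_along(v) - 1
    fit <- v[1] + (v[length(v)] - v[1]) * idx / (length(v) - 1)
    max(abs(v - fit))
  }
  for (r in unique(g$row)) {
    expect_lt(line_dev(g$protein[g$row == r]), 1e-9)
    expect_lt(line_dev(g$precipitant[g$row == r]), 1e-9)
  }
  for (cl in unique(g$col)) {
    expect_lt(line_dev(g$protein[g$col == cl]), 1e-9)
    expect_lt(line_dev(g$precipitant[g$col == cl]), 1e-9)
  }
})

test_that("plan_well reproduces the xylanase seed-well arithmetic", {
  w <- plan_well(15.95, 4.4556, xylanase_stocks(), simple_grid(drop = 2))
  expect_equal(w$v_protein_ul, 0.8861, tolerance = 1e-4)
  expect_equal(w$v_cocktail_ul, 1.1139, tolerance = 1e-4)
  expect_equal(w$v_diluent_ul, 0)
  expect_true(w$feasible)
})

test_that("plan_well handles degenerate and infeasible targets", {
  g <- simple_grid(drop = 2)
  w0 <- plan_well(0, 0, xylanase_stocks(), g)
  expect_equal(w0$v_diluent_ul, 2)
  expect_equal(w0$v_protein_ul + w0$v_cocktail_ul + w0$v_seed_ul, 0)
  expect_error(plan_well(40, 1, xylanase_stocks(), g),
               class = "pp_infeasible_error")
  # overfilled drop is flagged, not an error
  over <- plan_well(30, 6, xylanase_stocks(), g)
  expect_false(over$feasible)
})

test_that("planned plates conserve volume and reproduce corners", {
  set.seed(21)
  stocks <- xylanase_stocks()
  for (rep in 1:10) {
    rows <- sample(2:8, 1)
    cols <- sample(2:8, 1)
    drop <- sample(c(1, 2, 5), 1)
    corners <- corner_spec(runif(4, 0, 15), runif(4, 0, 3.5))
    grid <- grid_design(rows, cols, drop, corners, min_dispense_ul = 0)
    plate <- plan_plate(grid, stocks)
    w <- plate$wells[plate$wells$feasible, ]
    sums <- w$v_protein_ul + w$v_cocktail_ul + w$v_seed_ul + w$v_diluent_ul
    expect_equal(sums, rep(drop, nrow(w)), tolerance = 1e-9)
    # corner wells reproduce the corner spec exactly in target space
    corner_wells <- plate$wells[plate$wells$row %in% c(0, rows - 1) &
                                  plate$wells$col %in% c(0, cols - 1), ]
    expect_equal(sort(corner_wells$protein_mg_ml), sort(corners$protein))
    expect_equal(sort(corner_wells$precipitant_conc), sort(corners$precipitant))
  }
})

test_that("re-mixing the planned volumes recovers the target within rounding", {
  stocks <- xylanase_stocks()
  grid <- simple_grid(4, 4, 2, protein = c(20, 8, 10, 2),
                      precipitant = c(0.5, 5, 2, 6.5))
  plate <- plan_plate(grid, stocks)
  # one robot-precision step of stock mis-dispense bounds the error
  tol_p <- grid$robot_precision_ul / grid$drop_volume_ul * 36
  tol_c <- grid$robot_precision_ul / grid$drop_volume_ul * 8
  for (i in seq_len(nrow(plate$wells))) {
    comp <- well_composition(plate$wells[i, ], stocks)
    expect_lt(abs(conc_of(comp, "xylanase") - plate$wells$protein_mg_ml[i]), tol_p)
    expect_lt(abs(conc_of(comp, "sodium_formate") - plate$wells$precipitant_conc[i]), tol_c)
  }
})

test_that("the feasibility frontier matches the closed-form rule", {
  stocks <- xylanase_stocks()
  grid <- simple_grid(drop = 2, seed_mode = "separate_channel",
                      seed_fraction = 0.1, min_dispense_ul = 0)
  sweep <- expand.grid(P = seq(0, 36, length.out = 50),
                       c = seq(0, 8, length.out = 50))
  plans <- plan_well(sweep$P, sweep$c, stocks, grid)
  rule <- sweep$P / 36 + sweep$c / 8 + 0.1 <= 1 + 1e-5
  expect_equal(plans$feasible, rule)
})

test_that("consumption totals are additive and scale with drop volume", {
  stocks <- xylanase_stocks()
  # fine dispense grid so rounding does not mask the scaling law
  g1 <- simple_grid(4, 6, 2, protein = c(20, 8, 10, 2),
                    precipitant = c(0.5, 5, 2, 6.5),
                    robot_precision_ul = 1e-6)
  g2 <- simple_grid(4, 6, 4, protein = c(20, 8, 10, 2),
                    precipitant = c(0.5, 5, 2, 6.5),
                    robot_precision_ul = 1e-6)
  p1 <- plan_plate(g1, stocks)
  p2 <- plan_plate(g2, stocks)
  w <- p1$wells[p1$wells$feasible, ]
  expect_equal(p1$totals$volume_ul[["protein"]], sum(w$v_protein_ul))
  expect_equal(p1$totals$volume_ul[["diluent"]], sum(w$v_diluent_ul))
  expect_equal(unname(p2$totals$volume_ul), unname(2 * p1$totals$volume_ul),
               tolerance = 1e-6)
  expect_equal(p2$totals$protein_mass_mg, 2 * p1$totals$protein_mass_mg,
               tolerance = 1e-6)
})

test_that("protein budget endpoints follow from consumption accounting", {
  # 30 wells at 0.5 ul protein each from a 10 mg/ml stock: 15 ul = 0.15 mg
  cona <- stock_set(mk_mix(concanavalin_a = list(10, "mg_per_ml")),
                    mk_mix(ammonium_sulfate = list(4, "M")))
  grid <- grid_design(5, 6, 2, corner_spec(rep(2.5, 4), c(0.5, 2, 0.5, 2)))
  plate <- plan_plate(grid, cona)
  expect_equal(plate$totals$volume_ul[["protein"]], 15)
  expect_equal(plate$totals$protein_mass_mg, 0.15)

  # 30 wells at 2 ul neat protein from a 64 mg/ml stock: 60 ul = 3.84 mg,
  # 3.8 mg at two significant figures
  gmha <- stock_set(mk_mix(BpGmhA = list(64, "mg_per_ml")),
                    mk_mix(peg3350 = list(40, "percent_w_v")))
  grid2 <- grid_design(5, 6, 2, corner_spec(rep(64, 4), rep(0, 4)))
  plate2 <- plan_plate(grid2, gmha)
  expect_equal(plate2$totals$volume_ul[["protein"]], 60)
  expect_equal(plate2$totals$protein_mass_mg, 3.84)
  expect_equal(signif(plate2$totals$protein_mass_mg, 2), 3.8)
})

test_that("all-infeasible plates raise a design error", {
  expect_error(
    plan_plate(simple_grid(2, 2, 2, protein = rep(30, 4),
                           precipitant = rep(7, 4)),
               xylanase_stocks()),
    class = "pp_design_error")
})

test_that("worklists honor channel order, omit zeros, and round-trip", {
  stocks <- xylanase_stocks()
  grid <- simple_grid(2, 2, 2, protein = c(20, 8, 10, 2),
                      precipitant = c(0.5, 5, 2, 6.5))
  plate <- plan_plate(grid, stocks)
  wl <- export_worklist(plate)
  expect_true(all(wl$volume_ul > 0))
  expect_false("seed" %in% wl$channel)  # seed_mode none
  ord <- c(diluent = 1, cocktail = 2, seed = 3, protein = 4)
  for (wlab in unique(wl$well)) {
    expect_false(is.unsorted(ord[wl$channel[wl$well == wlab]]))
  }
  # wells appear in plate (row-major) order
  expect_equal(unique(wl$well), plate$wells$well[plate$wells$well %in% wl$well])

  path <- withr::local_tempfile(fileext = ".csv")
  write_worklist(plate, path)
  expect_identical(as.data.frame(read_worklist(path)), as.data.frame(wl))
})

test_that("plate maps round-trip through CSV", {
  plate <- plan_plate(simple_grid(3, 4, 2, protein = c(20, 8, 10, 2),
                                  precipitant = c(0.5, 5, 2, 6.5)),
                      xylanase_stocks())
  path <- withr::local_tempfile(fileext = ".csv")
  write_plate(plate, path)
  back <- read_plate(path)
  expect_equal(as.data.frame(back), as.data.frame(plate$wells))
})
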