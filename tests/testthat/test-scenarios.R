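test_that("counterfactual specs modify exactly their own stressor", {
  land <- tiny_landscape(seed = 15, rows = 6, cols = 6, depth = 0.3,
                         t_start = 1590)
  g <- land$grid
  human <- gen_human_field(g, seed = 2)
  p <- demographic_params(h_max = 0.2)
  nh <- apply_scenario(land, human, p, scenario_spec("no_hunting"))
  expect_equal(nh$params$h_max, 0)
  expect_identical(nh$landscape, land)
  nl <- apply_scenario(land, human, p, scenario_spec("no_landuse"))
  expect_equal(nl$params$h_max, 0.2)
  expect_true(all(nl$landscape$biomass_adjusted ==
                    matrix(rep(land$biomass_raw, each = g$n_steps),
                           g$n_steps, g$n_cells)))
  expect_true(all(nl$landscape$friction[!nl$landscape$ice] == 1))
  expect_true(all(nl$landscape$friction[nl$landscape$ice] == 0))
  # no_human composes both counterfactuals exactly
  nu <- apply_scenario(land, human, p, scenario_spec("no_human"))
  both <- apply_scenario(nl$landscape, human, nh$params,
                         scenario_spec("baseline"))
  expect_equal(nu$params$h_max, 0)
  expect_identical(nu$landscape$biomass_adjusted,
                   nl$landscape$biomass_adjusted)
  expect_identical(nu$landscape$friction, nl$landscape$friction)
  expect_identical(nu$landscape$env, nl$landscape$env)
  expect_error(scenario_spec("volcano"), "arg")
})

test_that("no hunting yields zero offtake and pointwise dominance", {
  land <- tiny_landscape(seed = 16, rows = 6, cols = 6, depth = 0.2,
                         t_start = 1590)
  g <- land$grid
  human <- matrix(0.7, g$n_steps, g$n_cells)
  p <- demographic_params(h_max = 0.25, r_sd = 0.05)
  base <- simulate_range(p, land, human, seed = 8)
  sc <- apply_scenario(land, human, p, scenario_spec("no_hunting"))
  cf <- simulate_range(sc$params, sc$landscape, human, seed = 8)
  expect_true(all(cf$offtake == 0))
  # shared random substreams: harvest removal cannot reduce abundance
  expect_true(all(cf$totals >= base$totals - 1e-9))
  expect_true(all(cf$abundance >= base$abundance - 1e-9))
})

test_that("harvest escalation scales the post-1500 CE rate and depletes monotonically", {
  land <- tiny_landscape(seed = 16, rows = 6, cols = 6, depth = 0.2,
                         t_start = 1590)
  g <- land$grid
  p <- demographic_params(h_max = 0.2)
  sc <- apply_scenario(land, NULL, p,
                       scenario_spec("harvest_scan",
                                     harvest_multiplier_post1500 = 0.3))
  step1500 <- paleorange:::step_for_bp(g, 450)
  expect_equal(sc$h_max_series[step1500 - 1], 0.2)
  expect_equal(sc$h_max_series[step1500], 0.2 * 1.3) # 30% escalation
  # per-model final totals are nonincreasing across multipliers (same seed)
  human <- matrix(0.7, g$n_steps, g$n_cells)
  finals <- sapply(c(0.1, 0.4, 0.7, 1.0), function(m) {
    s <- apply_scenario(land, NULL, p,
                        scenario_spec("harvest_scan",
                                      harvest_multiplier_post1500 = m))
    simulate_range(p, land, human, seed = 5,
                   h_max_series = s$h_max_series)$totals[g$n_steps]
  })
  expect_true(all(diff(finals) <= 1e-9))
  # degenerate multiplier 0 equals the baseline extension
  s0 <- apply_scenario(land, NULL, p,
                       scenario_spec("harvest_scan",
                                     harvest_multiplier_post1500 = 0))
  expect_equal(simulate_range(p, land, human, seed = 5,
                              h_max_series = s0$h_max_series)$totals,
               simulate_range(p, land, human, seed = 5)$totals)
})

test_that("the harvest scan reports the 1870 validation constant", {
  w <- small_world()
  post <- as.data.frame(unclass(demographic_params()))
  scan <- harvest_scan(post, w, multipliers = c(0.2, 0.6), seed = 4)
  expect_equal(nrow(scan), 2)
  expect_true(all(diff(scan$final_total) <= 1e-9))
  expect_equal(attr(scan, "historical_estimate_1870"), 3560)
  expect_equal(sum(historical_bison_1870()), 2000 + 1560)
  expect_error(harvest_scan(post[0, ], w), "empty")
})

test_that("extirpation attribution follows the counterfactual truth table", {
  g <- make_grid(1, 4, 120, 100, 10)
  occ <- function(cells) { # occupied throughout in `cells`, empty elsewhere
    ab <- matrix(0, g$n_steps, 4); ab[, cells] <- 10; fake_sim(ab, g)
  }
  ever <- function(cells, lost) { # occupied early, extirpated in `lost`
    ab <- matrix(0, g$n_steps, 4); ab[, cells] <- 10
    ab[g$n_steps, lost] <- 0; ab[2:g$n_steps, lost] <- 0
    fake_sim(ab, g)
  }
  # cell 1: back under no_hunting; cell 2: back under no_landuse;
  # cell 3: back only under the combined removal; cell 4: gone everywhere
  baseline <- list(ever(1:4, 1:4))
  cfs <- list(no_hunting = list(occ(1)), no_landuse = list(occ(2)),
              no_human = list(occ(c(1, 2, 3))))
  lab <- attribute_extirpation(baseline, cfs, g, at_year_ce = 1850)
  expect_equal(lab, c("hunting", "land_use", "human_combined", "climate"))
  # labels partition the extirpated cells: nothing else is labelled
  base2 <- list(occ(1:2)) # nothing extirpated
  lab2 <- attribute_extirpation(base2, cfs, g, at_year_ce = 1850)
  expect_true(all(is.na(lab2[1:2])))
  # grid mismatch errors
  g2 <- make_grid(2, 4, 120, 100, 10)
  expect_error(attribute_extirpation(baseline, cfs, g2), "mismatch")
})

test_that("occupancy maps are masked by model agreement and flag low abundance", {
  g <- make_grid(1, 2, 120, 100, 10)
  make <- function(v1, v2) fake_sim(matrix(c(rep(v1, 3), rep(v2, 3)), 3, 2), g)
  # 6 of 25 members occupy cell 2 (0.24 < 0.25): masked
  res <- c(lapply(1:6, function(i) make(100, 40)),
           lapply(7:25, function(i) make(100, 0)))
  om <- occupancy_agreement(res, distances = rep(1, 25))
  expect_false(om$shown[2])
  expect_true(is.na(om$abundance[2]))
  expect_true(om$shown[1])
  # ensemble abundance below 50 is flagged very low
  res2 <- lapply(1:4, function(i) make(49, 200))
  om2 <- occupancy_agreement(res2, distances = rep(1, 4))
  expect_true(om2$low_flag[1])
  expect_false(om2$low_flag[2])
  expect_error(occupancy_agreement(res2, rep(1, 4), agreement = 0), "agreement")
})
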