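test_that("carrying capacity reduces linearly with suitability", {
  # posterior maximum density on the Eurasian cell: ~2000 animals
  expect_equal(round(carrying_capacity(1, 0.3, 86.6 * 75.6) / 100) * 100, 2000)
  expect_equal(carrying_capacity(0, 0.3, 86.6 * 75.6), 0)
  expect_equal(carrying_capacity(0.5, 1, 100), 50)
})

test_that("Ricker growth has the closed form and its fixed point", {
  expect_equal(step_growth(1000, 1000, 0.4, 0), 1000) # N = K fixed point
  expect_equal(step_growth(100, 1000, 0.2, 0), 100 * exp(0.18))
  expect_equal(step_growth(100, 0, 0.2, 0), 0) # K = 0 collapses
  # stochastic draws come from Normal(r_max, r_sd)
  set.seed(1)
  n <- step_growth(rep(100, 1e4), rep(1e8, 1e4), 0.2, 0.05)
  r_real <- log(n / 100) / (1 - 100 / 1e8)
  expect_equal(mean(r_real), 0.2, tolerance = 0.01)
  expect_equal(sd(r_real), 0.05, tolerance = 0.05)
})

test_that("harvest is a capped generalized Holling response", {
  # no humans: the no-hunting counterfactual limit
  h0 <- step_harvest(500, 0, 0.2, 1.5, 300)
  expect_equal(h0$offtake, 0)
  expect_equal(h0$N, 500)
  # availability is 1/2 at the half-saturation abundance (type III)
  h3 <- step_harvest(300, 1, 0.2, 2, 300)
  expect_equal(h3$offtake, 0.2 * 300 / 2)
  # type II at q = 1
  h2 <- step_harvest(300, 1, 0.2, 1, 100)
  expect_equal(h2$offtake, 0.2 * 1 * 300 * 300 / (100 + 300))
  # the proportional cap binds as N grows large
  hc <- step_harvest(1e9, 1, 0.2, 1.5, 300)
  expect_equal(hc$offtake / 1e9, 0.2, tolerance = 1e-6)
})

test_that("the Allee rule extirpates strictly below the threshold", {
  expect_equal(apply_allee(8, 9), 0)
  expect_equal(apply_allee(9, 9), 9) # boundary persists
  expect_equal(apply_allee(c(0.5, 20), 0), c(0.5, 20)) # identity at zero
})

test_that("dispersal moves the expected mass and conserves animals", {
  g2 <- make_grid(1, 2, 110, 100, 10)
  N <- c(100, 0)
  out <- step_dispersal(N, c(1, 1), 0.05, 100, g2)
  expect_equal(out, c(95, 5)) # exactly 5% transferred
  expect_equal(step_dispersal(N, c(1, 1), 0, 100, g2), N)
  # blocked destinations: movers stay
  expect_equal(step_dispersal(N, c(1, 0), 0.05, 100, g2), N)
  # conservation on random landscapes
  g <- make_grid(6, 7, 190, 100, 10)
  set.seed(5)
  for (rep in 1:5) {
    N <- runif(g$n_cells, 0, 500)
    fr <- runif(g$n_cells)
    fr[sample(g$n_cells, 5)] <- 0
    out <- step_dispersal(N, fr, 0.2, 250, g)
    expect_lt(abs(sum(out) - sum(N)) / sum(N), 1e-9)
    expect_true(all(out >= 0))
  }
})

test_that("the compiled simulator reproduces the composed R step functions", {
  land <- flat_landscape(rows = 4, cols = 4, n_steps = 20, suit = 0.6)
  g <- land$grid
  set.seed(2)
  human <- matrix(runif(g$n_steps * g$n_cells), g$n_steps, g$n_cells)
  p <- demographic_params(r_max = 0.3, r_sd = 0, h_max = 0.15, q_shape = 1.4,
                          theta = 200, allee_threshold = 5,
                          dispersal_fraction = 0.1, dispersal_max_km = 150)
  sim <- simulate_range(p, land, human, seed = 9)
  K <- carrying_capacity(land$suitability, p$max_density, g$cell_area_km2)
  kern <- dispersal_kernel(g, p$dispersal_max_km)
  N <- K[1, ]
  for (s in 2:g$n_steps) {
    N <- step_growth(N, K[s, ], p$r_max, 0)
    hv <- step_harvest(N, human[s, ], p$h_max, p$q_shape, p$theta)
    N <- step_dispersal(hv$N, land$friction[s, ], p$dispersal_fraction,
                        p$dispersal_max_km, g, kern)
    N <- apply_allee(N, p$allee_threshold)
    expect_equal(sim$abundance[s, ], N, tolerance = 1e-12)
    expect_equal(sim$offtake[s, ], hv$offtake, tolerance = 1e-12)
  }
})

test_that("deterministic cell dynamics match a scalar Ricker reference", {
  land <- flat_landscape(rows = 1, cols = 1, n_steps = 101, suit = 0.7)
  p <- demographic_params(r_max = 0.45, r_sd = 0, h_max = 0,
                          dispersal_fraction = 0, allee_threshold = 0)
  sim <- simulate_range(p, land, no_humans(land), seed = 1,
                        init = 25) # far from K: full transient
  K <- carrying_capacity(0.7, p$max_density, land$grid$cell_area_km2)
  N <- 25
  ref <- numeric(101); ref[1] <- N
  for (s in 2:101) { N <- N * exp(0.45 * (1 - N / K)); ref[s] <- N }
  expect_equal(sim$totals, ref, tolerance = 1e-12)
})

test_that("simulation holds equilibrium and tracks a suitability collapse", {
  land <- flat_landscape(rows = 3, cols = 3, n_steps = 60, suit = 0.8)
  p <- demographic_params(h_max = 0, r_sd = 0, dispersal_fraction = 0,
                          allee_threshold = 0)
  sim <- simulate_range(p, land, no_humans(land), seed = 1)
  expect_lt(diff(range(sim$totals)), 1e-9) # constant at K
  # 50% suitability collapse mid-run: totals reach ~half within 5 generations
  land2 <- land
  land2$suitability[30:60, ] <- 0.4
  sim2 <- simulate_range(p, land2, no_humans(land2), seed = 1)
  expect_equal(sim2$totals[35] / sim2$totals[29], 0.5, tolerance = 0.1)
  # determinism: same seed reproduces the trajectory exactly
  p3 <- demographic_params(r_sd = 0.08, h_max = 0.1)
  land3 <- flat_landscape(rows = 3, cols = 3, n_steps = 60, suit = 0.8)
  h3 <- matrix(0.5, 60, 9)
  expect_identical(simulate_range(p3, land3, h3, seed = 4)$abundance,
                   simulate_range(p3, land3, h3, seed = 4)$abundance)
})

test_that("no animals ever occupy ice cells and harvest cannot help", {
  land <- tiny_landscape(seed = 13, rows = 8, cols = 6, depth = 0.3,
                         t_start = 1590)
  g <- land$grid
  hum <- matrix(0.6, g$n_steps, g$n_cells)
  p1 <- demographic_params(h_max = 0.1, r_sd = 0.05, allee_threshold = 2)
  sim1 <- simulate_range(p1, land, hum, seed = 6)
  expect_true(all(sim1$abundance[land$ice] == 0))
  expect_true(all(sim1$abundance >= 0))
  expect_true(all(sim1$offtake <= 0.1 * (sim1$abundance + sim1$offtake) + 1e-9))
  # raising h_max (same seed) never increases any per-step total
  p2 <- demographic_params(h_max = 0.3, r_sd = 0.05, allee_threshold = 2)
  sim2 <- simulate_range(p2, land, hum, seed = 6)
  expect_true(all(sim2$totals <= sim1$totals + 1e-9))
})

test_that("extirpation steps mark terminal zero runs", {
  land <- flat_landscape(rows = 1, cols = 3, n_steps = 5, suit = 0.5)
  # cell 2 loses all habitat from step 4; cell 3 never has any
  land$suitability[4:5, 2] <- 0
  land$suitability[, 3] <- 0
  psim <- demographic_params(h_max = 0, r_sd = 0, dispersal_fraction = 0,
                             allee_threshold = 0)
  s <- simulate_range(psim, land, no_humans(land), seed = 1)
  expect_true(is.na(s$extirpation_step[1])) # extant at the end
  expect_equal(s$extirpation_step[2], 4L)   # first step of the terminal zeros
  expect_equal(s$extirpation_step[3], 0L)   # never occupied
  # a recolonized gap does not count as extirpation
  land2 <- flat_landscape(rows = 1, cols = 2, n_steps = 6, suit = 0.5)
  land2$suitability[3, 2] <- 0 # habitat gap, then recovery
  land2$friction[3, 2] <- 0    # no immigration during the gap
  p2 <- demographic_params(h_max = 0, r_sd = 0, dispersal_fraction = 0.2,
                           dispersal_max_km = 100, allee_threshold = 0)
  s2 <- simulate_range(p2, land2, no_humans(land2), seed = 1)
  expect_equal(s2$abundance[3, 2], 0)
  expect_gt(s2$abundance[6, 2], 0)
  expect_true(is.na(s2$extirpation_step[2]))
})
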