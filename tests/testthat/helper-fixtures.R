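# Small in-code fixtures shared across tests.

tiny_grid <- function(rows = 5, cols = 5, t_start = 1090, t_end = 100,
                      step = 10) {
  make_grid(rows, cols, t_start, t_end, step)
}

tiny_landscape <- function(seed = 11, rows = 5, cols = 5, depth = 0,
                           t_start = 1090, ...) {
  gen_landscape(tiny_grid(rows, cols, t_start = t_start), collapse_depth = depth,
                seed = seed, ...)
}

# Landscape with no ice, static suitability and no land use: clean dynamics.
flat_landscape <- function(rows = 3, cols = 3, n_steps = 51, suit = 0.8) {
  grid <- make_grid(rows, cols, 100 + (n_steps - 1) * 10, 100, 10)
  S <- grid$n_steps; nc <- grid$n_cells
  env <- array(0, c(S, nc, 4),
               dimnames = list(NULL, NULL, c("precip", "winter_temp",
                                             "evapotranspiration",
                                             "biomass_adjusted")))
  structure(list(grid = grid,
                 suitability = matrix(suit, S, nc),
                 biomass_raw = rep(1, nc),
                 biomass_adjusted = matrix(1, S, nc),
                 ice = matrix(FALSE, S, nc),
                 friction = matrix(1, S, nc),
                 friction_landuse = matrix(1, S, nc),
                 env = env),
            class = "landscape_series")
}

no_humans <- function(landscape) {
  matrix(0, landscape$grid$n_steps, landscape$grid$n_cells)
}

# A minimal sim_result wrapper around a hand-built abundance matrix.
fake_sim <- function(abundance, grid, offtake = NULL) {
  if (is.null(offtake)) offtake <- abundance * 0
  structure(list(abundance = abundance, offtake = offtake,
                 totals = rowSums(abundance),
                 offtake_totals = rowSums(offtake),
                 extirpation_step = rep(NA_integer_, ncol(abundance)),
                 times_bp = grid$step_times_bp, grid = grid),
            class = "sim_result")
}

# Brute-force product-Gaussian KDE (independent oracle for the C++ kernel).
kde_oracle <- function(X, C, h) {
  apply(X, 1, function(x) {
    mean(apply(C, 1, function(ci) prod(stats::dnorm(x, ci, h))))
  })
}

# Small pom world cached per session (niche + targets on a 10x10 grid).
small_world <- local({
  w <- NULL
  function() {
    if (is.null(w)) w <<- pom_world(31, n_rows = 10, n_cols = 10,
                                    t_start_bp = 1590, n_fossils = 30)
    w
  }
})
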