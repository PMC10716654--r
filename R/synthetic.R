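# Synthetic landscapes, human fields and fossil records with the statistical
# shape the analysis assumes: a smooth suitability field with an abrupt
# collapse-and-recovery (a Bolling-Allerod analogue), a monotonically
# expanding human field with cell-wise uncertainty, late land-use onset, a
# poleward-retreating ice mask, and fossils sampled from a known-truth
# simulation with Gaussian dating error and integer quality scores.

# Smoothed-white-noise random field: Gaussian blur (sd = radius cells,
# truncated at 3 sd, replicate padding), rescaled to [0, 1].
smooth_field <- function(n_rows, n_cols, radius = 2) {
  z <- matrix(rnorm(n_rows * n_cols), n_rows, n_cols)
  hw <- max(1L, ceiling(3 * radius))
  k <- exp(-0.5 * ((-hw:hw) / radius)^2)
  k <- k / sum(k)
  blur1 <- function(m) { # along rows, replicate padding
    n <- nrow(m)
    idx <- pmin(pmax(outer(seq_len(n), -hw:hw, `+`), 1L), n)
    out <- 0 * m
    for (j in seq_along(k)) out <- out + k[j] * m[idx[, j], , drop = FALSE]
    out
  }
  z <- t(blur1(t(blur1(z))))
  rng <- range(z)
  if (diff(rng) < 1e-12) return(matrix(0.5, n_rows, n_cols))
  (z - rng[1]) / diff(rng)
}

# Smooth temporal drift series of length n, mean 0, sd 1. Moving average of
# a random walk with truncated windows at the edges (no flat segments, so
# distinct steps give distinct values).
smooth_drift <- function(n) {
  if (n == 1) return(0)
  w <- cumsum(rnorm(n))
  half <- 5L
  z <- vapply(seq_len(n), function(i)
    mean(w[max(1, i - half):min(n, i + half)]), numeric(1))
  s <- sd(z)
  if (s < 1e-12) return(rep(0, n))
  (z - mean(z)) / s
}

#' Generate a synthetic landscape time series
#'
#' Builds a spatially autocorrelated suitability field whose spatial mean
#' drops by `collapse_depth` at `collapse_step` and recovers linearly over
#' `recovery_steps` (an analogue of an abrupt warming event), an ice mask
#' retreating monotonically from the poleward (top) rows, a biomass index
#' reduced by land use in a contiguous block of cells after
#' `landuse_onset_step`, a dispersal-friction surface (0 on ice, reduced
#' under land use), and four environmental axes (annual precipitation,
#' winter temperature, spring-summer evapotranspiration, adjusted biomass)
#' used by the niche model. The warming event is also injected into the
#' temperature axis so niche-projected suitability reproduces the collapse.
#'
#' @param grid A `grid_spec`.
#' @param collapse_step 1-based step index of the abrupt suitability drop.
#' @param collapse_depth Fractional drop in mean suitability, in `[0, 1]`.
#' @param recovery_steps Steps over which suitability recovers linearly.
#' @param landuse_onset_step Step after which land use reduces biomass and
#'   dispersal friction in a contiguous block.
#' @param seed Integer seed; output is deterministic given the seed.
#' @param ice_rows_init Initial number of ice-covered top rows (default 30%
#'   of rows); ice retreats to zero by 60% of the series.
#' @return A `landscape_series`: grid, `suitability`, `biomass_raw`,
#'   `biomass_adjusted`, `ice`, `friction`, `friction_landuse` (all
#'   step x cell matrices except `biomass_raw`, per cell) and `env`, a
#'   step x cell x 4 array.
#' @export
gen_landscape <- function(grid, collapse_step = round(grid$n_steps * 0.4),
                          collapse_depth = 0.5,
                          recovery_steps = round(grid$n_steps * 0.2),
                          landuse_onset_step = round(grid$n_steps * 0.8),
                          seed = 1L,
                          ice_rows_init = round(0.3 * grid$n_rows)) {
  stopifnot(inherits(grid, "grid_spec"))
  if (collapse_depth < 0 || collapse_depth > 1)
    stop("collapse_depth must be in [0, 1]")
  if (collapse_step < 1 || collapse_step > grid$n_steps)
    stop("collapse_step outside the simulated span")
  S <- grid$n_steps; nc <- grid$n_cells
  with_seed(seed, {
    base <- smooth_field(grid$n_rows, grid$n_cols)
    biomass_base <- 0.2 + smooth_field(grid$n_rows, grid$n_cols)
    f_precip <- smooth_field(grid$n_rows, grid$n_cols)
    f_temp <- smooth_field(grid$n_rows, grid$n_cols)
    f_evap <- smooth_field(grid$n_rows, grid$n_cols)
    d_precip <- smooth_drift(S)
    d_temp <- smooth_drift(S)
    d_evap <- smooth_drift(S)

    # temporal collapse factor g(t): 1, drop to 1 - depth, linear recovery
    g <- rep(1, S)
    if (collapse_depth > 0) {
      idx <- collapse_step:S
      if (recovery_steps > 0) {
        rec <- pmin((idx - collapse_step) / recovery_steps, 1)
      } else rec <- rep(1, length(idx))
      if (recovery_steps == 0) rec[1] <- 0 # instantaneous dip
      g[idx] <- 1 - collapse_depth * (1 - rec)
      g[collapse_step] <- 1 - collapse_depth
    }

    # ice: top rows, retreating linearly to zero by 60% of the series
    rows <- cell_rowcol(grid, seq_len(nc))[, "row"]
    melt_end <- max(1, round(0.6 * S))
    ice_rows <- pmax(0, ceiling(ice_rows_init * (1 - (seq_len(S) - 1) / melt_end)))
    ice_rows[seq_len(S) > melt_end] <- 0
    ice <- matrix(FALSE, S, nc)
    for (s in seq_len(S)) if (ice_rows[s] > 0) ice[s, rows <= ice_rows[s]] <- TRUE

    # land use: contiguous block (south-west quadrant), linear intensification
    cols <- cell_rowcol(grid, seq_len(nc))[, "col"]
    lu_block <- rows > grid$n_rows / 2 & cols <= ceiling(grid$n_cols / 2)
    lu_intensity <- matrix(0, S, nc)
    if (landuse_onset_step < S) {
      after <- (landuse_onset_step + 1):S
      ramp <- (after - landuse_onset_step) / (S - landuse_onset_step)
      lu_intensity[after, lu_block] <- matrix(rep(ramp, sum(lu_block)),
                                              length(after), sum(lu_block))
    }

    # row-major flattening of the field matrices (cell ids are row-major)
    flat <- function(m) as.numeric(t(m))
    biomass_raw <- flat(biomass_base)
    base_v <- flat(base)
    suit <- outer(g, base_v)
    suit[ice] <- 0
    biomass_adjusted <- matrix(rep(biomass_raw, each = S), S, nc) * (1 - 0.5 * lu_intensity)

    friction_landuse <- 1 - 0.3 * lu_intensity
    friction <- friction_landuse
    friction[ice] <- 0

    lat <- (rows - mean(rows)) / max(1, sd(rows))
    std <- function(v) (v - mean(v)) / max(sd(v), 1e-12)
    env <- array(NA_real_, c(S, nc, 4),
                 dimnames = list(NULL, NULL,
                                 c("precip", "winter_temp", "evapotranspiration",
                                   "biomass_adjusted")))
    # warming pulse enters the temperature axis over a few generations
    # (abrupt at centennial scale, but trackable by dispersing populations)
    gs <- vapply(seq_len(S), function(i) mean(g[max(1, i - 4):i]), numeric(1))
    env[, , "precip"] <- outer(0.5 * d_precip, rep(1, nc)) +
      matrix(rep(std(flat(f_precip)), each = S), S, nc)
    env[, , "winter_temp"] <- outer(0.5 * d_temp + 1.5 * (1 - gs), rep(1, nc)) +
      matrix(rep(std(flat(f_temp)) - 0.8 * lat, each = S), S, nc)
    env[, , "evapotranspiration"] <- outer(0.5 * d_evap, rep(1, nc)) +
      matrix(rep(std(flat(f_evap)), each = S), S, nc)
    env[, , "biomass_adjusted"] <- biomass_adjusted

    structure(list(grid = grid, suitability = suit, biomass_raw = biomass_raw,
                   biomass_adjusted = biomass_adjusted, ice = ice,
                   friction = friction, friction_landuse = friction_landuse,
                   lu_block = lu_block, collapse_step = collapse_step,
                   collapse_depth = collapse_depth,
                   recovery_steps = recovery_steps,
                   landuse_onset_step = landuse_onset_step, env = env),
              class = "landscape_series")
  })
}

#' Construct a human-pressure field from mean and s.d. layers
#'
#' @param mean,sd Step x cell matrices of relative human abundance (mean and
#'   cell-wise standard deviation, same units).
#' @param times_bp Time coordinate (years BP, descending) of the rows.
#' @param grid Optional `grid_spec`.
#' @return A `human_field` object.
#' @export
human_field <- function(mean, sd, times_bp, grid = NULL) {
  stopifnot(all(dim(mean) == dim(sd)), nrow(mean) == length(times_bp))
  if (any(!is.finite(mean)) || any(!is.finite(sd)))
    stop("human field contains non-finite values")
  if (any(sd < 0)) stop("sd layer must be nonnegative")
  structure(list(mean = mean, sd = sd, times_bp = times_bp,
                 native_step_years = if (length(times_bp) > 1)
                   abs(diff(times_bp[1:2])) else NA_real_,
                 grid = grid),
            class = "human_field")
}

#' Generate a synthetic relative-human-abundance field
#'
#' Per-cell logistic growth toward a spatially heterogeneous carrying level,
#' starting from `start_frac` of that level, with an uncertainty layer equal
#' to `sd_frac` times the mean. With growth rate r from a fraction 0.01 of
#' the carrying level, the mean crosses half the carrying level near step
#' `log(99)/r`.
#'
#' @param grid A `grid_spec`.
#' @param growth_rate Logistic growth rate per step (negative allowed).
#' @param carrying_level Asymptotic level (before spatial heterogeneity).
#' @param sd_frac Cell-wise s.d. as a fraction of the mean (>= 0).
#' @param seed Integer seed.
#' @param start_frac Initial fraction of the carrying level.
#' @param het_range Range of the spatial heterogeneity multiplier on the
#'   carrying level.
#' @return A `human_field`.
#' @export
gen_human_field <- function(grid, growth_rate = 0.03, carrying_level = 1,
                            sd_frac = 0.25, seed = 1L, start_frac = 0.01,
                            het_range = c(0.6, 1)) {
  stopifnot(inherits(grid, "grid_spec"))
  if (!is.finite(growth_rate) || !is.finite(carrying_level) || !is.finite(sd_frac))
    stop("non-finite parameter")
  if (sd_frac < 0) stop("sd_frac must be >= 0")
  S <- grid$n_steps; nc <- grid$n_cells
  with_seed(seed, {
    het <- het_range[1] + diff(het_range) * as.numeric(t(smooth_field(grid$n_rows, grid$n_cols)))
    L <- carrying_level * het
    A <- (1 - start_frac) / start_frac
    tt <- seq_len(S) - 1
    m <- outer(1 / (1 + A * exp(-growth_rate * tt)), L)
    f <- human_field(m, sd_frac * m, grid$step_times_bp, grid)
    f$carrying <- L
    f
  })
}

#' Sample fossil records from a known-truth simulation
#'
#' Records are drawn from occupied (step, cell) pairs of a simulation
#' (probability proportional to abundance when `detection_prop_abundance`),
#' given Gaussian dating error (truncated at 3 s.d.) and integer quality
#' scores uniform on `quality_range`.
#'
#' @param truth A `sim_result`.
#' @param n_fossils Number of records.
#' @param age_sd_years Dating error s.d. in years.
#' @param quality_range Integer range (inclusive) of quality scores.
#' @param detection_prop_abundance If `TRUE`, sampling probability is
#'   proportional to simulated abundance.
#' @param seed Integer seed.
#' @param kind `"fossil"` or `"historical_sighting"` (the latter has exact
#'   ages: `age_sd` is forced to 0).
#' @return A data frame with columns `cell_id`, `age_bp`, `age_sd`,
#'   `quality`, `kind`.
#' @export
gen_fossils <- function(truth, n_fossils, age_sd_years = 15,
                        quality_range = c(5, 15),
                        detection_prop_abundance = TRUE, seed = 1L,
                        kind = c("fossil", "historical_sighting")) {
  kind <- match.arg(kind)
  occ <- which(truth$abundance > 0, arr.ind = TRUE)
  if (nrow(occ) == 0) stop("no occupied (step, cell) pairs in the truth simulation")
  if (n_fossils == 0)
    return(data.frame(cell_id = integer(), age_bp = numeric(),
                      age_sd = numeric(), quality = integer(),
                      kind = character()))
  if (kind == "historical_sighting") age_sd_years <- 0
  with_seed(seed, {
    p <- if (detection_prop_abundance) truth$abundance[occ] else NULL
    take <- sample.int(nrow(occ), n_fossils, replace = TRUE, prob = p)
    steps <- occ[take, "row"]; cells <- occ[take, "col"]
    # Gaussian dating error truncated at +/- 3 sd (inverse-CDF draw)
    u <- runif(n_fossils, stats::pnorm(-3), stats::pnorm(3))
    err <- age_sd_years * stats::qnorm(u)
    data.frame(cell_id = as.integer(cells),
               age_bp = truth$times_bp[steps] + err,
               age_sd = rep(age_sd_years, n_fossils),
               quality = sample(seq(quality_range[1], quality_range[2]),
                                n_fossils, replace = TRUE),
               kind = rep(kind, n_fossils))
  })
}

#' Build a known-truth bundle for parameter-recovery experiments
#'
#' Generates a landscape, fits a full niche to environmental conditions
#' sampled around a reference optimum, realizes the truth niche with the
#' supplied volume fraction and marginality, projects suitability, samples a
#' human surface, runs one simulation under the supplied parameters, and
#' samples fossils from it. If the simulated population goes extinct before
#' 10% of the span, the bundle is regenerated with a new derived seed (up to
#' `max_tries`, then rejected with an error).
#'
#' @param params A `demographic_params` (the truth).
#' @param grid A `grid_spec`.
#' @param seed Master seed; all stages use derived substreams.
#' @param n_fossils,fossil_age_sd Fossil sampling configuration.
#' @param n_founders Environmental points used to fit the full truth niche.
#' @param max_tries Regeneration attempts before the bundle is rejected.
#' @return A list with the landscape, human field and realization, the truth
#'   simulation, fossils, the full and realized niches, and the seed used.
#' @export
make_truth_bundle <- function(params, grid, seed, n_fossils = 40,
                              fossil_age_sd = 15, n_founders = 60,
                              max_tries = 10) {
  stopifnot(inherits(params, "demographic_params"), inherits(grid, "grid_spec"))
  for (try in seq_len(max_tries)) {
    seed_t <- if (try == 1) seed else derive_seed(seed, 100 + try)
    land <- gen_landscape(grid, seed = derive_seed(seed_t, 1))
    env_flat <- matrix(land$env, grid$n_steps * grid$n_cells, 4,
                       dimnames = list(NULL, dimnames(land$env)[[3]]))
    free <- which(!as.logical(land$ice))
    x_star <- colMeans(env_flat[free, , drop = FALSE])
    sds <- apply(env_flat[free, , drop = FALSE], 2, sd)
    founders <- with_seed(derive_seed(seed_t, 2), {
      z <- sweep(sweep(env_flat[free, , drop = FALSE], 2, x_star), 2,
                 1.5 * pmax(sds, 1e-9), "/")
      w <- exp(-0.5 * rowSums(z^2))
      pick <- sample(free, min(n_founders, length(free)), replace = FALSE,
                     prob = w)
      env_flat[pick, , drop = FALSE]
    })
    full <- fit_hypervolume(founders)
    truth_niche <- subsample_niche(full, params$volume_fraction,
                                   params$marginality, derive_seed(seed_t, 3))
    suit <- project_suitability(truth_niche, land$env)
    suit[land$ice] <- 0
    land$suitability <- suit
    human <- gen_human_field(grid, seed = derive_seed(seed_t, 4))
    human_real <- sample_human_surface(human, params$omega, derive_seed(seed_t, 5))
    sim <- simulate_range(params, land, human_real, seed = derive_seed(seed_t, 6))
    occupied_steps <- which(sim$totals > 0)
    if (length(occupied_steps) == 0 ||
        max(occupied_steps) < 0.1 * grid$n_steps) {
      warning(sprintf("truth simulation extinct before 10%% of steps (try %d); regenerating", try))
      next
    }
    fossils <- gen_fossils(sim, n_fossils, fossil_age_sd,
                           detection_prop_abundance = TRUE,
                           seed = derive_seed(seed_t, 7))
    return(list(grid = grid, landscape = land, human = human,
                human_real = human_real, sim = sim, fossils = fossils,
                params = params, full_niche = full,
                truth_niche = truth_niche, seed = seed_t))
  }
  stop("bundle rejected: truth simulation went extinct before 10% of steps in all attempts")
}
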