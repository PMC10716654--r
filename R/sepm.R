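# Spatially explicit population model: Ricker growth with environmental
# stochasticity, carrying capacity proportional to habitat suitability,
# saturating (type II-III) harvest driven by relative human abundance,
# friction-limited kernel dispersal, and hard Allee extirpation, run at
# generational time steps on the landscape grid.

#' Bundle one demographic/niche/human parametrization
#'
#' One point in the sampled parameter hypercube: growth, density, Allee,
#' dispersal, harvest, human-sampling and niche parameters.
#'
#' @param r_max Intrinsic per-generation growth rate (log of the finite rate
#'   of increase).
#' @param r_sd Environmental s.d. of the growth rate.
#' @param max_density Maximum density at suitability 1, animals per km2.
#' @param allee_threshold Abundance per cell below which a population is
#'   extirpated.
#' @param dispersal_fraction Proportion of each cell dispersing per
#'   generation, in `[0, 1]`.
#' @param dispersal_max_km Maximum dispersal distance, km.
#' @param h_max Maximum harvested proportion per generation, in `[0, 1]`.
#' @param q_shape Harvest functional-response exponent in `[1, 2]` (1 = type
#'   II, 2 = type III).
#' @param theta Half-saturation abundance of the harvest availability term.
#' @param omega Human-sampling window centre in `[-1, 1]`.
#' @param volume_fraction,marginality Realized-niche parameters.
#' @return A `demographic_params` list.
#' @export
demographic_params <- function(r_max = 0.35, r_sd = 0.05, max_density = 0.3,
                               allee_threshold = 9, dispersal_fraction = 0.1,
                               dispersal_max_km = 110, h_max = 0.15,
                               q_shape = 1.3, theta = 300, omega = 0,
                               volume_fraction = 0.65, marginality = 0.5) {
  p <- list(r_max = r_max, r_sd = r_sd, max_density = max_density,
            allee_threshold = allee_threshold,
            dispersal_fraction = dispersal_fraction,
            dispersal_max_km = dispersal_max_km, h_max = h_max,
            q_shape = q_shape, theta = theta, omega = omega,
            volume_fraction = volume_fraction, marginality = marginality)
  stopifnot(p$max_density > 0, p$theta > 0, p$r_sd >= 0,
            p$allee_threshold >= 0, p$dispersal_max_km >= 0)
  if (p$dispersal_fraction < 0 || p$dispersal_fraction > 1)
    stop("dispersal_fraction must be in [0, 1]")
  if (p$h_max < 0 || p$h_max > 1) stop("h_max must be in [0, 1]")
  if (p$q_shape < 1 || p$q_shape > 2) stop("q_shape must be in [1, 2]")
  if (p$omega < -1 || p$omega > 1) stop("omega must be in [-1, 1]")
  if (p$volume_fraction <= 0 || p$volume_fraction > 1)
    stop("volume_fraction must be in (0, 1]")
  structure(p, class = "demographic_params")
}

#' Default prior ranges for the parameter hypercube
#'
#' Wide but plausible uniform ranges: dispersal 5-25% per generation with a
#' 0-300 km maximum distance, harvest up to 40% with a type II-III exponent,
#' and per-generation growth rates conservative enough to keep the Ricker
#' map monotone below carrying capacity.
#'
#' @return Data frame with columns `param`, `lo`, `hi`.
#' @export
default_prior_ranges <- function() {
  data.frame(
    param = c("r_max", "r_sd", "max_density", "allee_threshold",
              "dispersal_fraction", "dispersal_max_km", "h_max", "q_shape",
              "theta", "omega", "volume_fraction", "marginality"),
    lo = c(0.10, 0.00, 0.10, 0, 0.05, 0, 0.00, 1, 50, -1, 0.30, 0.0),
    hi = c(0.60, 0.15, 1.00, 50, 0.25, 300, 0.40, 2, 2000, 1, 1.00, 1.0))
}

#' Carrying capacity from habitat suitability
#'
#' Linear reduction: `K = suitability * max_density * cell_area`, so a fully
#' suitable cell holds the maximum density over the whole cell.
#'
#' @param suitability Suitability in `[0, 1]` (vector or matrix).
#' @param max_density Animals per km2 at suitability 1.
#' @param cell_area_km2 Cell area in km2.
#' @return Carrying capacity in animals per cell, same shape as
#'   `suitability`.
#' @examples
#' carrying_capacity(1, 0.3, 86.6 * 75.6) # ~ 2000 animals per cell
#' @export
carrying_capacity <- function(suitability, max_density, cell_area_km2) {
  stopifnot(all(suitability >= 0), max_density >= 0, cell_area_km2 >= 0)
  suitability * max_density * cell_area_km2
}

#' One Ricker growth step
#'
#' `N' = N * exp(r_t * (1 - N/K))` with `r_t ~ Normal(r_max, r_sd)`; cells
#' with zero carrying capacity go to zero.
#'
#' @param N,K Abundance and carrying capacity (vectors).
#' @param r_max,r_sd Growth-rate mean and environmental s.d.
#' @param r_draw Optional pre-drawn growth rates (for common random
#'   numbers); otherwise drawn from the current RNG stream.
#' @return Updated abundance.
#' @export
step_growth <- function(N, K, r_max, r_sd = 0, r_draw = NULL) {
  if (is.null(r_draw))
    r_draw <- if (r_sd > 0) rnorm(length(N), r_max, r_sd) else rep(r_max, length(N))
  out <- ifelse(K > 0 & N > 0, N * exp(r_draw * (1 - N / K)), 0)
  out
}

#' One harvest step
#'
#' Offtake is a saturating function of prey abundance, relative human
#' abundance and the hunting rate:
#' `O = min(h_max * N, h_max * human * N * N^q / (theta^q + N^q))`, the
#' generalized Holling availability term (type II at `q = 1`, type III at
#' `q = 2`).
#'
#' @param N Abundance (vector).
#' @param human Realized relative human abundance in `[0, 1]`.
#' @param h_max Maximum harvested proportion.
#' @param q_shape Functional-response exponent in `[1, 2]`.
#' @param theta Half-saturation abundance.
#' @return List with updated abundance `N` and `offtake`.
#' @export
step_harvest <- function(N, human, h_max, q_shape, theta) {
  avail <- ifelse(N > 0, N^q_shape / (theta^q_shape + N^q_shape), 0)
  offtake <- pmin(h_max * N, h_max * human * N * avail)
  list(N = pmax(N - offtake, 0), offtake = offtake)
}

#' Hard Allee extirpation
#'
#' Populations strictly below the threshold go locally extinct; a
#' population exactly at the threshold persists.
#'
#' @param N Abundance (vector).
#' @param allee_threshold Extirpation threshold (animals per cell).
#' @return Updated abundance.
#' @export
apply_allee <- function(N, allee_threshold) {
  stopifnot(allee_threshold >= 0)
  N[N < allee_threshold] <- 0
  N
}

#' Precompute the dispersal kernel neighbourhood
#'
#' Destination cells within `dispersal_max_km` (grid-Euclidean distance
#' using the cell dimensions, source excluded) with kernel weights
#' `exp(-d / lambda)`, `lambda = dispersal_max_km / 3`. Returned in a
#' compressed (CSR) layout consumed by the simulator.
#'
#' @param grid A `grid_spec`.
#' @param dispersal_max_km Maximum dispersal distance, km.
#' @return List with 0-based `ptr`, `idx` and weights `w`.
#' @export
dispersal_kernel <- function(grid, dispersal_max_km) {
  nc <- grid$n_cells
  if (dispersal_max_km <= 0)
    return(list(ptr = integer(nc + 1), idx = integer(0), w = numeric(0)))
  lambda <- dispersal_max_km / 3
  dr_max <- floor(dispersal_max_km / grid$cell_height_km)
  dc_max <- floor(dispersal_max_km / grid$cell_width_km)
  offs <- expand.grid(dr = -dr_max:dr_max, dc = -dc_max:dc_max)
  dist <- sqrt((offs$dr * grid$cell_height_km)^2 + (offs$dc * grid$cell_width_km)^2)
  keep <- dist <= dispersal_max_km & dist > 0
  offs <- offs[keep, , drop = FALSE]
  w0 <- exp(-dist[keep] / lambda)
  rc <- cell_rowcol(grid, seq_len(nc))
  ptr <- integer(nc + 1)
  idx_list <- vector("list", nc)
  w_list <- vector("list", nc)
  for (c0 in seq_len(nc)) {
    r2 <- rc[c0, "row"] + offs$dr
    c2 <- rc[c0, "col"] + offs$dc
    ok <- r2 >= 1 & r2 <= grid$n_rows & c2 >= 1 & c2 <= grid$n_cols
    idx_list[[c0]] <- cell_id(grid, r2[ok], c2[ok]) - 1L
    w_list[[c0]] <- w0[ok]
    ptr[c0 + 1] <- ptr[c0] + sum(ok)
  }
  list(ptr = ptr, idx = unlist(idx_list), w = unlist(w_list))
}

#' One dispersal step (reference implementation)
#'
#' A fraction of each cell's animals emigrates and is distributed over
#' destination cells within the maximum dispersal distance, weighted by the
#' distance kernel times the destination friction; movers with no reachable
#' destination (all weights zero, e.g. surrounded by ice) remain. Total
#' abundance is conserved exactly.
#'
#' @param N Per-cell abundance.
#' @param friction Per-cell dispersal-success multiplier in `[0, 1]` (0 on
#'   ice).
#' @param dispersal_fraction Emigrating proportion per generation.
#' @param dispersal_max_km Maximum dispersal distance, km.
#' @param grid A `grid_spec`.
#' @param kernel Optional precomputed `dispersal_kernel`.
#' @return Updated abundance.
#' @export
step_dispersal <- function(N, friction, dispersal_fraction, dispersal_max_km,
                           grid, kernel = NULL) {
  stopifnot(all(friction >= 0 & friction <= 1))
  if (dispersal_fraction == 0) return(N)
  if (is.null(kernel)) kernel <- dispersal_kernel(grid, dispersal_max_km)
  if (length(kernel$idx) == 0) return(N)
  incoming <- numeric(length(N))
  out <- N
  for (c0 in seq_along(N)) {
    if (N[c0] <= 0) next
    span <- seq.int(kernel$ptr[c0] + 1L, length.out = kernel$ptr[c0 + 1] - kernel$ptr[c0])
    if (length(span) == 0) next
    dest <- kernel$idx[span] + 1L
    w <- kernel$w[span] * friction[dest]
    ws <- sum(w)
    if (ws <= 0) next
    movers <- dispersal_fraction * N[c0]
    incoming[dest] <- incoming[dest] + movers * w / ws
    out[c0] <- out[c0] - movers
  }
  out + incoming
}

#' Run the spatially explicit population model
#'
#' Per generation, in order: carrying-capacity update from the suitability
#' series, Ricker growth, harvest, dispersal, Allee extirpation. The first
#' step records the initial state. Growth-rate draws are pregenerated from
#' the seed, so runs that differ only in harvest share identical random
#' substreams (common random numbers for counterfactuals).
#'
#' @param params A `demographic_params`.
#' @param landscape A `landscape_series`.
#' @param human_real Step x cell matrix of realized relative human
#'   abundance.
#' @param seed Integer seed.
#' @param init `"K"` (start at carrying capacity) or a numeric per-cell
#'   vector.
#' @param h_max_series Optional per-step maximum harvest proportion
#'   (overrides the constant `params$h_max`; used by harvest-escalation
#'   scenarios).
#' @return A `sim_result`: `abundance` and `offtake` (step x cell),
#'   `totals` and `offtake_totals` (per step), `extirpation_step` (per
#'   cell: step index, `NA` if extant at the end, 0 if never occupied),
#'   `times_bp` and `grid`.
#' @export
simulate_range <- function(params, landscape, human_real, seed = 1L,
                           init = "K", h_max_series = NULL) {
  stopifnot(inherits(params, "demographic_params"),
            inherits(landscape, "landscape_series"))
  grid <- landscape$grid
  S <- grid$n_steps; nc <- grid$n_cells
  if (!all(dim(human_real) == c(S, nc)))
    stop("human realization shape does not match the landscape grid")
  if (!all(dim(landscape$suitability) == c(S, nc)))
    stop("suitability shape does not match the grid")
  K <- carrying_capacity(landscape$suitability, params$max_density,
                         grid$cell_area_km2)
  K[landscape$ice] <- 0
  rdraw <- with_seed(derive_seed(seed, 11), {
    if (params$r_sd > 0)
      matrix(rnorm(S * nc, params$r_max, params$r_sd), S, nc)
    else matrix(params$r_max, S, nc)
  })
  if (is.null(h_max_series)) h_max_series <- rep(params$h_max, S)
  stopifnot(length(h_max_series) == S)
  kernel <- dispersal_kernel(grid, params$dispersal_max_km)
  N0 <- if (identical(init, "K")) K[1, ] else {
    stopifnot(is.numeric(init), length(init) == nc)
    init
  }
  core <- .sim_core_cpp(K, human_real, rdraw, landscape$friction,
                        h_max_series, params$q_shape, params$theta,
                        params$allee_threshold, params$dispersal_fraction,
                        kernel$ptr, kernel$idx, kernel$w, N0)
  ab <- core$abundance
  ext <- integer(nc)
  for (c0 in seq_len(nc)) {
    occ <- ab[, c0] > 0
    if (!any(occ)) { ext[c0] <- 0L; next }
    if (occ[S]) { ext[c0] <- NA_integer_; next }
    ext[c0] <- max(which(occ)) + 1L # first step of the terminal zero run
  }
  structure(list(abundance = ab, offtake = core$offtake,
                 totals = rowSums(ab), offtake_totals = rowSums(core$offtake),
                 extirpation_step = ext, times_bp = grid$step_times_bp,
                 grid = grid, params = params, seed = seed),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("sim_result: %d steps x %d cells; initial total %.0f, final total %.0f\n",
              nrow(x$abundance), ncol(x$abundance), x$totals[1],
              x$totals[length(x$totals)]))
  invisible(x)
}
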