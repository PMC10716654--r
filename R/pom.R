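# Pattern-oriented validation: summary statistics against fossil and
# refugium targets, ABC rejection with iterative prior refinement, a
# convergence diagnostic, goodness of fit, and inverse-distance ensemble
# weighting.

#' Latin hypercube sample of the parameter priors
#'
#' Each one-dimensional margin is stratified into `n` equal-probability bins
#' with exactly one sample per bin, scaled to the uniform prior ranges.
#'
#' @param ranges Data frame with columns `param`, `lo`, `hi` (lo <= hi).
#' @param n Number of parameter vectors (>= 1).
#' @param seed Integer seed.
#' @return Data frame of `n` rows, one column per parameter.
#' @export
sample_priors_lhs <- function(ranges, n, seed = 1L) {
  stopifnot(is.data.frame(ranges), all(c("param", "lo", "hi") %in% names(ranges)))
  if (n < 1) stop("n must be >= 1")
  if (any(ranges$lo > ranges$hi)) stop("prior ranges must satisfy lo <= hi")
  k <- nrow(ranges)
  L <- with_seed(seed, lhs::randomLHS(as.integer(n), k))
  out <- as.data.frame(sweep(sweep(L, 2, ranges$hi - ranges$lo, "*"), 2,
                             ranges$lo, "+"))
  names(out) <- ranges$param
  out
}

# 8-connected component labelling of occupied cells on the grid.
connected_components <- function(occupied, grid) {
  labels <- integer(grid$n_cells)
  nextlab <- 0L
  rc <- cell_rowcol(grid, seq_len(grid$n_cells))
  for (start in which(occupied)) {
    if (labels[start] != 0L) next
    nextlab <- nextlab + 1L
    queue <- start
    labels[start] <- nextlab
    while (length(queue) > 0) {
      c0 <- queue[1]; queue <- queue[-1]
      nb <- moore_neighbours(grid, c0, rc)
      nb <- nb[occupied[nb] & labels[nb] == 0L]
      labels[nb] <- nextlab
      queue <- c(queue, nb)
    }
  }
  labels
}

# Cell plus (up to) eight Moore neighbours; without_self drops the centre.
moore_neighbours <- function(grid, cell, rc = NULL, include_self = FALSE) {
  if (is.null(rc)) rc <- cell_rowcol(grid, cell) else rc <- rc[cell, , drop = FALSE]
  r0 <- rc[1, "row"]; c0 <- rc[1, "col"]
  rr <- pmax(1L, r0 - 1L):pmin(grid$n_rows, r0 + 1L)
  cc <- pmax(1L, c0 - 1L):pmin(grid$n_cols, c0 + 1L)
  g <- expand.grid(row = rr, col = cc)
  ids <- cell_id(grid, g$row, g$col)
  if (!include_self) ids <- ids[ids != cell]
  ids
}

#' Fraction of fossils matched by a simulation
#'
#' A fossil matches if abundance is positive in its cell or any of its eight
#' Moore neighbours at any generational step within plus or minus two s.d.
#' of its calibrated age; historical sightings (`age_sd = 0`) use only the
#' deposition step.
#'
#' @param sim A `sim_result`.
#' @param fossils Fossil data frame (`cell_id`, `age_bp`, `age_sd`).
#' @param grid A `grid_spec`.
#' @param index Optional precomputed [fossil_match_index()] (avoids
#'   rebuilding the per-fossil step windows and neighbourhoods when scoring
#'   many simulations against the same fossils).
#' @return Matched fraction in `[0, 1]`.
#' @export
occurrence_match <- function(sim, fossils, grid, index = NULL) {
  if (nrow(fossils) == 0) stop("no fossil records to match against")
  if (is.null(index)) index <- fossil_match_index(fossils, grid)
  matched <- 0L
  for (ix in index) {
    if (length(ix$steps) > 0 && any(sim$abundance[ix$steps, ix$cells] > 0))
      matched <- matched + 1L
  }
  matched / nrow(fossils)
}

#' Precompute the spatio-temporal matching index for a fossil set
#'
#' Per fossil: the generational steps within plus or minus two dating s.d.
#' of its age (the deposition step only for exact ages) and its cell plus
#' the eight Moore neighbours.
#'
#' @param fossils Fossil data frame.
#' @param grid A `grid_spec`.
#' @return List (one element per fossil) of `steps` and `cells`.
#' @export
fossil_match_index <- function(fossils, grid) {
  lapply(seq_len(nrow(fossils)), function(i) {
    sdv <- fossils$age_sd[i]
    steps <- if (sdv > 0)
      steps_in_window(grid, fossils$age_bp[i] - 2 * sdv,
                      fossils$age_bp[i] + 2 * sdv)
    else step_for_bp(grid, fossils$age_bp[i])
    list(steps = steps[!is.na(steps)],
         cells = moore_neighbours(grid, fossils$cell_id[i],
                                  include_self = TRUE))
  })
}

#' Annual persistence penalty for refugium regions
#'
#' Per refugium, the number of years extirpation precedes `end_year_ce`
#' (zero if occupied through that year; if the set is never occupied, the
#' penalty runs from the start of the simulation), summed over refugia.
#'
#' @param sim A `sim_result`.
#' @param refugium_cells Named list of cell-id vectors.
#' @param end_year_ce Target persistence year (CE), default 1850.
#' @return Penalty in years (>= 0).
#' @export
persistence_penalty <- function(sim, refugium_cells, end_year_ce = 1850) {
  stopifnot(length(refugium_cells) > 0, all(lengths(refugium_cells) > 0))
  grid <- sim$grid
  total <- 0
  for (cells in refugium_cells) {
    occ <- rowSums(sim$abundance[, cells, drop = FALSE] > 0) > 0
    ce_last <- if (!any(occ)) bp_ce_convert(grid$t_start_bp)
      else bp_ce_convert(grid$step_times_bp[max(which(occ))])
    total <- total + max(0, end_year_ce - ce_last)
  }
  total
}

#' Refugia-count mismatch at a reference year
#'
#' Counts the spatially contiguous occupied patches (8-connectivity) at the
#' step containing `at_year_ce` and returns the absolute difference from the
#' expected count.
#'
#' @param sim A `sim_result`.
#' @param expected Expected number of refugial populations (default 2).
#' @param at_year_ce Reference year (CE), default 1850.
#' @return Nonnegative count difference.
#' @export
refugia_diff <- function(sim, expected = 2, at_year_ce = 1850) {
  grid <- sim$grid
  step <- step_for_bp(grid, bp_ce_convert(at_year_ce, "ce_to_bp"))
  if (is.na(step)) step <- grid$n_steps
  occ <- sim$abundance[step, ] > 0
  n_patches <- max(connected_components(occ, grid), 0L)
  abs(n_patches - expected)
}

#' Summary vector of one simulation against the validation targets
#'
#' @param sim A `sim_result`.
#' @param target A list with `fossils`, `refugium_cells`,
#'   `expected_refugia_count` and `persistence_end` (year CE).
#' @return Named vector: `occurrence_match`, `persistence_penalty`,
#'   `refugia_diff`.
#' @export
summarize_sim <- function(sim, target) {
  c(occurrence_match = occurrence_match(sim, target$fossils, sim$grid,
                                        index = target$match_index),
    persistence_penalty = persistence_penalty(sim, target$refugium_cells,
                                              target$persistence_end),
    refugia_diff = refugia_diff(sim, target$expected_refugia_count,
                                target$persistence_end))
}

# Perfect-match target corresponding to summarize_sim.
perfect_summary <- function() {
  c(occurrence_match = 1, persistence_penalty = 0, refugia_diff = 0)
}

#' Robust component scales for the ABC distance
#'
#' Across-simulation median absolute deviation per summary component, with
#' fallback to the standard deviation and then to 1 for degenerate
#' components.
#'
#' @param summaries Matrix of summary vectors (rows = simulations).
#' @return Positive scale per component.
#' @export
compute_scales <- function(summaries) {
  apply(as.matrix(summaries), 2, function(x) {
    s <- mad(x)
    if (!is.finite(s) || s <= 0) s <- sd(x)
    if (!is.finite(s) || s <= 0) s <- 1
    s
  })
}

#' Scaled Euclidean distance to the multivariate target
#'
#' @param summary,target Summary vectors.
#' @param scales Positive component scales.
#' @return Nonnegative distance; zero for a perfect match.
#' @export
abc_distance <- function(summary, target, scales) {
  stopifnot(all(scales > 0), length(summary) == length(target))
  sqrt(sum(((summary - target) / scales)^2))
}

#' ABC rejection
#'
#' Indices of the best `ceiling(n * tolerance_fraction)` simulations by
#' distance; ties are broken by lower index (stable).
#'
#' @param distances Distances of all simulations.
#' @param tolerance_fraction Accepted fraction (default 0.25%).
#' @return Accepted indices, best first.
#' @export
abc_reject <- function(distances, tolerance_fraction = 0.0025) {
  if (tolerance_fraction <= 0) stop("tolerance_fraction must be > 0")
  m <- ceiling(length(distances) * tolerance_fraction)
  order(distances)[seq_len(min(m, length(distances)))]
}

#' Refine uniform priors around accepted parametrizations
#'
#' New range per parameter: the accepted minimum-maximum expanded by
#' `expansion` about its midpoint, intersected with the original bounds.
#'
#' @param accepted Data frame of accepted parameter vectors (>= 2 rows).
#' @param original Original prior ranges (`param`, `lo`, `hi`).
#' @param expansion Range expansion factor (default 1.1).
#' @return Refined ranges in the same format.
#' @export
refine_priors <- function(accepted, original, expansion = 1.1) {
  stopifnot(nrow(accepted) >= 2)
  out <- original
  for (i in seq_len(nrow(original))) {
    p <- original$param[i]
    if (!p %in% names(accepted)) next
    v <- accepted[[p]]
    mid <- (min(v) + max(v)) / 2
    half <- (max(v) - min(v)) / 2 * expansion
    out$lo[i] <- max(original$lo[i], mid - half)
    out$hi[i] <- min(original$hi[i], mid + half)
  }
  out
}

#' Posterior convergence check between successive rounds
#'
#' Per-parameter histogram overlap coefficient between the accepted samples
#' of successive rounds (common equal-width bins over the pooled range);
#' converged when the minimum overlap of the final pair reaches the
#' threshold.
#'
#' @param samples_by_round List (length >= 2) of accepted-parameter data
#'   frames, one per round.
#' @param bins Number of histogram bins.
#' @param threshold Minimum-overlap convergence threshold (default 0.8).
#' @return List with `converged`, `statistic` (minimum overlap, final
#'   pair) and the per-parameter overlap matrix `by_pair`.
#' @export
convergence_check <- function(samples_by_round, bins = 20, threshold = 0.8) {
  stopifnot(length(samples_by_round) >= 2)
  params <- names(samples_by_round[[1]])
  n_pairs <- length(samples_by_round) - 1
  ov <- matrix(NA_real_, n_pairs, length(params),
               dimnames = list(NULL, params))
  for (r in seq_len(n_pairs)) {
    a <- samples_by_round[[r]]; b <- samples_by_round[[r + 1]]
    for (p in params) {
      x <- a[[p]]; y <- b[[p]]
      rng <- range(c(x, y))
      if (diff(rng) < 1e-12) { ov[r, p] <- 1; next }
      br <- seq(rng[1], rng[2], length.out = bins + 1)
      px <- tabulate(findInterval(x, br, rightmost.closed = TRUE,
                                  all.inside = TRUE), bins) / length(x)
      py <- tabulate(findInterval(y, br, rightmost.closed = TRUE,
                                  all.inside = TRUE), bins) / length(y)
      ov[r, p] <- sum(pmin(px, py))
    }
  }
  stat <- min(ov[n_pairs, ])
  list(converged = stat >= threshold, statistic = stat, by_pair = ov)
}

#' Goodness of fit of the target to the accepted summaries
#'
#' The null distribution is built from pseudo-observed summaries: repeatedly
#' draw one accepted summary and measure its scaled distance to the centroid
#' of the remainder; the p-value is the fraction of null distances at least
#' as large as the target's distance to the accepted centroid.
#'
#' @param accepted_summaries Matrix of accepted summary vectors (>= 2 rows).
#' @param target Target summary vector.
#' @param scales Optional component scales (default: computed from the
#'   accepted summaries).
#' @param n_reps Null draws (default 1000).
#' @param seed Integer seed.
#' @return p-value in `[0, 1]`.
#' @export
goodness_of_fit <- function(accepted_summaries, target, scales = NULL,
                            n_reps = 1000, seed = 1L) {
  S <- as.matrix(accepted_summaries)
  n <- nrow(S)
  stopifnot(n >= 2)
  if (is.null(scales)) scales <- compute_scales(S)
  observed <- abc_distance(colMeans(S), target, scales)
  null_d <- with_seed(seed, {
    idx <- sample.int(n, n_reps, replace = TRUE)
    vapply(idx, function(i)
      abc_distance(S[i, ], colMeans(S[-i, , drop = FALSE]), scales),
      numeric(1))
  })
  mean(null_d >= observed)
}

#' Inverse-distance weighted ensemble average
#'
#' Weights are proportional to the inverse Euclidean distance from the
#' validation target (zero distances are replaced by the smallest positive
#' distance times 1e-6) and normalized to sum to one.
#'
#' @param results List of `sim_result` objects.
#' @param distances Their distances to the target.
#' @return List with the weighted `abundance` map, `totals`, weighted
#'   occupancy fraction `occupancy` and the `weights`.
#' @export
ensemble_average <- function(results, distances) {
  if (length(results) == 0) stop("empty ensemble")
  stopifnot(length(results) == length(distances))
  d <- distances
  if (any(d == 0)) {
    posmin <- if (any(d > 0)) min(d[d > 0]) else 1
    d[d == 0] <- posmin * 1e-6
  }
  w <- (1 / d) / sum(1 / d)
  ab <- 0; occ <- 0; tot <- 0
  for (i in seq_along(results)) {
    ab <- ab + w[i] * results[[i]]$abundance
    occ <- occ + w[i] * (results[[i]]$abundance > 0)
    tot <- tot + w[i] * results[[i]]$totals
  }
  list(abundance = ab, totals = tot, occupancy = occ, weights = w)
}

#' Compare an ensemble trend with an external relative series
#'
#' Both series are normalized to their own maxima; reports the correlation
#' of their stepwise changes and whether the external series lies within the
#' ensemble min-max envelope at each overlapping step.
#'
#' @param totals_list List of per-step total-abundance series (ensemble
#'   members), on the time axis `times_bp`.
#' @param times_bp Time coordinate of the simulated series.
#' @param external Data frame with `time_bp` and `value`.
#' @return List with `correlation`, per-step `inside` flags and
#'   `inside_fraction`.
#' @export
compare_trend <- function(totals_list, times_bp, external) {
  keep <- external$time_bp <= max(times_bp) & external$time_bp >= min(times_bp)
  if (!any(keep)) stop("no temporal overlap between the series")
  ext <- external[keep, , drop = FALSE]
  norm1 <- function(v) if (max(v) > 0) v / max(v) else v
  members <- vapply(totals_list, function(tot)
    approx(times_bp, norm1(tot), xout = ext$time_bp, rule = 2)$y,
    numeric(nrow(ext)))
  members <- matrix(members, nrow = nrow(ext))
  env_lo <- apply(members, 1, min)
  env_hi <- apply(members, 1, max)
  ext_n <- norm1(ext$value)
  inside <- ext_n >= env_lo - 1e-12 & ext_n <= env_hi + 1e-12
  mean_sim <- rowMeans(members)
  # a flat series carries no trend signal: report zero correlation
  correlation <- if (nrow(ext) >= 3 && sd(diff(mean_sim)) > 0 && sd(diff(ext_n)) > 0)
    cor(diff(mean_sim), diff(ext_n)) else 0
  list(correlation = correlation, inside = inside,
       inside_fraction = mean(inside))
}

#' Run pattern-oriented calibration rounds
#'
#' Round 1 draws a Latin hypercube sample from the prior ranges; each later
#' round redraws from priors refined around the accepted parametrizations of
#' the previous round. Distances use across-simulation robust scales within
#' each round.
#'
#' @param eval_fun Function `(params_row, seed)` returning a summary vector
#'   (as from [summarize_sim()]).
#' @param ranges Prior ranges (`param`, `lo`, `hi`).
#' @param round_sizes Simulations per round, e.g. `c(25000, 10000, 10000,
#'   10000)` (full schedule) or `c(300, 200, 200)` (desk).
#' @param tolerance Accepted fraction per round.
#' @param seed Master seed.
#' @param target Target summary vector (default perfect match).
#' @return A `pom_result`: per-round params/summaries/distances/accepted
#'   indices and ranges, the final accepted table with normalized weights,
#'   and the convergence check.
#' @export
run_pom <- function(eval_fun, ranges, round_sizes = c(300, 200, 200),
                    tolerance = 0.1, seed = 1L,
                    target = perfect_summary()) {
  rounds <- list()
  current <- ranges
  accepted_by_round <- list()
  for (r in seq_along(round_sizes)) {
    n <- round_sizes[r]
    params <- sample_priors_lhs(current, n, derive_seed(seed, 1000 + r))
    summaries <- matrix(NA_real_, n, length(target),
                        dimnames = list(NULL, names(target)))
    for (i in seq_len(n))
      summaries[i, ] <- eval_fun(params[i, , drop = FALSE],
                                 derive_seed(seed, r * 100000 + i))
    scales <- compute_scales(summaries)
    distances <- apply(summaries, 1, abc_distance, target = target,
                       scales = scales)
    acc <- abc_reject(distances, tolerance)
    rounds[[r]] <- list(params = params, summaries = summaries,
                        distances = distances, accepted = acc,
                        ranges = current, scales = scales)
    accepted_by_round[[r]] <- params[acc, , drop = FALSE]
    if (r < length(round_sizes))
      current <- refine_priors(params[acc, , drop = FALSE], ranges)
  }
  final <- rounds[[length(rounds)]]
  d_acc <- final$distances[final$accepted]
  d_fix <- d_acc
  if (any(d_fix == 0)) {
    posmin <- if (any(d_fix > 0)) min(d_fix[d_fix > 0]) else 1
    d_fix[d_fix == 0] <- posmin * 1e-6
  }
  accepted_df <- final$params[final$accepted, , drop = FALSE]
  accepted_df$distance <- d_acc
  accepted_df$weight <- (1 / d_fix) / sum(1 / d_fix)
  conv <- if (length(round_sizes) >= 2)
    convergence_check(accepted_by_round) else NULL
  structure(list(rounds = rounds, accepted = accepted_df,
                 convergence = conv, target = target,
                 round_sizes = round_sizes, tolerance = tolerance,
                 seed = seed),
            class = "pom_result")
}
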