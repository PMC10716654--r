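# Known-truth parameter-recovery harness: builds a synthetic world (truth
# bundle + validation targets + fossil-fitted niche), evaluates candidate
# parametrizations through the full niche -> suitability -> simulation ->
# summary pathway, and runs repeated desk-scale calibration experiments.

#' Build a synthetic calibration world with known truth
#'
#' Generates a truth bundle and derives the validation targets from it (its
#' fossils, its refugial patches at the persistence year, and their count).
#' Candidate parametrizations subsample the same full (potential) niche the
#' truth was realized from, so the volume-fraction parameter means the same
#' thing in truth and candidates; a niche refit from the fossils alone
#' reflects the truth's already-truncated realized niche and biases the
#' recoverable volume fraction towards one. The fossil pathway (quality
#' filter, occurrence-environment intersection, hypervolume fit) is still
#' run and returned as `fossil_niche`. Regenerates with a derived seed if
#' the truth population is not extant at the end of the series.
#'
#' @param seed Master seed.
#' @param n_rows,n_cols,t_start_bp,t_end_bp Grid configuration (default a
#'   20 x 20 grid over a 300-generation span).
#' @param truth_params The known-truth `demographic_params`.
#' @param n_fossils Fossils sampled from the truth simulation.
#' @param max_tries Attempts before giving up.
#' @return A list with `bundle`, `target`, `full_fit` (niche), `priors` and
#'   the `grid`.
#' @export
pom_world <- function(seed, n_rows = 20, n_cols = 20, t_start_bp = 3090,
                      t_end_bp = 100, truth_params = demographic_params(),
                      n_fossils = 40, max_tries = 10) {
  grid <- make_grid(n_rows, n_cols, t_start_bp, t_end_bp)
  persist_step <- step_for_bp(grid, bp_ce_convert(1850, "ce_to_bp"))
  if (is.na(persist_step)) persist_step <- grid$n_steps
  for (try in seq_len(max_tries)) {
    bundle <- make_truth_bundle(truth_params, grid,
                                derive_seed(seed, 17 * try), n_fossils)
    occ_end <- bundle$sim$abundance[persist_step, ] > 0
    if (any(occ_end)) break
    if (try == max_tries)
      stop("could not generate a truth bundle extant at the persistence year")
  }
  labels <- connected_components(occ_end, grid)
  n_patches <- max(labels)
  patch_mass <- vapply(seq_len(n_patches), function(l)
    sum(bundle$sim$abundance[persist_step, labels == l]), numeric(1))
  keep <- order(patch_mass, decreasing = TRUE)[seq_len(min(2, n_patches))]
  refugia <- lapply(keep, function(l) which(labels == l))
  names(refugia) <- paste0("refugium_", seq_along(refugia))
  target <- list(fossils = bundle$fossils, refugium_cells = refugia,
                 expected_refugia_count = n_patches, persistence_end = 1850,
                 match_index = fossil_match_index(bundle$fossils, grid))
  recs <- filter_fossils(bundle$fossils)
  pts <- intersect_occurrences(recs, bundle$landscape$env, grid)
  fossil_niche <- if (nrow(pts) >= 10) fit_hypervolume(pts) else NULL
  full_fit <- bundle$full_niche
  env_std <- niche_standardize(full_fit,
                               matrix(bundle$landscape$env,
                                      grid$n_steps * grid$n_cells, 4))
  list(bundle = bundle, target = target, full_fit = full_fit,
       fossil_niche = fossil_niche, env_std = env_std,
       priors = default_prior_ranges(), grid = grid)
}

# Turn one row of the sampled hypercube into demographic_params.
params_from_row <- function(row) {
  do.call(demographic_params, as.list(row[, intersect(
    names(row), names(formals(demographic_params))), drop = FALSE]))
}

#' Evaluate one candidate parametrization in a calibration world
#'
#' Realizes the candidate niche from the fossil-fitted full hypervolume,
#' projects suitability, samples the candidate human surface, simulates,
#' and returns the summary vector against the world's targets.
#'
#' @param world A `pom_world`.
#' @param row One-row data frame of parameter values.
#' @param seed Integer seed for this candidate.
#' @param return_sim If `TRUE`, also return the `sim_result`.
#' @return Summary vector, or a list with `summary` and `sim`.
#' @export
evaluate_candidate <- function(world, row, seed, return_sim = FALSE) {
  p <- params_from_row(row)
  niche_i <- subsample_niche(world$full_fit, p$volume_fraction,
                             p$marginality, derive_seed(seed, 1))
  land <- world$bundle$landscape
  suit <- if (!is.null(world$env_std))
    project_suitability_std(niche_i, world$env_std, world$grid$n_steps,
                            world$grid$n_cells)
  else project_suitability(niche_i, land$env)
  suit[land$ice] <- 0
  land$suitability <- suit
  human_real <- sample_human_surface(world$bundle$human, p$omega,
                                     derive_seed(seed, 2))
  sim <- simulate_range(p, land, human_real, seed = derive_seed(seed, 3))
  s <- summarize_sim(sim, world$target)
  if (return_sim) list(summary = s, sim = sim) else s
}

#' Repeated parameter-recovery experiments
#'
#' For each repeat: build a fresh world with known truth, run the
#' desk-profile calibration rounds, and record whether the truth values of
#' the maximum harvest rate and the niche volume fraction fall inside the
#' accepted minimum-maximum range of the final round.
#'
#' @param n_repeats Number of independent experiments.
#' @param seed Master seed.
#' @param round_sizes,tolerance Calibration schedule (desk default: 300 then
#'   two refinement rounds of 200, best 10% accepted).
#' @param truth_params Known-truth parameters.
#' @param ... Passed to [pom_world()].
#' @return Data frame with one row per repeat: accepted ranges and coverage
#'   flags for `h_max` and `volume_fraction`.
#' @export
recovery_experiment <- function(n_repeats = 10, seed = 1L,
                                round_sizes = c(300, 200, 200),
                                tolerance = 0.1,
                                truth_params = demographic_params(), ...) {
  out <- vector("list", n_repeats)
  for (rep in seq_len(n_repeats)) {
    seed_r <- derive_seed(seed, 7000 + rep)
    world <- pom_world(seed_r, truth_params = truth_params, ...)
    pom <- run_pom(function(row, s) evaluate_candidate(world, row, s),
                   world$priors, round_sizes = round_sizes,
                   tolerance = tolerance, seed = seed_r)
    acc <- pom$accepted
    out[[rep]] <- data.frame(
      rep = rep,
      h_max_lo = min(acc$h_max), h_max_hi = max(acc$h_max),
      vf_lo = min(acc$volume_fraction), vf_hi = max(acc$volume_fraction),
      h_max_true = truth_params$h_max,
      vf_true = truth_params$volume_fraction,
      h_max_covered = truth_params$h_max >= min(acc$h_max) &
        truth_params$h_max <= max(acc$h_max),
      vf_covered = truth_params$volume_fraction >= min(acc$volume_fraction) &
        truth_params$volume_fraction <= max(acc$volume_fraction))
  }
  do.call(rbind, out)
}
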