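# Counterfactual scenarios (no hunting, no land-use change, no human
# pressures), the post-1500 CE harvest-escalation scan, extirpation-cause
# attribution, and agreement-masked ensemble occupancy maps.

#' Historical refugial population estimate for 1870 CE
#'
#' The historical validation constant for the harvest-escalation scan: the
#' two refugial population estimates in 1870 CE.
#'
#' @return Named vector (`caucasus`, `bialowieza`), animals.
#' @export
historical_bison_1870 <- function() {
  c(caucasus = 2000, bialowieza = 1560)
}

#' Specify a counterfactual or harvest-escalation scenario
#'
#' @param name One of `"baseline"`, `"no_hunting"`, `"no_landuse"`,
#'   `"no_human"`, `"harvest_scan"`.
#' @param harvest_multiplier_post1500 Escalation fraction m (post-1500 CE
#'   harvest rate becomes `(1 + m) * h_max`); scan scenarios only.
#' @param end_year_ce End of the scenario window (1500 for counterfactuals,
#'   1870 for the scan).
#' @return A `scenario_spec`.
#' @export
scenario_spec <- function(name = c("baseline", "no_hunting", "no_landuse",
                                   "no_human", "harvest_scan"),
                          harvest_multiplier_post1500 = NULL,
                          end_year_ce = if (identical(name[1], "harvest_scan")) 1870 else 1500) {
  name <- match.arg(name)
  if (name == "harvest_scan") {
    if (is.null(harvest_multiplier_post1500))
      stop("harvest_scan requires harvest_multiplier_post1500")
    if (harvest_multiplier_post1500 < 0)
      stop("harvest multiplier must be >= 0")
  }
  structure(list(name = name,
                 harvest_multiplier_post1500 = harvest_multiplier_post1500,
                 end_year_ce = end_year_ce),
            class = "scenario_spec")
}

#' Apply a scenario to the model inputs
#'
#' `no_hunting` sets the maximum harvest rate to zero; `no_landuse` restores
#' the unmodified biomass (including the niche's biomass axis) and lifts the
#' land-use dispersal friction (ice friction remains); `no_human` composes
#' both; `harvest_scan` escalates the harvest rate to `(1 + m) * h_max` from
#' the step containing 1500 CE. Counterfactual runs reuse the same seed so
#' baseline and scenario share random substreams.
#'
#' @param landscape A `landscape_series`.
#' @param human A `human_field` (returned unchanged; hunting is removed via
#'   the harvest rate).
#' @param params A `demographic_params`.
#' @param spec A `scenario_spec`.
#' @param niche Optional realized `niche_model`; when supplied and the
#'   scenario changes the biomass axis, suitability is re-projected.
#' @return List with modified `landscape`, `human`, `params` and, for the
#'   scan, a per-step `h_max_series`.
#' @export
apply_scenario <- function(landscape, human, params, spec, niche = NULL) {
  stopifnot(inherits(spec, "scenario_spec"))
  h_max_series <- NULL
  if (spec$name %in% c("no_hunting", "no_human"))
    params$h_max <- 0
  if (spec$name %in% c("no_landuse", "no_human")) {
    S <- landscape$grid$n_steps
    landscape$biomass_adjusted <-
      matrix(rep(landscape$biomass_raw, each = S), S, landscape$grid$n_cells)
    landscape$env[, , "biomass_adjusted"] <- landscape$biomass_adjusted
    landscape$friction_landuse[] <- 1
    landscape$friction <- landscape$friction_landuse
    landscape$friction[landscape$ice] <- 0
    if (!is.null(niche)) {
      suit <- project_suitability(niche, landscape$env)
      suit[landscape$ice] <- 0
      landscape$suitability <- suit
    }
  }
  if (spec$name == "harvest_scan") {
    grid <- landscape$grid
    step1500 <- step_for_bp(grid, bp_ce_convert(1500, "ce_to_bp"))
    if (is.na(step1500)) step1500 <- grid$n_steps
    h_max_series <- rep(params$h_max, grid$n_steps)
    h_max_series[step1500:grid$n_steps] <-
      params$h_max * (1 + spec$harvest_multiplier_post1500)
  }
  list(landscape = landscape, human = human, params = params,
       h_max_series = h_max_series)
}

#' Harvest-escalation scan over the posterior ensemble
#'
#' For each escalation multiplier and each posterior model, reruns the
#' simulation with the post-1500 CE harvest rate escalated to
#' `(1 + m) * h_max` under the model's own seed (common random numbers, so
#' the pre-1500 trajectory is identical to baseline) and reports the total
#' population at the step containing `end_year_ce` (or the final step if
#' outside the series).
#'
#' @param posterior Data frame of accepted parameter vectors; a `seed`
#'   column is used when present, otherwise seeds derive from `seed`.
#' @param world A `pom_world` (supplies landscape, human field, niche fit).
#' @param multipliers Escalation fractions (default 0.1 to 1 by 0.1).
#' @param end_year_ce Evaluation year (default 1870).
#' @param seed Master seed.
#' @return Data frame (`multiplier`, `model`, `final_total`) with attribute
#'   `historical_estimate_1870` (3560 = 2000 + 1560).
#' @export
harvest_scan <- function(posterior, world, multipliers = seq(0.1, 1, by = 0.1),
                         end_year_ce = 1870, seed = 1L) {
  if (nrow(posterior) == 0) stop("empty posterior")
  grid <- world$grid
  eval_step <- step_for_bp(grid, bp_ce_convert(end_year_ce, "ce_to_bp"))
  if (is.na(eval_step)) eval_step <- grid$n_steps
  rows <- list()
  for (i in seq_len(nrow(posterior))) {
    seed_i <- if ("seed" %in% names(posterior)) posterior$seed[i]
      else derive_seed(seed, 300 + i)
    p <- params_from_row(posterior[i, , drop = FALSE])
    niche_i <- subsample_niche(world$full_fit, p$volume_fraction,
                               p$marginality, derive_seed(seed_i, 1))
    land <- world$bundle$landscape
    suit <- project_suitability(niche_i, land$env)
    suit[land$ice] <- 0
    land$suitability <- suit
    human_real <- sample_human_surface(world$bundle$human, p$omega,
                                       derive_seed(seed_i, 2))
    for (m in multipliers) {
      sc <- apply_scenario(land, world$bundle$human, p,
                           scenario_spec("harvest_scan",
                                         harvest_multiplier_post1500 = m,
                                         end_year_ce = end_year_ce))
      sim <- simulate_range(p, land, human_real,
                            seed = derive_seed(seed_i, 3),
                            h_max_series = sc$h_max_series)
      rows[[length(rows) + 1]] <- data.frame(multiplier = m, model = i,
                                             final_total = sim$totals[eval_step])
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "historical_estimate_1870") <- sum(historical_bison_1870())
  out
}

# Ensemble occupancy fraction at a step: share of members with abundance > 0.
occupancy_fraction <- function(results, step) {
  Reduce(`+`, lapply(results, function(r) (r$abundance[step, ] > 0) / length(results)))
}

#' Attribute causes of local extirpation from counterfactual ensembles
#'
#' For each cell extirpated in the baseline by the reference year (ever
#' occupied, but below the occupancy-agreement threshold at the reference
#' step): labelled `"hunting"` if occupied under the no-hunting
#' counterfactual, else `"land_use"` if occupied under no-land-use, else
#' `"human_combined"` if occupied only under the combined removal, else
#' `"climate"`. Occupancy means ensemble agreement at or above `agreement`.
#'
#' @param baseline List of baseline `sim_result`s.
#' @param counterfactuals Named list (`no_hunting`, `no_landuse`,
#'   `no_human`) of `sim_result` lists.
#' @param grid A `grid_spec`.
#' @param at_year_ce Reference year (default 1500).
#' @param agreement Occupancy-agreement threshold (default 0.25).
#' @return Character vector per cell: a cause label for baseline-extirpated
#'   cells, `NA` elsewhere.
#' @export
attribute_extirpation <- function(baseline, counterfactuals, grid,
                                  at_year_ce = 1500, agreement = 0.25) {
  need <- c("no_hunting", "no_landuse", "no_human")
  stopifnot(all(need %in% names(counterfactuals)))
  all_res <- c(baseline, unlist(counterfactuals, recursive = FALSE))
  for (r in all_res)
    if (!all(dim(r$abundance) == c(grid$n_steps, grid$n_cells)))
      stop("grid mismatch between ensembles")
  step <- step_for_bp(grid, bp_ce_convert(at_year_ce, "ce_to_bp"))
  if (is.na(step)) step <- grid$n_steps
  occ_at <- function(results) occupancy_fraction(results, step) >= agreement
  ever <- Reduce(`|`, lapply(baseline, function(r) colSums(r$abundance > 0) > 0))
  base_occ <- occ_at(baseline)
  lost <- ever & !base_occ
  occ_nh <- occ_at(counterfactuals$no_hunting)
  occ_nl <- occ_at(counterfactuals$no_landuse)
  occ_nu <- occ_at(counterfactuals$no_human)
  label <- rep(NA_character_, grid$n_cells)
  label[lost] <- "climate"
  label[lost & occ_nu] <- "human_combined"
  label[lost & occ_nl] <- "land_use"
  label[lost & occ_nh] <- "hunting"
  label
}

#' Agreement-masked ensemble abundance map
#'
#' Cells are shown only where the fraction of models simulating occupancy
#' reaches the agreement threshold; shown values are the inverse-distance
#' weighted ensemble abundance, with a very-low-abundance flag below 50
#' animals.
#'
#' @param results List of `sim_result`s.
#' @param distances Their target distances (for the ensemble weights).
#' @param step Step index of the map (default: final step).
#' @param agreement Agreement threshold in (0, 1] (default 0.25).
#' @param low_threshold Very-low-abundance flag threshold (default 50).
#' @return List with `abundance` (NA where masked), `shown`, `low_flag` and
#'   the `agreement` fractions.
#' @export
occupancy_agreement <- function(results, distances, step = NULL,
                                agreement = 0.25, low_threshold = 50) {
  if (agreement <= 0 || agreement > 1) stop("agreement must be in (0, 1]")
  if (is.null(step)) step <- nrow(results[[1]]$abundance)
  frac <- occupancy_fraction(results, step)
  ens <- ensemble_average(results, distances)
  shown <- frac >= agreement
  ab <- ens$abundance[step, ]
  ab[!shown] <- NA_real_
  list(abundance = ab, shown = shown,
       low_flag = shown & !is.na(ab) & ab < low_threshold,
       agreement = frac)
}
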