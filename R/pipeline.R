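# End-to-end orchestration over a synthetic calibration world: niche fit,
# human surfaces, calibration rounds, ensemble, counterfactual scenarios,
# harvest scan and driver binning, with a YAML manifest of seeds and output
# hashes.

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[stage %s] %s", stage, conditionMessage(e)), call. = FALSE))
}

#' Run the full analysis pipeline on a synthetic world
#'
#' Stages, in order: synthetic world and truth bundle; niche fit from the
#' quality-filtered fossils; calibration rounds (Latin hypercube priors, ABC
#' rejection, prior refinement); posterior rerun and inverse-distance
#' ensemble; counterfactual scenarios and extirpation attribution; harvest
#' scan; centennial driver binning. Artifacts are written as CSV/JSON/YAML
#' under `out_dir`, together with a manifest recording the configuration,
#' seeds and MD5 hashes of every output. Deterministic stages are bit-stable
#' when rerun with the same configuration.
#'
#' @param config Configuration list (see [default_run_config()]).
#' @param out_dir Output directory.
#' @param n_scenario_models Posterior models rerun under each counterfactual
#'   (default 5; they are the best-ranked accepted models).
#' @return The output directory, invisibly.
#' @export
run_pipeline <- function(config = default_run_config("desk"), out_dir,
                         n_scenario_models = 5) {
  config <- validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed)

  world <- run_stage("synthetic_world", {
    pom_world(seed, n_rows = config$n_rows, n_cols = config$n_cols,
              t_start_bp = config$t_start_bp, t_end_bp = config$t_end_bp,
              n_fossils = config$n_fossils)
  })
  run_stage("serialize_world", {
    write_landscape(world$bundle$landscape, file.path(out_dir, "landscape"))
    write_fossils(world$bundle$fossils, file.path(out_dir, "fossils.csv"),
                  world$grid)
  })

  pom <- run_stage("calibration", {
    run_pom(function(row, s) evaluate_candidate(world, row, s),
            config$priors, round_sizes = config$round_sizes,
            tolerance = config$tolerance, seed = seed)
  })
  run_stage("posterior_tables", {
    write.csv(pom$accepted, file.path(out_dir, "accepted_parameters.csv"),
              row.names = FALSE)
    final <- pom$rounds[[length(pom$rounds)]]
    write.csv(data.frame(distance = final$distances, final$summaries),
              file.path(out_dir, "distances.csv"), row.names = FALSE)
  })

  # rerun the accepted models to rebuild their trajectories
  final_round <- length(pom$round_sizes)
  acc_idx <- pom$rounds[[final_round]]$accepted
  acc_seeds <- vapply(acc_idx, function(i)
    derive_seed(seed, final_round * 100000 + i), integer(1))
  posterior <- run_stage("posterior_rerun", {
    lapply(seq_along(acc_idx), function(j)
      evaluate_candidate(world,
                         pom$rounds[[final_round]]$params[acc_idx[j], , drop = FALSE],
                         acc_seeds[j], return_sim = TRUE)$sim)
  })
  ens <- run_stage("ensemble", {
    e <- ensemble_average(posterior, pom$accepted$distance)
    write_series_csv(e$abundance, world$grid$step_times_bp,
                     file.path(out_dir, "ensemble_abundance.csv"))
    write.csv(data.frame(time_bp = world$grid$step_times_bp,
                         total = e$totals),
              file.path(out_dir, "ensemble_totals.csv"), row.names = FALSE)
    e
  })

  scen_results <- run_stage("scenarios", {
    n_use <- min(n_scenario_models, length(posterior))
    res <- list(baseline = posterior[seq_len(n_use)])
    for (sc in config$scenarios) {
      res[[sc]] <- lapply(seq_len(n_use), function(j) {
        row <- pom$rounds[[final_round]]$params[acc_idx[j], , drop = FALSE]
        p <- params_from_row(row)
        niche_j <- subsample_niche(world$full_fit, p$volume_fraction,
                                   p$marginality, derive_seed(acc_seeds[j], 1))
        mod <- apply_scenario(world$bundle$landscape, world$bundle$human, p,
                              scenario_spec(sc), niche = niche_j)
        land <- mod$landscape
        suit <- project_suitability(niche_j, land$env)
        suit[land$ice] <- 0
        land$suitability <- suit
        human_real <- sample_human_surface(world$bundle$human, p$omega,
                                           derive_seed(acc_seeds[j], 2))
        simulate_range(mod$params, land, human_real,
                       seed = derive_seed(acc_seeds[j], 3))
      })
    }
    res
  })
  run_stage("attribution", {
    if (all(c("no_hunting", "no_landuse", "no_human") %in% names(scen_results))) {
      lab <- attribute_extirpation(scen_results$baseline,
                                   scen_results[c("no_hunting", "no_landuse",
                                                  "no_human")],
                                   world$grid)
      write.csv(data.frame(cell_id = seq_along(lab), cause = lab),
                file.path(out_dir, "extirpation_causes.csv"),
                row.names = FALSE)
    }
  })
  scan <- run_stage("harvest_scan", {
    post_df <- pom$accepted[seq_len(min(n_scenario_models, nrow(pom$accepted))), ,
                            drop = FALSE]
    post_df$seed <- acc_seeds[seq_len(nrow(post_df))]
    s <- harvest_scan(post_df, world, multipliers = config$scan_multipliers,
                      seed = seed)
    write.csv(s, file.path(out_dir, "harvest_scan.csv"), row.names = FALSE)
    s
  })
  binned <- run_stage("drivers", {
    b <- bin_drivers(posterior, world$bundle$landscape,
                     world$bundle$human$mean)
    write.csv(b, file.path(out_dir, "binned_drivers.csv"), row.names = FALSE)
    b
  })

  run_stage("manifest", {
    files <- setdiff(list.files(out_dir, recursive = TRUE),
                     "manifest.yaml")
    hashes <- as.list(tools::md5sum(file.path(out_dir, files)))
    names(hashes) <- files
    manifest <- list(
      package_version = as.character(utils::packageVersion("paleorange")),
      seed = seed, profile = config$profile,
      round_sizes = config$round_sizes, tolerance = config$tolerance,
      grid = list(n_rows = config$n_rows, n_cols = config$n_cols,
                  t_start_bp = config$t_start_bp, t_end_bp = config$t_end_bp),
      convergence = list(converged = isTRUE(pom$convergence$converged),
                         statistic = pom$convergence$statistic),
      outputs = hashes)
    yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  })
  invisible(out_dir)
}
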