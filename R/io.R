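# Plain-text serialization: gridded step x cell series as wide CSV (one row
# per generational step, first column the time in years BP), fossils as CSV,
# configurations and manifests as YAML.

write_series_csv <- function(mat, times_bp, path) {
  df <- data.frame(time_bp = times_bp, mat, check.names = FALSE)
  names(df) <- c("time_bp", paste0("cell_", seq_len(ncol(mat))))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

read_series_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  dimnames(m) <- NULL
  m
}

#' Write a landscape series to a directory of CSV/YAML files
#'
#' @param landscape A `landscape_series`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_landscape <- function(landscape, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  g <- landscape$grid
  times <- g$step_times_bp
  write_series_csv(landscape$suitability, times, file.path(dir, "suitability.csv"))
  write_series_csv(landscape$biomass_adjusted, times, file.path(dir, "biomass_adjusted.csv"))
  write_series_csv(landscape$ice * 1, times, file.path(dir, "ice.csv"))
  write_series_csv(landscape$friction, times, file.path(dir, "friction.csv"))
  for (a in dimnames(landscape$env)[[3]])
    write_series_csv(landscape$env[, , a], times,
                     file.path(dir, paste0("env_", a, ".csv")))
  yaml::write_yaml(list(n_rows = g$n_rows, n_cols = g$n_cols,
                        t_start_bp = g$t_start_bp, t_end_bp = g$t_end_bp,
                        step_years = g$step_years,
                        cell_width_km = g$cell_width_km,
                        cell_height_km = g$cell_height_km,
                        biomass_raw = as.numeric(landscape$biomass_raw)),
                   file.path(dir, "grid.yaml"))
  invisible(dir)
}

#' Read a landscape series written by [write_landscape()]
#'
#' @param dir Directory containing the CSV/YAML files.
#' @return A `landscape_series`.
#' @export
read_landscape <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "grid.yaml"))
  grid <- make_grid(meta$n_rows, meta$n_cols, meta$t_start_bp, meta$t_end_bp,
                    meta$step_years, meta$cell_width_km, meta$cell_height_km)
  axes <- c("precip", "winter_temp", "evapotranspiration", "biomass_adjusted")
  env <- array(NA_real_, c(grid$n_steps, grid$n_cells, length(axes)),
               dimnames = list(NULL, NULL, axes))
  for (a in axes)
    env[, , a] <- read_series_csv(file.path(dir, paste0("env_", a, ".csv")))
  ice <- read_series_csv(file.path(dir, "ice.csv")) > 0
  friction <- read_series_csv(file.path(dir, "friction.csv"))
  fl <- friction
  fl[ice] <- 1
  structure(list(grid = grid,
                 suitability = read_series_csv(file.path(dir, "suitability.csv")),
                 biomass_raw = as.numeric(meta$biomass_raw),
                 biomass_adjusted = read_series_csv(file.path(dir, "biomass_adjusted.csv")),
                 ice = ice, friction = friction, friction_landuse = fl,
                 env = env),
            class = "landscape_series")
}

#' Write fossil records to CSV
#'
#' Columns: `cell_id, lon, lat, age_bp, age_sd, quality, kind`; `lon`/`lat`
#' are projected cell-centre coordinates in km (eastings/northings of the
#' synthetic equal-area grid).
#'
#' @param records Fossil data frame.
#' @param path Output file.
#' @param grid A `grid_spec` (for cell-centre coordinates).
#' @return The path, invisibly.
#' @export
write_fossils <- function(records, path, grid) {
  rc <- cell_rowcol(grid, records$cell_id)
  df <- data.frame(cell_id = records$cell_id,
                   lon = (rc[, "col"] - 0.5) * grid$cell_width_km,
                   lat = (grid$n_rows - rc[, "row"] + 0.5) * grid$cell_height_km,
                   age_bp = records$age_bp, age_sd = records$age_sd,
                   quality = records$quality, kind = records$kind)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read fossil records from CSV
#'
#' @param path CSV written by [write_fossils()] (or hand-built with the same
#'   header).
#' @return Fossil data frame.
#' @export
read_fossils <- function(path) {
  df <- read.csv(path)
  df[, c("cell_id", "age_bp", "age_sd", "quality", "kind")]
}

#' Default run configuration
#'
#' The `"full"` profile reproduces the study schedule (25 000 simulations,
#' then three refinement rounds of 10 000, best 0.25% accepted) on the full
#' Eurasian grid span; the `"desk"` profile is a 20 x 20 grid over 300
#' generations with rounds of 300 + 2 x 200 and 10% acceptance, sized for a
#' single workstation CPU.
#'
#' @param profile `"desk"` or `"full"`.
#' @return A named configuration list.
#' @export
default_run_config <- function(profile = c("desk", "full")) {
  profile <- match.arg(profile)
  base <- list(profile = profile, seed = 1L,
               priors = default_prior_ranges(),
               scenarios = c("no_hunting", "no_landuse", "no_human"),
               scan_multipliers = seq(0.1, 1, by = 0.1),
               n_fossils = 40)
  if (profile == "full") {
    c(base, list(n_rows = 80, n_cols = 140, t_start_bp = 21000,
                 t_end_bp = 100, round_sizes = c(25000, 10000, 10000, 10000),
                 tolerance = 0.0025))
  } else {
    c(base, list(n_rows = 20, n_cols = 20, t_start_bp = 3090, t_end_bp = 100,
                 round_sizes = c(300, 200, 200), tolerance = 0.1))
  }
}

#' Read and validate a run configuration from YAML
#'
#' @param path YAML file; missing fields take the desk-profile defaults.
#' @return A validated configuration list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("[stage config] missing input path: %s", path))
  user <- yaml::read_yaml(path)
  cfg <- default_run_config(if (!is.null(user$profile)) user$profile else "desk")
  for (nm in setdiff(names(user), "priors")) cfg[[nm]] <- user[[nm]]
  if (!is.null(user$priors)) {
    pr <- as.data.frame(user$priors)
    stopifnot(all(c("param", "lo", "hi") %in% names(pr)))
    cfg$priors <- pr
  }
  validate_config(cfg)
}

validate_config <- function(cfg) {
  if (any(cfg$priors$lo > cfg$priors$hi))
    stop("[stage config] prior ranges must satisfy lo <= hi")
  stopifnot(all(cfg$round_sizes >= 1), cfg$tolerance > 0)
  cfg
}
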