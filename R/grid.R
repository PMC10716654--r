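#' Define the simulation grid and generational time axis
#'
#' A grid specification couples an equal-area lattice of cells (dimensions in
#' km) with a generational time axis in years before present (BP, relative to
#' 1950 CE). The defaults mirror an Albers equal-area discretization of
#' Eurasia at 86.6 x 75.6 km and a 10-year generation, spanning 21 ka BP to
#' 100 BP.
#'
#' @param n_rows,n_cols Number of grid rows (northernmost row first) and
#'   columns.
#' @param t_start_bp,t_end_bp First and last simulated time, years BP.
#' @param step_years Generation length in years; the span must be a positive
#'   multiple of it.
#' @param cell_width_km,cell_height_km Cell dimensions in km.
#' @return An object of class `grid_spec` with `n_steps`, `n_cells`,
#'   `step_times_bp` (descending BP times) and `cell_area_km2`.
#' @examples
#' g <- make_grid(5, 5)
#' g$n_steps # 2091 generational steps from 21 ka BP to 100 BP
#' @export
make_grid <- function(n_rows, n_cols, t_start_bp = 21000, t_end_bp = 100,
                      step_years = 10, cell_width_km = 86.6,
                      cell_height_km = 75.6) {
  stopifnot(n_rows >= 1, n_cols >= 1, cell_width_km > 0, cell_height_km > 0,
            step_years > 0)
  span <- t_start_bp - t_end_bp
  if (span <= 0 || abs(span / step_years - round(span / step_years)) > 1e-9)
    stop("time span (t_start_bp - t_end_bp) must be a positive multiple of step_years")
  n_steps <- as.integer(round(span / step_years)) + 1L
  g <- list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
            n_cells = as.integer(n_rows) * as.integer(n_cols),
            cell_width_km = cell_width_km, cell_height_km = cell_height_km,
            cell_area_km2 = cell_width_km * cell_height_km,
            t_start_bp = t_start_bp, t_end_bp = t_end_bp,
            step_years = step_years, n_steps = n_steps,
            step_times_bp = seq(t_start_bp, t_end_bp, by = -step_years))
  class(g) <- "grid_spec"
  g
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d x %d cells (%.1f x %.1f km), %d steps of %g y (%g-%g BP)\n",
              x$n_rows, x$n_cols, x$cell_width_km, x$cell_height_km,
              x$n_steps, x$step_years, x$t_start_bp, x$t_end_bp))
  invisible(x)
}

#' Convert between years BP and calendar years CE
#'
#' Years before present are counted from 1950 CE, so `CE = 1950 - BP` in both
#' directions (450 BP is 1500 CE).
#'
#' @param year Numeric year(s).
#' @param direction `"bp_to_ce"` or `"ce_to_bp"`.
#' @return Converted year(s).
#' @export
bp_ce_convert <- function(year, direction = c("bp_to_ce", "ce_to_bp")) {
  direction <- match.arg(direction)
  1950 - year
}

# Cell id <-> (row, col); cells are numbered row-major, row 1 at the top
# (poleward) edge.
cell_id <- function(grid, row, col) (row - 1L) * grid$n_cols + col

cell_rowcol <- function(grid, cell) {
  cell <- as.integer(cell)
  row <- (cell - 1L) %/% grid$n_cols + 1L
  col <- (cell - 1L) %% grid$n_cols + 1L
  cbind(row = row, col = col)
}

# Index of the generational step whose time is nearest to `bp`; NA outside
# the simulated span (with half-step slack at the edges).
step_for_bp <- function(grid, bp) {
  i <- round((grid$t_start_bp - bp) / grid$step_years) + 1
  i[i < 1 | i > grid$n_steps] <- NA_integer_
  as.integer(i)
}

# All step indices whose BP time lies in [lo_bp, hi_bp] (inclusive).
steps_in_window <- function(grid, lo_bp, hi_bp) {
  which(grid$step_times_bp >= lo_bp - 1e-9 & grid$step_times_bp <= hi_bp + 1e-9)
}

#' Derive a reproducible substream seed from a master seed
#'
#' Modules draw their randomness from substreams derived from one master seed
#' by sequence number, so individual stages can be re-run independently and
#' deterministically.
#'
#' @param seed Master seed (integer).
#' @param k Substream sequence number.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, k) {
  s <- (abs(as.double(seed)) %% 2147483647) * 69069 + as.double(k) * 1234567
  as.integer(s %% 2147483629) + 1L
}

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG
# state afterwards.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  code
}
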