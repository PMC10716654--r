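# Multi-temporal ecological niche model: fossil filtering, occurrence -
# environment intersection, a product-Gaussian kernel-density hypervolume
# with cross-validated bandwidths, niche subsampling by volume fraction and
# marginality, and projection of habitat suitability through time.

#' Filter fossil records by age quality score
#'
#' Only records with a quality score strictly greater than `min_quality`
#' are retained (a score of exactly 10 is excluded under the default).
#'
#' @param records Fossil data frame with a `quality` column.
#' @param min_quality Strict lower bound (default 10).
#' @return The filtered records, original order preserved.
#' @export
filter_fossils <- function(records, min_quality = 10) {
  stopifnot(is.data.frame(records), "quality" %in% names(records))
  records[records$quality > min_quality, , drop = FALSE]
}

#' Average sub-generational layers onto the generational time axis
#'
#' Each output step is the mean of all input layers whose time falls within
#' a centred window (default 30 years) around the step; at the edges the
#' window is truncated to the available layers. If no layer falls in a
#' window, the nearest layer is used.
#'
#' @param values Matrix (input time x cell) of layer values.
#' @param times_in Input time coordinate, years BP.
#' @param times_out Output (generational) time coordinate, years BP.
#' @param window_years Width of the centred averaging window.
#' @return Matrix (output time x cell).
#' @export
generational_means <- function(values, times_in, times_out, window_years = 30) {
  values <- as.matrix(values)
  if (nrow(values) == 0) stop("empty input series")
  stopifnot(nrow(values) == length(times_in))
  half <- window_years / 2
  out <- matrix(NA_real_, length(times_out), ncol(values))
  for (i in seq_along(times_out)) {
    idx <- which(abs(times_in - times_out[i]) <= half + 1e-9)
    if (length(idx) == 0) idx <- which.min(abs(times_in - times_out[i]))
    out[i, ] <- colMeans(values[idx, , drop = FALSE])
  }
  out
}

#' Intersect fossil occurrences with environmental layers
#'
#' For each record, one environmental point is taken at its cell for every
#' generational step within plus or minus two standard deviations of its
#' calibrated age (historical sightings, with `age_sd = 0`, use only the
#' deposition step). Duplicate (cell, step) bins arising from overlapping
#' records are collapsed to a single point; records falling outside the grid
#' or time span are skipped and counted.
#'
#' @param records Filtered fossil data frame (`cell_id`, `age_bp`, `age_sd`).
#' @param env Step x cell x axis array of environmental values.
#' @param grid A `grid_spec`.
#' @return A matrix of environmental points (one row per retained bin) with
#'   attributes `bins` (data frame of step and cell) and `n_skipped`.
#' @export
intersect_occurrences <- function(records, env, grid) {
  stopifnot(length(dim(env)) == 3, dim(env)[1] == grid$n_steps,
            dim(env)[2] == grid$n_cells)
  pairs <- matrix(integer(), 0, 2)
  skipped <- 0L
  for (i in seq_len(nrow(records))) {
    cell <- records$cell_id[i]
    if (is.na(cell) || cell < 1 || cell > grid$n_cells) { skipped <- skipped + 1L; next }
    sdv <- records$age_sd[i]
    steps <- if (sdv > 0)
      steps_in_window(grid, records$age_bp[i] - 2 * sdv, records$age_bp[i] + 2 * sdv)
    else step_for_bp(grid, records$age_bp[i])
    steps <- steps[!is.na(steps)]
    if (length(steps) == 0) { skipped <- skipped + 1L; next }
    pairs <- rbind(pairs, cbind(steps, rep(as.integer(cell), length(steps))))
  }
  if (nrow(pairs) > 0) pairs <- unique(pairs)
  pts <- matrix(NA_real_, nrow(pairs), dim(env)[3],
                dimnames = list(NULL, dimnames(env)[[3]]))
  for (a in seq_len(dim(env)[3]))
    pts[, a] <- env[cbind(pairs[, 1], pairs[, 2], a)]
  attr(pts, "bins") <- data.frame(step = pairs[, 1], cell = pairs[, 2])
  attr(pts, "n_skipped") <- skipped
  if (skipped > 0)
    message(sprintf("intersect_occurrences: skipped %d record(s) outside the grid/time span", skipped))
  pts
}

# Silverman's rule-of-thumb bandwidth for a d-dimensional product-Gaussian
# KDE, per axis (on the scale of the data).
silverman_bw <- function(points) {
  n <- nrow(points); d <- ncol(points)
  apply(points, 2, sd) * (4 / (d + 2))^(1 / (d + 4)) * n^(-1 / (d + 4))
}

#' Fit a Gaussian hypervolume niche model
#'
#' Product-Gaussian kernel density over standardized environmental points.
#' A single bandwidth multiplier (shared across axes, on the standardized
#' scale) is chosen by K-fold least-squares cross-validation: the score is
#' the closed-form integral of the squared density minus twice the mean
#' held-out density, the CV estimate of density mean squared error up to a
#' constant. Fold assignment is deterministic (interleaved by index).
#'
#' @param points Matrix of environmental points (rows) by axes (columns);
#'   at least 10 rows, no zero-variance axis.
#' @param k_folds Number of CV folds.
#' @param bw_grid Log-spaced grid of candidate bandwidths, in units of the
#'   per-axis standard deviation.
#' @param mass_samples Monte Carlo sample size used to tabulate the density
#'   mass profile (for volume-fraction thresholds).
#' @return A `niche_model` with `volume_fraction = 1`, `marginality = 0`,
#'   zero density threshold and zero centroid shift.
#' @export
fit_hypervolume <- function(points, k_folds = 5,
                            bw_grid = exp(seq(log(0.1), log(2), length.out = 15)),
                            mass_samples = 32768) {
  points <- as.matrix(points)
  n <- nrow(points); d <- ncol(points)
  if (n < 10) stop("at least 10 environmental points are required")
  scl <- apply(points, 2, sd)
  if (any(scl <= 0)) {
    ax <- colnames(points)[which(scl <= 0)[1]]
    if (is.null(ax)) ax <- paste0("axis ", which(scl <= 0)[1])
    stop(sprintf("degenerate axis with zero variance: %s", ax))
  }
  ctr <- colMeans(points)
  pts_std <- sweep(sweep(points, 2, ctr), 2, scl, "/")
  fold <- (seq_len(n) - 1L) %% k_folds + 1L
  score <- vapply(bw_grid, function(h) {
    hv <- rep(h, d)
    s <- 0
    for (f in seq_len(k_folds)) {
      train <- pts_std[fold != f, , drop = FALSE]
      test <- pts_std[fold == f, , drop = FALSE]
      if (nrow(train) == 0 || nrow(test) == 0) next
      s <- s + .kde_l2_cpp(train, hv) - 2 * mean(.kde_eval_cpp(test, train, hv))
    }
    s
  }, numeric(1))
  h_opt <- bw_grid[which.min(score)]
  bandwidth <- rep(h_opt, d)
  # density mass profile: f evaluated at a fixed-seed sample from f itself
  density_ref <- with_seed(20260923L, {
    idx <- sample.int(n, mass_samples, replace = TRUE)
    X <- pts_std[idx, , drop = FALSE] +
      matrix(rnorm(mass_samples * d), mass_samples, d) %*% diag(bandwidth, d)
    sort(.kde_eval_cpp(X, pts_std, bandwidth))
  })
  structure(list(center = ctr, scale = scl, points = points,
                 points_std = pts_std, bandwidth = bandwidth,
                 bw_multiplier = h_opt,
                 cv = data.frame(bandwidth = bw_grid, score = score),
                 silverman = silverman_bw(pts_std),
                 volume_fraction = 1, marginality = 0, threshold = 0,
                 shift = rep(0, d), density_ref = density_ref,
                 axes = colnames(points)),
            class = "niche_model")
}

#' @export
print.niche_model <- function(x, ...) {
  cat(sprintf("niche_model: %d points, %d axes, bandwidth %.3f sd, volume %.2f, marginality %.2f\n",
              nrow(x$points), length(x$bandwidth), x$bw_multiplier,
              x$volume_fraction, x$marginality))
  invisible(x)
}

#' Subsample a realized niche from the full hypervolume
#'
#' The realized niche truncates the full kernel density at the threshold
#' enclosing `volume_fraction` of its density mass and displaces the niche
#' centroid by `marginality` (in per-axis standard-deviation units) along a
#' seeded random unit direction. The direction is drawn from the training
#' cloud itself (towards a randomly chosen training point), so the displaced
#' niche stays within the manifold of conditions that actually occur;
#' gridded environments typically occupy a low-dimensional sheet of the
#' full environmental space, and an isotropic random direction would almost
#' surely leave it. `volume_fraction = 1` with zero marginality reproduces
#' the full niche exactly.
#'
#' @param full A full `niche_model`.
#' @param volume_fraction Fraction of density mass retained, in (0, 1].
#' @param marginality Centroid displacement in standardized units (>= 0).
#' @param seed Integer seed for the displacement direction.
#' @return A realized `niche_model`.
#' @export
subsample_niche <- function(full, volume_fraction, marginality, seed = 1L) {
  stopifnot(inherits(full, "niche_model"))
  if (volume_fraction <= 0 || volume_fraction > 1)
    stop("volume_fraction must be in (0, 1]")
  if (marginality < 0) stop("marginality must be >= 0")
  d <- length(full$bandwidth)
  out <- full
  out$volume_fraction <- volume_fraction
  out$marginality <- marginality
  out$threshold <- if (volume_fraction == 1) 0 else
    as.numeric(quantile(full$density_ref, 1 - volume_fraction, names = FALSE))
  out$shift <- if (marginality > 0) with_seed(seed, {
    ctr <- colMeans(full$points_std)
    for (try in seq_len(10)) {
      v <- full$points_std[sample.int(nrow(full$points_std), 1), ] - ctr
      if (sum(v^2) > 1e-12) break
    }
    if (sum(v^2) <= 1e-12) v <- rnorm(d)
    marginality * v / sqrt(sum(v^2))
  }) else rep(0, d)
  out
}

# Raw kernel density of a (possibly shifted) niche at standardized points.
# Shifting the niche by delta means evaluating f(x - delta), i.e. the kernel
# centres move by +delta; shifting the (few) centres is cheaper than the
# (many) queries.
niche_density_std <- function(niche, Xs) {
  ctr <- if (any(niche$shift != 0))
    sweep(niche$points_std, 2, niche$shift, "+") else niche$points_std
  .kde_eval_cpp(Xs, ctr, niche$bandwidth)
}

# Standardize raw-scale points onto the niche's axes.
niche_standardize <- function(niche, X) {
  sweep(sweep(as.matrix(X), 2, niche$center), 2, niche$scale, "/")
}

niche_density <- function(niche, X) {
  niche_density_std(niche, niche_standardize(niche, X))
}

#' Project habitat suitability through time
#'
#' Evaluates the niche kernel density at every (step, cell) environmental
#' point, scales the pooled distribution (over all steps and cells) by its
#' 95th percentile with values above it clipped to 1, and zeroes cells below
#' the realized niche's density threshold. The scale is computed on the
#' untruncated densities so that shrinking the volume fraction can only
#' remove suitability, never inflate it.
#'
#' @param niche A `niche_model`.
#' @param env Step x cell x axis array; axes must match the niche's.
#' @return Step x cell matrix of suitability in `[0, 1]`.
#' @export
project_suitability <- function(niche, env) {
  stopifnot(inherits(niche, "niche_model"), length(dim(env)) == 3)
  d <- length(niche$bandwidth)
  if (dim(env)[3] != d)
    stop("environmental axes do not match the niche axes")
  if (!is.null(niche$axes) && !is.null(dimnames(env)[[3]]) &&
      !identical(niche$axes, dimnames(env)[[3]]))
    stop("environmental axes do not match the niche axes")
  S <- dim(env)[1]; nc <- dim(env)[2]
  project_suitability_std(niche, niche_standardize(niche, matrix(env, S * nc, d)),
                          S, nc)
}

# Projection core on pre-standardized query points (reused across realized
# niches that share the full fit's centring).
project_suitability_std <- function(niche, Xs, S, nc) {
  dens <- niche_density_std(niche, Xs)
  scale95 <- as.numeric(quantile(dens, 0.95, names = FALSE))
  if (scale95 <= 0) return(matrix(0, S, nc))
  suit <- pmin(dens / scale95, 1)
  suit[dens < niche$threshold] <- 0
  matrix(suit, S, nc)
}
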