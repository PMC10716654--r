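# Driver analysis: centennial binning of ensemble outputs and penalized
# smooth regression (double-penalty thin-plate splines, maximum-likelihood
# smoothness selection) of abundance on climate, human pressure and land-use
# change, with chi-squared comparison of nested fits.

epoch_label <- function(bin_start_bp) {
  ifelse(bin_start_bp > 11700, "pleistocene",
         ifelse(bin_start_bp > 4250, "early_mid_holocene",
                ifelse(bin_start_bp > 450, "late_holocene", "post_1500")))
}

#' Aggregate ensemble outputs to centennial driver bins
#'
#' Per model and 100-year bin: mean total abundance over the generations in
#' the bin, and the three driver covariates (temperature, relative human
#' abundance, fractional land-use biomass reduction) averaged over the cells
#' occupied by that model at each generation, then over the bin. Bins where
#' a model is entirely absent yield missing covariates and are dropped.
#'
#' @param results List of `sim_result`s (the posterior ensemble).
#' @param landscape The `landscape_series` (supplies temperature and
#'   land-use change).
#' @param human Step x cell matrix of relative human abundance, or a list of
#'   such matrices (one per model).
#' @param bin_years Bin width in years (default 100).
#' @return Data frame: `model_id`, `bin_start_bp`, `epoch`, `abundance`,
#'   `temperature`, `human`, `landuse`.
#' @export
bin_drivers <- function(results, landscape, human, bin_years = 100) {
  grid <- landscape$grid
  steps_per_bin <- max(1L, as.integer(round(bin_years / grid$step_years)))
  S <- grid$n_steps
  bin_id <- (seq_len(S) - 1L) %/% steps_per_bin
  temp <- landscape$env[, , "winter_temp"]
  landuse <- 1 - landscape$biomass_adjusted /
    matrix(rep(pmax(landscape$biomass_raw, 1e-12), each = S), S, grid$n_cells)
  rows <- list()
  for (m in seq_along(results)) {
    sim <- results[[m]]
    hm <- if (is.list(human)) human[[m]] else human
    occ <- sim$abundance > 0
    nocc <- rowSums(occ)
    mean_occ <- function(mat) {
      v <- rowSums(mat * occ) / nocc
      v[nocc == 0] <- NA_real_
      v
    }
    step_df <- data.frame(bin = bin_id, total = sim$totals,
                          temperature = mean_occ(temp),
                          human = mean_occ(hm),
                          landuse = mean_occ(landuse))
    agg <- lapply(split(step_df, step_df$bin), function(d)
      data.frame(bin = d$bin[1], abundance = mean(d$total),
                 temperature = mean(d$temperature, na.rm = TRUE),
                 human = mean(d$human, na.rm = TRUE),
                 landuse = mean(d$landuse, na.rm = TRUE)))
    agg <- do.call(rbind, agg)
    agg$model_id <- m
    agg$bin_start_bp <- grid$t_start_bp - agg$bin * steps_per_bin * grid$step_years
    rows[[m]] <- agg
  }
  out <- do.call(rbind, rows)
  out$epoch <- epoch_label(out$bin_start_bp)
  out$model_id <- factor(out$model_id)
  out <- out[complete.cases(out[, c("abundance", "temperature", "human",
                                    "landuse")]), ]
  rownames(out) <- NULL
  out[, c("model_id", "bin_start_bp", "epoch", "abundance", "temperature",
          "human", "landuse")]
}

#' Fit the penalized smooth driver model
#'
#' Abundance regressed on double-penalty ("shrinkage") thin-plate smooths of
#' temperature, human pressure and land-use change, with a model-ID random
#' effect, optimized by maximum likelihood; with `with_interactions`,
#' pairwise tensor-interaction smooths are added. Double-penalty shrinkage
#' lets uninformative covariates be penalized to a flat effect.
#'
#' @param binned Output of [bin_drivers()].
#' @param epoch Epoch label to subset on, or `"all"`.
#' @param with_interactions Add the three pairwise interaction smooths.
#' @param k_main,k_int Basis dimensions of the main-effect and interaction
#'   smooths.
#' @return A `driver_fit`: the `mgcv` fit, the minimized (negative log) ML
#'   criterion `ml`, the coefficient count `n_coef` and total effective
#'   degrees of freedom `edf`.
#' @export
fit_driver_model <- function(binned, epoch = "all", with_interactions = FALSE,
                             k_main = 8, k_int = 3) {
  d <- if (identical(epoch, "all")) binned else binned[binned$epoch == epoch, ]
  d <- d[complete.cases(d), ]
  if (nrow(d) < 30) stop("need at least 30 bins to fit the driver model")
  for (cv in c("temperature", "human", "landuse"))
    if (length(unique(d[[cv]])) < k_main)
      stop(sprintf("rank deficiency: covariate '%s' has too few unique values", cv))
  d$model_id <- droplevels(factor(d$model_id))
  terms <- sprintf("s(%s, bs = 'ts', k = %d)",
                   c("temperature", "human", "landuse"), k_main)
  if (nlevels(d$model_id) >= 2)
    terms <- c(terms, "s(model_id, bs = 're')")
  if (with_interactions)
    terms <- c(terms, sprintf("ti(%s, %s, bs = c('ts', 'ts'), k = c(%d, %d))",
                              c("temperature", "temperature", "human"),
                              c("human", "landuse", "landuse"), k_int, k_int))
  fml <- stats::as.formula(paste("abundance ~", paste(terms, collapse = " + ")))
  fit <- mgcv::gam(fml, data = d, method = "ML")
  structure(list(fit = fit, ml = as.numeric(fit$gcv.ubre),
                 n_coef = length(stats::coef(fit)),
                 edf = sum(fit$edf), with_interactions = with_interactions,
                 epoch = epoch, n = nrow(d)),
            class = "driver_fit")
}

#' Partial effect curve of one driver
#'
#' Evaluates the fitted smooth of one covariate over its observed range,
#' holding the other covariates at their medians and excluding the random
#' effect.
#'
#' @param dfit A `driver_fit`.
#' @param covariate `"temperature"`, `"human"` or `"landuse"`.
#' @param n Grid size.
#' @return Data frame with the covariate grid and the partial `effect`.
#' @export
driver_partial_effect <- function(dfit, covariate, n = 100) {
  d <- dfit$fit$model
  grid_x <- seq(min(d[[covariate]]), max(d[[covariate]]), length.out = n)
  nd <- data.frame(temperature = median(d$temperature),
                   human = median(d$human), landuse = median(d$landuse),
                   model_id = d$model_id[1])
  nd <- nd[rep(1, n), , drop = FALSE]
  nd[[covariate]] <- grid_x
  tm <- stats::predict(dfit$fit, newdata = nd, type = "terms")
  keep <- grep(paste0("s\\(", covariate, "\\)"), colnames(tm))
  data.frame(x = grid_x, effect = rowSums(tm[, keep, drop = FALSE]))
}

#' Chi-squared comparison of nested driver models
#'
#' Statistic: twice the absolute difference of the minimized ML criteria.
#' Degrees of freedom: the difference in effective parameters (total
#' effective degrees of freedom) between the interaction and null fits,
#' floored at one; with double-penalty shrinkage an unneeded interaction is
#' penalized toward zero effective parameters, and the floor keeps the
#' upper-tail chi-squared reference calibrated at its nominal level (the
#' raw-coefficient count makes the test far too conservative, the unfloored
#' effective difference far too liberal). The p-value is the upper
#' chi-squared tail.
#'
#' @param fit_null,fit_interaction Nested `driver_fit`s on the same data
#'   (without and with interaction smooths).
#' @return List with `statistic`, `df` and `p`.
#' @export
compare_models <- function(fit_null, fit_interaction) {
  stopifnot(inherits(fit_null, "driver_fit"),
            inherits(fit_interaction, "driver_fit"))
  if (fit_null$with_interactions || !fit_interaction$with_interactions ||
      fit_null$n != fit_interaction$n)
    stop("fits are not nested on the same data")
  if (fit_interaction$n_coef <= fit_null$n_coef)
    stop("fits are not nested: no added parameters")
  statistic <- 2 * abs(fit_null$ml - fit_interaction$ml)
  df <- max(fit_interaction$edf - fit_null$edf, 1)
  list(statistic = statistic, df = df,
       p = pchisq(statistic, df, lower.tail = FALSE))
}

#' Null-calibration simulation for the interaction test
#'
#' Simulates centennial-binned data with purely additive smooth driver
#' effects plus a model-level random intercept, fits the driver model with
#' and without interactions, and returns the comparison p-values. Used to
#' check that the interaction test rejects at about its nominal level when
#' no interaction exists.
#'
#' @param n_reps Number of simulated datasets.
#' @param seed Integer seed.
#' @param n_models Ensemble members per dataset.
#' @param n_bins Bins per member.
#' @param interaction_strength Coefficient of a `temperature x human`
#'   interaction in the truth (0 = null).
#' @return Vector of p-values, length `n_reps`.
#' @export
driver_null_calibration <- function(n_reps = 200, seed = 1L, n_models = 6,
                                    n_bins = 60, interaction_strength = 0) {
  pvals <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    d <- with_seed(derive_seed(seed, r), {
      per <- lapply(seq_len(n_models), function(m) {
        temperature <- smooth_drift(n_bins)
        human <- smooth_drift(n_bins)
        landuse <- smooth_drift(n_bins)
        y <- 1.5 * sin(temperature) - 1.0 * human + 0.5 * landuse^2 +
          interaction_strength * temperature * human +
          rnorm(1, 0, 0.5) + rnorm(n_bins, 0, 0.5)
        data.frame(model_id = m, bin_start_bp = seq_len(n_bins),
                   epoch = "all", abundance = y, temperature = temperature,
                   human = human, landuse = landuse)
      })
      do.call(rbind, per)
    })
    d$model_id <- factor(d$model_id)
    f0 <- fit_driver_model(d, with_interactions = FALSE)
    f1 <- fit_driver_model(d, with_interactions = TRUE)
    pvals[r] <- compare_models(f0, f1)$p
  }
  pvals
}
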