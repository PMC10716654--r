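test_that("quality filtering is strictly greater-than and order preserving", {
  recs <- data.frame(cell_id = 1:4, age_bp = c(500, 400, 300, 200),
                     age_sd = 10, quality = c(5, 10, 11, 15), kind = "fossil")
  kept <- filter_fossils(recs)
  expect_equal(nrow(kept), 2)
  expect_equal(kept$quality, c(11, 15))
  expect_equal(kept$cell_id, c(3, 4)) # order preserved
  expect_equal(nrow(filter_fossils(recs[0, ])), 0)
})

test_that("generational means average a centred window with truncated edges", {
  times_in <- seq(200, 100, by = -1)
  const <- matrix(2.5, length(times_in), 3)
  out <- generational_means(const, times_in, c(190, 150, 110))
  expect_true(all(out == 2.5))
  # linear ramp: symmetric windows average to the centre value
  ramp <- matrix(times_in, length(times_in), 1)
  out2 <- generational_means(ramp, times_in, c(180, 150, 120))
  expect_equal(as.numeric(out2), c(180, 150, 120))
  # single slice: truncated window returns the slice
  out3 <- generational_means(matrix(7, 1, 2), 150, c(160, 150, 140))
  expect_true(all(out3 == 7))
  expect_error(generational_means(matrix(0, 0, 2), numeric(0), 100), "empty")
})

test_that("occurrence-environment intersection windows and dedupes bins", {
  g <- make_grid(3, 3, 1090, 100, 10)
  env <- array(seq_len(g$n_steps * g$n_cells * 4), c(g$n_steps, g$n_cells, 4),
               dimnames = list(NULL, NULL, c("a", "b", "c", "d")))
  r1 <- data.frame(cell_id = 5, age_bp = 500, age_sd = 0, quality = 12)
  expect_equal(nrow(intersect_occurrences(r1, env, g)), 1)
  # sd = 10 y with 10 y steps: window +/- 20 y spans 5 generational steps
  r2 <- data.frame(cell_id = 5, age_bp = 500, age_sd = 10, quality = 12)
  p2 <- intersect_occurrences(r2, env, g)
  expect_equal(nrow(p2), 5)
  # overlapping records in the same cell: shared bins counted once
  r3 <- rbind(r2, data.frame(cell_id = 5, age_bp = 510, age_sd = 10,
                             quality = 12))
  p3 <- intersect_occurrences(r3, env, g)
  expect_equal(nrow(p3), 6) # steps 530..480, not 10
  # out-of-grid and out-of-span records are skipped and counted
  r4 <- rbind(r2, data.frame(cell_id = c(99, 5), age_bp = c(500, 9000),
                             age_sd = 0, quality = 12))
  expect_message(p4 <- intersect_occurrences(r4, env, g), "skipped 2")
  expect_equal(attr(p4, "n_skipped"), 2L)
  expect_equal(nrow(p4), 5)
})

test_that("kernel density matches a brute-force sum of Gaussians", {
  set.seed(42)
  for (rep in 1:3) {
    C <- matrix(rnorm(2 * sample(10:50, 1)), ncol = 2)
    X <- matrix(rnorm(60), ncol = 2)
    h <- runif(2, 0.2, 1)
    expect_lt(max(abs(paleorange:::.kde_eval_cpp(X, C, h) -
                        kde_oracle(X, C, h))), 1e-10)
  }
  # closed-form L2 norm agrees with the convolution identity oracle
  C <- matrix(rnorm(40), ncol = 2)
  h <- c(0.5, 0.7)
  l2_oracle <- mean(outer(seq_len(nrow(C)), seq_len(nrow(C)),
                          Vectorize(function(i, j)
                            prod(stats::dnorm(C[i, ], C[j, ], h * sqrt(2))))))
  expect_equal(paleorange:::.kde_l2_cpp(C, h), l2_oracle, tolerance = 1e-12)
})

test_that("bandwidth cross-validation lands near Silverman's rule", {
  set.seed(7)
  pts <- matrix(rnorm(500 * 4), ncol = 4,
                dimnames = list(NULL, c("p", "t", "e", "b")))
  nm <- fit_hypervolume(pts)
  silv <- mean(nm$silverman) # standardized scale, all axes ~ equal
  expect_gt(nm$bw_multiplier, 0.5 * silv)
  expect_lt(nm$bw_multiplier, 2 * silv)
  # duplicated point cloud selects the same bandwidth (CV symmetry)
  nm2 <- fit_hypervolume(rbind(pts, pts))
  expect_equal(nm2$bw_multiplier, nm$bw_multiplier)
  expect_error(fit_hypervolume(pts[1:5, ]), "at least 10")
  bad <- pts; bad[, 2] <- 1
  expect_error(fit_hypervolume(bad), "t")
})

test_that("niche subsampling truncates the stated density mass and shifts the centroid", {
  set.seed(8)
  pts <- matrix(rnorm(400 * 4), ncol = 4)
  full <- fit_hypervolume(pts)
  expect_error(subsample_niche(full, 0, 0), "volume_fraction")
  # identity at volume 1, zero marginality
  env <- array(rnorm(50 * 4 * 4), c(50, 4, 4))
  s_full <- project_suitability(full, env)
  s_id <- project_suitability(subsample_niche(full, 1, 0, seed = 3), env)
  expect_lt(max(abs(s_full - s_id)), 1e-12)
  # Monte Carlo mass oracle: independent draw from the full mixture
  real <- subsample_niche(full, 0.65, 0, seed = 5)
  set.seed(99)
  n_mc <- 1e5
  idx <- sample.int(nrow(pts), n_mc, replace = TRUE)
  Xmc <- full$points_std[idx, ] +
    matrix(rnorm(n_mc * 4), ncol = 4) %*% diag(full$bandwidth)
  fmc <- paleorange:::.kde_eval_cpp(Xmc, full$points_std, full$bandwidth)
  expect_equal(mean(fmc >= real$threshold), 0.65, tolerance = 0.01)
  # centroid displacement equals the requested marginality exactly
  real2 <- subsample_niche(full, 0.8, 0.37, seed = 6)
  expect_equal(sqrt(sum(real2$shift^2)), 0.37, tolerance = 1e-6)
})

test_that("suitability projection scales by the pooled 95th percentile", {
  set.seed(9)
  pts <- matrix(rnorm(200 * 4), ncol = 4)
  full <- fit_hypervolume(pts)
  # every cell at the niche centroid: pooled p95 equals the common density
  env1 <- array(rep(colMeans(pts), each = 12), c(4, 3, 4))
  expect_true(all(project_suitability(full, env1) == 1))
  # environments >10 bandwidths outside the niche are unsuitable
  env2 <- array(rep(colMeans(pts) + 50 * apply(pts, 2, sd), each = 12),
                c(4, 3, 4))
  expect_true(all(project_suitability(full, env2) < 1e-6))
  # hand case: scaled values follow the oracle densities
  env3 <- array(rnorm(40 * 4 * 4, sd = 1.5), c(40, 4, 4))
  dens <- kde_oracle(paleorange:::niche_standardize(full, matrix(env3, 160, 4)),
                     full$points_std, full$bandwidth)
  expected <- pmin(dens / quantile(dens, 0.95, names = FALSE), 1)
  expect_equal(as.numeric(project_suitability(full, env3)), expected,
               tolerance = 1e-10)
  # axis mismatch errors
  expect_error(project_suitability(full, array(0, c(4, 3, 3))), "axes")
})

test_that("pooled-p95 scaling and volume monotonicity invariants hold", {
  set.seed(10)
  pts <- matrix(rnorm(300 * 4), ncol = 4)
  full <- fit_hypervolume(pts)
  env <- array(rnorm(60 * 5 * 4), c(60, 5, 4))
  s <- project_suitability(full, env)
  expect_true(all(s >= 0 & s <= 1))
  expect_gte(mean(s == 1), 0.05) # clip mass at the pooled p95
  expect_lte(quantile(s, 0.95), 1)
  # shrinking volume_fraction never increases suitability anywhere
  prev <- s
  for (vf in c(0.9, 0.6, 0.3)) {
    cur <- project_suitability(subsample_niche(full, vf, 0, seed = 4), env)
    expect_true(all(cur <= prev + 1e-12))
    prev <- cur
  }
})
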