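test_that("Latin hypercube sampling stratifies every margin", {
  ranges <- data.frame(param = c("a", "b", "c"), lo = c(0, -1, 2),
                       hi = c(1, 1, 2))
  x <- sample_priors_lhs(ranges, 10, seed = 3)
  expect_equal(nrow(x), 10)
  # each decile of each margin contains exactly one sample
  expect_true(all(table(cut(x$a, seq(0, 1, 0.1))) == 1))
  expect_true(all(table(cut(x$b, seq(-1, 1, 0.2))) == 1))
  expect_true(all(x$c == 2)) # degenerate range collapses
  expect_error(sample_priors_lhs(ranges, 0, seed = 1), "n must be")
  bad <- ranges; bad$lo[1] <- 2
  expect_error(sample_priors_lhs(bad, 5, seed = 1), "lo <= hi")
})

test_that("occurrence matching agrees with an exhaustive enumeration oracle", {
  g <- make_grid(5, 5, 190, 100, 10)
  set.seed(21)
  ab <- matrix(rbinom(g$n_steps * g$n_cells, 1, 0.25) * runif(250, 1, 50),
               g$n_steps, g$n_cells)
  sim <- fake_sim(ab, g)
  fossils <- data.frame(cell_id = sample(25, 6), age_bp = runif(6, 110, 180),
                        age_sd = c(0, 0, 10, 10, 20, 5), quality = 12,
                        kind = c("historical_sighting", "historical_sighting",
                                 rep("fossil", 4)))
  # oracle: brute force over every step and Moore neighbour
  oracle <- mean(sapply(seq_len(6), function(i) {
    lo <- fossils$age_bp[i] - 2 * fossils$age_sd[i]
    hi <- fossils$age_bp[i] + 2 * fossils$age_sd[i]
    steps <- if (fossils$age_sd[i] == 0)
      which.min(abs(g$step_times_bp - fossils$age_bp[i]))
    else which(g$step_times_bp >= lo & g$step_times_bp <= hi)
    rc <- paleorange:::cell_rowcol(g, fossils$cell_id[i])
    hit <- FALSE
    for (s in steps) for (dr in -1:1) for (dc in -1:1) {
      r2 <- rc[1, "row"] + dr; c2 <- rc[1, "col"] + dc
      if (r2 >= 1 && r2 <= 5 && c2 >= 1 && c2 <= 5 &&
          ab[s, paleorange:::cell_id(g, r2, c2)] > 0) hit <- TRUE
    }
    hit
  }))
  expect_equal(occurrence_match(sim, fossils, g), oracle)
  # an exactly-dated fossil on an occupied cell matches
  occ <- which(ab > 0, arr.ind = TRUE)[1, ]
  f1 <- data.frame(cell_id = occ["col"], age_bp = g$step_times_bp[occ["row"]],
                   age_sd = 0, quality = 12, kind = "fossil")
  expect_equal(occurrence_match(sim, f1, g), 1)
  # empty landscape matches nothing; no fossils is an error
  expect_equal(occurrence_match(fake_sim(ab * 0, g), fossils, g), 0)
  expect_error(occurrence_match(sim, fossils[0, ], g), "no fossil")
})

test_that("persistence penalties count years short of 1850 CE", {
  g <- make_grid(2, 2, 21000, 100, 10)
  ab <- matrix(1, g$n_steps, 4)
  refug <- list(a = 1L, b = 4L)
  expect_equal(persistence_penalty(fake_sim(ab, g), refug), 0)
  # refugium a last occupied at 1700 CE (250 BP), b persists: penalty 150
  ab2 <- ab
  last_step <- paleorange:::step_for_bp(g, 250)
  ab2[(last_step + 1):g$n_steps, 1] <- 0
  expect_equal(persistence_penalty(fake_sim(ab2, g), refug), 150)
  # both never occupied: penalty runs from 21 ka BP (= -19050 CE) each
  expect_equal(persistence_penalty(fake_sim(ab * 0, g), refug),
               2 * (1850 - (1950 - 21000)))
})

test_that("refugia are counted as 8-connected patches at 1850 CE", {
  g <- make_grid(5, 5, 1090, 100, 10)
  ab <- matrix(0, g$n_steps, g$n_cells)
  # two disjoint patches: cells (1,1)+(2,2) touch diagonally; (5,5) apart
  ab[, c(1, 7, 25)] <- 10
  expect_equal(refugia_diff(fake_sim(ab, g), expected = 2), 0)
  # five isolated cells
  ab2 <- matrix(0, g$n_steps, g$n_cells)
  ab2[, c(1, 3, 5, 11, 23)] <- 1
  expect_equal(refugia_diff(fake_sim(ab2, g), expected = 2), 3)
  # empty map
  expect_equal(refugia_diff(fake_sim(ab * 0, g), expected = 2), 2)
})

test_that("the ABC distance is a scaled Euclidean norm", {
  target <- c(occurrence_match = 1, persistence_penalty = 0, refugia_diff = 0)
  expect_equal(abc_distance(target, target, c(1, 1, 1)), 0)
  expect_equal(abc_distance(c(0.8, 0, 0), target, c(0.1, 15, 1)), 2)
  expect_equal(abc_distance(c(0.8, 30, 1), target, c(0.1, 15, 1)),
               sqrt(2^2 + 2^2 + 1^2))
  expect_error(abc_distance(c(1, 0), target[1:2], c(1, 0)), "scales")
  # robust scales: MAD, then sd, then 1
  s <- compute_scales(cbind(c(1, 2, 3, 10), c(5, 5, 5, 5)))
  expect_equal(s[[2]], 1)
  expect_gt(s[[1]], 0)
})

test_that("ABC rejection equals the full-sort oracle and is stable", {
  expect_equal(length(abc_reject(runif(10000), 0.0025)), 25)
  d <- c(0.5, 0, 0.3)
  expect_equal(abc_reject(d, 0.5)[1], 2L) # zero distance ranks first
  expect_error(abc_reject(d, 0), "tolerance")
  set.seed(13)
  for (rep in 1:10) {
    dd <- sample(round(runif(1000, 0, 10), 1)) # heavy ties
    tol <- runif(1, 0.01, 0.3)
    acc <- abc_reject(dd, tol)
    m <- ceiling(1000 * tol)
    expect_equal(length(acc), m)
    expect_equal(sort(dd)[seq_len(m)], sort(dd[acc]))
    # stable: among equal distances, lower indices win
    cutoff <- max(dd[acc])
    tied_in <- acc[dd[acc] == cutoff]
    tied_all <- which(dd == cutoff)
    expect_equal(sort(tied_in), head(tied_all, length(tied_in)))
  }
})

test_that("prior refinement expands the accepted envelope within bounds", {
  orig <- data.frame(param = c("x", "y"), lo = c(0, 0), hi = c(1, 1))
  acc <- data.frame(x = c(0.2, 0.3, 0.4), y = c(0.5, 0.5, 0.5))
  ref <- refine_priors(acc, orig, expansion = 1.1)
  expect_equal(ref$lo[1], 0.19)
  expect_equal(ref$hi[1], 0.41)
  expect_equal(ref$lo[2], 0.5) # degenerate accepted range collapses
  expect_equal(ref$hi[2], 0.5)
  # refined ranges always sit inside the original bounds
  set.seed(3)
  for (rep in 1:10) {
    acc2 <- data.frame(x = runif(5, -0.5, 1.5), y = runif(5))
    r2 <- refine_priors(acc2, orig, expansion = 1.5)
    expect_true(all(r2$lo >= orig$lo - 1e-12))
    expect_true(all(r2$hi <= orig$hi + 1e-12))
  }
  expect_error(refine_priors(acc[1, , drop = FALSE], orig), "nrow")
})

test_that("convergence is judged by histogram overlap of posteriors", {
  set.seed(5)
  a <- data.frame(x = rnorm(20000))
  same <- convergence_check(list(a, a))
  expect_true(same$converged)
  expect_equal(same$statistic, 1)
  disj <- convergence_check(list(data.frame(x = runif(500)),
                                 data.frame(x = runif(500) + 10)))
  expect_false(disj$converged)
  expect_equal(disj$statistic, 0)
  # two normals one s.d. apart: overlap ~ 2 * pnorm(-1/2) ~ 0.617
  b <- data.frame(x = rnorm(20000, 1))
  ov <- convergence_check(list(a, b), bins = 40)
  expect_equal(ov$statistic, 2 * pnorm(-0.5), tolerance = 0.05)
})

test_that("goodness of fit separates central from outlying targets", {
  set.seed(8)
  S <- cbind(m = rnorm(40, 0.9, 0.05), p = rnorm(40, 10, 3),
             d = rnorm(40, 1, 0.5))
  p_centre <- goodness_of_fit(S, colMeans(S), n_reps = 500, seed = 2)
  expect_gte(p_centre, 0.5)
  far <- colMeans(S) + 10 * compute_scales(S)
  p_far <- goodness_of_fit(S, far, n_reps = 500, seed = 2)
  expect_lt(p_far, 0.05)
  expect_true(p_centre >= 0 && p_centre <= 1)
  expect_identical(p_far, goodness_of_fit(S, far, n_reps = 500, seed = 2))
})

test_that("ensemble weights are inverse-distance and normalized", {
  g <- make_grid(1, 1, 140, 100, 10)
  r10 <- fake_sim(matrix(10, 5, 1), g)
  r20 <- fake_sim(matrix(20, 5, 1), g)
  ens <- ensemble_average(list(r10, r20), c(1, 3))
  expect_equal(ens$abundance[1, 1], 0.75 * 10 + 0.25 * 20)
  expect_equal(sum(ens$weights), 1, tolerance = 1e-12)
  # equal distances: arithmetic mean; single member: unchanged
  expect_equal(ensemble_average(list(r10, r20), c(2, 2))$totals[1], 15)
  expect_equal(ensemble_average(list(r20), 5)$abundance, r20$abundance)
  # identical members: any member
  expect_equal(ensemble_average(list(r10, r10, r10), c(1, 2, 3))$abundance,
               r10$abundance)
  # zero distances get a tiny positive epsilon, weights still sum to one
  ens0 <- ensemble_average(list(r10, r20), c(0, 1))
  expect_equal(sum(ens0$weights), 1, tolerance = 1e-12)
  expect_gt(ens0$weights[1], 0.99)
  expect_error(ensemble_average(list(), numeric(0)), "empty")
})

test_that("trend comparison reports envelope membership and change correlation", {
  times <- seq(500, 100, -10)
  m1 <- 1000 * exp(-seq_along(times) / 20)
  m2 <- 800 * exp(-seq_along(times) / 15)
  # a member of the ensemble lies inside the envelope everywhere
  ext <- data.frame(time_bp = times, value = m1)
  tr <- compare_trend(list(m1, m2), times, ext)
  expect_true(all(tr$inside))
  expect_gt(tr$correlation, 0.9)
  # constant external vs a declining ensemble: zero change correlation
  tr2 <- compare_trend(list(m1, m2), times,
                       data.frame(time_bp = times, value = rep(3, length(times))))
  expect_equal(tr2$correlation, 0)
  # hand-built 5-point case vs 2-member ensemble
  t5 <- c(300, 250, 200, 150, 100)
  e5 <- data.frame(time_bp = t5, value = c(1, 0.9, 0.1, 0.5, 0.4))
  mA <- c(1, 0.8, 0.6, 0.4, 0.2); mB <- c(1, 1, 0.2, 0.6, 0.5)
  tr3 <- compare_trend(list(mA, mB), t5, e5)
  expect_equal(tr3$inside, c(TRUE, TRUE, FALSE, TRUE, TRUE))
  expect_error(compare_trend(list(m1), times,
                             data.frame(time_bp = 5000, value = 1)), "overlap")
})
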