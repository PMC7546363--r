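cfg <- default_config()

sim_scanpaths <- function(truth, n, recording_s, seed0 = 1) {
  lapply(seq_len(n), function(i)
    simulate_scanpath(truth, paste0("p", i), "s1", recording_s,
                      seed = seed0 + i)$scanpath)
}

test_that("a single-state model collapses to its closed form", {
  tm <- make_two_state_truth()
  sps <- sim_scanpaths(tm, 3, 15)
  tf <- fit_feature_transform(sps)
  fit <- vbem_fit(sps, 1, cfg, transform = tf, restarts = 1, seed = 1)
  expect_equal(fit$model$pi, 1)
  expect_equal(fit$model$A, matrix(1, 1, 1))
  # posterior mean location = (beta0 m0 + N xbar) / (beta0 + N)
  X <- do.call(rbind, lapply(sps, scanpath_features, tf = tf))
  pr <- gazehmm:::make_prior(X, 1)
  expected <- (pr$beta0[1] * pr$m0[1, ] + nrow(X) * colMeans(X)) /
    (pr$beta0[1] + nrow(X))
  expect_equal(unname(fit$model$means[1, ]), unname(expected),
               tolerance = 1e-10)
})

test_that("the ELBO is bounded by the exact single-Gaussian evidence", {
  tm <- make_two_state_truth()
  sps <- sim_scanpaths(tm, 1, 2)  # a handful of observations
  tf <- fit_feature_transform(sps)
  fit <- vbem_fit(sps, 1, cfg, transform = tf, restarts = 1, seed = 1)
  X <- do.call(rbind, lapply(sps, scanpath_features, tf = tf))
  pr <- gazehmm:::make_prior(X, 1)
  ev <- oracle_nw_log_evidence(X, pr$m0[1, ], pr$beta0[1], pr$nu0[1],
                               pr$W0inv[, , 1])
  expect_lte(fit$elbo, ev + 1e-8)
})

test_that("well-separated two-state structure is recovered", {
  tm <- make_two_state_truth(sep_px = 600, sd_px = 50)
  sps <- sim_scanpaths(tm, 8, 40)
  fit <- vbem_fit(sps, 2, cfg, restarts = 2, seed = 7)
  tf <- fit$model$transform
  est_px <- t(apply(fit$model$means, 1, gazehmm:::state_mean_px, tf = tf))
  true_px <- cbind(tm$rois$mx, tm$rois$my)
  p <- best_permutation(est_px, true_px)
  expect_lt(max(abs(est_px[p, ] - true_px)), 15)
  expect_lt(max(abs(fit$model$A[p, p] - tm$A)), 0.05)
})

test_that("duplicating every sequence leaves the point model nearly fixed", {
  tm <- make_two_state_truth()
  sps <- sim_scanpaths(tm, 8, 60)
  tf <- fit_feature_transform(sps)
  cfg_tight <- default_config(elbo_tol = 1e-9)
  f1 <- vbem_fit(sps, 2, cfg_tight, transform = tf, restarts = 1, seed = 2)
  f2 <- vbem_fit(c(sps, sps), 2, cfg_tight, transform = tf, restarts = 1,
                 seed = 2)
  px1 <- t(apply(f1$model$means, 1, gazehmm:::state_mean_px, tf = tf))
  px2 <- t(apply(f2$model$means, 1, gazehmm:::state_mean_px, tf = tf))
  p <- best_permutation(px2, px1)
  expect_lt(max(abs(px2[p, ] - px1)), 1)  # shrinkage shift < 1 px
})

test_that("posterior point models always satisfy stochasticity invariants", {
  for (s in 1:6) {
    tm <- make_two_state_truth(A = matrix(c(.9, .1, .4, .6), 2, byrow = TRUE))
    sps <- sim_scanpaths(tm, 3, 15, seed0 = 100 * s)
    K <- sample(1:3, 1)
    fit <- vbem_fit(sps, K, cfg, restarts = 1, seed = s)
    expect_equal(sum(fit$model$pi), 1, tolerance = 1e-10)
    expect_equal(unname(rowSums(fit$model$A)), rep(1, K), tolerance = 1e-10)
    for (k in seq_len(K))
      expect_gt(min(eigen(fit$model$covs[, , k])$values), 0)
    # ELBO non-decreasing within the restart
    expect_gte(min(diff(fit$posterior$elbo_trace)),
               -1e-6 * max(abs(fit$posterior$elbo_trace)))
  }
})

test_that("infeasible state counts are rejected", {
  tm <- make_two_state_truth()
  sps <- sim_scanpaths(tm, 1, 3)
  n <- nrow(sps[[1]]$fixations)
  expect_error(vbem_fit(sps, n + 1, cfg, restarts = 1, seed = 1),
               class = "gazehmm_infeasible_error")
  expect_error(vbem_fit(sps, 0, cfg), class = "gazehmm_domain_error")
})

test_that("ELBO recomputation matches the trace's final value", {
  tm <- make_two_state_truth()
  sps <- sim_scanpaths(tm, 3, 20)
  tf <- fit_feature_transform(sps)
  fit <- vbem_fit(sps, 2, cfg, transform = tf, restarts = 1, seed = 3)
  tr <- fit$posterior$elbo_trace
  expect_equal(elbo(sps, fit$posterior, tf), tr[length(tr)],
               tolerance = 1e-6 * abs(tr[length(tr)]))
})

test_that("state-count selection behaves at the edges", {
  tm <- make_two_state_truth()
  sps <- sim_scanpaths(tm, 3, 15)
  sel <- select_state_count(sps, k_range = 2, cfg, restarts = 1, seed = 1)
  expect_equal(sel$K, 2)
  expect_error(select_state_count(sps, k_range = integer(0), cfg),
               class = "gazehmm_config_error")

  # near-point-mass data: one state suffices
  set.seed(41)
  sp0 <- scanpath("p", "s", data.frame(onset = 0:29 * 400, duration = 300,
                                       x = 500 + rnorm(30, 0, 1e-3),
                                       y = 400 + rnorm(30, 0, 1e-3)))
  sel0 <- select_state_count(list(sp0), k_range = 1:3,
                             default_config(restarts = 1), seed = 1)
  expect_equal(sel0$K, 1)
})

test_that("decoding matches exhaustive path enumeration", {
  set.seed(99)
  maxerr <- 0
  for (r in 1:40) {
    K <- sample(2:3, 1); Tn <- sample(2:8, 1)
    model <- random_valid_model(K)
    X <- matrix(rnorm(Tn * 3), Tn)
    d <- decode(model, X)
    g <- oracle_enum_gamma(model, X)
    maxerr <- max(maxerr, max(abs(d$gamma - g)))
    expect_equal(unname(rowSums(d$gamma)), rep(1, Tn), tolerance = 1e-12)
    expect_equal(d$map_states, apply(d$gamma, 1, which.max))
  }
  expect_lt(maxerr, 1e-10)
})

test_that("decoding limits: separation and symmetry", {
  means <- rbind(c(0, 0, 0), c(30, 30, 0))
  covs <- array(diag(3), c(3, 3, 2))
  model <- bhmm_model(c(.5, .5), matrix(.5, 2, 2), means, covs)
  d <- decode(model, rbind(c(0, 0, 0)))
  expect_equal(d$map_states, 1)
  expect_gt(d$gamma[1, 1], 0.99)

  # identical states, uniform transitions: all rows 1/K
  modu <- bhmm_model(c(1 / 3, 1 / 3, 1 / 3), matrix(1 / 3, 3, 3),
                     rbind(c(0, 0, 0), c(0, 0, 0), c(0, 0, 0)),
                     array(diag(3), c(3, 3, 3)))
  du <- decode(modu, matrix(rnorm(12), 4))
  expect_equal(du$gamma, matrix(1 / 3, 4, 3), tolerance = 1e-12)
})

test_that("relabelling the generator permutes the recovered model", {
  tm <- make_two_state_truth(A = matrix(c(.85, .15, .25, .75), 2, byrow = TRUE))
  tm_swapped <- tm
  tm_swapped$A <- tm$A[2:1, 2:1]
  tm_swapped$rois <- tm$rois[2:1, ]
  sps1 <- sim_scanpaths(tm, 5, 25, seed0 = 10)
  sps2 <- sim_scanpaths(tm_swapped, 5, 25, seed0 = 10)
  f1 <- vbem_fit(sps1, 2, cfg, restarts = 1, seed = 5)
  f2 <- vbem_fit(sps2, 2, cfg, restarts = 1, seed = 5)
  px1 <- t(apply(f1$model$means, 1, gazehmm:::state_mean_px,
                 tf = f1$model$transform))
  px2 <- t(apply(f2$model$means, 1, gazehmm:::state_mean_px,
                 tf = f2$model$transform))
  p <- best_permutation(px2, px1)
  expect_lt(max(abs(px2[p, ] - px1)), 10)
  expect_lt(max(abs(f2$model$A[p, p] - f1$model$A)), 0.05)
})
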