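cfg <- default_config()

# Small deterministic variable table: n participants x 2 stimuli, one
# response variable plus both covariates.
toy_table <- function(values, groups, covariate = NULL,
                      variable = "transition_count", category = "face_face") {
  n <- length(values) / 2
  participants <- rep(sprintf("p%02d", seq_len(n)), each = 2)
  stim <- rep(c("A1", "B1"), n)
  actors <- rep(c("four", "one"), n)
  base <- data.frame(participant = participants,
                     group = rep(groups, each = 2),
                     stimulus = stim, actors = actors)
  tab <- rbind(cbind(base, variable = variable, category = category,
                     value = values),
               cbind(base, variable = "total_transitions", category = "all",
                     value = covariate %||% rep(300, 2 * n)),
               cbind(base, variable = "total_fixation_duration",
                     category = "all", value = rep(110, 2 * n)))
  tab
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("covariate centering is exact and idempotent", {
  tab <- toy_table(rep(5, 6), rep("TD", 3), covariate = c(290, 310, 300,
                                                          300, 310, 290))
  c1 <- center_covariate(tab, "total_transitions")
  v <- c1$value[c1$variable == "total_transitions"]
  expect_equal(v, c(-10, 10, 0, 0, 10, -10))
  expect_lt(abs(mean(v)), 1e-10)
  c2 <- center_covariate(c1, "total_transitions")
  expect_equal(c2$value, c1$value)
  expect_equal(center_covariate(tab, "total_transitions")$value[1:6],
               tab$value[1:6])  # response untouched
  tab$value[tab$variable == "total_transitions"][2] <- NA
  expect_error(center_covariate(tab, "total_transitions"),
               class = "gazehmm_validation_error")
})

test_that("marginal means equal group means in a balanced design", {
  set.seed(8)
  groups <- rep(c("TD", "ASD", "ASD_ADHD"), each = 8)
  mu <- c(TD = 10, ASD = 9, ASD_ADHD = 7)[groups]
  values <- as.numeric(rep(mu, each = 2)) + rnorm(48, 0, .5)
  tab <- toy_table(values, groups)
  res <- fit_lmm(tab, lmm_spec("transition_count", "face_face"), cfg)
  gm <- tapply(values, rep(groups, each = 2), mean)
  expect_equal(as.numeric(res$emmeans$emmean[match(names(gm),
                                                   res$emmeans$group)]),
               as.numeric(gm), tolerance = 1e-6)
  # contrast estimates are differences of marginal means
  d <- res$contrasts$estimate[grep("^ASD - TD$", res$contrasts$contrast)]
  expect_equal(d, unname(gm["ASD"] - gm["TD"]), tolerance = 1e-6)
})

test_that("results are invariant to row order and to covariate centering", {
  set.seed(9)
  groups <- rep(c("TD", "ASD_ADHD"), each = 10)
  values <- rnorm(40, 10)
  covv <- rnorm(40, 300, 20)
  tab <- toy_table(values, groups, covariate = covv)
  spec <- lmm_spec("transition_count", "face_face", "total_transitions")
  r1 <- fit_lmm(tab, spec, cfg)
  r2 <- fit_lmm(tab[sample(nrow(tab)), ], spec, cfg)
  expect_equal(r1$F_group, r2$F_group, tolerance = 1e-8)
  # pre-centering the covariate leaves the group F untouched
  r3 <- fit_lmm(center_covariate(tab, "total_transitions"), spec, cfg)
  expect_equal(r1$F_group, r3$F_group, tolerance = 1e-8)
})

test_that("a planted covariate slope is recovered", {
  set.seed(10)
  groups <- rep(c("TD", "ASD", "ASD_ADHD"), times = c(12, 8, 8))
  covv <- rnorm(56, 300, 30)
  values <- 5 + 1.0 * (covv - mean(covv)) + rnorm(56, 0, 2)
  tab <- toy_table(values, groups, covariate = covv)
  res <- fit_lmm(tab, lmm_spec("transition_count", "face_face",
                               "total_transitions"), cfg)
  # refit to read the slope directly
  df <- gazehmm:::lmm_frame(tab, lmm_spec("transition_count", "face_face",
                                          "total_transitions"))
  m <- lmerTest::lmer(value ~ group + actors + group:actors + covariate +
                        (1 | participant), data = df)
  expect_lt(abs(lme4::fixef(m)[["covariate"]] - 1.0), 0.1)
})

test_that("missing group levels and degenerate tables error cleanly", {
  tab <- toy_table(rnorm(10, 5), rep("TD", 5))
  expect_error(fit_lmm(tab, lmm_spec("transition_count", "face_face"), cfg),
               class = "gazehmm_validation_error")
  expect_error(fit_lmm(tab, lmm_spec("nope", "face_face"), cfg),
               class = "gazehmm_validation_error")
})

test_that("the full battery reports sixteen models", {
  co <- simulate_cohort(group_sizes = c(TD = 6, ASD = 5, ASD_ADHD = 5),
                        n_four = 1, n_one = 1, recording_s = 30, seed = 77)
  tab <- variable_table_from_truth(co, cfg)
  rep <- suppressMessages(run_all_models(tab, cfg))
  expect_equal(nrow(rep$results), 16)
  expect_setequal(unique(rep$results$variable),
                  c("transition_count", "transition_probability",
                    "fixation_count", "visit_count"))
  expect_equal(nrow(rep$covariate_pretests), 2)
  expect_output(print(rep), "Mixed-effects group comparisons")
})
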