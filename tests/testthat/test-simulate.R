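cfg <- default_config()

test_that("templates honour the stimulus-class ROI structure", {
  t4 <- make_template("four_actor", seed = 3)
  expect_equal(nrow(t4$rois), 12)
  expect_equal(sum(t4$rois$category == "face"), 5)
  expect_equal(sum(t4$rois$category == "body"), 3)
  expect_equal(sum(t4$rois$category == "nonsocial"), 4)
  expect_equal(sum(t4$rois$sparse), 1)
  t1 <- make_template("one_actor", seed = 3)
  expect_equal(nrow(t1$rois), 9)
  expect_equal(sum(t1$rois$category == "face"), 1)
  expect_equal(sum(t1$rois$category == "body"), 1)
  # on-canvas means, sensible spreads, determinism
  expect_true(all(t4$rois$mx >= 0 & t4$rois$mx <= 1920))
  expect_true(all(t4$rois$my >= 0 & t4$rois$my <= 1080))
  expect_identical(make_template("four_actor", seed = 3), t4)
  expect_false(identical(make_template("four_actor", seed = 4)$rois, t4$rois))
})

test_that("group templates plant the face-to-face effect exactly", {
  td <- group_template("TD")
  aa <- group_template("ASD_ADHD")
  expect_equal(td$cat_matrix["face", "face"], 0.30)
  expect_equal(aa$cat_matrix["face", "face"], 0.22)
  expect_equal(group_template("ASD")$cat_matrix["face", "face"], 0.26)
  expect_equal(unname(rowSums(aa$cat_matrix)), rep(1, 3), tolerance = 1e-12)
  # non-face rows untouched
  expect_equal(aa$cat_matrix["body", ], td$cat_matrix["body", ])
})

test_that("participant models converge to the group template as jitter vanishes", {
  t4 <- make_template("four_actor", seed = 1)
  g <- group_template("TD")
  m_inf <- sample_participant_model(t4, g, seed = 2, concentration = Inf,
                                    mean_jitter_px = 0)
  base <- gazehmm:::expand_to_states(t4, g$cat_matrix)
  expect_equal(m_inf$A, base, tolerance = 1e-12)
  m_hi <- sample_participant_model(t4, g, seed = 2, concentration = 1e5,
                                   mean_jitter_px = 0)
  expect_lt(max(abs(m_hi$A - base)), 0.01)
})

test_that("the measured category probability matches the planted value", {
  t4 <- make_template("four_actor", seed = 6)
  labs <- truth_labels(t4)
  for (g in c("TD", "ASD", "ASD_ADHD")) {
    gt <- group_template(g)
    m <- sample_participant_model(t4, gt, seed = 1, concentration = Inf)
    tp <- transition_probability(list(K = nrow(m$A), A = m$A), labs,
                                 occupancy = "stationary")
    expect_equal(unname(tp$pairs["face_face"]),
                 gt$cat_matrix["face", "face"], tolerance = 1e-10)
    expect_equal(unname(tp$pairs["body_body"]),
                 gt$cat_matrix["body", "body"], tolerance = 1e-10)
  }
})

test_that("scanpath simulation respects duration and state structure", {
  # absorbing single state
  tm1 <- structure(list(A = matrix(1, 1, 1), pi = 1,
                        rois = data.frame(mx = 700, my = 300, sdx = 20,
                                          sdy = 20, corr = 0,
                                          mu_log = log(300), sd_log = .3,
                                          sparse = FALSE)),
                   class = "gazehmm_truth_model")
  sim <- simulate_scanpath(tm1, recording_s = 30, seed = 1)
  expect_true(all(sim$states == 1))
  expect_lt(max(abs(sim$scanpath$fixations$x - 700)), 150)

  # fixation count for a 400 ms median renewal process over 120 s
  tm <- make_two_state_truth()
  tm$rois$mu_log <- log(400)
  counts <- vapply(1:12, function(s)
    nrow(simulate_scanpath(tm, recording_s = 120, seed = s)$scanpath$fixations),
    0)
  expect_gte(mean(counts >= 250 & counts <= 350), 0.9)

  # empirical transition frequencies approach the generator matrix
  long <- simulate_scanpath(tm, recording_s = 5000, seed = 3)
  st <- long$states
  emp <- matrix(0, 2, 2)
  for (t in seq_len(length(st) - 1)) emp[st[t], st[t + 1]] <-
      emp[st[t], st[t + 1]] + 1
  emp <- emp / rowSums(emp)
  expect_lt(max(abs(emp - tm$A)), 0.02)
})

test_that("cohort generation is deterministic and complete", {
  co <- simulate_cohort(group_sizes = c(TD = 3, ASD_ADHD = 2, ASD = 2),
                        n_four = 2, n_one = 2, recording_s = 5, seed = 31)
  expect_equal(nrow(co$cohort), 7)
  expect_length(co$scanpaths, 7 * 4)
  expect_equal(nrow(co$stimuli), 4)

  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  co1 <- simulate_cohort(group_sizes = c(TD = 2, ASD = 2), n_four = 1,
                         n_one = 1, recording_s = 5, seed = 8, out_dir = dir1)
  co2 <- simulate_cohort(group_sizes = c(TD = 2, ASD = 2), n_four = 1,
                         n_one = 1, recording_s = 5, seed = 8, out_dir = dir2)
  for (f in c("fixations.csv", "cohort.csv", "stimuli.csv", "truth.json"))
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)))

  # null effect: group templates identical
  con <- simulate_cohort(group_sizes = c(TD = 1, ASD_ADHD = 1), n_four = 1,
                         n_one = 0, recording_s = 5, seed = 2,
                         effect = c(TD = 1, ASD_ADHD = 1))
  expect_equal(con$group_templates$TD$cat_matrix,
               con$group_templates$ASD_ADHD$cat_matrix)
  expect_error(simulate_cohort(group_sizes = c(TD = 0)),
               class = "gazehmm_domain_error")
})

test_that("rendered raw samples honour the sampling rate", {
  sp <- scanpath("p", "s", data.frame(onset = 0, duration = 400,
                                      x = 500, y = 400))
  raw <- render_raw_samples(sp, cfg, noise_px = 0, seed = 1)
  expect_equal(sum(raw$valid), 48)  # 400 ms at 120 Hz
  expect_true(all(raw$x[raw$valid] == 500))
})

test_that("heavy sample loss fails the tracking-ratio gate", {
  tm <- make_two_state_truth()
  sp <- simulate_scanpath(tm, recording_s = 20, seed = 5)$scanpath
  raw <- render_raw_samples(sp, cfg, noise_px = 0, seed = 5)
  set.seed(6)
  drop <- sample(nrow(raw), round(0.3 * nrow(raw)))
  raw$valid[drop] <- FALSE
  fx <- detect_fixations_idt(raw, cfg)
  q <- compute_quality(raw, fx, 20000, cfg)
  expect_lt(q$tracking_ratio, 0.75)
  expect_false(q$passed)
})

test_that("truth-based variable tables satisfy type invariants", {
  co <- simulate_cohort(group_sizes = c(TD = 3, ASD = 2), n_four = 1,
                        n_one = 1, recording_s = 30, seed = 13)
  tab <- variable_table_from_truth(co, cfg)
  expect_setequal(unique(tab$variable),
                  c("transition_count", "transition_probability",
                    "fixation_count", "visit_count", "total_transitions",
                    "total_fixation_duration"))
  # conservation per recording
  for (p in unique(tab$participant)) for (s in unique(tab$stimulus)) {
    sub <- tab[tab$participant == p & tab$stimulus == s, ]
    tc <- sub$value[sub$variable == "transition_count"]
    tot <- sub$value[sub$variable == "total_transitions"]
    expect_equal(sum(tc), tot)
  }
  # probabilities are fractions
  pr <- tab$value[tab$variable == "transition_probability"]
  expect_true(all(is.na(pr) | (pr >= 0 & pr <= 1)))
})
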