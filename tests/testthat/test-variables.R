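# label map used by the worked examples: F1 F2 B1 N1 X(excluded)
lab5 <- roi_labels(c("face", "face", "body", "nonsocial", "excluded"))

test_that("the worked transition example counts by hand", {
  # F1 F1 F2 B1 N1 F1 -> face_face 1, face_body 1, mixed 2, total 4
  seq <- c(1, 1, 2, 3, 4, 1)
  tc <- count_transitions(seq, lab5)
  expect_equal(unname(tc$counts["face_face"]), 1)
  expect_equal(unname(tc$counts["face_body"]), 1)
  expect_equal(unname(tc$counts["mixed"]), 2)
  expect_equal(tc$total, 4)
  expect_equal(total_transitions(seq, lab5), 4)

  expect_equal(count_transitions(rep(1, 10), lab5)$total, 0)
  # F1 X F2: both legs touch the excluded state
  expect_equal(count_transitions(c(1, 5, 2), lab5)$total, 0)
})

test_that("counting matches the brute-force oracle with conservation", {
  set.seed(31)
  for (r in 1:200) {
    K <- sample(3:7, 1)
    cats <- sample(c("face", "body", "nonsocial", "excluded"), K,
                   replace = TRUE)
    if (all(cats == "excluded")) cats[1] <- "face"
    labs <- roi_labels(cats)
    seq <- sample.int(K, sample(1:40, 1), replace = TRUE)
    tc <- count_transitions(seq, labs)
    or <- oracle_count_transitions(seq, labs)
    expect_equal(tc$counts, or$counts)
    expect_equal(tc$total, or$total)
    expect_equal(sum(tc$counts), tc$total)  # conservation incl. mixed
  }
})

test_that("fixation and visit counts follow the visit definition", {
  # F1 F1 B1 F1 -> faces: 3 fixations, 2 visits; bodies: 1 and 1
  fv <- count_fixations_visits(c(1, 1, 3, 1), lab5, rep(250, 4))
  expect_equal(unname(fv$fixation_count["face"]), 3)
  expect_equal(unname(fv$visit_count["face"]), 2)
  expect_equal(unname(fv$fixation_count["body"]), 1)
  expect_equal(unname(fv$visit_count["body"]), 1)
  expect_equal(fv$total_fixation_duration_s, 1.0)

  fv0 <- count_fixations_visits(integer(0), lab5, numeric(0))
  expect_true(all(fv0$fixation_count == 0) && all(fv0$visit_count == 0))
  expect_equal(count_fixations_visits(c(1, 2, 3), lab5,
                                      c(200, 300, 500))$total_fixation_duration_s, 1.0)
  expect_error(count_fixations_visits(c(1, 2), lab5, c(100)),
               class = "gazehmm_validation_error")
})

test_that("visit counts equal run-length encoding restricted by category", {
  set.seed(77)
  for (r in 1:100) {
    K <- sample(3:6, 1)
    cats <- sample(c("face", "body", "nonsocial", "excluded"), K,
                   replace = TRUE)
    if (all(cats == "excluded")) cats[1] <- "body"
    labs <- roi_labels(cats)
    seq <- sample.int(K, sample(1:50, 1), replace = TRUE)
    fv <- count_fixations_visits(seq, labs, rep(100, length(seq)))
    expect_equal(fv$visit_count, oracle_visits(seq, labs))
    expect_equal(fv$fixation_count, oracle_fixations(seq, labs))
  }
})

test_that("category transition probabilities follow the hand example", {
  # F1 F2 N1 with symmetric rows [self .5, .25, .25]: remove self,
  # renormalize -> P(face->face) = .5, P(face->nonsocial) = .5
  A <- matrix(c(.5, .25, .25,
                .25, .5, .25,
                .25, .25, .5), 3, byrow = TRUE)
  labs <- roi_labels(c("face", "face", "nonsocial"))
  model <- list(K = 3, A = A)
  tp <- transition_probability(model, labs, occupancy = "uniform")
  expect_equal(unname(tp$pairs["face_face"]), 0.5)
  expect_equal(unname(tp$matrix["face", "nonsocial"]), 0.5)

  # two states, one face one body: the only destination gets probability 1
  m2 <- list(K = 2, A = matrix(c(.9, .1, .6, .4), 2, byrow = TRUE))
  tp2 <- transition_probability(m2, roi_labels(c("face", "body")),
                                occupancy = "uniform")
  expect_equal(unname(tp2$pairs["face_body"]), 1)
  expect_equal(unname(tp2$pairs["face_face"]), 0)
})

test_that("destination probabilities sum to one and ignore state relabelling", {
  set.seed(5)
  for (r in 1:20) {
    K <- sample(4:7, 1)
    cats <- sample(c("face", "body", "nonsocial"), K, replace = TRUE)
    labs <- roi_labels(cats)
    model <- random_valid_model(K)
    tp <- transition_probability(model, labs, occupancy = "stationary")
    sums <- rowSums(tp$matrix)
    expect_equal(unname(sums[!is.na(sums)]),
                 rep(1, sum(!is.na(sums))), tolerance = 1e-10)

    # permute states within categories: category probabilities unchanged
    perm <- unlist(lapply(unique(cats), function(cc) {
      idx <- which(cats == cc)
      idx[sample.int(length(idx))]
    }))
    model_p <- list(K = K, A = model$A[perm, perm])
    labs_p <- roi_labels(cats[perm])
    tp_p <- transition_probability(model_p, labs_p, occupancy = "stationary")
    expect_equal(tp_p$pairs, tp$pairs, tolerance = 1e-10)
  }
})

test_that("empty source categories yield missing, not zero", {
  m <- list(K = 2, A = matrix(c(.5, .5, .5, .5), 2))
  tp <- transition_probability(m, roi_labels(c("face", "nonsocial")),
                               occupancy = "uniform")
  expect_true(is.na(tp$pairs["body_body"]))
  expect_true(is.na(tp$pairs["body_face"]))
})

test_that("empirical transition frequencies converge to the model values", {
  set.seed(12)
  K <- 5
  cats <- c("face", "face", "body", "nonsocial", "nonsocial")
  labs <- roi_labels(cats)
  A <- matrix(rgamma(K * K, 2) + .2, K); A <- A / rowSums(A)
  # simulate a long chain
  Tn <- 10000
  st <- integer(Tn); st[1] <- 1
  for (t in 2:Tn) st[t] <- sample.int(K, 1, prob = A[st[t - 1], ])
  # empirical category frequencies among distinct-state transitions
  runs <- rle(st)$values
  emp <- matrix(0, 3, 3, dimnames = list(c("face", "body", "nonsocial"),
                                         c("face", "body", "nonsocial")))
  from_tot <- c(face = 0, body = 0, nonsocial = 0)
  for (t in seq_len(length(runs) - 1)) {
    c1 <- cats[runs[t]]; c2 <- cats[runs[t + 1]]
    emp[c1, c2] <- emp[c1, c2] + 1
    from_tot[c1] <- from_tot[c1] + 1
  }
  emp <- emp / from_tot
  g <- matrix(0, Tn, K); g[cbind(seq_len(Tn), st)] <- 1
  tp <- transition_probability(list(K = K, A = A), labs,
                               occupancy = "empirical", gamma = g)
  expect_lt(max(abs(emp - tp$matrix)), 0.02)
})

test_that("the sparse catch-all state is flagged only on both criteria", {
  base_cov <- function(s, d) {
    C <- diag(c(s^2, s^2, d))
    C
  }
  mk <- function(durs, sds) {
    K <- length(durs)
    covs <- array(0, c(3, 3, K))
    for (k in seq_len(K)) covs[, , k] <- base_cov(sds[k], .2)
    bhmm_model(rep(1 / K, K), matrix(1 / K, K, K),
               cbind(seq_len(K), seq_len(K), durs), covs)
  }
  # one broad, long-duration state: flagged
  m1 <- mk(durs = c(0, .1, 2), sds = c(.5, .6, 2.5))
  expect_equal(flag_sparse_state(m1), 3L)
  # all states identical: no winner
  m2 <- mk(durs = c(.5, .5, .5), sds = c(1, 1, 1))
  expect_true(is.na(flag_sparse_state(m2)))
  # longest durations but spatially tight: both criteria required
  m3 <- mk(durs = c(0, .1, 2), sds = c(2.5, .6, .5))
  expect_true(is.na(flag_sparse_state(m3)))
})
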