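#' Default category-level transition structure per group
#'
#' Source-by-destination category rows (face, body, nonsocial). The TD row
#' set puts 30% of distinct-ROI transitions from faces onto other faces;
#' group effects rescale the face-to-face mass (ASD 26/30, ASD+ADHD 22/30
#' by default) and redistribute the remainder proportionally, leaving ROI
#' geometry untouched — the planted mechanism is purely transitional.
#'
#' @param group `"TD"`, `"ASD"` or `"ASD_ADHD"`.
#' @param face_face_multiplier optional override of the group multiplier.
#' @return list with `group`, `cat_matrix` (3 x 3), `multiplier`.
#' @export
group_template <- function(group = c("TD", "ASD", "ASD_ADHD"),
                           face_face_multiplier = NULL) {
  group <- match.arg(group)
  base <- rbind(face      = c(face = 0.30, body = 0.11, nonsocial = 0.59),
                body      = c(face = 0.09, body = 0.38, nonsocial = 0.53),
                nonsocial = c(face = 0.44, body = 0.32, nonsocial = 0.24))
  mult <- face_face_multiplier %||%
    switch(group, TD = 1, ASD = 26 / 30, ASD_ADHD = 22 / 30)
  m <- base
  ff <- base["face", "face"] * mult
  rest <- base["face", c("body", "nonsocial")]
  m["face", ] <- c(ff, rest / sum(rest) * (1 - ff))
  list(group = group, cat_matrix = m, multiplier = mult)
}

#' Build a stimulus ROI template
#'
#' Four-actor scenes carry 12 ROIs (5 faces across the upper canvas,
#' 3 bodies below, 4 non-social including one sparse catch-all state);
#' one-actor scenes carry 9 ROIs (1 face, 1 body, 7 non-social). Spatial
#' SDs are drawn in 30-60 px; fixation durations are lognormal with median
#' ~300 ms. The sparse state gets 3x the median duration and 4x the spatial
#' SD, emulating the long-duration, regionless state that fitted models
#' devote to stray fixations.
#'
#' @param class `"four_actor"` or `"one_actor"`.
#' @param seed integer seed (same seed, same template).
#' @return list of class `gazehmm_template`: `class`, `rois` (data.frame),
#'   `canvas`.
#' @export
make_template <- function(class = c("four_actor", "one_actor"), seed = 1L) {
  class <- match.arg(class)
  set.seed(seed)
  jit <- function(n, s = 25) stats::rnorm(n, 0, s)
  if (class == "four_actor") {
    cats <- c(rep("face", 5), rep("body", 3), rep("nonsocial", 4))
    mx <- c(seq(300, 1620, length.out = 5) + jit(5),
            seq(450, 1470, length.out = 3) + jit(3),
            c(200, 960, 1720, 960) + jit(4))
    my <- c(rep(260, 5) + jit(5), rep(620, 3) + jit(3),
            c(900, 950, 900, 120) + jit(4))
  } else {
    cats <- c("face", "body", rep("nonsocial", 7))
    mx <- c(960 + jit(1), 960 + jit(1),
            c(250, 550, 1370, 1670, 350, 1570, 960) + jit(7))
    my <- c(280 + jit(1), 640 + jit(1),
            c(250, 850, 850, 250, 550, 550, 120) + jit(7))
  }
  n <- length(cats)
  sparse <- which(cats == "nonsocial")[length(which(cats == "nonsocial"))]
  sdx <- stats::runif(n, 30, 60)
  sdy <- stats::runif(n, 30, 60)
  corr <- stats::runif(n, -0.3, 0.3)
  mu_log <- log(stats::runif(n, 260, 340))
  sd_log <- rep(0.4, n)
  sdx[sparse] <- sdx[sparse] * 4
  sdy[sparse] <- sdy[sparse] * 4
  mu_log[sparse] <- log(900)
  rois <- data.frame(state = seq_len(n), category = cats,
                     mx = pmin(pmax(mx, 80), 1840),
                     my = pmin(pmax(my, 80), 1000),
                     sdx = sdx, sdy = sdy, corr = corr,
                     mu_log = mu_log, sd_log = sd_log,
                     sparse = seq_len(n) == sparse,
                     stringsAsFactors = FALSE)
  structure(list(class = class, rois = rois, canvas = c(1920, 1080)),
            class = "gazehmm_template")
}

# Expand a category matrix to a state-level transition matrix over template
# ROIs. Each row keeps `self_p` on itself, routes `excl_p` to the sparse
# state, and distributes the rest over non-sparse destinations per the
# category matrix (uniformly within a destination category, excluding the
# source state). Category mass that has no admissible destination (e.g.
# face-to-face with a single face ROI) is redistributed proportionally, so
# the analyzed category-level probabilities reproduce the category matrix
# exactly wherever they are defined.
expand_to_states <- function(template, cat_matrix, self_p = 0.05,
                             excl_p = 0.08) {
  rois <- template$rois
  n <- nrow(rois)
  A <- matrix(0, n, n)
  sparse <- which(rois$sparse)
  for (i in seq_len(n)) {
    ci <- rois$category[i]
    row <- numeric(n)
    avail <- cat_matrix[ci, ]
    dest_sets <- lapply(colnames(cat_matrix), function(c2)
      setdiff(which(rois$category == c2 & !rois$sparse), i))
    names(dest_sets) <- colnames(cat_matrix)
    empty <- vapply(dest_sets, length, 1L) == 0
    if (any(empty)) {
      avail[empty] <- 0
      avail <- avail / sum(avail)
    }
    main <- 1 - self_p - excl_p * (length(sparse) > 0 && i != sparse)
    for (c2 in colnames(cat_matrix)) {
      ds <- dest_sets[[c2]]
      if (length(ds)) row[ds] <- main * avail[c2] / length(ds)
    }
    row[i] <- row[i] + self_p
    if (length(sparse) && i != sparse)
      row[sparse] <- row[sparse] + excl_p
    A[i, ] <- row / sum(row)
  }
  A
}

#' Sample a participant-level generating model
#'
#' The participant's category transition rows are Dirichlet perturbations
#' of the group rows (`concentration` controls between-participant spread;
#' the default 20 gives SD ~0.10 on the face-to-face probability), expanded
#' to template states; emission means get small spatial jitter (SD 10 px).
#'
#' @param template a [make_template()] result.
#' @param group a [group_template()] result.
#' @param seed integer seed.
#' @param concentration Dirichlet concentration of the row jitter
#'   (`Inf` for no jitter).
#' @param mean_jitter_px SD of the ROI mean jitter.
#' @param self_p,excl_p state-level self-transition and sparse-state
#'   visitation mass.
#' @return list of class `gazehmm_truth_model`: `A` (state-level), `pi`,
#'   `rois` (jittered), `cat_matrix` (participant-level), `template_class`.
#' @export
sample_participant_model <- function(template, group, seed = 1L,
                                     concentration = 20, mean_jitter_px = 10,
                                     self_p = 0.05, excl_p = 0.08) {
  set.seed(seed)
  cm <- group$cat_matrix
  if (is.finite(concentration)) {
    for (r in seq_len(nrow(cm))) {
      g <- stats::rgamma(ncol(cm), shape = concentration * cm[r, ], rate = 1)
      if (sum(g) > 0) cm[r, ] <- g / sum(g)
    }
  }
  rois <- template$rois
  rois$mx <- rois$mx + stats::rnorm(nrow(rois), 0, mean_jitter_px)
  rois$my <- rois$my + stats::rnorm(nrow(rois), 0, mean_jitter_px)
  A <- expand_to_states(template, cm, self_p, excl_p)
  structure(list(A = A, pi = stationary_distribution(A), rois = rois,
                 cat_matrix = cm, template_class = template$class),
            class = "gazehmm_truth_model")
}

#' Simulate a scanpath from a generating model
#'
#' Samples the hidden state chain from `pi` and `A`, then for each fixation
#' a position from the state's spatial Gaussian and a duration from its
#' lognormal (truncated below at 100 ms so generated fixations stay clear
#' of the 60 ms detector minimum). Fixations are separated by a saccade gap
#' and accumulate until the recording length is reached.
#'
#' @param truth a `gazehmm_truth_model` (or compatible list).
#' @param participant_id,stimulus_id identifiers for the [scanpath()].
#' @param recording_s recording length in seconds.
#' @param seed integer seed.
#' @param gap_ms inter-fixation (saccade) gap.
#' @return list with `scanpath` and `states` (true state sequence).
#' @export
simulate_scanpath <- function(truth, participant_id = "p1",
                              stimulus_id = "s1", recording_s = 120,
                              seed = 1L, gap_ms = 30) {
  set.seed(seed)
  rois <- truth$rois
  K <- nrow(rois)
  states <- integer(0)
  ons <- dur <- xs <- ys <- numeric(0)
  t_ms <- 0
  limit <- recording_s * 1000
  k <- sample.int(K, 1, prob = truth$pi)
  repeat {
    d <- max(100, stats::rlnorm(1, rois$mu_log[k], rois$sd_log[k]))
    if (t_ms + d > limit && length(states) > 0) break
    z <- stats::rnorm(2)
    x <- rois$mx[k] + rois$sdx[k] * z[1]
    y <- rois$my[k] + rois$sdy[k] *
      (rois$corr[k] * z[1] + sqrt(1 - rois$corr[k]^2) * z[2])
    states <- c(states, k)
    ons <- c(ons, t_ms); dur <- c(dur, d); xs <- c(xs, x); ys <- c(ys, y)
    t_ms <- t_ms + d + gap_ms
    if (t_ms >= limit) break
    k <- sample.int(K, 1, prob = truth$A[k, ])
  }
  list(scanpath = scanpath(participant_id, stimulus_id,
                           data.frame(onset = ons, duration = dur,
                                      x = xs, y = ys)),
       states = states)
}

#' Render a scanpath as a raw 120 Hz sample stream
#'
#' Each fixation becomes `duration * rate` samples at the fixation point
#' plus Gaussian noise; saccade gaps (and any configured blinks) are
#' emitted as invalid samples, which break fixation-detection windows.
#'
#' @param sp a [scanpath()].
#' @param cfg a [default_config()] (for the sampling rate).
#' @param noise_px sample noise SD (>= 0).
#' @param blinks optional list `list(n = ..., duration_ms = ...)`; each
#'   blink invalidates a contiguous stretch of samples.
#' @param seed integer seed.
#' @return data.frame with `timestamp_ms`, `x`, `y`, `valid`.
#' @export
render_raw_samples <- function(sp, cfg = default_config(), noise_px = 0,
                               blinks = NULL, seed = 1L) {
  if (noise_px < 0) gh_stop("noise must be >= 0", "gazehmm_domain_error")
  set.seed(seed)
  dt <- 1000 / cfg$sample_rate_hz
  fx <- sp$fixations
  end <- max(fx$onset + fx$duration)
  ts <- seq(0, end - dt / 2, by = dt)
  n <- length(ts)
  x <- stats::runif(n, 0, cfg$resolution_x)
  y <- stats::runif(n, 0, cfg$resolution_y)
  valid <- rep(FALSE, n)
  for (i in seq_len(nrow(fx))) {
    idx <- which(ts >= fx$onset[i] & ts < fx$onset[i] + fx$duration[i])
    valid[idx] <- TRUE
    x[idx] <- fx$x[i] + stats::rnorm(length(idx), 0, noise_px)
    y[idx] <- fx$y[i] + stats::rnorm(length(idx), 0, noise_px)
  }
  if (!is.null(blinks) && blinks$n > 0) {
    len <- max(1L, round(blinks$duration_ms / dt))
    for (b in seq_len(blinks$n)) {
      s <- sample.int(max(1L, n - len), 1)
      valid[s:(s + len - 1)] <- FALSE
    }
  }
  data.frame(timestamp_ms = ts, x = x, y = y, valid = valid)
}

#' Simulate a full cohort with planted group effects
#'
#' Generates stimulus templates (two per class by default, emulating the
#' paired free-viewing stimuli), per-participant generating models and
#' 120-s scanpaths, with the face-to-face transition effect planted per
#' group. Group sizes default to 25 TD, 15 ASD+ADHD and 12 ASD.
#'
#' @param group_sizes named integer vector (names among `TD`, `ASD`,
#'   `ASD_ADHD`).
#' @param n_four,n_one recordings per participant of each stimulus class.
#' @param recording_s recording length (seconds).
#' @param seed integer master seed; all per-participant seeds derive from it.
#' @param effect named multipliers on the face-to-face mass per group
#'   (`NULL` for the Table-style defaults; set all to 1 for a null cohort).
#' @param concentration Dirichlet jitter concentration (see
#'   [sample_participant_model()]).
#' @param out_dir if non-NULL, write `fixations.csv`, `cohort.csv`,
#'   `stimuli.csv` and `truth.json` there.
#' @param cfg a [default_config()] (only used for file headers).
#' @return list of class `gazehmm_cohort`: `scanpaths`, `states` (true
#'   state sequences, parallel to `scanpaths`), `cohort` (data.frame),
#'   `stimuli` (data.frame), `templates`, `truth_models`, `seed`.
#' @export
simulate_cohort <- function(group_sizes = c(TD = 25, ASD_ADHD = 15, ASD = 12),
                            n_four = 2, n_one = 2, recording_s = 120,
                            seed = 1L, effect = NULL, concentration = 20,
                            out_dir = NULL, cfg = default_config()) {
  if (any(group_sizes < 1)) gh_stop("group sizes must be >= 1",
                                    "gazehmm_domain_error")
  groups <- names(group_sizes)
  if (!all(groups %in% c("TD", "ASD", "ASD_ADHD")))
    gh_stop("group names must be TD, ASD or ASD_ADHD", "gazehmm_domain_error")

  templates <- list()
  stimuli <- data.frame()
  if (n_four > 0) for (i in seq_len(n_four)) {
    id <- paste0("A", i)
    templates[[id]] <- make_template("four_actor", seed = seed * 100 + i)
    stimuli <- rbind(stimuli, data.frame(stimulus_id = id, actors = "four",
                                         class = "four_actor"))
  }
  if (n_one > 0) for (i in seq_len(n_one)) {
    id <- paste0("B", i)
    templates[[id]] <- make_template("one_actor", seed = seed * 100 + 50 + i)
    stimuli <- rbind(stimuli, data.frame(stimulus_id = id, actors = "one",
                                         class = "one_actor"))
  }
  if (!length(templates)) gh_stop("no stimuli requested", "gazehmm_domain_error")

  gtmpl <- lapply(setNames(groups, groups), function(g)
    group_template(g, face_face_multiplier = effect[[g]] %||% NULL))

  cohort <- data.frame(participant_id = character(0), group = character(0))
  scanpaths <- list(); states <- list(); truth_models <- list()
  pnum <- 0
  for (g in groups) {
    for (j in seq_len(group_sizes[[g]])) {
      pnum <- pnum + 1
      pid <- sprintf("P%03d", pnum)
      cohort <- rbind(cohort, data.frame(participant_id = pid, group = g))
      for (sid in names(templates)) {
        pseed <- (seed * 7919 + pnum * 131 + match(sid, names(templates))) %%
          2147483647
        tm <- sample_participant_model(templates[[sid]], gtmpl[[g]],
                                       seed = pseed,
                                       concentration = concentration)
        sim <- simulate_scanpath(tm, pid, sid, recording_s,
                                 seed = (pseed + 17) %% 2147483647)
        key <- paste(pid, sid, sep = ":")
        scanpaths[[key]] <- sim$scanpath
        states[[key]] <- sim$states
        truth_models[[key]] <- tm
      }
    }
  }

  out <- structure(list(scanpaths = scanpaths, states = states,
                        cohort = cohort, stimuli = stimuli,
                        templates = templates, truth_models = truth_models,
                        group_templates = gtmpl, seed = seed),
                   class = "gazehmm_cohort")
  if (!is.null(out_dir)) write_cohort_files(out, out_dir, cfg)
  out
}

#' Ground-truth ROI labels of a template
#'
#' Category per template ROI, with the sparse catch-all ROI excluded —
#' the label map a perfectly informed analyst would use.
#'
#' @param template a [make_template()] result.
#' @return a [roi_labels()] map.
#' @export
truth_labels <- function(template) {
  cats <- template$rois$category
  cats[template$rois$sparse] <- "excluded"
  roi_labels(cats)
}

#' Gaze-variable table from the generator's ground truth
#'
#' Computes the full variable table directly from the true state sequences
#' and true participant transition matrices, bypassing model fitting: the
#' variable-extraction and statistics stages under a perfect decoder. Used
#' for statistical calibration studies where refitting every replicate adds
#' nothing but runtime.
#'
#' @param cohort a `gazehmm_cohort` from [simulate_cohort()].
#' @param cfg a [default_config()].
#' @return data.frame in the [write_variable_table()] layout.
#' @export
variable_table_from_truth <- function(cohort, cfg = default_config()) {
  labels <- lapply(cohort$templates, truth_labels)
  group_of <- setNames(cohort$cohort$group, cohort$cohort$participant_id)
  actors_of <- setNames(cohort$stimuli$actors, cohort$stimuli$stimulus_id)
  records <- lapply(names(cohort$scanpaths), function(key) {
    sp <- cohort$scanpaths[[key]]
    st <- cohort$states[[key]]
    tm <- cohort$truth_models[[key]]
    K <- nrow(tm$A)
    g <- matrix(0, length(st), K)
    g[cbind(seq_along(st), st)] <- 1
    list(participant = sp$participant_id,
         group = group_of[[sp$participant_id]],
         stimulus = sp$stimulus_id,
         actors = actors_of[[sp$stimulus_id]],
         map_states = st, gamma = g,
         model = list(K = K, A = tm$A),
         durations_ms = sp$fixations$duration)
  })
  build_variable_table(records, labels, cfg)
}

#' @export
print.gazehmm_cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d participants x %d stimuli (%d recordings)\n",
              nrow(x$cohort), nrow(x$stimuli), length(x$scanpaths)))
  invisible(x)
}
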