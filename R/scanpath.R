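#' Construct a scanpath
#'
#' A scanpath is the ordered fixation sequence of one participant on one
#' stimulus: onsets, durations (ms) and centroid positions (px).
#'
#' @param participant_id,stimulus_id identifiers.
#' @param fixations data.frame with columns `onset`, `duration`, `x`, `y`.
#' @param min_duration_ms minimum admissible fixation duration.
#' @return Object of class `gazehmm_scanpath`.
#' @export
scanpath <- function(participant_id, stimulus_id, fixations,
                     min_duration_ms = 60) {
  need <- c("onset", "duration", "x", "y")
  if (!all(need %in% names(fixations)))
    gh_stop("fixations need columns onset, duration, x, y", "gazehmm_format_error")
  if (nrow(fixations) < 1)
    gh_stop("a scanpath needs at least one fixation", "gazehmm_validation_error")
  fixations <- fixations[order(fixations$onset), need, drop = FALSE]
  rownames(fixations) <- NULL
  if (any(fixations$duration < min_duration_ms))
    gh_stop(sprintf("participant %s, stimulus %s: fixation shorter than %g ms",
                    participant_id, stimulus_id, min_duration_ms),
            "gazehmm_validation_error")
  if (nrow(fixations) > 1) {
    ends <- fixations$onset + fixations$duration
    if (any(fixations$onset[-1] < ends[-nrow(fixations)] - 1e-9))
      gh_stop(sprintf("participant %s, stimulus %s: overlapping fixations",
                      participant_id, stimulus_id), "gazehmm_validation_error")
  }
  structure(list(participant_id = as.character(participant_id),
                 stimulus_id = as.character(stimulus_id),
                 fixations = fixations),
            class = "gazehmm_scanpath")
}

#' @export
print.gazehmm_scanpath <- function(x, ...) {
  cat(sprintf("<scanpath> participant %s, stimulus %s: %d fixations (%.1f s)\n",
              x$participant_id, x$stimulus_id, nrow(x$fixations),
              sum(x$fixations$duration) / 1000))
  invisible(x)
}

#' Fit a feature transform for model fitting
#'
#' The model operates on (x, y, duration) triples. Durations are
#' log-transformed (fixation durations are right-skewed, approximately
#' lognormal) and all three axes are standardized over the supplied
#' scanpaths, so the duration axis neither dominates nor vanishes against
#' the pixel axes. The stored means and SDs allow exact back-transformation.
#'
#' @param scanpaths list of [scanpath()] objects (typically all recordings
#'   of one stimulus).
#' @param log_duration log-transform durations before standardizing.
#' @return list of class `gazehmm_transform` with `center`, `scale`,
#'   `log_duration`.
#' @export
fit_feature_transform <- function(scanpaths, log_duration = TRUE) {
  X <- do.call(rbind, lapply(scanpaths, raw_features, log_duration = log_duration))
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl < 1e-12] <- 1
  structure(list(center = ctr, scale = scl, log_duration = log_duration),
            class = "gazehmm_transform")
}

raw_features <- function(sp, log_duration = TRUE) {
  d <- sp$fixations$duration
  if (any(d <= 0)) gh_stop("durations must be positive", "gazehmm_validation_error")
  cbind(x = sp$fixations$x, y = sp$fixations$y,
        d = if (log_duration) log(d) else d)
}

#' Apply / invert a feature transform
#'
#' @param sp a [scanpath()] (or a raw 3-column matrix for `inverse_features`).
#' @param tf a `gazehmm_transform`.
#' @return `scanpath_features()`: a T x 3 standardized feature matrix.
#'   `inverse_features()`: a matrix in pixel/ms units.
#' @export
scanpath_features <- function(sp, tf) {
  X <- raw_features(sp, tf$log_duration)
  sweep(sweep(X, 2, tf$center), 2, tf$scale, "/")
}

#' @rdname scanpath_features
#' @param Z standardized feature matrix.
#' @export
inverse_features <- function(Z, tf) {
  X <- sweep(sweep(Z, 2, tf$scale, "*"), 2, tf$center, "+")
  if (tf$log_duration) X[, 3] <- exp(X[, 3])
  X
}

# Back-transform a state mean / covariance to pixel units for the spatial
# part (x, y). Used for drift flags, sparse-state ranking and reporting.
state_mean_px <- function(mean3, tf) mean3[1:2] * tf$scale[1:2] + tf$center[1:2]
state_cov_px <- function(cov3, tf) {
  S <- cov3[1:2, 1:2]
  D <- diag(tf$scale[1:2])
  D %*% S %*% D
}
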