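#' Convert a visual angle to on-screen pixels
#'
#' Uses the exact chord formula `2 * d * tan(angle/2)` at viewing distance
#' `d`, converted through the horizontal pixel density of the screen.
#'
#' @param angle_deg visual angle in degrees (> 0).
#' @param cfg a [default_config()] list carrying the screen geometry.
#' @return Width in pixels.
#' @export
#' @examples
#' degrees_to_pixels(2, default_config())  # ~88 px at 70 cm on a 24" screen
degrees_to_pixels <- function(angle_deg, cfg = default_config()) {
  if (!is.numeric(angle_deg) || angle_deg <= 0)
    gh_stop("angle must be a positive number of degrees", "gazehmm_domain_error")
  cm <- 2 * cfg$viewing_distance_cm * tan(angle_deg * pi / 360)
  cm * cfg$resolution_x / cfg$screen_width_cm
}

#' Dispersion-threshold (I-DT) fixation detection
#'
#' Classifies raw gaze samples into fixations: maximal windows of valid
#' samples whose spatial dispersion, `max(range(x), range(y))`, stays within
#' the pixel equivalent of `dispersion_deg`, and that span at least
#' `min_fix_duration_ms`. Invalid samples (blinks, off-screen) break
#' candidate windows. The fixation position is the centroid of the window.
#'
#' @param samples data.frame with columns `timestamp_ms`, `x`, `y`, `valid`
#'   (logical), timestamps strictly increasing.
#' @param cfg a [default_config()] list (detector parameters + geometry).
#' @return data.frame with columns `onset`, `duration`, `x`, `y`, sorted and
#'   non-overlapping; zero rows if no fixation qualifies.
#' @export
detect_fixations_idt <- function(samples, cfg = default_config()) {
  need <- c("timestamp_ms", "x", "y", "valid")
  if (!all(need %in% names(samples)))
    gh_stop("samples need columns timestamp_ms, x, y, valid", "gazehmm_format_error")
  if (nrow(samples) == 0)
    return(data.frame(onset = numeric(0), duration = numeric(0),
                      x = numeric(0), y = numeric(0)))
  if (any(diff(samples$timestamp_ms) <= 0))
    gh_stop("sample timestamps must be strictly increasing", "gazehmm_validation_error")

  disp_px <- degrees_to_pixels(cfg$dispersion_deg, cfg)
  dt <- 1000 / cfg$sample_rate_hz
  out <- list()

  # segments of consecutive valid samples
  v <- samples$valid
  runs <- rle(v)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  for (r in seq_along(runs$values)) {
    if (!runs$values[r]) next
    seg <- samples[starts[r]:ends[r], , drop = FALSE]
    n <- nrow(seg)
    i <- 1
    while (i <= n) {
      # grow the smallest window spanning min duration
      j <- i
      while (j < n && (seg$timestamp_ms[j] - seg$timestamp_ms[i] + dt) <
               cfg$min_fix_duration_ms) j <- j + 1
      span_ok <- (seg$timestamp_ms[j] - seg$timestamp_ms[i] + dt) >=
        cfg$min_fix_duration_ms
      if (!span_ok) break  # segment tail too short
      disp <- function(a, b) {
        max(diff(range(seg$x[a:b])), diff(range(seg$y[a:b])))
      }
      if (disp(i, j) > disp_px) { i <- i + 1; next }
      while (j < n && disp(i, j + 1) <= disp_px) j <- j + 1
      out[[length(out) + 1]] <- data.frame(
        onset = seg$timestamp_ms[i],
        duration = seg$timestamp_ms[j] - seg$timestamp_ms[i] + dt,
        x = mean(seg$x[i:j]), y = mean(seg$y[i:j]))
      i <- j + 1
    }
  }
  if (!length(out))
    return(data.frame(onset = numeric(0), duration = numeric(0),
                      x = numeric(0), y = numeric(0)))
  res <- do.call(rbind, out)
  res[order(res$onset), , drop = FALSE]
}

#' Recording quality metrics and pass/fail decision
#'
#' Tracking ratio is the number of valid samples over the number expected
#' from the sampling rate and stimulus duration; total fixation time is the
#' summed fixation durations. A recording passes only if the tracking ratio
#' is strictly above `tracking_ratio_min` and the fixation-time fraction
#' strictly above `fixation_time_min` (boundary values fail).
#'
#' @param samples raw-sample data.frame (may be `NULL` if only fixation
#'   events are available; the ratio test is then skipped with a warning
#'   unless `tracking_ratio` is supplied).
#' @param fixations fixation data.frame with a `duration` column (ms).
#' @param stimulus_duration_ms stimulus duration (> 0).
#' @param cfg a [default_config()] list.
#' @param tracking_ratio optional precomputed ratio (used when `samples` is
#'   `NULL`, e.g. from an eye-tracker export's metadata).
#' @return list with `tracking_ratio`, `total_fixation_time`,
#'   `stimulus_duration`, `passed`, `reason`.
#' @export
compute_quality <- function(samples, fixations, stimulus_duration_ms,
                            cfg = default_config(), tracking_ratio = NULL) {
  if (!is.numeric(stimulus_duration_ms) || stimulus_duration_ms <= 0)
    gh_stop("stimulus duration must be positive", "gazehmm_domain_error")
  expected <- cfg$sample_rate_hz * stimulus_duration_ms / 1000
  if (expected <= 0) gh_stop("zero expected samples", "gazehmm_domain_error")

  if (is.null(samples)) {
    ratio <- tracking_ratio
    if (is.null(ratio)) {
      warning("no raw samples or tracking ratio supplied; skipping ratio test")
      ratio <- NA_real_
    }
  } else {
    ratio <- sum(samples$valid) / expected
  }
  fix_time <- sum(fixations$duration)
  frac <- fix_time / stimulus_duration_ms

  ratio_ok <- is.na(ratio) || ratio > cfg$tracking_ratio_min
  time_ok <- frac > cfg$fixation_time_min
  reason <- c(if (!ratio_ok) sprintf("tracking ratio %.3f <= %.2f", ratio,
                                     cfg$tracking_ratio_min),
              if (!time_ok) sprintf("fixation time fraction %.3f <= %.2f",
                                    frac, cfg$fixation_time_min))
  list(tracking_ratio = ratio,
       total_fixation_time = fix_time,
       stimulus_duration = stimulus_duration_ms,
       passed = ratio_ok && time_ok,
       reason = if (length(reason)) paste(reason, collapse = "; ") else "")
}

#' Drop fixations whose centroid falls off the screen
#'
#' Keeps fixations with centroid inside `[0, resolution)` on both axes
#' (half-open: the last addressable pixel row/column is on-screen).
#'
#' @param fixations fixation data.frame with `x`, `y`.
#' @param cfg a [default_config()] list.
#' @return The filtered data.frame, original order preserved.
#' @export
exclude_invalid_fixations <- function(fixations, cfg = default_config()) {
  keep <- fixations$x >= 0 & fixations$x < cfg$resolution_x &
    fixations$y >= 0 & fixations$y < cfg$resolution_y
  fixations[keep, , drop = FALSE]
}
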