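# File formats. All tabular artifacts are UTF-8 comma-separated CSV with a
# mandatory header row, '.' decimal, and '#'-prefixed provenance comment
# lines (config hash + seed) above the header. Coordinates are pixels with
# the origin top-left; times are milliseconds.

provenance_header <- function(cfg, seed) {
  c(sprintf("# gazehmm config_hash=%s seed=%s", config_hash(cfg),
            format(seed)))
}

write_table_with_header <- function(df, path, cfg, seed) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(cfg, seed), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a fixation-event table into scanpaths
#'
#' Expects columns `participant_id`, `stimulus_id`, `onset_ms`,
#' `duration_ms`, `x_px`, `y_px` (optionally `tracking_ratio`). Rows are
#' grouped into one [scanpath()] per participant-by-stimulus, sorted by
#' onset. Malformed rows are reported with their line numbers; overlapping
#' fixations raise a validation error naming the participant.
#'
#' @param path CSV file path.
#' @param cfg a [default_config()] (minimum fixation duration).
#' @return named list of [scanpath()] objects (`"participant:stimulus"`),
#'   with a `tracking_ratio` attribute when the column is present.
#' @export
read_fixation_table <- function(path, cfg = default_config()) {
  if (!file.exists(path)) gh_stop(paste0("file not found: ", path),
                                  "gazehmm_io_error")
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("participant_id", "stimulus_id", "onset_ms", "duration_ms",
            "x_px", "y_px")
  miss <- setdiff(need, names(df))
  if (length(miss))
    gh_stop(paste0("missing required column(s): ", paste(miss, collapse = ", ")),
            "gazehmm_format_error")
  num <- c("onset_ms", "duration_ms", "x_px", "y_px")
  for (cc in num) df[[cc]] <- suppressWarnings(as.numeric(df[[cc]]))
  bad <- which(!stats::complete.cases(df[num]) | df$duration_ms <= 0 |
                 df$onset_ms < 0)
  if (length(bad))
    gh_stop(paste0("malformed data row(s) (1-based, excluding header/comments): ",
                   paste(head(bad, 20), collapse = ", ")),
            "gazehmm_format_error")
  keys <- paste(df$participant_id, df$stimulus_id, sep = ":")
  out <- lapply(split(df, keys), function(d)
    scanpath(d$participant_id[1], d$stimulus_id[1],
             data.frame(onset = d$onset_ms, duration = d$duration_ms,
                        x = d$x_px, y = d$y_px),
             min_duration_ms = cfg$min_fix_duration_ms))
  if ("tracking_ratio" %in% names(df)) {
    tr <- vapply(split(df$tracking_ratio, keys), function(v) v[1], 0)
    attr(out, "tracking_ratio") <- tr
  }
  out
}

#' Write scanpaths as a fixation-event table
#'
#' @param scanpaths list of [scanpath()] objects.
#' @param path output CSV path.
#' @param cfg,seed provenance recorded in the header comment.
#' @return `path`, invisibly.
#' @export
write_fixation_table <- function(scanpaths, path, cfg = default_config(),
                                 seed = cfg$seed) {
  rows <- lapply(scanpaths, function(sp)
    data.frame(participant_id = sp$participant_id,
               stimulus_id = sp$stimulus_id,
               onset_ms = sp$fixations$onset,
               duration_ms = sp$fixations$duration,
               x_px = sp$fixations$x, y_px = sp$fixations$y))
  df <- do.call(rbind, rows)
  df <- df[order(df$participant_id, df$stimulus_id, df$onset_ms), ]
  write_table_with_header(df, path, cfg, seed)
}

#' Read / write the cohort table (participant -> group)
#' @param path CSV path.
#' @return `read_cohort_table()` returns a data.frame with `participant_id`
#'   and `group` (levels TD, ASD, ASD_ADHD).
#' @export
read_cohort_table <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("participant_id", "group") %in% names(df)))
    gh_stop("cohort file needs columns participant_id, group",
            "gazehmm_format_error")
  bad <- !df$group %in% c("TD", "ASD", "ASD_ADHD")
  if (any(bad))
    gh_stop(paste0("unknown group label(s): ",
                   paste(unique(df$group[bad]), collapse = ", ")),
            "gazehmm_format_error")
  if (anyDuplicated(df$participant_id))
    gh_stop("cohort file must have one row per participant",
            "gazehmm_format_error")
  df
}

#' Write a long-format gaze-variable table
#'
#' Columns: participant, group, stimulus, actors, variable, category,
#' value; rows ordered by (participant, stimulus, variable, category) so
#' repeated runs are byte-identical.
#'
#' @param table non-empty data.frame in the layout above.
#' @param path output CSV path.
#' @param cfg,seed provenance for the header comment.
#' @return `path`, invisibly.
#' @export
write_variable_table <- function(table, path, cfg = default_config(),
                                 seed = cfg$seed) {
  need <- c("participant", "group", "stimulus", "actors", "variable",
            "category", "value")
  if (!all(need %in% names(table)))
    gh_stop("variable table missing required columns", "gazehmm_format_error")
  if (nrow(table) == 0)
    gh_stop("refusing to write an empty variable table", "gazehmm_validation_error")
  table <- table[order(table$participant, table$stimulus, table$variable,
                       table$category), need]
  write_table_with_header(table, path, cfg, seed)
}

#' @rdname write_variable_table
#' @export
read_variable_table <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  df$value <- as.numeric(df$value)
  df
}

#' Serialize / deserialize a fitted model as JSON text
#'
#' Stores K, the feature transform, `pi`, the transition matrix (row-major)
#' and per-state means and covariances at full precision; round-trips to
#' better than 1e-12.
#'
#' @param model a [bhmm_model()].
#' @param path file path.
#' @return `read_bhmm()` returns a [bhmm_model()].
#' @export
write_bhmm <- function(model, path) {
  obj <- list(K = model$K,
              transform = if (!is.null(model$transform))
                list(center = unname(model$transform$center),
                     scale = unname(model$transform$scale),
                     log_duration = model$transform$log_duration),
              pi = model$pi,
              A = as.vector(t(model$A)),
              means = lapply(seq_len(model$K), function(k)
                unname(model$means[k, ])),
              covs = lapply(seq_len(model$K), function(k)
                as.vector(model$covs[, , k])))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_bhmm
#' @export
read_bhmm <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  K <- obj$K
  # per-state lists of equal length may come back simplified to matrices
  means <- if (is.matrix(obj$means)) obj$means else
    do.call(rbind, obj$means)
  D <- ncol(means)
  covs <- array(0, c(D, D, K))
  for (k in seq_len(K)) {
    v <- if (is.matrix(obj$covs)) obj$covs[k, ] else obj$covs[[k]]
    covs[, , k] <- matrix(v, D, D)
  }
  tf <- if (!is.null(obj$transform))
    structure(list(center = obj$transform$center,
                   scale = obj$transform$scale,
                   log_duration = obj$transform$log_duration),
              class = "gazehmm_transform")
  bhmm_model(pi = obj$pi, A = matrix(obj$A, K, K, byrow = TRUE),
             means = means, covs = covs, transform = tf)
}

# Write the cohort artifacts produced by simulate_cohort().
write_cohort_files <- function(cohort, dir, cfg = default_config()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fixation_table(cohort$scanpaths, file.path(dir, "fixations.csv"),
                       cfg, cohort$seed)
  write_table_with_header(cohort$cohort, file.path(dir, "cohort.csv"),
                          cfg, cohort$seed)
  write_table_with_header(cohort$stimuli, file.path(dir, "stimuli.csv"),
                          cfg, cohort$seed)
  truth <- list(seed = cohort$seed,
                states = cohort$states,
                cat_matrices = lapply(cohort$truth_models, `[[`, "cat_matrix"),
                templates = lapply(cohort$templates, function(t)
                  list(class = t$class,
                       rois = t$rois[c("state", "category", "mx", "my",
                                       "sdx", "sdy", "sparse")])))
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read the generator ground truth written alongside a synthetic cohort
#'
#' @param path path to a `truth.json` produced by [simulate_cohort()] with
#'   `out_dir` set.
#' @return list with `seed`, `states`, `cat_matrices` and `templates`
#'   (reconstructed `gazehmm_template` objects usable for labelling).
#' @export
read_truth <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$templates <- lapply(obj$templates, function(t)
    structure(list(class = t$class, rois = as.data.frame(t$rois),
                   canvas = c(1920, 1080)), class = "gazehmm_template"))
  obj$states <- lapply(obj$states, as.integer)
  obj
}
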