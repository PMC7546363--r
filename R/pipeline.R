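#' Label representative states from a generator template
#'
#' Convenience for synthetic cohorts: each representative state is given
#' the category of the nearest template ROI (spatial means, pixel space);
#' states matched to the template's sparse catch-all ROI are labelled
#' `"excluded"`. For real data the label map comes from a user-curated ROI
#' label file instead ([read_roi_labels()]).
#'
#' Besides matching, states with no regional pattern are excluded: a state
#' whose fitted spatial footprint (square root of the spatial covariance
#' determinant, an area) exceeds `exclude_spread_ratio` times the footprint
#' of its matched template ROI is a catch-all for scattered fixations, the
#' construct the analysis drops, not a semantic region.
#'
#' @param representative a `gazehmm_representative`.
#' @param template a [make_template()] result.
#' @param exclude_spread_ratio area ratio above which a state is treated as
#'   a regionless catch-all and excluded.
#' @return a [roi_labels()] map.
#' @export
label_states_from_template <- function(representative, template,
                                       exclude_spread_ratio = 8) {
  tf <- representative$transform
  model <- representative$model
  px <- t(apply(model$means, 1, state_mean_px, tf = tf))
  rois <- template$rois
  cats <- vapply(seq_len(model$K), function(k) {
    d2 <- (rois$mx - px[k, 1])^2 + (rois$my - px[k, 2])^2
    i <- which.min(d2)
    if (rois$sparse[i]) return("excluded")
    area_fit <- sqrt(max(det(state_cov_px(model$covs[, , k], tf)), 0))
    area_roi <- rois$sdx[i] * rois$sdy[i]
    if (area_fit > exclude_spread_ratio * area_roi) return("excluded")
    rois$category[i]
  }, "")
  roi_labels(cats)
}

#' Quality-control a set of scanpaths
#'
#' @param scanpaths named list of [scanpath()] objects (from
#'   [read_fixation_table()] or [simulate_cohort()]).
#' @param stimulus_duration_ms recording length.
#' @param cfg a [default_config()].
#' @param tracking_ratios optional named vector (by scanpath key); absent
#'   ratios skip the ratio test (logged once).
#' @return data.frame: participant, stimulus, tracking_ratio,
#'   fixation_time_fraction, passed, reason.
#' @export
qc_scanpaths <- function(scanpaths, stimulus_duration_ms = 120000,
                         cfg = default_config(), tracking_ratios = NULL) {
  if (is.null(tracking_ratios)) {
    message("no tracking ratios available; QC uses the fixation-time test only")
    tracking_ratios <- setNames(rep(NA_real_, length(scanpaths)),
                                names(scanpaths))
  }
  rows <- lapply(names(scanpaths), function(key) {
    sp <- scanpaths[[key]]
    q <- compute_quality(NULL, sp$fixations, stimulus_duration_ms, cfg,
                         tracking_ratio = tracking_ratios[[key]] %||% NA_real_)
    data.frame(participant = sp$participant_id, stimulus = sp$stimulus_id,
               tracking_ratio = q$tracking_ratio,
               fixation_time_fraction =
                 q$total_fixation_time / q$stimulus_duration,
               passed = q$passed, reason = q$reason)
  })
  do.call(rbind, rows)
}

#' Build the long-format gaze-variable table
#'
#' One row per participant x stimulus x variable x category: the five
#' category-pair transition counts (+ mixed), the five transition
#' probabilities, fixation and visit counts per ROI category, total
#' transition count and total fixation duration.
#'
#' @param records list of per-recording results, each with `participant`,
#'   `group`, `stimulus`, `actors`, `map_states`, `gamma`, `model`
#'   (individual [bhmm_model()]), `durations_ms`.
#' @param labels_by_stimulus named list of [roi_labels()] per stimulus id.
#' @param cfg a [default_config()].
#' @return data.frame in the [write_variable_table()] layout.
#' @export
build_variable_table <- function(records, labels_by_stimulus,
                                 cfg = default_config()) {
  rows <- list()
  for (rec in records) {
    labels <- labels_by_stimulus[[rec$stimulus]]
    tc <- count_transitions(rec$map_states, labels)
    tp <- transition_probability(rec$model, labels,
                                 occupancy = cfg$occupancy,
                                 gamma = rec$gamma)
    fv <- count_fixations_visits(rec$map_states, labels, rec$durations_ms)
    base <- data.frame(participant = rec$participant, group = rec$group,
                       stimulus = rec$stimulus, actors = rec$actors,
                       stringsAsFactors = FALSE)
    add <- function(variable, category, value)
      cbind(base, data.frame(variable = variable, category = category,
                             value = unname(value)))
    rows[[length(rows) + 1]] <- rbind(
      do.call(rbind, lapply(names(tc$counts), function(p)
        add("transition_count", p, tc$counts[[p]]))),
      do.call(rbind, lapply(names(tp$pairs), function(p)
        add("transition_probability", p, tp$pairs[[p]]))),
      do.call(rbind, lapply(names(fv$fixation_count), function(cc)
        add("fixation_count", cc, fv$fixation_count[[cc]]))),
      do.call(rbind, lapply(names(fv$visit_count), function(cc)
        add("visit_count", cc, fv$visit_count[[cc]]))),
      add("total_transitions", "all", tc$total),
      add("total_fixation_duration", "all", fv$total_fixation_duration_s))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$participant, out$stimulus, out$variable, out$category), ]
}

#' Run the full analysis pipeline
#'
#' Quality control, representative model per stimulus (Step 1), individual
#' models initialised from it (Step 2), ROI semantics, gaze variables and
#' the mixed-effects group comparison. Identical inputs, config and seed
#' give identical outputs.
#'
#' @param cohort a `gazehmm_cohort` from [simulate_cohort()], or a list
#'   with `scanpaths` (named `"participant:stimulus"`), `cohort`
#'   (participant/group data.frame), `stimuli` (stimulus_id/actors) and
#'   optionally `templates` for automatic labelling.
#' @param cfg a [default_config()].
#' @param labels `"auto_template"` (label representative states from the
#'   generator templates; synthetic cohorts only) or a named list of
#'   [roi_labels()] per stimulus id.
#' @param stimulus_duration_ms recording length used by QC.
#' @param seed integer seed for all fitting stages.
#' @param stats fit the full mixed-model battery (`FALSE` returns the
#'   variable table without the report, for callers running their own
#'   models).
#' @return list of class `gazehmm_result`: `qc`, `representatives`,
#'   `individuals`, `labels`, `sparse_flags`, `table`, `report`, `cfg`,
#'   `seed`.
#' @export
run_pipeline <- function(cohort, cfg = default_config(),
                         labels = "auto_template",
                         stimulus_duration_ms = 120000, seed = cfg$seed,
                         stats = TRUE) {
  validate_config(cfg)
  scanpaths <- cohort$scanpaths
  stimuli <- cohort$stimuli
  cohort_df <- cohort$cohort

  qc <- qc_scanpaths(scanpaths, stimulus_duration_ms, cfg,
                     tracking_ratios = attr(scanpaths, "tracking_ratio"))
  keep <- qc$passed
  if (!any(keep))
    gh_stop("all recordings excluded by quality control", "gazehmm_qc_error")
  kept_keys <- paste(qc$participant, qc$stimulus, sep = ":")[keep]
  message(sprintf("stage=qc in=%d out=%d seed=%d", nrow(qc), sum(keep), seed))

  group_of <- setNames(cohort_df$group, cohort_df$participant_id)
  actors_of <- setNames(stimuli$actors, stimuli$stimulus_id)

  representatives <- list(); individuals <- list()
  label_maps <- list(); sparse_flags <- list()
  records <- list()
  for (sid in stimuli$stimulus_id) {
    sps <- scanpaths[kept_keys[endsWith(kept_keys, paste0(":", sid))]]
    if (length(sps) < 2)
      gh_stop(sprintf("stimulus %s: fewer than 2 recordings pass QC", sid),
              "gazehmm_qc_error")
    rep_fit <- fit_representative(sps, cfg, seed = seed)
    representatives[[sid]] <- rep_fit
    message(sprintf("stage=fit_representative stimulus=%s K=%d n=%d seed=%d",
                    sid, rep_fit$model$K, length(sps), seed))
    sparse_flags[[sid]] <- flag_sparse_state(rep_fit)

    label_maps[[sid]] <- if (identical(labels, "auto_template")) {
      if (is.null(cohort$templates))
        gh_stop("auto_template labelling needs generator templates",
                "gazehmm_validation_error")
      label_states_from_template(rep_fit, cohort$templates[[sid]])
    } else labels[[sid]]

    for (key in names(sps)) {
      sp <- sps[[key]]
      ind <- tryCatch(fit_individual(sp, rep_fit, cfg, seed = seed),
                      gazehmm_infeasible_error = function(e) NULL)
      if (is.null(ind)) next  # flagged: too short for model-based variables
      individuals[[key]] <- ind
      dec <- decode(ind$model, sp)
      records[[key]] <- list(participant = sp$participant_id,
                             group = group_of[[sp$participant_id]],
                             stimulus = sid,
                             actors = actors_of[[sid]],
                             map_states = dec$map_states,
                             gamma = dec$gamma,
                             model = ind$model,
                             durations_ms = sp$fixations$duration)
    }
  }

  table <- build_variable_table(records, label_maps, cfg)
  report <- if (stats) run_all_models(table, cfg)
  structure(list(qc = qc, representatives = representatives,
                 individuals = individuals, labels = label_maps,
                 sparse_flags = sparse_flags, table = table,
                 report = report, cfg = cfg, seed = seed),
            class = "gazehmm_result")
}

#' @export
print.gazehmm_result <- function(x, ...) {
  cat(sprintf("<pipeline result> %d recordings passed QC; %d stimuli; %d models fit\n",
              sum(x$qc$passed), length(x$representatives),
              length(x$individuals)))
  if (!is.null(x$report)) print(x$report)
  invisible(x)
}
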