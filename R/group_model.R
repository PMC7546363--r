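#' Fit the representative (group-level) model for one stimulus
#'
#' Step 1 of the two-step procedure: scanpaths of all participants are
#' clustered into representative ROIs. Two modes are supported. `"pooled"`
#' (default) fits one Bayesian HMM to the pooled scanpath collection,
#' selecting the state count by ELBO over `cfg$k_range`. `"vhem"` fits one
#' model per participant and reduces the ensemble with [vhem_reduce()].
#'
#' @param scanpaths list of [scanpath()] objects (all participants, one
#'   stimulus).
#' @param cfg a [default_config()].
#' @param transform shared feature transform; fitted from `scanpaths` when
#'   `NULL`.
#' @param seed integer seed.
#' @return Object of class `gazehmm_representative`: `model`, `posterior`
#'   (pooled mode), `provenance`, `participants`, `elbos`, `transform`.
#' @export
fit_representative <- function(scanpaths, cfg = default_config(),
                               transform = NULL, seed = cfg$seed) {
  participants <- unique(vapply(scanpaths, `[[`, "", "participant_id"))
  if (is.null(transform))
    transform <- fit_feature_transform(scanpaths, cfg$log_duration)

  if (cfg$representative_mode == "pooled") {
    sel <- select_state_count(scanpaths, cfg$k_range, cfg, transform,
                              restarts = cfg$restarts, seed = seed)
    fit <- sel$fits[[as.character(sel$K)]]
    rep_model <- fit$model
    out <- list(model = rep_model, posterior = fit$posterior,
                provenance = "pooled", participants = participants,
                elbos = sel$elbos, transform = transform)
  } else {
    by_p <- split(scanpaths,
                  vapply(scanpaths, `[[`, "", "participant_id"))
    indiv <- lapply(seq_along(by_p), function(i) {
      sel <- select_state_count(by_p[[i]], cfg$k_range, cfg, transform,
                                restarts = cfg$restarts, seed = seed + i)
      sel$fits[[as.character(sel$K)]]$model
    })
    K_target <- if (length(cfg$k_range) == 1) cfg$k_range else
      as.integer(round(stats::median(vapply(indiv, function(m) m$K, 1L))))
    rep_model <- vhem_reduce(indiv, K_target, seed = seed)
    out <- list(model = rep_model, posterior = NULL, provenance = "vhem",
                participants = participants, elbos = NULL,
                transform = transform)
  }
  class(out) <- "gazehmm_representative"
  out
}

#' @export
print.gazehmm_representative <- function(x, ...) {
  cat(sprintf("<representative model> K = %d (%s) from %d participants\n",
              x$model$K, x$provenance, length(x$participants)))
  invisible(x)
}

#' Fit an individual model initialised from the representative ROIs
#'
#' Step 2: the participant's scanpath is modelled by a Bayesian HMM with
#' the representative state count, initialised from the representative
#' parameters (the first E-step decodes the scanpath under the
#' representative model). State correspondence to the representative states
#' is the identity by construction; it is verified by nearest-mean matching
#' and any state whose spatial mean drifts beyond `cfg$drift_flag_px` from
#' its representative counterpart is flagged.
#'
#' With `cfg$individual_emission = "anchored"`, emissions additionally
#' carry an informative Normal-Wishart prior centred on the representative
#' states; the default `"free"` re-estimates them under the standard
#' data-driven prior.
#'
#' @param sp a [scanpath()] that passed quality control.
#' @param representative a `gazehmm_representative`.
#' @param cfg a [default_config()].
#' @param seed integer seed.
#' @return Object of class `gazehmm_individual`: `participant_id`,
#'   `stimulus_id`, `model`, `posterior`, `correspondence` (data.frame),
#'   `drift_flagged`.
#' @export
fit_individual <- function(sp, representative, cfg = default_config(),
                           seed = cfg$seed) {
  rep_model <- representative$model
  K <- rep_model$K
  if (nrow(sp$fixations) < K)
    gh_stop(sprintf("participant %s: scanpath shorter than K = %d",
                    sp$participant_id, K), "gazehmm_infeasible_error")
  tf <- representative$transform
  X <- scanpath_features(sp, tf)
  init <- decode(rep_model, X)

  prior <- if (cfg$individual_emission == "anchored")
    anchored_prior(X, rep_model) else NULL
  fit <- vbem_fit(list(sp), K, cfg, transform = tf, restarts = 1,
                  seed = seed, init_gamma = list(init$gamma), prior = prior)

  rep_px <- t(apply(rep_model$means, 1, state_mean_px, tf = tf))
  ind_px <- t(apply(fit$model$means, 1, state_mean_px, tf = tf))
  drift <- sqrt(rowSums((ind_px - rep_px)^2))
  # nearest representative state for each individual state (verification)
  nearest <- apply(ind_px, 1, function(p)
    which.min(colSums((t(rep_px) - p)^2)))
  corr <- data.frame(individual_state = seq_len(K),
                     representative_state = seq_len(K),
                     nearest_representative = as.integer(nearest),
                     mean_drift_px = drift,
                     flagged = drift > cfg$drift_flag_px)
  structure(list(participant_id = sp$participant_id,
                 stimulus_id = sp$stimulus_id,
                 model = fit$model, posterior = fit$posterior,
                 correspondence = corr,
                 drift_flagged = any(corr$flagged)),
            class = "gazehmm_individual")
}
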