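#' Default pipeline configuration
#'
#' Returns the full set of pipeline settings with documented defaults.
#' Quality thresholds, the fixation-detector parameters and the screen
#' geometry follow the recording setup the pipeline emulates (70 cm viewing
#' distance, 24-inch 1920 x 1080 screen, 120 Hz tracker, fixations of at
#' least 60 ms within 2 degrees dispersion; recordings kept only with a
#' tracking ratio above 75 percent and total fixation time above 50 percent
#' of the stimulus duration).
#'
#' @param ... named overrides of individual settings.
#' @return A list of class `gazehmm_config`.
#' @export
#' @examples
#' cfg <- default_config(restarts = 2, k_range = 2:6)
#' cfg$dispersion_deg
default_config <- function(...) {
  cfg <- list(
    # quality control (strict inequalities)
    tracking_ratio_min   = 0.75,
    fixation_time_min    = 0.50,
    # fixation detection
    min_fix_duration_ms  = 60,
    dispersion_deg       = 2,
    sample_rate_hz       = 120,
    # screen geometry: 24" 16:9 at 70 cm
    viewing_distance_cm  = 70,
    screen_width_cm      = 53.1,
    screen_height_cm     = 29.9,
    resolution_x         = 1920,
    resolution_y         = 1080,
    # model fitting
    k_range              = 1:15,
    restarts             = 5,
    max_iter             = 300,
    elbo_tol             = 1e-6,
    seed                 = 1L,
    log_duration         = TRUE,
    representative_mode  = "pooled",   # or "vhem"
    individual_emission  = "free",     # or "anchored"
    drift_flag_px        = 150,
    occupancy            = "empirical", # or "stationary", "uniform"
    # statistics
    reml                 = TRUE,
    alpha                = 0.05,
    p_adjust             = "none"      # or "BH"
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(cfg))
    if (length(bad)) gh_stop(paste0("unknown config keys: ",
                                    paste(bad, collapse = ", ")),
                             "gazehmm_config_error")
    cfg[names(over)] <- over
  }
  class(cfg) <- "gazehmm_config"
  validate_config(cfg)
  cfg
}

#' Validate a pipeline configuration
#'
#' @param cfg a `gazehmm_config` list.
#' @return `cfg`, invisibly, if valid; otherwise an error.
#' @export
validate_config <- function(cfg) {
  chk <- function(ok, msg) if (!isTRUE(ok)) gh_stop(msg, "gazehmm_config_error")
  chk(cfg$tracking_ratio_min > 0 && cfg$tracking_ratio_min <= 1,
      "tracking_ratio_min must be in (0, 1]")
  chk(cfg$fixation_time_min > 0 && cfg$fixation_time_min <= 1,
      "fixation_time_min must be in (0, 1]")
  chk(cfg$min_fix_duration_ms > 0, "min_fix_duration_ms must be positive")
  chk(cfg$dispersion_deg > 0, "dispersion_deg must be positive")
  chk(length(cfg$k_range) >= 1 && min(cfg$k_range) >= 1,
      "k_range must be non-empty with minimum >= 1")
  chk(cfg$restarts >= 1, "restarts must be >= 1")
  chk(all(c(cfg$viewing_distance_cm, cfg$screen_width_cm, cfg$screen_height_cm,
            cfg$resolution_x, cfg$resolution_y) > 0),
      "screen geometry values must be positive")
  chk(cfg$representative_mode %in% c("pooled", "vhem"),
      "representative_mode must be 'pooled' or 'vhem'")
  chk(cfg$occupancy %in% c("empirical", "stationary", "uniform"),
      "occupancy must be 'empirical', 'stationary' or 'uniform'")
  invisible(cfg)
}

#' Read / write a configuration as a flat key=value text file
#'
#' @param path file path.
#' @return `read_config()` returns a `gazehmm_config`;
#'   `write_config()` returns `path` invisibly.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) gh_stop(paste0("config file not found: ", path),
                                  "gazehmm_io_error")
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- vapply(kv, length, 1L) != 2L
  if (any(bad)) gh_stop(paste0("malformed config line(s): ",
                               paste(which(bad), collapse = ", ")),
                        "gazehmm_io_error")
  keys <- trimws(vapply(kv, `[[`, "", 1L))
  vals <- trimws(vapply(kv, `[[`, "", 2L))
  parse_val <- function(v) {
    if (grepl("^-?[0-9][0-9.eE+:-]*$", v)) {
      if (grepl(":", v, fixed = TRUE)) {
        rng <- as.integer(strsplit(v, ":", fixed = TRUE)[[1]])
        return(rng[1]:rng[2])
      }
      return(as.numeric(v))
    }
    if (v %in% c("TRUE", "FALSE")) return(as.logical(v))
    v
  }
  do.call(default_config, setNames(lapply(vals, parse_val), keys))
}

#' @rdname read_config
#' @param cfg a `gazehmm_config`.
#' @export
write_config <- function(cfg, path) {
  fmt <- function(v) {
    if (length(v) > 1 && is.numeric(v) && all(diff(v) == 1))
      return(paste0(v[1], ":", v[length(v)]))
    as.character(v)
  }
  writeLines(c("# gazehmm configuration",
               paste0(names(cfg), " = ", vapply(cfg, fmt, ""))), path)
  invisible(path)
}

# Short stable hash of a config for output provenance headers.
config_hash <- function(cfg) {
  s <- paste(names(cfg), vapply(cfg, function(v) paste(format(v), collapse = ","), ""),
             sep = "=", collapse = ";")
  # simple polynomial rolling hash; avoids an external digest dependency
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}
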