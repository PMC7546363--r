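#' Specification of one mixed-effects model
#'
#' Fixed effects are clinical group, number of depicted actors and their
#' interaction; the covariate (mean-centered) is the total transition count
#' for transition-count responses, the total fixation duration for fixation
#' and visit counts, and none for probability responses; participants get a
#' random intercept.
#'
#' @param variable response variable name in the long table.
#' @param category ROI category (or category pair) of the response.
#' @param covariate `"total_transitions"`, `"total_fixation_duration"` or
#'   `NA` for none.
#' @return list of class `gazehmm_lmm_spec`.
#' @export
lmm_spec <- function(variable, category, covariate = NA_character_) {
  if (!is.na(covariate) &&
      !covariate %in% c("total_transitions", "total_fixation_duration"))
    gh_stop("unknown covariate", "gazehmm_validation_error")
  structure(list(variable = variable, category = category,
                 covariate = covariate), class = "gazehmm_lmm_spec")
}

#' Center a covariate column of the long variable table at its grand mean
#'
#' Rows whose `variable` equals `covariate` have their values replaced by
#' deviations from the grand mean; re-centering is a no-op.
#'
#' @param table long-format variable table.
#' @param covariate variable name to center.
#' @return The table with the covariate centered.
#' @export
center_covariate <- function(table, covariate) {
  idx <- table$variable == covariate
  if (!any(idx)) gh_stop(paste0("covariate not in table: ", covariate),
                         "gazehmm_validation_error")
  if (anyNA(table$value[idx]))
    gh_stop(paste0("missing covariate values in rows: ",
                   paste(which(idx & is.na(table$value)), collapse = ", ")),
            "gazehmm_validation_error")
  table$value[idx] <- table$value[idx] - mean(table$value[idx])
  table
}

# Assemble the analysis frame for one model: one row per participant x
# stimulus with the response, design factors and (centered) covariate.
lmm_frame <- function(table, spec) {
  resp <- table[table$variable == spec$variable &
                  table$category == spec$category, ]
  if (!nrow(resp)) gh_stop(sprintf("no rows for %s / %s", spec$variable,
                                   spec$category), "gazehmm_validation_error")
  df <- data.frame(participant = resp$participant,
                   group = resp$group, stimulus = resp$stimulus,
                   actors = resp$actors, value = resp$value)
  if (!is.na(spec$covariate)) {
    cov <- table[table$variable == spec$covariate, ]
    key <- paste(df$participant, df$stimulus)
    ckey <- paste(cov$participant, cov$stimulus)
    m <- match(key, ckey)
    if (anyNA(m))
      gh_stop(paste0("covariate missing for rows: ",
                     paste(which(is.na(m)), collapse = ", ")),
              "gazehmm_validation_error")
    df$covariate <- cov$value[m] - mean(cov$value[m])
  }
  df <- df[!is.na(df$value), ]
  df$group <- factor(df$group, levels = intersect(c("TD", "ASD", "ASD_ADHD"),
                                                  unique(df$group)))
  df$actors <- factor(df$actors)
  df
}

#' Fit one linear mixed-effects group-comparison model
#'
#' REML fit of
#' `value ~ 1 + group + actors + group:actors + covariate + (1 | participant)`
#' (the covariate mean-centered; dropped for probability variables, and the
#' actor terms dropped when only one actor condition is present). The group
#' effect is tested with a Type-III F test with Satterthwaite degrees of
#' freedom; estimated marginal means are evaluated at covariate 0 and
#' balanced actor conditions, with unadjusted contrasts of each clinical
#' group against TD.
#'
#' @param table long-format variable table.
#' @param spec a [lmm_spec()].
#' @param cfg a [default_config()] (REML flag, alpha).
#' @return list of class `gazehmm_lmm_result`: `spec`, `n`, `F_group`,
#'   `df_group`, `p_group`, `emmeans` (data.frame), `contrasts`
#'   (data.frame), `singular`, `converged`.
#' @export
fit_lmm <- function(table, spec, cfg = default_config()) {
  df <- lmm_frame(table, spec)
  if (nlevels(df$group) < 2)
    gh_stop("need at least two groups", "gazehmm_validation_error")
  has_actors <- nlevels(df$actors) > 1
  has_cov <- !is.na(spec$covariate)
  rhs <- paste(c("group",
                 if (has_actors) c("actors", "group:actors"),
                 if (has_cov) "covariate",
                 "(1 | participant)"), collapse = " + ")
  form <- stats::as.formula(paste("value ~ 1 +", rhs))
  ctr <- c(list(group = "contr.sum"),
           if (has_actors) list(actors = "contr.sum"))
  fit <- lmerTest::lmer(form, data = df, REML = cfg$reml, contrasts = ctr)
  singular <- lme4::isSingular(fit, tol = 1e-5)
  conv <- length(fit@optinfo$conv$lme4$messages) == 0

  a3 <- stats::anova(fit, type = 3)
  F_group <- a3["group", "F value"]
  p_group <- a3["group", "Pr(>F)"]
  df_group <- c(a3["group", "NumDF"], a3["group", "DenDF"])

  emm <- emmeans::emmeans(fit, "group", lmer.df = "satterthwaite")
  emm_df <- as.data.frame(emm)
  con <- emmeans::contrast(emm, method = "trt.vs.ctrl", ref = 1,
                           adjust = "none")
  con_df <- as.data.frame(con)

  structure(list(spec = spec, n = nrow(df), F_group = F_group,
                 df_group = df_group, p_group = p_group,
                 emmeans = emm_df, contrasts = con_df,
                 singular = singular, converged = conv),
            class = "gazehmm_lmm_result")
}

#' @export
print.gazehmm_lmm_result <- function(x, ...) {
  cat(sprintf("LMM %s / %s: F(group) = %.2f, p = %.4g%s\n",
              x$spec$variable, x$spec$category, x$F_group, x$p_group,
              if (x$singular) " [singular]" else ""))
  invisible(x)
}

#' Run the full battery of group-comparison models
#'
#' Sixteen models: transition count and transition probability for the five
#' analyzed category pairs (faces-to-faces, bodies-to-bodies, face-to-body,
#' body-to-face, non-social), and fixation and visit count for the three
#' ROI categories. Covariates follow [lmm_spec()]; the covariates
#' themselves are pre-tested for a group effect before being used. A
#' failing model is recorded in the report and the rest proceed.
#'
#' @param table long-format variable table.
#' @param cfg a [default_config()].
#' @return list of class `gazehmm_report`: `results` (one row per model),
#'   `models` (the [fit_lmm()] objects), `covariate_pretests`, `alpha`.
#' @export
run_all_models <- function(table, cfg = default_config()) {
  specs <- c(
    lapply(transition_pairs, function(p)
      lmm_spec("transition_count", p, "total_transitions")),
    lapply(transition_pairs, function(p)
      lmm_spec("transition_probability", p)),
    lapply(c("face", "body", "nonsocial"), function(cc)
      lmm_spec("fixation_count", cc, "total_fixation_duration")),
    lapply(c("face", "body", "nonsocial"), function(cc)
      lmm_spec("visit_count", cc, "total_fixation_duration")))

  pretests <- lapply(c("total_transitions", "total_fixation_duration"),
                     function(v) {
    r <- tryCatch(fit_lmm(table, lmm_spec(v, "all")), error = function(e) NULL)
    if (is.null(r)) NULL else
      data.frame(covariate = v, F_group = r$F_group, p_group = r$p_group)
  })
  pretests <- do.call(rbind, pretests)

  models <- list(); rows <- list()
  for (s in specs) {
    key <- paste(s$variable, s$category, sep = ":")
    res <- tryCatch(fit_lmm(table, s, cfg), error = function(e) e)
    if (inherits(res, "error")) {
      rows[[key]] <- data.frame(variable = s$variable, category = s$category,
                                F_group = NA, p_group = NA,
                                em_TD = NA, se_TD = NA, em_ASD = NA,
                                se_ASD = NA, em_ASD_ADHD = NA,
                                se_ASD_ADHD = NA,
                                p_TD_vs_ASD = NA, p_TD_vs_ASD_ADHD = NA,
                                singular = NA, error = conditionMessage(res))
      next
    }
    models[[key]] <- res
    em <- function(g, col) {
      i <- match(g, res$emmeans$group)
      if (is.na(i)) NA_real_ else res$emmeans[[col]][i]
    }
    pc <- function(g) {
      i <- grep(g, res$contrasts$contrast)
      if (length(i) != 1) NA_real_ else res$contrasts$p.value[i]
    }
    rows[[key]] <- data.frame(variable = s$variable, category = s$category,
                              F_group = res$F_group, p_group = res$p_group,
                              em_TD = em("TD", "emmean"),
                              se_TD = em("TD", "SE"),
                              em_ASD = em("ASD", "emmean"),
                              se_ASD = em("ASD", "SE"),
                              em_ASD_ADHD = em("ASD_ADHD", "emmean"),
                              se_ASD_ADHD = em("ASD_ADHD", "SE"),
                              p_TD_vs_ASD = pc("^ASD - TD$"),
                              p_TD_vs_ASD_ADHD = pc("^ASD_ADHD - TD$"),
                              singular = res$singular, error = NA_character_)
  }
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  if (cfg$p_adjust == "BH")
    results$p_group_adj <- stats::p.adjust(results$p_group, "BH")
  structure(list(results = results, models = models,
                 covariate_pretests = pretests, alpha = cfg$alpha),
            class = "gazehmm_report")
}

#' @export
print.gazehmm_report <- function(x, ...) {
  cat("Mixed-effects group comparisons (estimated marginal means +/- SE)\n")
  cat(sprintf("%-24s %-20s %7s %8s %8s %8s %10s %10s\n", "variable",
              "category", "F", "TD", "ASD", "ASD+ADHD", "p TD-ASD",
              "p TD-A+A"))
  for (i in seq_len(nrow(x$results))) {
    r <- x$results[i, ]
    cat(sprintf("%-24s %-20s %7.2f %8.3g %8.3g %8.3g %10.3g %10.3g%s\n",
                r$variable, r$category, r$F_group, r$em_TD, r$em_ASD,
                r$em_ASD_ADHD, r$p_TD_vs_ASD, r$p_TD_vs_ASD_ADHD,
                ifelse(isTRUE(r$singular), " [singular]", "")))
  }
  invisible(x)
}
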