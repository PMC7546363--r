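#' ROI label map: semantic category per representative state
#'
#' @param categories character vector of length K with values `"face"`,
#'   `"body"`, `"nonsocial"` or `"excluded"`.
#' @return data.frame of class `gazehmm_labels` with columns `state`,
#'   `category`.
#' @export
roi_labels <- function(categories) {
  ok <- c("face", "body", "nonsocial", "excluded")
  if (!all(categories %in% ok))
    gh_stop(paste0("categories must be one of: ", paste(ok, collapse = ", ")),
            "gazehmm_validation_error")
  if (all(categories == "excluded"))
    gh_stop("at least one state must be non-excluded", "gazehmm_validation_error")
  structure(data.frame(state = seq_along(categories),
                       category = categories,
                       stringsAsFactors = FALSE),
            class = c("gazehmm_labels", "data.frame"))
}

#' Read / write a ROI label CSV (state_index, category[, name])
#' @param path file path.
#' @return `read_roi_labels()` returns a `gazehmm_labels`.
#' @export
read_roi_labels <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("state_index", "category") %in% names(df)))
    gh_stop("label file needs columns state_index, category",
            "gazehmm_format_error")
  df <- df[order(df$state_index), ]
  roi_labels(df$category)
}

#' @rdname read_roi_labels
#' @param labels a `gazehmm_labels`.
#' @export
write_roi_labels <- function(labels, path) {
  utils::write.csv(data.frame(state_index = labels$state,
                              category = labels$category),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Flag the sparse catch-all state of a representative model
#'
#' Fitted models typically devote one state to sparse fixations with the
#' longest durations and no regional pattern. A state is flagged only if it
#' is top-ranked on BOTH criteria: largest mean fixation duration and
#' largest spatial covariance determinant (spatial spread). The flagged
#' state should be labelled `"excluded"` pending user confirmation.
#'
#' @param representative a `gazehmm_representative` (or a bare
#'   [bhmm_model()] with a transform).
#' @return The flagged state index, or `NA_integer_` if no state wins both
#'   rankings (including ties).
#' @export
flag_sparse_state <- function(representative) {
  model <- if (inherits(representative, "gazehmm_representative"))
    representative$model else representative
  K <- model$K
  if (K == 1) return(NA_integer_)
  dur <- model$means[, 3]  # monotone in real duration under the transform
  det_sp <- vapply(seq_len(K), function(k) det(model$covs[1:2, 1:2, k]), 0)
  top_dur <- which(dur == max(dur))
  top_det <- which(det_sp == max(det_sp))
  if (length(top_dur) == 1 && length(top_det) == 1 && top_dur == top_det)
    return(as.integer(top_dur))
  NA_integer_
}

transition_pairs <- c("face_face", "body_body", "face_body", "body_face",
                      "nonsocial_nonsocial")

pair_of <- function(c1, c2) {
  social <- c("face", "body")
  if ((c1 %in% social) != (c2 %in% social)) return("mixed")
  if (c1 == "nonsocial") return("nonsocial_nonsocial")
  paste(c1, c2, sep = "_")
}

#' Count category-level ROI transitions in a decoded scanpath
#'
#' Consecutive fixations in the same state are collapsed (self-transitions
#' are not transitions); every change between two distinct non-excluded
#' states is one unidirectional transition, categorized by the source and
#' destination ROI categories. Transitions touching an excluded state are
#' dropped entirely; social-to-nonsocial (and vice versa) changes are
#' tallied as `"mixed"` for conservation but not analyzed.
#'
#' @param map_states integer vector of MAP state labels (one per fixation).
#' @param labels a [roi_labels()] map covering every state.
#' @return list with `counts` (named: the five category pairs + `mixed`)
#'   and `total` (total transition count).
#' @export
count_transitions <- function(map_states, labels) {
  if (length(map_states) && max(map_states) > nrow(labels))
    gh_stop("state label outside label map", "gazehmm_validation_error")
  counts <- setNames(numeric(6), c(transition_pairs, "mixed"))
  run <- rle(as.integer(map_states))$values
  total <- 0
  if (length(run) > 1) {
    cat <- labels$category[run]
    for (t in seq_len(length(run) - 1)) {
      if (cat[t] == "excluded" || cat[t + 1] == "excluded") next
      p <- pair_of(cat[t], cat[t + 1])
      counts[p] <- counts[p] + 1
      total <- total + 1
    }
  }
  list(counts = counts, total = total)
}

#' Total number of ROI transitions in a decoded scanpath
#'
#' State changes between distinct non-excluded states, including mixed
#' social/non-social pairs.
#'
#' @inheritParams count_transitions
#' @return integer count.
#' @export
total_transitions <- function(map_states, labels) {
  count_transitions(map_states, labels)$total
}

#' Category-level transition probabilities from an individual model
#'
#' The Bayesian transition probability of linking two ROI categories. For
#' each non-excluded state i the self-transition is removed and the row is
#' renormalized over the other non-excluded states. Category-level
#' probabilities aggregate these rows weighted by the expected state
#' occupancy:
#' `P(c1 -> c2) = sum_{i in c1} w_i sum_{j in c2, j != i} A~_ij / sum_{i in c1} w_i`.
#' For each source category the probabilities over the three destination
#' categories sum to 1.
#'
#' Occupancy weights are multiplied by each state's probability of leaving
#' (one minus its self-transition mass), so the aggregate equals the
#' long-run conditional frequency of category transitions: on sequences
#' simulated from the model, empirical category transition frequencies
#' converge to these values.
#'
#' @param model a [bhmm_model()] (typically an individual fit).
#' @param labels a [roi_labels()] map.
#' @param occupancy `"empirical"` (from decoded responsibilities, requires
#'   `gamma`), `"stationary"` (stationary distribution of the restricted
#'   transition matrix) or `"uniform"`.
#' @param gamma optional T x K responsibility matrix for empirical weights.
#' @return list with `pairs` (named vector over the five analyzed category
#'   pairs; `NA` where the source category has no state) and `matrix`
#'   (3 x 3 source-by-destination category matrix).
#' @export
transition_probability <- function(model, labels,
                                   occupancy = c("empirical", "stationary",
                                                 "uniform"),
                                   gamma = NULL) {
  occupancy <- match.arg(occupancy)
  if (nrow(labels) != model$K)
    gh_stop("label map and model disagree on K", "gazehmm_validation_error")
  S <- which(labels$category != "excluded")
  if (!length(S)) gh_stop("all states excluded", "gazehmm_validation_error")
  cats <- c("face", "body", "nonsocial")

  # restricted, self-transition-free, renormalized rows
  At <- matrix(0, model$K, model$K)
  for (i in S) {
    js <- setdiff(S, i)
    if (!length(js)) next
    mass <- model$A[i, js]
    At[i, js] <- if (sum(mass) > 1e-300) mass / sum(mass) else
      1 / length(js)
  }

  w <- switch(occupancy,
    empirical = {
      if (is.null(gamma))
        gh_stop("empirical occupancy needs gamma", "gazehmm_validation_error")
      colSums(gamma)
    },
    stationary = {
      Ar <- model$A[S, S, drop = FALSE]
      Ar <- Ar / pmax(rowSums(Ar), 1e-300)
      v <- numeric(model$K)
      v[S] <- stationary_distribution(Ar)
      v
    },
    uniform = as.numeric(seq_len(model$K) %in% S))
  w <- w * (1 - diag(model$A))  # departure weighting
  if (length(S) < model$K) w[-S] <- 0

  mat <- matrix(NA_real_, 3, 3, dimnames = list(cats, cats))
  for (c1 in cats) {
    src <- S[labels$category[S] == c1]
    if (!length(src) || sum(w[src]) <= 0) next
    for (c2 in cats) {
      dst <- S[labels$category[S] == c2]
      p <- sum(vapply(src, function(i) w[i] * sum(At[i, setdiff(dst, i)]), 0))
      mat[c1, c2] <- p / sum(w[src])
    }
  }
  pairs <- c(face_face = mat["face", "face"],
             body_body = mat["body", "body"],
             face_body = mat["face", "body"],
             body_face = mat["body", "face"],
             nonsocial_nonsocial = mat["nonsocial", "nonsocial"])
  list(pairs = pairs, matrix = mat)
}

#' Fixation and visit counts per ROI category, and total fixation duration
#'
#' Fixation count is the number of MAP fixations per category (excluded
#' states dropped); a visit is a maximal run of consecutive same-state
#' fixations, counted under the category of that state. Total fixation
#' duration sums all fixation durations regardless of ROI, in seconds.
#'
#' @param map_states integer MAP state labels.
#' @param labels a [roi_labels()] map.
#' @param durations_ms fixation durations aligned with `map_states`.
#' @return list with `fixation_count`, `visit_count` (named by category)
#'   and `total_fixation_duration_s`.
#' @export
count_fixations_visits <- function(map_states, labels, durations_ms) {
  if (length(map_states) != length(durations_ms))
    gh_stop("map_states and durations differ in length",
            "gazehmm_validation_error")
  cats <- c("face", "body", "nonsocial")
  fix <- setNames(numeric(3), cats)
  vis <- setNames(numeric(3), cats)
  if (length(map_states)) {
    cat_seq <- labels$category[map_states]
    for (cc in cats) fix[cc] <- sum(cat_seq == cc)
    runs <- rle(as.integer(map_states))
    run_cat <- labels$category[runs$values]
    for (cc in cats) vis[cc] <- sum(run_cat == cc)
  }
  list(fixation_count = fix, visit_count = vis,
       total_fixation_duration_s = sum(durations_ms) / 1000)
}
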