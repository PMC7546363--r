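#' Construct a Gaussian hidden Markov model
#'
#' A point model: initial state probabilities `pi`, transition matrix `A`
#' and one 3-D Gaussian emission per state over the standardized
#' (x, y, log-duration) feature space.
#'
#' @param pi length-K initial probability vector (sums to 1).
#' @param A K x K transition matrix (rows sum to 1).
#' @param means K x 3 matrix of state means.
#' @param covs 3 x 3 x K array of positive-definite covariances.
#' @param transform the `gazehmm_transform` the features were fitted in.
#' @return Object of class `gazehmm_bhmm`.
#' @export
bhmm_model <- function(pi, A, means, covs, transform = NULL) {
  K <- length(pi)
  tol <- 1e-10
  if (any(pi < -tol) || abs(sum(pi) - 1) > tol)
    gh_stop("pi must be a probability vector", "gazehmm_validation_error")
  if (!is.matrix(A) || nrow(A) != K || ncol(A) != K ||
      any(A < -tol) || any(abs(rowSums(A) - 1) > tol))
    gh_stop("A must be a K x K stochastic matrix", "gazehmm_validation_error")
  means <- matrix(means, nrow = K)
  if (length(dim(covs)) != 3 || dim(covs)[3] != K)
    gh_stop("covs must be a D x D x K array", "gazehmm_validation_error")
  for (k in seq_len(K)) {
    ev <- eigen(covs[, , k], symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 1e-12)
      gh_stop(sprintf("state %d covariance is not positive definite", k),
              "gazehmm_validation_error")
  }
  structure(list(K = K, pi = as.numeric(pi), A = A, means = means,
                 covs = covs, transform = transform),
            class = "gazehmm_bhmm")
}

#' @export
print.gazehmm_bhmm <- function(x, ...) {
  cat(sprintf("<bhmm> K = %d states over (x, y, duration)\n", x$K))
  invisible(x)
}

# ---- priors --------------------------------------------------------------

# Conjugate prior: symmetric Dirichlet(1) on pi and on each row of A;
# Normal-Wishart per state centred at the grand mean with prior expected
# covariance diag(feature variances) / 4 (prior state SD half the data SD
# per axis). The scale is deliberately independent of K: a K-dependent
# prior footprint rewards larger models through the Wishart evidence terms
# and defeats ELBO-based state-count selection. Stored per state (m0:
# K x D, beta0/nu0: length K, W0/W0inv: D x D x K) so informative
# per-state priors (template anchoring) use the same machinery.
make_prior <- function(X, K) {
  D <- ncol(X)
  v <- apply(X, 2, stats::var)
  # floor keeps degenerate (constant) feature axes positive definite all the
  # way through to the posterior point covariance
  v[v < 1e-6] <- 1e-6
  Sigma0 <- diag(v / 4, D)
  nu0 <- D + 2
  W0 <- solve(Sigma0) / nu0
  list(alpha_pi = 1, alpha_A = 1,
       m0 = matrix(colMeans(X), K, D, byrow = TRUE),
       beta0 = rep(1, K),
       W0 = array(W0, c(D, D, K)), nu0 = rep(nu0, K),
       W0inv = array(Sigma0 * nu0, c(D, D, K)), D = D)
}

# Informative per-state prior anchoring emissions near a template model.
anchored_prior <- function(X, template, beta0 = 10, nu0 = 25) {
  K <- template$K; D <- ncol(X)
  W0 <- array(0, c(D, D, K)); W0inv <- array(0, c(D, D, K))
  for (k in seq_len(K)) {
    W0[, , k] <- solve(template$covs[, , k]) / nu0
    W0inv[, , k] <- template$covs[, , k] * nu0
  }
  list(alpha_pi = 1, alpha_A = 1, m0 = template$means,
       beta0 = rep(beta0, K), W0 = W0, nu0 = rep(nu0, K),
       W0inv = W0inv, D = D)
}

# ---- expected log emission densities -------------------------------------

expected_log_obs <- function(X, post) {
  K <- length(post$nu); D <- ncol(X)
  out <- matrix(0, nrow(X), K)
  for (k in seq_len(K)) {
    R <- chol(post$W[, , k])
    logdetW <- 2 * sum(log(diag(R)))
    Elogdet <- sum(digamma((post$nu[k] + 1 - seq_len(D)) / 2)) +
      D * log(2) + logdetW
    Xc <- sweep(X, 2, post$m[k, ])
    q <- rowSums((Xc %*% t(R))^2)  # (x-m)' W (x-m)
    out[, k] <- 0.5 * Elogdet - D / (2 * post$beta[k]) -
      0.5 * post$nu[k] * q - D / 2 * log(2 * pi)
  }
  out
}

# ---- KL divergences for the ELBO ----------------------------------------

kl_dirichlet <- function(a, a0) {
  a0 <- rep(a0, length.out = length(a))
  lgamma(sum(a)) - sum(lgamma(a)) - lgamma(sum(a0)) + sum(lgamma(a0)) +
    sum((a - a0) * (digamma(a) - digamma(sum(a))))
}

log_wishart_B <- function(W, nu) {
  D <- ncol(W)
  R <- chol(W)
  -(nu / 2) * (2 * sum(log(diag(R)))) - (nu * D / 2) * log(2) -
    (D * (D - 1) / 4) * log(pi) - sum(lgamma((nu + 1 - seq_len(D)) / 2))
}

kl_normal_wishart <- function(m1, beta1, W1, nu1, m0, beta0, W0, W0inv, nu0) {
  D <- length(m1)
  Elogdet <- sum(digamma((nu1 + 1 - seq_len(D)) / 2)) + D * log(2) +
    2 * sum(log(diag(chol(W1))))
  klw <- log_wishart_B(W1, nu1) - log_wishart_B(W0, nu0) +
    ((nu1 - nu0) / 2) * Elogdet - nu1 * D / 2 +
    (nu1 / 2) * sum(W0inv * W1)
  dm <- m1 - m0
  kln <- 0.5 * (D * log(beta1 / beta0) - D + D * beta0 / beta1 +
                  beta0 * nu1 * drop(t(dm) %*% W1 %*% dm))
  klw + kln
}

posterior_kl <- function(post) {
  K <- length(post$nu)
  p <- post$prior
  kl <- kl_dirichlet(post$alpha_pi, p$alpha_pi)
  for (j in seq_len(K))
    kl <- kl + kl_dirichlet(post$alpha_A[j, ], p$alpha_A)
  for (k in seq_len(K))
    kl <- kl + kl_normal_wishart(post$m[k, ], post$beta[k], post$W[, , k],
                                 post$nu[k], p$m0[k, ], p$beta0[k],
                                 p$W0[, , k], p$W0inv[, , k], p$nu0[k])
  kl
}

# ---- M-step --------------------------------------------------------------

# stats: list(N [K], Sx [K x D], Sxx [D x D x K], g1 [K], xi [K x K])
m_step <- function(stats, prior) {
  K <- length(stats$N); D <- prior$D
  post <- list(prior = prior,
               alpha_pi = prior$alpha_pi + stats$g1,
               alpha_A = prior$alpha_A + stats$xi,
               m = matrix(0, K, D), beta = numeric(K),
               W = array(0, c(D, D, K)), nu = numeric(K))
  for (k in seq_len(K)) {
    N <- stats$N[k]
    m0 <- prior$m0[k, ]; b0 <- prior$beta0[k]
    xbar <- if (N > 1e-12) stats$Sx[k, ] / N else m0
    Sk <- if (N > 1e-12) stats$Sxx[, , k] / N - tcrossprod(xbar) else
      matrix(0, D, D)
    post$beta[k] <- b0 + N
    post$nu[k] <- prior$nu0[k] + N
    post$m[k, ] <- (b0 * m0 + N * xbar) / post$beta[k]
    dm <- xbar - m0
    Winv <- prior$W0inv[, , k] + N * Sk + (b0 * N / (b0 + N)) * tcrossprod(dm)
    Winv <- (Winv + t(Winv)) / 2
    post$W[, , k] <- solve(Winv)
  }
  post
}

# E-step over a list of feature matrices; returns sufficient stats + logZ
# + responsibilities. The expected log emission densities are computed once
# on the stacked observation matrix; the forward-backward recursion runs
# per sequence.
e_step <- function(Xs, post, keep_gamma = FALSE) {
  K <- length(post$nu); D <- ncol(Xs[[1]])
  Elog_pi <- digamma(post$alpha_pi) - digamma(sum(post$alpha_pi))
  Elog_A <- digamma(post$alpha_A) -
    matrix(digamma(rowSums(post$alpha_A)), K, K)
  lens <- vapply(Xs, nrow, 1L)
  ends <- cumsum(lens)
  starts <- ends - lens + 1
  Xfull <- if (length(Xs) == 1) Xs[[1]] else do.call(rbind, Xs)
  logobs_full <- expected_log_obs(Xfull, post)

  G <- matrix(0, nrow(Xfull), K)
  g1 <- numeric(K); xi <- matrix(0, K, K); logZ <- 0
  for (s in seq_along(Xs)) {
    rows <- starts[s]:ends[s]
    fb <- fb_logspace(logobs_full[rows, , drop = FALSE], Elog_pi, Elog_A)
    G[rows, ] <- fb$gamma
    logZ <- logZ + fb$logZ
    g1 <- g1 + fb$gamma[1, ]
    xi <- xi + fb$xi
  }
  stats <- list(N = colSums(G), Sx = crossprod(G, Xfull),
                Sxx = array(0, c(D, D, K)), g1 = g1, xi = xi)
  for (k in seq_len(K))
    stats$Sxx[, , k] <- crossprod(Xfull * sqrt(G[, k]))
  gammas <- if (keep_gamma)
    lapply(seq_along(Xs), function(s) G[starts[s]:ends[s], , drop = FALSE])
  list(stats = stats, logZ = logZ, gamma = gammas)
}

# ---- initial responsibilities --------------------------------------------

init_stats_from_labels <- function(Xs, labels, K) {
  D <- ncol(Xs[[1]])
  stats <- list(N = numeric(K), Sx = matrix(0, K, D),
                Sxx = array(0, c(D, D, K)), g1 = numeric(K),
                xi = matrix(0, K, K))
  for (s in seq_along(Xs)) {
    X <- Xs[[s]]; lab <- labels[[s]]
    stats$g1[lab[1]] <- stats$g1[lab[1]] + 1
    for (k in seq_len(K)) {
      idx <- lab == k
      stats$N[k] <- stats$N[k] + sum(idx)
      if (any(idx)) {
        stats$Sx[k, ] <- stats$Sx[k, ] + colSums(X[idx, , drop = FALSE])
        stats$Sxx[, , k] <- stats$Sxx[, , k] + crossprod(X[idx, , drop = FALSE])
      }
    }
    if (length(lab) > 1)
      for (t in seq_len(length(lab) - 1))
        stats$xi[lab[t], lab[t + 1]] <- stats$xi[lab[t], lab[t + 1]] + 1
  }
  stats
}

# Initial hard partition of the pooled observations. The first restart uses
# model-based Gaussian-mixture clustering on the spatial axes (the duration
# axis carries no spatial cluster information and, being iid within a state,
# only blurs distance-based partitions); later restarts use seeded k-means
# on the full feature space for diversity.
init_labels <- function(Xs, K, method = c("gmm2d", "kmeans")) {
  method <- match.arg(method)
  X <- do.call(rbind, Xs)
  lab <- NULL
  if (K == 1) lab <- rep(1L, nrow(X))
  if (is.null(lab) && method == "gmm2d") {
    mc <- tryCatch(
      mclust::Mclust(X[, 1:2, drop = FALSE], G = K, modelNames = "VVV",
                     verbose = FALSE),
      error = function(e) NULL)
    if (!is.null(mc) && length(unique(mc$classification)) == K)
      lab <- as.integer(mc$classification)
  }
  if (is.null(lab)) {
    km <- tryCatch(
      suppressWarnings(stats::kmeans(X, centers = K, nstart = 8,
                                     iter.max = 30)),
      error = function(e) NULL)
    lab <- if (is.null(km)) sample(rep_len(seq_len(K), nrow(X))) else
      km$cluster
  }
  split(lab, rep(seq_along(Xs), vapply(Xs, nrow, 1L)))
}

# ---- main fit ------------------------------------------------------------

#' Variational Bayesian EM for a Gaussian hidden Markov model
#'
#' Learns the posterior over HMM parameters (Dirichlet over initial and
#' transition probabilities, Normal-Wishart over each state's Gaussian
#' emission) by alternating a variational E-step (forward-backward under
#' the expected log-parameters) and conjugate M-step updates. The evidence
#' lower bound (ELBO) is non-decreasing over iterations and automatically
#' penalizes model complexity, which drives state-count selection.
#'
#' @param scanpaths list of [scanpath()] objects.
#' @param K number of hidden states (>= 1).
#' @param cfg a [default_config()] (convergence and restart settings).
#' @param transform feature transform; fitted from the data when `NULL`.
#' @param restarts number of seeded restarts (k-means initialisations).
#' @param seed integer seed; restart r uses `seed + r - 1`.
#' @param init_gamma optional list of T x K responsibility matrices used as
#'   the initial E-step (overrides the k-means initialisation; one restart).
#' @param prior optional prior list (as built internally) to override the
#'   data-dependent default.
#' @return list with `model` (posterior-mean [bhmm_model()]), `posterior`
#'   (hyperparameters + `elbo_trace`), `elbo`, `restart` (index of the best
#'   restart).
#' @export
vbem_fit <- function(scanpaths, K, cfg = default_config(), transform = NULL,
                     restarts = cfg$restarts, seed = cfg$seed,
                     init_gamma = NULL, prior = NULL) {
  if (K < 1) gh_stop("K must be >= 1", "gazehmm_domain_error")
  if (is.null(transform)) transform <- fit_feature_transform(scanpaths,
                                                             cfg$log_duration)
  Xs <- lapply(scanpaths, scanpath_features, tf = transform)
  Ttot <- sum(vapply(Xs, nrow, 1L))
  if (K > Ttot)
    gh_stop(sprintf("K = %d exceeds the %d available observations", K, Ttot),
            "gazehmm_infeasible_error")
  if (is.null(prior)) prior <- make_prior(do.call(rbind, Xs), K)

  run_one <- function(stats0) {
    post <- m_step(stats0, prior)
    trace <- numeric(0)
    last <- -Inf
    for (it in seq_len(cfg$max_iter)) {
      es <- e_step(Xs, post)
      elbo <- es$logZ - posterior_kl(post)
      trace <- c(trace, elbo)
      if (is.finite(last) &&
          abs(elbo - last) < cfg$elbo_tol * abs(elbo)) break
      last <- elbo
      post <- m_step(es$stats, prior)
    }
    post$elbo_trace <- trace
    post
  }

  fits <- list()
  if (!is.null(init_gamma)) {
    stats0 <- gamma_to_stats(Xs, init_gamma, K)
    fits[[1]] <- run_one(stats0)
  } else {
    for (r in seq_len(restarts)) {
      set.seed(seed + r - 1)
      labels <- init_labels(Xs, K, method = if (r == 1) "gmm2d" else "kmeans")
      fits[[r]] <- run_one(init_stats_from_labels(Xs, labels, K))
    }
  }
  best <- which.max(vapply(fits, function(f) f$elbo_trace[length(f$elbo_trace)],
                           0))
  post <- fits[[best]]
  list(model = posterior_point_model(post, transform),
       posterior = post,
       elbo = post$elbo_trace[length(post$elbo_trace)],
       restart = best)
}

gamma_to_stats <- function(Xs, gammas, K) {
  D <- ncol(Xs[[1]])
  stats <- list(N = numeric(K), Sx = matrix(0, K, D),
                Sxx = array(0, c(D, D, K)), g1 = numeric(K),
                xi = matrix(0, K, K))
  for (s in seq_along(Xs)) {
    X <- Xs[[s]]; g <- gammas[[s]]
    stats$g1 <- stats$g1 + g[1, ]
    stats$N <- stats$N + colSums(g)
    stats$Sx <- stats$Sx + crossprod(g, X)
    for (k in seq_len(K))
      stats$Sxx[, , k] <- stats$Sxx[, , k] + crossprod(X * sqrt(g[, k]))
    if (nrow(g) > 1) {
      # hard pseudo-transitions from MAP labels as an initial xi
      lab <- max.col(g, ties.method = "first")
      for (t in seq_len(length(lab) - 1))
        stats$xi[lab[t], lab[t + 1]] <- stats$xi[lab[t], lab[t + 1]] + 1
    }
  }
  stats
}

# Posterior-mean point model.
posterior_point_model <- function(post, transform) {
  K <- length(post$nu); D <- post$prior$D
  covs <- array(0, c(D, D, K))
  for (k in seq_len(K)) {
    S <- solve(post$W[, , k]) / (post$nu[k] - D - 1)
    covs[, , k] <- (S + t(S)) / 2
  }
  bhmm_model(pi = post$alpha_pi / sum(post$alpha_pi),
             A = post$alpha_A / rowSums(post$alpha_A),
             means = post$m, covs = covs, transform = transform)
}

#' Evidence lower bound of a fitted posterior on data
#'
#' Recomputes the ELBO: the variational log normaliser from the
#' forward-backward recursion under the expected log-parameters, minus the
#' KL divergence of the posterior hyperparameters from the prior.
#'
#' @param scanpaths list of [scanpath()] objects.
#' @param posterior a posterior as returned by [vbem_fit()].
#' @param transform the feature transform used in fitting.
#' @return scalar ELBO.
#' @export
elbo <- function(scanpaths, posterior, transform) {
  Xs <- lapply(scanpaths, scanpath_features, tf = transform)
  es <- e_step(Xs, posterior)
  es$logZ - posterior_kl(posterior)
}

#' Select the number of hidden states by ELBO
#'
#' Fits each candidate K with seeded restarts and picks the K whose best
#' restart attains the highest ELBO; exact ties resolve to the smaller K.
#'
#' @inheritParams vbem_fit
#' @param k_range candidate state counts.
#' @return list with `K` (selected), `elbos` (named vector) and `fits`
#'   (per-K [vbem_fit()] results).
#' @export
select_state_count <- function(scanpaths, k_range = NULL,
                               cfg = default_config(), transform = NULL,
                               restarts = cfg$restarts, seed = cfg$seed) {
  k_range <- sort(unique(k_range %||% cfg$k_range))
  if (length(k_range) < 1) gh_stop("empty state-count range",
                                   "gazehmm_config_error")
  if (is.null(transform)) transform <- fit_feature_transform(scanpaths,
                                                             cfg$log_duration)
  fits <- list()
  elbos <- setNames(rep(-Inf, length(k_range)), k_range)
  for (i in seq_along(k_range)) {
    f <- tryCatch(vbem_fit(scanpaths, k_range[i], cfg, transform,
                           restarts = restarts, seed = seed),
                  gazehmm_infeasible_error = function(e) NULL)
    if (!is.null(f)) { fits[[as.character(k_range[i])]] <- f
      elbos[i] <- f$elbo }
  }
  if (all(!is.finite(elbos)))
    gh_stop("no feasible state count in range", "gazehmm_infeasible_error")
  K <- k_range[which.max(elbos)]
  list(K = K, elbos = elbos, fits = fits)
}

#' Posterior state decoding of a scanpath
#'
#' Computes smoothed per-fixation state marginals (responsibilities) by the
#' forward-backward recursion in scaled/log space and assigns each fixation
#' to its maximum-posterior state (per-fixation argmax, not the jointly
#' best Viterbi path). Ties resolve to the lowest state index.
#'
#' @param model a [bhmm_model()].
#' @param sp a [scanpath()], or a precomputed feature matrix.
#' @return list with `gamma` (T x K responsibilities) and `map_states`
#'   (length-T integer labels).
#' @export
decode <- function(model, sp) {
  X <- if (is.matrix(sp)) sp else scanpath_features(sp, model$transform)
  K <- model$K
  logobs <- matrix(0, nrow(X), K)
  for (k in seq_len(K))
    logobs[, k] <- log_dmvnorm(X, model$means[k, ], model$covs[, , k])
  fb <- fb_logspace(logobs, log(pmax(model$pi, 1e-300)),
                    log(pmax(model$A, 1e-300)))
  list(gamma = fb$gamma,
       map_states = max.col(fb$gamma, ties.method = "first"),
       loglik = fb$logZ)
}

log_dmvnorm <- function(X, mean, cov) {
  R <- chol(cov)
  Xc <- sweep(X, 2, mean)
  q <- rowSums((Xc %*% solve(R))^2)
  -0.5 * (ncol(X) * log(2 * pi) + 2 * sum(log(diag(R))) + q)
}
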