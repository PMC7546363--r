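#' Reduce an ensemble of HMMs to one representative HMM (variational HEM)
#'
#' Summarizes a collection of individual Gaussian HMMs by a single reduced
#' model with `K_target` states. Each input state is treated as a source of
#' `n_virtual` virtual observations (weighted by that state's expected
#' occupancy in its model); the algorithm iteratively maximizes a
#' variational lower bound on the expected log-likelihood of those virtual
#' samples under the reduced model. All expectations are available in
#' closed form from the input parameters (no sampling), so the procedure is
#' deterministic given the seed used for initialisation. The reduced
#' states are responsibility-weighted moment matches of the input states;
#' reduced transitions aggregate the input transition mass through the same
#' responsibilities.
#'
#' @param models list of [bhmm_model()] objects sharing one feature space.
#' @param K_target number of states of the reduced model (>= 1, and at most
#'   the total number of input states).
#' @param seed integer seed for the k-means initialisation.
#' @param n_virtual virtual samples per input state (sharpness of the
#'   assignment; the classical algorithm's free parameter).
#' @param max_iter,tol convergence controls on the lower bound.
#' @return A [bhmm_model()] with `K_target` states.
#' @export
vhem_reduce <- function(models, K_target, seed = 1L, n_virtual = 100,
                        max_iter = 200, tol = 1e-10) {
  if (K_target < 1) gh_stop("K_target must be >= 1", "gazehmm_domain_error")
  Ktot <- sum(vapply(models, function(m) m$K, 1L))
  if (K_target > Ktot)
    gh_stop("K_target exceeds the total number of input states",
            "gazehmm_domain_error")
  D <- nrow(models[[1]]$covs[, , 1])

  # flatten input states with occupancy weights
  mu <- list(); Sg <- list(); w <- c(); midx <- c(); sidx <- c()
  for (m in seq_along(models)) {
    mod <- models[[m]]
    occ <- stationary_distribution(mod$A)
    for (k in seq_len(mod$K)) {
      mu[[length(mu) + 1]] <- mod$means[k, ]
      Sg[[length(Sg) + 1]] <- mod$covs[, , k]
      w <- c(w, occ[k] * n_virtual)
      midx <- c(midx, m); sidx <- c(sidx, k)
    }
  }
  n <- length(w)
  M <- do.call(rbind, mu)

  set.seed(seed)
  centers <- if (K_target == 1) matrix(colMeans(M), 1) else {
    km <- tryCatch(stats::kmeans(M, centers = K_target, nstart = 5,
                                 iter.max = 50),
                   error = function(e) NULL)
    if (is.null(km)) M[sample(n, K_target), , drop = FALSE] else km$centers
  }
  p_b <- rep(1 / K_target, K_target)
  mu_b <- centers
  Sg_b <- lapply(seq_len(K_target), function(b) Reduce(`+`, Sg) / n)

  # expected log N(x | b) for x ~ input state i
  exp_ll <- function() {
    out <- matrix(0, n, K_target)
    for (b in seq_len(K_target)) {
      R <- chol(Sg_b[[b]])
      logdet <- 2 * sum(log(diag(R)))
      Sinv <- chol2inv(R)
      for (i in seq_len(n)) {
        dm <- mu[[i]] - mu_b[b, ]
        out[i, b] <- -0.5 * (D * log(2 * pi) + logdet +
                               sum(Sinv * Sg[[i]]) +
                               drop(t(dm) %*% Sinv %*% dm))
      }
    }
    out
  }

  bound_last <- -Inf
  z <- matrix(0, n, K_target)
  for (it in seq_len(max_iter)) {
    ell <- exp_ll()
    lw <- sweep(w * ell, 2, log(pmax(p_b, 1e-300)), `+`)
    norm <- apply(lw, 1, logsumexp)
    z <- exp(lw - norm)
    bound <- sum(norm)
    if (is.finite(bound_last) && abs(bound - bound_last) <
        tol * max(1, abs(bound))) break
    bound_last <- bound
    # M-step: weighted moment matching
    wz <- z * w
    tot <- colSums(wz)
    for (b in seq_len(K_target)) {
      if (tot[b] < 1e-12) next  # keep previous parameters for empty clusters
      mu_b[b, ] <- colSums(wz[, b] * M) / tot[b]
      S <- matrix(0, D, D)
      for (i in seq_len(n)) {
        dm <- mu[[i]] - mu_b[b, ]
        S <- S + wz[i, b] * (Sg[[i]] + tcrossprod(dm))
      }
      Sg_b[[b]] <- (S + t(S)) / (2 * tot[b])
    }
    p_b <- tot / sum(tot)
  }

  # aggregate initial and transition structure through the responsibilities
  pi_red <- numeric(K_target)
  A_red <- matrix(0, K_target, K_target)
  for (m in seq_along(models)) {
    mod <- models[[m]]
    rows <- which(midx == m)
    zm <- z[rows, , drop = FALSE]           # K_m x K_target
    occ <- stationary_distribution(mod$A)
    pi_red <- pi_red + drop(crossprod(zm, mod$pi))
    A_red <- A_red + crossprod(zm, (occ * mod$A) %*% zm)
  }
  pi_red <- pi_red / sum(pi_red)
  rs <- rowSums(A_red)
  rs[rs < 1e-300] <- 1
  A_red <- A_red / rs
  deg <- rowSums(A_red) == 0
  if (any(deg)) A_red[deg, ] <- 1 / K_target

  covs <- array(0, c(D, D, K_target))
  for (b in seq_len(K_target)) covs[, , b] <- Sg_b[[b]]
  bhmm_model(pi = pi_red, A = A_red, means = mu_b, covs = covs,
             transform = models[[1]]$transform)
}

# Stationary distribution of a stochastic matrix (left eigenvector),
# falling back to the uniform distribution for degenerate inputs.
stationary_distribution <- function(A) {
  K <- nrow(A)
  if (K == 1) return(1)
  e <- eigen(t(A))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  if (all(abs(v) < 1e-12)) return(rep(1 / K, K))
  v <- abs(v)
  v / sum(v)
}
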