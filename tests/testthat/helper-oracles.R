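# Independent oracles kept deliberately naive: straight loops over pairs and
# exhaustive path sums, no shared code with the implementation.

# Category of each state under a label map, as a plain character vector.
oracle_cats <- function(labels) labels$category

# Brute-force transition counting: walk consecutive fixation pairs, skip
# self-transitions by first removing repeats with an explicit loop.
oracle_count_transitions <- function(map_states, labels) {
  dedup <- integer(0)
  for (s in map_states)
    if (!length(dedup) || s != dedup[length(dedup)]) dedup <- c(dedup, s)
  cats <- oracle_cats(labels)
  out <- c(face_face = 0, body_body = 0, face_body = 0, body_face = 0,
           nonsocial_nonsocial = 0, mixed = 0)
  total <- 0
  if (length(dedup) > 1) for (t in 1:(length(dedup) - 1)) {
    c1 <- cats[dedup[t]]; c2 <- cats[dedup[t + 1]]
    if (c1 == "excluded" || c2 == "excluded") next
    total <- total + 1
    soc1 <- c1 %in% c("face", "body"); soc2 <- c2 %in% c("face", "body")
    key <- if (soc1 != soc2) "mixed"
    else if (c1 == "nonsocial") "nonsocial_nonsocial"
    else paste(c1, c2, sep = "_")
    out[key] <- out[key] + 1
  }
  list(counts = out, total = total)
}

# Independent run-length encoding for visit counting.
oracle_visits <- function(map_states, labels) {
  cats <- oracle_cats(labels)
  out <- c(face = 0, body = 0, nonsocial = 0)
  prev <- -1L
  for (s in map_states) {
    if (s != prev) {
      cc <- cats[s]
      if (cc %in% names(out)) out[cc] <- out[cc] + 1
    }
    prev <- s
  }
  out
}

oracle_fixations <- function(map_states, labels) {
  cats <- oracle_cats(labels)
  out <- c(face = 0, body = 0, nonsocial = 0)
  for (s in map_states) {
    cc <- cats[s]
    if (cc %in% names(out)) out[cc] <- out[cc] + 1
  }
  out
}

# Exhaustive-path smoothed marginals for small T and K.
oracle_enum_gamma <- function(model, X) {
  K <- model$K; Tn <- nrow(X)
  logobs <- sapply(seq_len(K), function(k)
    mvn_logpdf(X, model$means[k, ], model$covs[, , k]))
  logobs <- matrix(logobs, nrow = Tn)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), Tn)))
  lp <- apply(paths, 1, function(z) {
    v <- log(model$pi[z[1]]) + logobs[1, z[1]]
    if (Tn > 1) for (t in 2:Tn)
      v <- v + log(model$A[z[t - 1], z[t]]) + logobs[t, z[t]]
    v
  })
  w <- exp(lp - max(lp)); w <- w / sum(w)
  g <- matrix(0, Tn, K)
  for (t in seq_len(Tn)) for (k in seq_len(K))
    g[t, k] <- sum(w[paths[, t] == k])
  g
}

mvn_logpdf <- function(X, mean, cov) {
  X <- matrix(X, ncol = length(mean))
  Xc <- sweep(X, 2, mean)
  Sinv <- solve(cov)
  q <- rowSums((Xc %*% Sinv) * Xc)
  -0.5 * (ncol(X) * log(2 * pi) + as.numeric(determinant(cov)$modulus) + q)
}

# Closed-form log marginal likelihood under a Normal-Wishart prior
# (single Gaussian, no latent states).
oracle_nw_log_evidence <- function(X, m0, kappa0, nu0, S0) {
  D <- ncol(X); N <- nrow(X)
  lmg <- function(a) (D * (D - 1) / 4) * log(pi) +
    sum(lgamma(a + (1 - seq_len(D)) / 2))
  xb <- colMeans(X)
  Sc <- crossprod(sweep(X, 2, xb))
  kN <- kappa0 + N; nuN <- nu0 + N
  SN <- S0 + Sc + (kappa0 * N / kN) * tcrossprod(xb - m0)
  -N * D / 2 * log(pi) + lmg(nuN / 2) - lmg(nu0 / 2) +
    nu0 / 2 * as.numeric(determinant(S0)$modulus) -
    nuN / 2 * as.numeric(determinant(SN)$modulus) +
    D / 2 * (log(kappa0) - log(kN))
}

# Best-permutation matching of estimated states to true states (K <= 6).
best_permutation <- function(est_means, true_means) {
  K <- nrow(true_means)
  perms <- gtools_permutations(K)
  costs <- apply(perms, 1, function(p)
    sum((est_means[p, , drop = FALSE] - true_means)^2))
  perms[which.min(costs), ]
}

gtools_permutations <- function(K) {
  if (K == 1) return(matrix(1, 1, 1))
  sub <- gtools_permutations(K - 1)
  out <- NULL
  for (i in seq_len(K)) {
    m <- cbind(i, matrix(setdiff(seq_len(K), i)[sub], nrow(sub)))
    out <- rbind(out, m)
  }
  out
}

# Small two-state generator used across recovery tests.
make_two_state_truth <- function(sep_px = 600, sd_px = 50,
                                 A = matrix(c(.8, .2, .3, .7), 2, byrow = TRUE)) {
  structure(list(
    A = A, pi = c(.5, .5),
    rois = data.frame(mx = c(660, 660 + sep_px), my = c(400, 700),
                      sdx = sd_px, sdy = sd_px, corr = 0,
                      mu_log = log(300), sd_log = 0.4, sparse = FALSE)),
    class = "gazehmm_truth_model")
}

random_valid_model <- function(K, D = 3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- rgamma(K, 1) + .05; p <- p / sum(p)
  A <- matrix(rgamma(K * K, 1) + .05, K); A <- A / rowSums(A)
  means <- matrix(rnorm(K * D, 0, 2), K)
  covs <- array(0, c(D, D, K))
  for (k in seq_len(K)) {
    M <- matrix(rnorm(D * D), D)
    covs[, , k] <- crossprod(M) + diag(D) * .5
  }
  bhmm_model(p, A, means, covs)
}
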