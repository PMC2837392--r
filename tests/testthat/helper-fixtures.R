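# Shared fixtures and independent oracles used across the test files.

# Small expression matrix with deterministic values.
make_expr <- function(gene_ids, sample_ids, seed = 1) {
  set.seed(seed)
  expression_matrix(
    matrix(round(rnorm(length(gene_ids) * length(sample_ids)), 3),
           length(gene_ids), length(sample_ids)),
    gene_ids, sample_ids
  )
}

# Random valid parameter set for the pure K^2 model.
random_params <- function(K, d1, d2, seed = 1, gamma = NULL) {
  set.seed(seed)
  scsc_params(
    K,
    mu1 = matrix(rnorm(K * d1, sd = 3), K, d1),
    var1 = matrix(runif(K * d1, 0.5, 2), K, d1),
    mu2 = matrix(rnorm(K * d2, sd = 3), K, d2),
    var2 = matrix(runif(K * d2, 0.5, 2), K, d2),
    alpha = c(0, rnorm(K - 1)),
    beta = c(0, rnorm(K - 1)),
    gamma = if (is.null(gamma)) runif(1, 0, 2) else gamma
  )
}

# Random paired dataset (profiles only, no structure).
random_pairs <- function(n, d1, d2, n_u1 = 0, n_u2 = 0, seed = 1) {
  set.seed(seed)
  e1 <- expression_matrix(matrix(rnorm((n + n_u1) * d1, sd = 2),
                                 n + n_u1, d1),
                          sprintf("a%03d", seq_len(n + n_u1)),
                          sprintf("s%02d", seq_len(d1)))
  e2 <- expression_matrix(matrix(rnorm((n + n_u2) * d2, sd = 2),
                                 n + n_u2, d2),
                          sprintf("b%03d", seq_len(n + n_u2)),
                          sprintf("t%02d", seq_len(d2)))
  map <- ortholog_map(sprintf("a%03d", seq_len(n)),
                      sprintf("b%03d", seq_len(n)))
  build_paired_dataset(e1, e2, map)
}

# Scalar Gaussian log-density oracle (no vectorization tricks).
oracle_dnorm_profile <- function(x, mu, v) {
  sum(dnorm(x, mu, sqrt(v), log = TRUE))
}

# Brute-force oracle for the joint log-likelihood and responsibilities:
# enumerates all K^2 joint labels per pair in the probability domain.
oracle_loglik <- function(data, params) {
  K <- params$K
  pi <- compute_prior(params)
  ll <- 0
  for (i in seq_len(nrow(data$x1))) {
    tot <- 0
    for (k in seq_len(K)) {
      for (kp in seq_len(K)) {
        tot <- tot + pi[k, kp] *
          exp(oracle_dnorm_profile(data$x1[i, ], params$mu1[k, ],
                                   params$var1[k, ]) +
                oracle_dnorm_profile(data$x2[i, ], params$mu2[kp, ],
                                     params$var2[kp, ]))
      }
    }
    ll <- ll + log(tot)
  }
  for (i in seq_len(nrow(data$u1))) {
    tot <- 0
    for (k in seq_len(K)) {
      tot <- tot + sum(pi[k, ]) *
        exp(oracle_dnorm_profile(data$u1[i, ], params$mu1[k, ],
                                 params$var1[k, ]))
    }
    ll <- ll + log(tot)
  }
  for (i in seq_len(nrow(data$u2))) {
    tot <- 0
    for (kp in seq_len(K)) {
      tot <- tot + sum(pi[, kp]) *
        exp(oracle_dnorm_profile(data$u2[i, ], params$mu2[kp, ],
                                 params$var2[kp, ]))
    }
    ll <- ll + log(tot)
  }
  ll
}

# Brute-force responsibilities for pair i (K x K matrix).
oracle_pair_responsibility <- function(data, params, i) {
  K <- params$K
  pi <- compute_prior(params)
  w <- matrix(0, K, K)
  for (k in seq_len(K)) {
    for (kp in seq_len(K)) {
      w[k, kp] <- pi[k, kp] *
        exp(oracle_dnorm_profile(data$x1[i, ], params$mu1[k, ],
                                 params$var1[k, ]) +
              oracle_dnorm_profile(data$x2[i, ], params$mu2[kp, ],
                                   params$var2[kp, ]))
    }
  }
  w / sum(w)
}

# Reshape an e_step pair-responsibility row into a K x K matrix
# (species-1 label in rows).
tau_matrix <- function(soft, i) {
  Ke <- if (is.null(soft$K_eff)) soft$K else soft$K_eff
  matrix(soft$tau[i, ], Ke, Ke)
}

# Exhaustive assignment solver over all permutations (small n).
oracle_assignment <- function(cost) {
  n <- nrow(cost)
  perms <- function(v) {
    if (length(v) == 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    }
    out
  }
  best <- NULL
  best_cost <- Inf
  for (p in perms(seq_len(n))) {
    cc <- sum(cost[cbind(seq_len(n), p)])
    if (cc < best_cost - 1e-12) {
      best_cost <- cc
      best <- p
    }
  }
  list(perm = best, cost = best_cost)
}
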