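## n x K matrix of log N(x_i; mu_k, diag(var_k)) for all rows of X.
gauss_log_density_matrix <- function(X, mu, var) {
  n <- nrow(X)
  d <- ncol(X)
  K <- nrow(mu)
  out <- matrix(0, n, K)
  if (n == 0L) return(out)
  for (k in seq_len(K)) {
    v <- var[k, ]
    Z <- sweep(X, 2L, mu[k, ])
    out[, k] <- -0.5 * (d * log(2 * pi) + sum(log(v)) +
                          rowSums(sweep(Z^2, 2L, v, "/")))
  }
  out
}

## Joint-label column index convention: column j of a P x K^2 responsibility
## matrix is the joint label (k, k') with k = (j-1) %% K + 1 (species 1,
## fastest) and k' = (j-1) %/% K + 1 (species 2). as.vector() of a K x K
## matrix with rows = k matches this order.

## n x (K + noise) per-species log-density matrix: Gaussian components
## plus, when present, the broad background component's column.
species_log_density <- function(X, mu, var, bg) {
  ld <- gauss_log_density_matrix(X, mu, var)
  if (!is.null(bg)) {
    ld <- cbind(ld, gauss_log_density_matrix(X, rbind(bg$mu),
                                             rbind(bg$var)))
  }
  ld
}

## P x Ke^2 matrix of log pi[k,k'] + log-density of pair i under (k, k'),
## Ke = K + background.
joint_log_matrix <- function(data, params) {
  Ke <- n_comp(params)
  ld1 <- species_log_density(data$x1, params$mu1, params$var1, params$bg1)
  ld2 <- species_log_density(data$x2, params$mu2, params$var2, params$bg2)
  lp <- as.vector(log_prior(params))
  jl <- ld1[, rep(seq_len(Ke), times = Ke), drop = FALSE] +
    ld2[, rep(seq_len(Ke), each = Ke), drop = FALSE]
  sweep(jl, 2L, lp, "+")
}

#' Log density of one ortholog pair under a fixed joint label
#'
#' Given the joint label `(k, kp)`, the two species' profiles are
#' conditionally independent Gaussians:
#' `log N(x1; mu1[k], diag(var1[k])) + log N(x2; mu2[kp], diag(var2[kp]))`.
#'
#' @param x1,x2 numeric profiles of lengths d1 and d2.
#' @param k,kp cluster indices for species 1 and 2.
#' @param params an [scsc_params()] object.
#' @return scalar log density.
#' @export
pair_log_density <- function(x1, x2, k, kp, params) {
  if (length(x1) != ncol(params$mu1) || length(x2) != ncol(params$mu2)) {
    stop("profile length does not match the model dimension")
  }
  gauss_log_density_matrix(matrix(x1, 1L), params$mu1[k, , drop = FALSE],
                           params$var1[k, , drop = FALSE])[1L, 1L] +
    gauss_log_density_matrix(matrix(x2, 1L), params$mu2[kp, , drop = FALSE],
                             params$var2[kp, , drop = FALSE])[1L, 1L]
}

## Per-unpaired-gene log joint (density + log marginal prior) matrices.
unpaired_log_matrices <- function(data, params) {
  pi <- compute_prior(params)
  list(
    l1 = sweep(species_log_density(data$u1, params$mu1, params$var1,
                                   params$bg1),
               2L, log(rowSums(pi)), "+"),
    l2 = sweep(species_log_density(data$u2, params$mu2, params$var2,
                                   params$bg2),
               2L, log(colSums(pi)), "+")
  )
}

#' Total observed-data log-likelihood
#'
#' Sums, over ortholog pairs, the log of the prior-weighted mixture over all
#' `K^2` joint labels, and, over unpaired genes, the log of their own
#' species' mixture with the marginal prior as mixing weights. All sums are
#' computed in the log domain (log-sum-exp).
#'
#' @param data a [build_paired_dataset()] result.
#' @param params an [scsc_params()] object.
#' @return scalar log-likelihood.
#' @export
total_log_likelihood <- function(data, params) {
  if (nrow(data$x1) == 0L && nrow(data$u1) == 0L && nrow(data$u2) == 0L) {
    stop("empty dataset")
  }
  ll <- 0
  if (nrow(data$x1) > 0L) {
    ll <- ll + sum(row_logsumexp(joint_log_matrix(data, params)))
  }
  um <- unpaired_log_matrices(data, params)
  if (nrow(um$l1) > 0L) ll <- ll + sum(row_logsumexp(um$l1))
  if (nrow(um$l2) > 0L) ll <- ll + sum(row_logsumexp(um$l2))
  ll
}

#' E-step: posterior responsibilities over cluster labels
#'
#' For each ortholog pair, the posterior over the `K^2` joint labels
#' (proportional to prior times pair density); for each unpaired gene, the
#' posterior over its own species' `K` labels (proportional to marginal
#' prior times density). Computed in the log domain, so no responsibility
#' row can underflow to all zeros.
#'
#' @inheritParams total_log_likelihood
#' @return an object of class `scsc_soft`: list with `tau` (pairs x K^2,
#'   species-1 label varying fastest along columns), `tau1`/`tau2`
#'   (unpaired-gene responsibilities), `K`, the gene identifiers, and the
#'   total log-likelihood `loglik` evaluated at `params`.
#' @export
e_step <- function(data, params) {
  K <- params$K
  Ke <- n_comp(params)
  jl <- joint_log_matrix(data, params)
  ll_pairs <- if (nrow(jl) > 0L) row_logsumexp(jl) else numeric(0)
  tau <- exp(jl - ll_pairs)
  um <- unpaired_log_matrices(data, params)
  ll_u1 <- if (nrow(um$l1) > 0L) row_logsumexp(um$l1) else numeric(0)
  ll_u2 <- if (nrow(um$l2) > 0L) row_logsumexp(um$l2) else numeric(0)
  tau1 <- exp(um$l1 - ll_u1)
  tau2 <- exp(um$l2 - ll_u2)
  if ((nrow(tau) && any(rowSums(tau) == 0)) ||
      (nrow(tau1) && any(rowSums(tau1) == 0)) ||
      (nrow(tau2) && any(rowSums(tau2) == 0))) {
    stop("internal error: all-zero responsibility row")
  }
  structure(list(tau = tau, tau1 = tau1, tau2 = tau2, K = K, K_eff = Ke,
                 pair_id1 = data$pair_id1, pair_id2 = data$pair_id2,
                 u1_ids = rownames(data$u1), u2_ids = rownames(data$u2),
                 loglik = sum(ll_pairs) + sum(ll_u1) + sum(ll_u2)),
            class = "scsc_soft")
}

## Row (species-1) and column (species-2) marginal weights of the pair
## responsibilities over all labels (including any background): P x Ke each.
pair_margins <- function(soft) {
  K <- if (is.null(soft$K_eff)) soft$K else soft$K_eff
  M1 <- kronecker(matrix(1, K, 1L), diag(K))  # sum over k'
  M2 <- kronecker(diag(K), matrix(1, K, 1L))  # sum over k
  list(w1 = soft$tau %*% M1, w2 = soft$tau %*% M2)
}
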