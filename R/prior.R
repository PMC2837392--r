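#' Construct and validate SCSC model parameters
#'
#' The parameter set of the coupled two-species mixture: `K` clusters per
#' species (the same number in both species), per-species Gaussian component
#' means and diagonal variances, and the multinomial-logit prior parameters
#' over joint labels — row effects `alpha` (species 1), column effects
#' `beta` (species 2), and the correspondence affinity `gamma >= 0` that
#' rewards a pair landing in correspondent clusters. `alpha[1] = beta[1] = 0`
#' for identifiability. `correspondence` maps each species-1 cluster index to
#' its correspondent species-2 index (a permutation; the identity during
#' fitting).
#'
#' @param K number of clusters per species.
#' @param mu1,var1 K x d1 matrices of component means and (positive)
#'   per-coordinate variances for species 1.
#' @param mu2,var2 analogous K x d2 matrices for species 2.
#' @param alpha,beta length-K logit effect vectors with first element 0.
#' @param gamma non-negative scalar correspondence affinity.
#' An optional per-species background ("noise") component can be attached
#' via `bg1`/`bg2`: a broad diagonal Gaussian (fields `mu`, `var`, and a
#' per-coordinate variance floor `floor` that keeps it broad) holding the
#' genes that belong to no coherent cluster. Genes captured by the
#' background are the model's scattered genes; `alpha_bg`/`beta_bg` are the
#' background's logit effects, and `gamma` also rewards the joint
#' background label (a scattered pair is scattered in both species). With
#' `bg1 = bg2 = NULL` (the default) the model is the pure `K^2` joint
#' mixture.
#'
#' @param correspondence integer permutation of `1:K`.
#' @param gamma_max upper bound for `gamma` (default 50).
#' @param bg1,bg2 optional per-species background components: lists with
#'   numeric vectors `mu`, `var`, `floor` of length d (`NULL`: no
#'   background).
#' @param alpha_bg,beta_bg logit effects of the background component.
#' @return an object of class `scsc_params`.
#' @export
scsc_params <- function(K, mu1, var1, mu2, var2,
                        alpha = rep(0, K), beta = rep(0, K), gamma = 0,
                        correspondence = seq_len(K), gamma_max = 50,
                        bg1 = NULL, bg2 = NULL,
                        alpha_bg = 0, beta_bg = 0) {
  K <- as.integer(K)
  mu1 <- rbind(mu1); var1 <- rbind(var1)
  mu2 <- rbind(mu2); var2 <- rbind(var2)
  stopifnot(K >= 1L, nrow(mu1) == K, nrow(mu2) == K,
            all(dim(var1) == dim(mu1)), all(dim(var2) == dim(mu2)),
            length(alpha) == K, length(beta) == K, length(gamma) == 1L)
  if (!all(is.finite(mu1)) || !all(is.finite(mu2)) ||
      !all(is.finite(var1)) || !all(is.finite(var2)) ||
      !all(is.finite(alpha)) || !all(is.finite(beta)) || !is.finite(gamma)) {
    stop("non-finite model parameters")
  }
  if (any(var1 <= 0) || any(var2 <= 0)) stop("variances must be positive")
  if (abs(alpha[1L]) > 1e-12 || abs(beta[1L]) > 1e-12) {
    stop("identifiability requires alpha[1] = beta[1] = 0")
  }
  if (gamma < 0 || gamma > gamma_max) {
    stop("gamma must lie in [0, gamma_max]")
  }
  correspondence <- as.integer(correspondence)
  if (!identical(sort(correspondence), seq_len(K))) {
    stop("'correspondence' must be a permutation of 1:K")
  }
  noise <- !is.null(bg1)
  if (noise != !is.null(bg2)) {
    stop("background components must be set for both species or neither")
  }
  if (noise) {
    check_bg <- function(bg, d, what) {
      if (!is.list(bg) || !all(c("mu", "var", "floor") %in% names(bg)) ||
          length(bg$mu) != d || length(bg$var) != d ||
          length(bg$floor) != d ||
          !all(is.finite(c(bg$mu, bg$var, bg$floor))) ||
          any(bg$var <= 0) || any(bg$floor <= 0)) {
        stop("invalid background component for ", what)
      }
    }
    check_bg(bg1, ncol(mu1), "species 1")
    check_bg(bg2, ncol(mu2), "species 2")
    if (!is.finite(alpha_bg) || !is.finite(beta_bg)) {
      stop("non-finite background logit effects")
    }
  }
  structure(list(K = K, alpha = as.numeric(alpha), beta = as.numeric(beta),
                 gamma = as.numeric(gamma), correspondence = correspondence,
                 mu1 = mu1, var1 = var1, mu2 = mu2, var2 = var2,
                 gamma_max = gamma_max,
                 bg1 = bg1, bg2 = bg2,
                 alpha_bg = if (noise) as.numeric(alpha_bg) else NULL,
                 beta_bg = if (noise) as.numeric(beta_bg) else NULL),
            class = "scsc_params")
}

## TRUE when the model carries a background component.
has_noise <- function(params) !is.null(params$bg1)

## Number of labels per species including the background.
n_comp <- function(params) params$K + has_noise(params)

## Logit effect vectors / correspondence extended with the background label
## (always the last index, corresponding to itself).
alpha_ext <- function(params) {
  if (has_noise(params)) c(params$alpha, params$alpha_bg) else params$alpha
}
beta_ext <- function(params) {
  if (has_noise(params)) c(params$beta, params$beta_bg) else params$beta
}
corr_ext <- function(params) {
  if (has_noise(params)) c(params$correspondence, params$K + 1L) else
    params$correspondence
}

#' Prior probabilities over joint cluster labels
#'
#' Evaluates the multinomial-logit prior
#' `pi[k, k'] = exp(alpha[k] + beta[k'] + gamma * I(k' = sigma(k))) / Z`,
#' where `Z` normalizes over all `K^2` joint labels and `sigma` is the
#' cluster correspondence. `gamma = 0` decouples the species; large `gamma`
#' concentrates mass on correspondent-cluster pairs.
#'
#' When the model carries a background component the matrix gains one
#' trailing row and column for the background label of each species (also
#' gamma-coupled on its diagonal cell).
#'
#' @param params an [scsc_params()] object.
#' @return a K x K matrix of strictly positive probabilities summing to 1
#'   (one extra row/column with a background component); rows index
#'   species-1 labels, columns species-2 labels.
#' @export
compute_prior <- function(params) {
  eta <- log_prior_unnorm(params)
  p <- exp(eta - logsumexp(eta))
  p / sum(p)
}

log_prior_unnorm <- function(params) {
  eta <- outer(alpha_ext(params), beta_ext(params), "+")
  ce <- corr_ext(params)
  idx <- cbind(seq_along(ce), ce)
  eta[idx] <- eta[idx] + params$gamma
  eta
}

## Normalized log prior matrix.
log_prior <- function(params) {
  eta <- log_prior_unnorm(params)
  eta - logsumexp(eta)
}

#' Maximize the logit prior given expected joint-label counts
#'
#' Finds `(alpha, beta, gamma)` maximizing
#' `sum(counts * log pi(alpha, beta, gamma))` subject to
#' `alpha[1] = beta[1] = 0` and `0 <= gamma <= gamma_max`. The objective is
#' a concave multinomial-logit log-likelihood; it is maximized by bounded
#' quasi-Newton ascent (L-BFGS-B) with the analytic gradient, warm-started
#' from the supplied values.
#'
#' @param counts K x K matrix of non-negative expected counts per joint
#'   label (rows: species-1 clusters, columns: species-2 clusters).
#' @param correspondence integer permutation giving the gamma-rewarded cell
#'   of each row.
#' @param gamma_max upper bound for gamma.
#' @param alpha0,beta0,gamma0 starting values.
#' @param fix_gamma if non-NULL, gamma is held at this value and only the
#'   row/column effects are optimized.
#' @return list with `alpha`, `beta`, `gamma`, and `converged`.
#' @export
fit_logit_prior <- function(counts, correspondence = seq_len(nrow(counts)),
                            gamma_max = 50,
                            alpha0 = rep(0, nrow(counts)),
                            beta0 = rep(0, nrow(counts)),
                            gamma0 = 0, fix_gamma = NULL) {
  K <- nrow(counts)
  stopifnot(is.matrix(counts), ncol(counts) == K, all(counts >= 0),
            all(is.finite(counts)))
  N <- sum(counts)
  if (N <= 0) stop("'counts' must have positive total mass")
  diag_idx <- cbind(seq_len(K), as.integer(correspondence))
  free_gamma <- is.null(fix_gamma)
  gfix <- if (free_gamma) NULL else min(max(fix_gamma, 0), gamma_max)

  unpack <- function(theta) {
    alpha <- c(0, theta[seq_len(K - 1L)])
    beta <- c(0, theta[K - 1L + seq_len(K - 1L)])
    gamma <- if (free_gamma) theta[2L * K - 1L] else gfix
    list(alpha = alpha, beta = beta, gamma = gamma)
  }
  objective <- function(theta) {
    p <- unpack(theta)
    eta <- outer(p$alpha, p$beta, "+")
    eta[diag_idx] <- eta[diag_idx] + p$gamma
    -(sum(counts * eta) - N * logsumexp(eta))
  }
  gradient <- function(theta) {
    p <- unpack(theta)
    eta <- outer(p$alpha, p$beta, "+")
    eta[diag_idx] <- eta[diag_idx] + p$gamma
    pi <- exp(eta - logsumexp(eta))
    D <- counts - N * pi
    g <- c(rowSums(D)[-1L], colSums(D)[-1L])
    if (free_gamma) g <- c(g, sum(D[diag_idx]))
    -g
  }
  theta0 <- c(alpha0[-1L], beta0[-1L])
  lower <- rep(-Inf, length(theta0))
  upper <- rep(Inf, length(theta0))
  if (free_gamma) {
    theta0 <- c(theta0, min(max(gamma0, 0), gamma_max))
    lower <- c(lower, 0)
    upper <- c(upper, gamma_max)
  }
  if (K == 1L && !free_gamma) {
    return(list(alpha = 0, beta = 0, gamma = gfix, converged = TRUE))
  }
  if (length(theta0) == 0L) {
    return(list(alpha = rep(0, K), beta = rep(0, K),
                gamma = if (free_gamma) 0 else gfix, converged = TRUE))
  }
  fit <- stats::optim(theta0, objective, gradient, method = "L-BFGS-B",
                      lower = lower, upper = upper,
                      control = list(maxit = 500L, factr = 10,
                                     pgtol = 1e-10))
  out <- unpack(fit$par)
  out$converged <- fit$convergence == 0L
  ## boundary case: with all mass on the correspondence cells the
  ## likelihood increases in gamma without bound, so gamma takes its cap
  if (free_gamma && K > 1L && sum(counts) - sum(counts[diag_idx]) == 0) {
    out$gamma <- gamma_max
  }
  out
}

#' Logit-prior M-step from soft assignments
#'
#' Accumulates expected joint-label counts from the pair responsibilities and
#' allocates each unpaired gene's marginal responsibility across the hidden
#' partner label using the current prior's conditional distribution (the
#' exact expected complete-data count), then maximizes the prior
#' log-likelihood with [fit_logit_prior()]. On inner-solver failure the
#' previous values are kept and a message is emitted.
#'
#' @param soft a soft assignment as returned by [e_step()].
#' @param params the current [scsc_params()] (source of the conditional
#'   allocation, the warm start, and `gamma_max`).
#' @param fix_gamma optional fixed gamma (see [fit_logit_prior()]).
#' @return list with updated `alpha`, `beta`, `gamma`.
#' @export
m_step_logit <- function(soft, params, fix_gamma = NULL) {
  K <- params$K
  Ke <- n_comp(params)
  C <- matrix(colSums(soft$tau), Ke, Ke)  # columns are k-fastest joint labels
  pi <- compute_prior(params)
  if (nrow(soft$tau1) > 0L) {
    cond1 <- pi / rowSums(pi)           # P(k' | k)
    C <- C + colSums(soft$tau1) * cond1
  }
  if (nrow(soft$tau2) > 0L) {
    cond2 <- sweep(pi, 2L, colSums(pi), "/")  # P(k | k')
    C <- C + sweep(cond2, 2L, colSums(soft$tau2), "*")
  }
  fit <- tryCatch(
    fit_logit_prior(C, corr_ext(params), params$gamma_max,
                    alpha0 = alpha_ext(params), beta0 = beta_ext(params),
                    gamma0 = params$gamma, fix_gamma = fix_gamma),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    message("logit M-step failed; keeping previous prior parameters")
    return(list(alpha = params$alpha, beta = params$beta,
                gamma = params$gamma,
                alpha_bg = params$alpha_bg, beta_bg = params$beta_bg))
  }
  out <- list(alpha = fit$alpha[seq_len(K)], beta = fit$beta[seq_len(K)],
              gamma = fit$gamma, alpha_bg = NULL, beta_bg = NULL)
  if (has_noise(params)) {
    out$alpha_bg <- fit$alpha[K + 1L]
    out$beta_bg <- fit$beta[K + 1L]
  }
  out
}
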