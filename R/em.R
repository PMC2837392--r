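#' Fitting configuration
#'
#' Bundles the tuning constants of the fitting procedure. Defaults: 10
#' random restarts, relative log-likelihood tolerance 1e-8, at most 500
#' iterations, initial correspondence affinity `gamma_init = 1`, bound
#' `gamma_max = 50`, variance floor 1e-6, posterior scatter threshold 0.5
#' (0 disables scatter flagging), no per-gene standardization, seed 1.
#'
#' @param K optional cluster count (used by the CLI; `fit_scsc()` takes K
#'   explicitly).
#' @param n_starts number of random restarts.
#' @param max_iter maximum EM iterations per restart.
#' @param tol relative log-likelihood convergence tolerance.
#' @param gamma_init initial value of gamma.
#' @param gamma_max upper bound for gamma.
#' @param variance_floor lower clip for component variances.
#' @param scatter_threshold posterior threshold below which a gene is
#'   flagged as scattered.
#' @param standardize per-gene standardization mode (see
#'   [standardize_profiles()]).
#' @param seed integer seed; restart r uses `seed + r - 1`.
#' @param fix_gamma optional fixed gamma (NULL: gamma is estimated).
#' @param noise if `TRUE` (default) the model carries a per-species broad
#'   Gaussian background component (variance floored at half the pooled
#'   data variance); genes captured by it are reported as scattered.
#'   `FALSE` fits the pure `K^2` joint mixture.
#' @return an object of class `scsc_config`.
#' @export
scsc_config <- function(K = NULL, n_starts = 10L, max_iter = 500L,
                        tol = 1e-8, gamma_init = 1, gamma_max = 50,
                        variance_floor = 1e-6, scatter_threshold = 0.5,
                        standardize = "none", seed = 1L, fix_gamma = NULL,
                        noise = TRUE) {
  stopifnot(n_starts >= 1L, max_iter >= 1L, tol > 0, gamma_max > 0,
            gamma_init >= 0, gamma_init <= gamma_max, variance_floor > 0,
            scatter_threshold >= 0, scatter_threshold < 1)
  standardize <- match.arg(standardize, c("none", "center", "zscore"))
  structure(list(K = K, n_starts = as.integer(n_starts),
                 max_iter = as.integer(max_iter), tol = tol,
                 gamma_init = gamma_init, gamma_max = gamma_max,
                 variance_floor = variance_floor,
                 scatter_threshold = scatter_threshold,
                 standardize = standardize, seed = as.integer(seed),
                 fix_gamma = fix_gamma, noise = isTRUE(noise)),
            class = "scsc_config")
}

#' Gaussian M-step: weighted component means and variances
#'
#' Each species-1 gene contributes to cluster `k` with weight equal to its
#' responsibility summed over the partner label (row margin of the joint
#' responsibilities), plus the marginal responsibilities of unpaired
#' species-1 genes; symmetrically for species 2 with column margins. Means
#' are the weighted profile averages; variances are weighted per-coordinate
#' variances about the new means, clipped below at `floor`. A cluster whose
#' total weight falls below 1e-12 keeps its previous parameters.
#'
#' @param data a [build_paired_dataset()] result.
#' @param soft an [e_step()] result.
#' @param floor variance floor.
#' @param prev optional previous [scsc_params()] supplying the empty-cluster
#'   fallback.
#' @return list with `mu1`, `var1`, `mu2`, `var2`.
#' @export
m_step_gaussian <- function(data, soft, floor = 1e-6, prev = NULL) {
  K <- soft$K
  mg_all <- pair_margins(soft)
  mg <- list(w1 = mg_all$w1[, seq_len(K), drop = FALSE],
             w2 = mg_all$w2[, seq_len(K), drop = FALSE])
  tau1 <- soft$tau1[, seq_len(K), drop = FALSE]
  tau2 <- soft$tau2[, seq_len(K), drop = FALSE]
  update_species <- function(W, X, mu_prev, var_prev) {
    wsum <- colSums(W)
    mu <- matrix(0, ncol(W), ncol(X))
    va <- matrix(floor, ncol(W), ncol(X))
    ok <- wsum >= 1e-12
    if (any(ok)) {
      Wok <- W[, ok, drop = FALSE]
      mu[ok, ] <- crossprod(Wok, X) / wsum[ok]
      ex2 <- crossprod(Wok, X^2) / wsum[ok]
      va[ok, ] <- pmax(ex2 - mu[ok, , drop = FALSE]^2, floor)
    }
    if (any(!ok)) {
      message(sum(!ok), " empty cluster(s) kept previous parameters")
      if (!is.null(mu_prev)) {
        mu[!ok, ] <- mu_prev[!ok, , drop = FALSE]
        va[!ok, ] <- var_prev[!ok, , drop = FALSE]
      }
    }
    list(mu = mu, va = va)
  }
  W1 <- rbind(mg$w1, tau1)
  W2 <- rbind(mg$w2, tau2)
  X1 <- rbind(data$x1, data$u1)
  X2 <- rbind(data$x2, data$u2)
  s1 <- update_species(W1, X1, prev$mu1, prev$var1)
  s2 <- update_species(W2, X2, prev$mu2, prev$var2)
  out <- list(mu1 = s1$mu, var1 = s1$va, mu2 = s2$mu, var2 = s2$va)
  if (!is.null(soft$K_eff) && soft$K_eff > K) {
    bg_update <- function(w, X, bg_prev) {
      wsum <- sum(w)
      if (wsum < 1e-12 || is.null(bg_prev)) return(bg_prev)
      mu <- as.vector(crossprod(w, X)) / wsum
      va <- as.vector(crossprod(w, X^2)) / wsum - mu^2
      list(mu = mu, var = pmax(va, bg_prev$floor), floor = bg_prev$floor)
    }
    out$bg1 <- bg_update(c(mg_all$w1[, K + 1L], soft$tau1[, K + 1L]),
                         X1, prev$bg1)
    out$bg2 <- bg_update(c(mg_all$w2[, K + 1L], soft$tau2[, K + 1L]),
                         X2, prev$bg2)
  }
  out
}

## Random initialization for one restart. Primary path ("joint" style):
## k-means++/Lloyd seeding on the concatenated paired profiles
## (label-consistent across the species by construction) with one
## outlier-trimming re-seed pass so that scattered pairs cannot claim
## seeded centers. Alternative path ("species" style, used on alternate
## restarts for diversity, and as fallback for tiny datasets): per-species
## seeding with greedy ortholog-overlap pairing of the seeded clusters.
## Variances start at the pooled per-coordinate variance.
init_params <- function(data, K, config, style = "joint",
                        trim_keep = 0.7) {
  X1 <- rbind(data$x1, data$u1)
  X2 <- rbind(data$x2, data$u2)
  lloyd <- function(X, c0) {
    km <- tryCatch(
      suppressWarnings(stats::kmeans(X, c0, iter.max = 10L,
                                     algorithm = "Lloyd")),
      error = function(e) NULL
    )
    if (!is.null(km) && all(km$size > 0L)) unname(km$centers) else c0
  }
  seed_centers <- function(X) {
    c0 <- kmeanspp_centers(X, K)
    if (K > 1L && nrow(X) > K) c0 <- lloyd(X, c0)
    c0
  }
  c1 <- c2 <- NULL
  if (style == "joint" && K > 1L && nrow(data$x1) >= max(2L * K, 20L)) {
    XJ <- cbind(data$x1, data$x2)
    cJ <- lloyd(XJ, kmeanspp_centers(XJ, K))
    dmin <- sqrt(rowSums((XJ - cJ[nearest_centroid(XJ, cJ), ,
                                  drop = FALSE])^2))
    keep <- dmin < stats::quantile(dmin, trim_keep)
    if (sum(keep) >= 2L * K) {
      Xk <- XJ[keep, , drop = FALSE]
      cJ <- lloyd(Xk, kmeanspp_centers(Xk, K))
    }
    c1 <- cJ[, seq_len(data$d1), drop = FALSE]
    c2 <- cJ[, data$d1 + seq_len(data$d2), drop = FALSE]
  }
  if (is.null(c1)) {
    c1 <- seed_centers(X1)
    c2 <- seed_centers(X2)
    if (nrow(data$x1) > 0L && K > 1L) {
      ## pair seeded clusters greedily by ortholog overlap
      lab1 <- nearest_centroid(data$x1, c1)
      lab2 <- nearest_centroid(data$x2, c2)
      tab <- matrix(0, K, K)
      for (i in seq_along(lab1)) {
        tab[lab1[i], lab2[i]] <- tab[lab1[i], lab2[i]] + 1
      }
      perm <- integer(K)
      for (step in seq_len(K)) {
        j <- which.max(tab)  # first maximum in column-major order
        r <- (j - 1L) %% K + 1L
        cc <- (j - 1L) %/% K + 1L
        perm[r] <- cc
        tab[r, ] <- -1
        tab[, cc] <- -1
      }
      c2 <- c2[perm, , drop = FALSE]
    }
  }
  v1 <- pmax(matrix(apply(X1, 2L, stats::var), K, data$d1, byrow = TRUE),
             config$variance_floor)
  v2 <- pmax(matrix(apply(X2, 2L, stats::var), K, data$d2, byrow = TRUE),
             config$variance_floor)
  bg1 <- bg2 <- NULL
  if (isTRUE(config$noise)) {
    bg1 <- init_background(X1, config)
    bg2 <- init_background(X2, config)
  }
  scsc_params(K, mu1 = c1, var1 = v1, mu2 = c2, var2 = v2,
              gamma = config$gamma_init, gamma_max = config$gamma_max,
              bg1 = bg1, bg2 = bg2)
}

## Initial background component: a broad Gaussian at the grand moments of
## the species' data. Its per-coordinate variance is floored at half the
## pooled data variance so that the background can tighten onto a diffuse
## scatter cloud but can never collapse onto a coherent cluster.
init_background <- function(X, config) {
  v <- pmax(apply(X, 2L, stats::var), config$variance_floor)
  list(mu = colMeans(X), var = v, floor = pmax(0.5 * v,
                                               config$variance_floor))
}

#' Run the EM loop from given starting parameters
#'
#' Alternates [e_step()], [m_step_gaussian()] and [m_step_logit()] until the
#' relative change in log-likelihood falls below `config$tol` or
#' `config$max_iter` is reached. The per-iteration log-likelihood trace is
#' non-decreasing (up to the variance floor and inner-solver tolerance).
#'
#' @param data a [build_paired_dataset()] result.
#' @param params starting [scsc_params()].
#' @param config an [scsc_config()].
#' @return list with final `params`, `soft`, `loglik_trace`, `converged`,
#'   `n_iter`.
#' @export
scsc_em <- function(data, params, config = scsc_config()) {
  trace <- numeric(0)
  ll_prev <- -Inf
  converged <- FALSE
  it <- 0L
  soft <- NULL
  for (it in seq_len(config$max_iter)) {
    soft <- e_step(data, params)
    ll <- soft$loglik
    trace <- c(trace, ll)
    if (is.finite(ll_prev) && abs(ll - ll_prev) < config$tol * max(1, abs(ll))) {
      converged <- TRUE
      break
    }
    ll_prev <- ll
    g <- m_step_gaussian(data, soft, config$variance_floor, params)
    lg <- m_step_logit(soft, params, fix_gamma = config$fix_gamma)
    params <- scsc_params(params$K, g$mu1, g$var1, g$mu2, g$var2,
                          alpha = lg$alpha, beta = lg$beta, gamma = lg$gamma,
                          correspondence = params$correspondence,
                          gamma_max = config$gamma_max,
                          bg1 = if (is.null(g$bg1)) params$bg1 else g$bg1,
                          bg2 = if (is.null(g$bg2)) params$bg2 else g$bg2,
                          alpha_bg = if (is.null(lg$alpha_bg)) 0 else lg$alpha_bg,
                          beta_bg = if (is.null(lg$beta_bg)) 0 else lg$beta_bg)
  }
  list(params = params, soft = soft, loglik_trace = trace,
       converged = converged, n_iter = it)
}

#' Fit the soft cross-species clustering model
#'
#' Runs `config$n_starts` restarts of the EM procedure and keeps the restart
#' with the highest final log-likelihood. Each restart is initialized by
#' k-means++/Lloyd seeding on the concatenated paired profiles with an
#' outlier-trimming re-seed pass (trim strength alternating across restarts);
#' small datasets fall back to per-species seeding with the seeded clusters
#' paired greedily by ortholog overlap. Cluster indices of the winning fit
#' are then aligned so
#' that the two species' clusters sharing the largest intersection of
#' orthologous genes receive the same numerical label
#' ([align_cluster_labels()]).
#'
#' @param data a [build_paired_dataset()] result with at least one ortholog
#'   pair.
#' @param K number of clusters per species (same in both species).
#' @param config an [scsc_config()]; `config$seed` drives all randomness
#'   (restart r uses `seed + r - 1`).
#' @return an object of class `scsc_fit`: list with `params`, `soft`,
#'   `loglik_trace`, `converged`, `n_iter`, `seed`, `restart_index`,
#'   `config`.
#' @export
fit_scsc <- function(data, K, config = scsc_config()) {
  K <- as.integer(K)
  if (K < 1L) stop("K must be at least 1")
  if (nrow(data$x1) < 1L) stop("dataset has no ortholog pairs")
  if (K > nrow(data$x1)) stop("K exceeds the number of ortholog pairs")
  allX <- rbind(data$x1, data$u1)
  if (all(abs(sweep(allX, 2L, allX[1L, ])) < 1e-12) &&
      all(abs(sweep(rbind(data$x2, data$u2), 2L,
                    rbind(data$x2, data$u2)[1L, ])) < 1e-12)) {
    stop("degenerate dataset: all profiles identical")
  }
  best <- NULL
  best_r <- NA_integer_
  for (r in seq_len(config$n_starts)) {
    set.seed(config$seed + r - 1L)
    ## alternate the trimming strength across restarts for diversity
    p0 <- init_params(data, K, config, style = "joint",
                      trim_keep = if (r %% 2L == 0L) 0.85 else 0.7)
    run <- scsc_em(data, p0, config)
    if (is.null(best) ||
        run$loglik_trace[length(run$loglik_trace)] >
          best$loglik_trace[length(best$loglik_trace)]) {
      best <- run
      best_r <- r
    }
  }
  fit <- structure(list(params = best$params, soft = best$soft,
                        loglik_trace = best$loglik_trace,
                        converged = best$converged, n_iter = best$n_iter,
                        seed = config$seed, restart_index = best_r,
                        config = config),
                   class = "scsc_fit")
  align_cluster_labels(fit)
}

#' @export
print.scsc_fit <- function(x, ...) {
  cat("scsc_fit: K =", x$params$K,
      "| final loglik =", format(x$loglik_trace[length(x$loglik_trace)]),
      "| gamma =", format(round(x$params$gamma, 4)),
      "| iterations =", x$n_iter,
      "| converged =", x$converged,
      "| restart =", x$restart_index, "\n")
  invisible(x)
}

## K x K contingency table of hard joint labels of the ortholog pairs
## (pairs whose argmax involves a background label are excluded).
pair_label_table <- function(soft) {
  K <- soft$K
  Ke <- if (is.null(soft$K_eff)) K else soft$K_eff
  j <- max.col(soft$tau, ties.method = "first")
  k <- (j - 1L) %% Ke + 1L
  kp <- (j - 1L) %/% Ke + 1L
  tab <- matrix(0, K, K)
  keep <- k <= K & kp <= K
  for (i in which(keep)) tab[k[i], kp[i]] <- tab[k[i], kp[i]] + 1
  tab
}

#' Align cluster indices across the two species
#'
#' Builds the contingency table of hard joint labels over the ortholog pairs
#' and finds the species-2 label permutation maximizing the on-diagonal
#' count (exact assignment; ties broken toward the lowest index), so that
#' the clusters with the largest intersection of orthologous genes share the
#' same numerical label. Species-2 parameters and responsibilities are
#' permuted accordingly. The relabeling is likelihood-neutral: the
#' correspondence permutation is updated alongside so that the
#' gamma-rewarded cells are unchanged (it remains the identity whenever the
#' optimal matching already is, the usual case).
#'
#' @param fit an `scsc_fit` object.
#' @return the fit with aligned labels.
#' @export
align_cluster_labels <- function(fit) {
  K <- fit$params$K
  if (K == 1L) return(fit)
  tab <- pair_label_table(fit$soft)
  m <- solve_assignment(-tab)  # maximize diagonal count
  if (identical(m, seq_len(K))) return(fit)
  p <- fit$params
  shift <- p$beta[m][1L]
  p$mu2 <- p$mu2[m, , drop = FALSE]
  p$var2 <- p$var2[m, , drop = FALSE]
  p$beta <- p$beta[m] - shift
  m_inv <- order(m)
  p$correspondence <- m_inv[p$correspondence]
  fit$params <- scsc_params(p$K, p$mu1, p$var1, p$mu2, p$var2, p$alpha,
                            p$beta, p$gamma, p$correspondence, p$gamma_max,
                            bg1 = p$bg1, bg2 = p$bg2,
                            alpha_bg = if (is.null(p$alpha_bg)) 0 else p$alpha_bg,
                            beta_bg = if (is.null(p$beta_bg)) 0 else
                              p$beta_bg - shift)
  ## permute joint responsibility columns: new (k, kp) reads old (k, m[kp]);
  ## a background label stays in place
  Ke <- n_comp(fit$params)
  m_ext <- if (Ke > K) c(m, Ke) else m
  colperm <- as.vector(outer(seq_len(Ke), (m_ext - 1L) * Ke, "+"))
  fit$soft$tau <- fit$soft$tau[, colperm, drop = FALSE]
  fit$soft$tau2 <- fit$soft$tau2[, m_ext, drop = FALSE]
  fit
}

#' Harden a soft assignment, flagging scattered genes
#'
#' Each ortholog pair receives its maximum-posterior joint label (the two
#' genes get the species-1 and species-2 indices respectively, both with the
#' joint maximum as posterior mass); each unpaired gene receives its
#' marginal maximum-posterior label. A gene whose maximal posterior is below
#' `scatter_threshold` is flagged as scattered — it belongs to no multi-gene
#' cluster (`cluster` is `NA`). `scatter_threshold = 0` disables flagging.
#'
#' @param soft an [e_step()] result.
#' @param scatter_threshold posterior threshold in `[0, 1)`.
#' @return an object of class `scsc_hard`: data frame with columns
#'   `gene_id`, `species` (1 or 2), `cluster` (integer, `NA` when
#'   scattered), `scatter` (logical), `max_posterior`.
#' @export
harden_assignment <- function(soft, scatter_threshold = 0.5) {
  stopifnot(scatter_threshold >= 0, scatter_threshold < 1)
  K <- soft$K
  Ke <- if (is.null(soft$K_eff)) K else soft$K_eff
  rows <- list()
  if (nrow(soft$tau) > 0L) {
    j <- max.col(soft$tau, ties.method = "first")
    p <- soft$tau[cbind(seq_along(j), j)]
    k <- (j - 1L) %% Ke + 1L
    kp <- (j - 1L) %/% Ke + 1L
    rows$p1 <- data.frame(gene_id = soft$pair_id1, species = 1L,
                          cluster = k, max_posterior = p,
                          stringsAsFactors = FALSE)
    rows$p2 <- data.frame(gene_id = soft$pair_id2, species = 2L,
                          cluster = kp, max_posterior = p,
                          stringsAsFactors = FALSE)
  }
  unp <- function(tau, ids, species) {
    if (nrow(tau) == 0L) return(NULL)
    j <- max.col(tau, ties.method = "first")
    data.frame(gene_id = ids, species = species, cluster = j,
               max_posterior = tau[cbind(seq_along(j), j)],
               stringsAsFactors = FALSE)
  }
  rows$u1 <- unp(soft$tau1, soft$u1_ids, 1L)
  rows$u2 <- unp(soft$tau2, soft$u2_ids, 2L)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  ## scattered: captured by the background component, or low-confidence
  out$scatter <- out$cluster > K | out$max_posterior < scatter_threshold
  out$cluster[out$scatter] <- NA_integer_
  out <- out[, c("gene_id", "species", "cluster", "scatter",
                 "max_posterior")]
  structure(out, class = c("scsc_hard", "data.frame"))
}

#' Choose the number of clusters by BIC
#'
#' Fits each candidate K and computes
#' `BIC = -2 loglik + p log(N)`, with `p = 2K(d1 + d2) + (2K - 2) + 1` free
#' parameters (means and variances, logit row/column effects, gamma) and `N`
#' the total number of genes in both species. Returns the candidate with
#' the smallest BIC; failed fits are recorded and skipped.
#'
#' @param data a [build_paired_dataset()] result.
#' @param K_candidates integer vector of candidate cluster counts.
#' @param config an [scsc_config()].
#' @return list with `K_best` and `table` (data frame: K, loglik, n_par,
#'   bic, error).
#' @export
select_k_bic <- function(data, K_candidates, config = scsc_config()) {
  stopifnot(length(K_candidates) >= 1L, all(K_candidates >= 1L))
  N <- n_genes_total(data)
  rows <- lapply(as.integer(K_candidates), function(K) {
    ## means/variances + free logit effects + gamma (+2 background effects)
    p <- 2L * K * (data$d1 + data$d2) + (2L * K - 2L) + 1L +
      if (isTRUE(config$noise)) 2L else 0L
    fit <- tryCatch(fit_scsc(data, K, config), error = function(e) e)
    if (inherits(fit, "error")) {
      return(data.frame(K = K, loglik = NA_real_, n_par = p, bic = NA_real_,
                        error = conditionMessage(fit),
                        stringsAsFactors = FALSE))
    }
    ll <- fit$loglik_trace[length(fit$loglik_trace)]
    data.frame(K = K, loglik = ll, n_par = p, bic = -2 * ll + p * log(N),
               error = NA_character_, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (all(is.na(tab$bic))) stop("every candidate fit failed")
  list(K_best = tab$K[which.min(tab$bic)], table = tab)
}
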