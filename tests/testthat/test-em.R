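test_that("Gaussian M-step reproduces weighted moment formulas", {
  # all responsibility on one component: its mean is the sample mean
  e1 <- expression_matrix(matrix(c(0, 1, 2), 3, 1), paste0("a", 1:3), "s1")
  e2 <- expression_matrix(matrix(c(4, 5, 6), 3, 1), paste0("b", 1:3), "t1")
  d <- build_paired_dataset(e1, e2, ortholog_map(paste0("a", 1:3),
                                                 paste0("b", 1:3)))
  soft <- structure(list(
    tau = matrix(rep(c(1, 0, 0, 0), each = 3), 3, 4), K = 2L,
    tau1 = matrix(numeric(0), 0, 2), tau2 = matrix(numeric(0), 0, 2)
  ), class = "scsc_soft")
  g <- m_step_gaussian(d, soft, floor = 1e-6,
                       prev = random_params(2, 1, 1))
  expect_equal(g$mu1[1, ], 1)
  expect_equal(g$mu2[1, ], 5)

  # uniform responsibilities: every component mean is the grand mean
  soft_u <- structure(list(
    tau = matrix(0.25, 3, 4), K = 2L,
    tau1 = matrix(numeric(0), 0, 2), tau2 = matrix(numeric(0), 0, 2)
  ), class = "scsc_soft")
  gu <- m_step_gaussian(d, soft_u, floor = 1e-6,
                        prev = random_params(2, 1, 1))
  expect_equal(gu$mu1, matrix(1, 2, 1))
  expect_equal(gu$mu2, matrix(5, 2, 1))

  # explicit weighted mean: weights (.2,.3,.5) on points (0,1,2) -> 1.3
  soft_w <- structure(list(
    tau = cbind(c(0.2, 0.3, 0.5), 0, 0, c(0.8, 0.7, 0.5)), K = 2L,
    tau1 = matrix(numeric(0), 0, 2), tau2 = matrix(numeric(0), 0, 2)
  ), class = "scsc_soft")
  gw <- m_step_gaussian(d, soft_w, floor = 1e-6,
                        prev = random_params(2, 1, 1))
  expect_equal(gw$mu1[1, ], 1.3)

  # an empty component keeps its previous parameters
  prev <- random_params(2, 1, 1, seed = 4)
  soft_e <- structure(list(
    tau = cbind(1, 0, 0, 0)[rep(1, 3), ], K = 2L,
    tau1 = matrix(numeric(0), 0, 2), tau2 = matrix(numeric(0), 0, 2)
  ), class = "scsc_soft")
  expect_message(ge <- m_step_gaussian(d, soft_e, floor = 1e-6,
                                       prev = prev),
                 "empty")
  expect_equal(ge$mu1[2, ], prev$mu1[2, ])
  expect_equal(ge$var1[2, ], prev$var1[2, ])
})

test_that("EM log-likelihood traces are non-decreasing on random problems", {
  worst <- Inf
  for (seed in 1:15) {
    set.seed(seed)
    d <- random_pairs(sample(15:30, 1), 3, 3,
                      n_u1 = sample(0:4, 1), n_u2 = sample(0:4, 1),
                      seed = seed + 30)
    cfg <- scsc_config(n_starts = 2, max_iter = 60, seed = seed,
                       noise = seed %% 2 == 0)
    fit <- fit_scsc(d, sample(2:3, 1), cfg)
    worst <- min(worst, min(diff(fit$loglik_trace)))
  }
  expect_gt(worst, -1e-8)
})

test_that("K = 1 collapses to per-species sample means", {
  d <- random_pairs(20, 4, 3, n_u1 = 3, n_u2 = 2, seed = 41)
  fit <- fit_scsc(d, 1, scsc_config(n_starts = 2, seed = 5, noise = FALSE))
  expect_equal(fit$params$mu1[1, ], unname(colMeans(rbind(d$x1, d$u1))),
               tolerance = 1e-8)
  expect_equal(fit$params$mu2[1, ], unname(colMeans(rbind(d$x2, d$u2))),
               tolerance = 1e-8)
})

test_that("well-separated clusters are recovered exactly", {
  # 1-d pairs from two clusters with means 0 and 10, member SD 0.5
  set.seed(99)
  lab <- rep(1:2, each = 25)
  mu <- c(0, 10)
  e1 <- expression_matrix(matrix(rnorm(50, mu[lab], 0.5), 50, 1),
                          sprintf("a%02d", 1:50), "s1")
  e2 <- expression_matrix(matrix(rnorm(50, mu[lab], 0.5), 50, 1),
                          sprintf("b%02d", 1:50), "t1")
  d <- build_paired_dataset(e1, e2, ortholog_map(rownames(e1),
                                                 rownames(e2)))
  fit <- fit_scsc(d, 2, scsc_config(n_starts = 4, seed = 17))
  hard <- harden_assignment(fit$soft, 0.5)
  truth <- data.frame(gene_id = c(rownames(e1), rownames(e2)),
                      species = rep(1:2, each = 50),
                      true_label = c(lab, lab))
  expect_equal(misassignment_proportion(truth, hard), 0)
})

test_that("with gamma fixed at zero the species-1 fit matches one-species EM", {
  # independent one-species Gaussian-mixture EM oracle (same update order)
  gmm_em <- function(X, mu0, var0, w0, iters, floor) {
    mu <- mu0; va <- var0; w <- w0
    for (it in seq_len(iters)) {
      ld <- sapply(seq_len(nrow(mu)), function(k) {
        apply(X, 1, oracle_dnorm_profile, mu = mu[k, ], v = va[k, ])
      })
      ld <- ld + rep(log(w), each = nrow(X))
      m <- apply(ld, 1, max)
      tau <- exp(ld - m) / rowSums(exp(ld - m))
      wsum <- colSums(tau)
      mu <- crossprod(tau, X) / wsum
      va <- pmax(crossprod(tau, X^2) / wsum - mu^2, floor)
      w <- wsum / sum(wsum)
    }
    list(mu = mu, var = va, w = w)
  }
  d <- random_pairs(40, 2, 2, seed = 77)
  K <- 2
  rp <- random_params(K, 2, 2, seed = 78)
  p0 <- scsc_params(K, rp$mu1, rp$var1, rp$mu2, rp$var2, gamma = 0)
  cfg <- scsc_config(n_starts = 1, max_iter = 12, tol = 1e-300,
                     fix_gamma = 0, noise = FALSE)
  run <- scsc_em(d, p0, cfg)
  expect_false(run$converged)
  # same initialization, same number of update cycles, uniform weights
  ref <- gmm_em(d$x1, p0$mu1, p0$var1, rep(1 / K, K),
                iters = run$n_iter, floor = cfg$variance_floor)
  expect_equal(unname(run$params$mu1), unname(ref$mu), tolerance = 1e-6)
})

test_that("degenerate inputs are rejected", {
  d <- random_pairs(5, 2, 2, seed = 3)
  expect_error(fit_scsc(d, 0), "at least 1")
  expect_error(fit_scsc(d, 6), "exceeds")
  e1 <- expression_matrix(matrix(1, 4, 2), paste0("a", 1:4), c("s1", "s2"))
  e2 <- expression_matrix(matrix(2, 4, 2), paste0("b", 1:4), c("t1", "t2"))
  dd <- build_paired_dataset(e1, e2, ortholog_map(paste0("a", 1:4),
                                                  paste0("b", 1:4)))
  expect_error(fit_scsc(dd, 2), "degenerate")
})
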