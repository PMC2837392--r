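make_hard <- function(gene_id, species, cluster, scatter = FALSE) {
  structure(data.frame(gene_id = gene_id, species = species,
                       cluster = cluster,
                       scatter = rep_len(scatter, length(gene_id)),
                       max_posterior = NA_real_,
                       stringsAsFactors = FALSE),
            class = c("scsc_hard", "data.frame"))
}

test_that("global scatter averages distances to assigned centers", {
  e1 <- expression_matrix(matrix(c(0, 2), 2, 1), c("a1", "a2"), "s1")
  e2 <- expression_matrix(matrix(c(0, 2), 2, 1), c("b1", "b2"), "t1")
  d <- build_paired_dataset(e1, e2, ortholog_map(c("a1", "a2"),
                                                 c("b1", "b2")))
  centers <- list(centers1 = matrix(1, 1, 1), centers2 = matrix(1, 1, 1))
  hard <- make_hard(c("a1", "a2", "b1", "b2"), c(1, 1, 2, 2), 1L)
  gs <- average_global_scatter(d, hard, centers)
  expect_equal(gs$value, 1.0)
  expect_equal(gs$n_used, 4L)
  # points exactly at their centers give zero
  centers0 <- list(centers1 = matrix(c(0, 2), 2, 1),
                   centers2 = matrix(c(0, 2), 2, 1))
  hard2 <- make_hard(c("a1", "a2", "b1", "b2"), c(1, 1, 2, 2),
                     c(1L, 2L, 1L, 2L))
  expect_equal(average_global_scatter(d, hard2, centers0)$value, 0)
  # scattered genes are excluded and counted
  hard3 <- make_hard(c("a1", "a2", "b1", "b2"), c(1, 1, 2, 2),
                     c(1L, NA, 1L, NA), scatter = c(FALSE, TRUE, FALSE, TRUE))
  gs3 <- average_global_scatter(d, hard3, centers)
  expect_equal(gs3$n_scatter_flagged, 2L)
  expect_equal(gs3$value, 1.0)
  # label without a center is an error
  expect_error(average_global_scatter(d, make_hard("a1", 1, 5L), centers),
               "center")
})

test_that("global scatter is invariant under joint relabeling", {
  d <- random_pairs(10, 3, 3, seed = 21)
  set.seed(22)
  centers1 <- matrix(rnorm(9), 3, 3)
  centers2 <- matrix(rnorm(9), 3, 3)
  lab <- sample(3, 10, replace = TRUE)
  hard <- make_hard(c(d$pair_id1, d$pair_id2), rep(1:2, each = 10),
                    c(lab, lab))
  v1 <- average_global_scatter(d, hard,
                               list(centers1 = centers1,
                                    centers2 = centers2))$value
  perm <- c(3L, 1L, 2L)
  hard_p <- make_hard(c(d$pair_id1, d$pair_id2), rep(1:2, each = 10),
                      c(perm[lab], perm[lab]))
  relab <- list(centers1 = centers1[order(perm), ],
                centers2 = centers2[order(perm), ])
  expect_equal(average_global_scatter(d, hard_p, relab)$value, v1)
})

test_that("center scatter uses optimal matching and detects translation", {
  truth <- list(centers1 = matrix(c(0, 10), 2, 1),
                centers2 = matrix(c(0, 10), 2, 1))
  est <- list(centers1 = matrix(c(10.5, 0.2), 2, 1),
              centers2 = matrix(c(0, 10), 2, 1))
  # species 1: optimal matching gives (0.2 + 0.5); species 2 exact
  expect_equal(average_center_scatter(truth, est), 0.7 / 4)
  expect_equal(average_center_scatter(truth, truth), 0)
  # single species worked example: (0.2 + 0.5) / 2 = 0.35
  one <- average_center_scatter(list(centers1 = truth$centers1,
                                     centers2 = matrix(0, 1, 1)),
                                list(centers1 = est$centers1,
                                     centers2 = matrix(0, 1, 1)))
  expect_equal(one, (0.2 + 0.5) / 3)
  # translating every estimated center by v gives ||v||
  set.seed(31)
  tc <- list(centers1 = matrix(rnorm(8), 4, 2),
             centers2 = matrix(rnorm(8), 4, 2))
  v <- c(1, -2)
  ec <- list(centers1 = sweep(tc$centers1, 2, -v),
             centers2 = sweep(tc$centers2, 2, -v))
  expect_equal(average_center_scatter(tc, ec), sqrt(sum(v^2)),
               tolerance = 1e-10)
  expect_error(average_center_scatter(tc,
                                      list(centers1 = tc$centers1[1:2, ],
                                           centers2 = tc$centers2)),
               "differ")
})

test_that("misassignment matches hand-computed examples", {
  truth <- data.frame(gene_id = paste0("g", 1:4), species = 1L,
                      true_label = c(1L, 1L, 2L, 2L))
  # perfect recovery
  expect_equal(misassignment_proportion(
    truth, make_hard(paste0("g", 1:4), 1L, c(1L, 1L, 2L, 2L))), 0)
  # label-permuted copy still perfect
  expect_equal(misassignment_proportion(
    truth, make_hard(paste0("g", 1:4), 1L, c(2L, 2L, 1L, 1L))), 0)
  # one gene wrong out of four
  expect_equal(misassignment_proportion(
    truth, make_hard(paste0("g", 1:4), 1L, c(1L, 2L, 2L, 2L))), 0.25)
  # scatter disagreement counts as wrong in both directions
  truth_sc <- data.frame(gene_id = paste0("g", 1:4), species = 1L,
                         true_label = c(1L, 1L, 2L, NA))
  expect_equal(misassignment_proportion(
    truth_sc, make_hard(paste0("g", 1:4), 1L, c(1L, 1L, 2L, NA),
                        scatter = c(FALSE, FALSE, FALSE, TRUE))), 0)
  expect_equal(misassignment_proportion(
    truth_sc, make_hard(paste0("g", 1:4), 1L, c(1L, 1L, 2L, 2L))), 0.25)
  expect_error(misassignment_proportion(
    truth, make_hard("unknown", 1L, 1L)), "unknown")
})

test_that("misassignment is invariant to cluster label permutations", {
  set.seed(41)
  for (rep in 1:5) {
    n <- 40
    truth <- data.frame(gene_id = paste0("g", 1:n),
                        species = rep(1:2, each = n / 2),
                        true_label = sample(3, n, replace = TRUE))
    est <- sample(3, n, replace = TRUE)
    hard <- make_hard(truth$gene_id, truth$species, est)
    base <- misassignment_proportion(truth, hard)
    perm <- sample(3)
    hard_p <- make_hard(truth$gene_id, truth$species, perm[est])
    expect_equal(misassignment_proportion(truth, hard_p), base)
    expect_gte(base, 0)
    expect_lte(base, 1)
  }
})

test_that("BHI matches the worked pair-counting examples", {
  # clusters identical to functional groups
  hard <- make_hard(c("A", "B", "C", "D"), 1L, c(1L, 1L, 2L, 2L))
  annot_perfect <- list(A = "f1", B = "f1", C = "f2", D = "f2")
  expect_equal(bhi(hard, annot_perfect), 1.0)
  # one cluster {A,B,C}; only A and B share a label: 1/3 of pairs
  hard3 <- make_hard(c("A", "B", "C"), 1L, 1L)
  expect_equal(bhi(hard3, list(A = "f1", B = "f1", C = "f2")), 1 / 3)
  # no shared labels anywhere
  expect_equal(bhi(hard3, list(A = "f1", B = "f2", C = "f3")), 0)
  # multi-label genes share through any common group
  expect_equal(bhi(hard3, list(A = c("f1", "f9"), B = "f9", C = "f2")),
               1 / 3)
  # unannotated genes are ignored; need two annotated genes somewhere
  expect_error(bhi(hard3, list(A = "f1")), "two or more")
  expect_error(bhi(hard3, list(A = character(0), B = "f1")), "empty")
})

test_that("k-means baseline collapses, reproduces, and splits blobs", {
  e1 <- make_expr(paste0("a", 1:12), paste0("s", 1:3), seed = 51)
  e2 <- make_expr(paste0("b", 1:12), paste0("t", 1:3), seed = 52)
  km1 <- kmeans_baseline(e1, e2, 1, n_starts = 2, seed = 9)
  expect_equal(km1$centers1[1, ], unname(colMeans(e1)))
  expect_equal(unique(km1$hard$cluster), 1L)
  # reproducibility
  km_a <- kmeans_baseline(e1, e2, 3, n_starts = 3, seed = 4)
  km_b <- kmeans_baseline(e1, e2, 3, n_starts = 3, seed = 4)
  expect_identical(km_a$hard, km_b$hard)
  # two well-separated blobs are split perfectly
  spec <- synthetic_spec(n_clusters = 2, d1 = 2, d2 = 2,
                         genes_per_cluster = 15, n_scatter = 0,
                         mean_range = c(0, 40), sd1 = 1, sd2 = 1)
  sim <- generate_paired_dataset(spec, seed = 6)
  km <- kmeans_baseline(sim$expr1, sim$expr2, 2, n_starts = 5, seed = 7)
  expect_equal(misassignment_proportion(sim$truth, km$hard), 0)
  expect_error(kmeans_baseline(e1, e2, 40, seed = 1), "exceeds")
})

test_that("random baseline assigns every gene to its nearest centroid", {
  e <- make_expr(paste0("g", 1:30), paste0("s", 1:4), seed = 61)
  rb <- random_baseline(e, 3, seed = 13)
  # brute-force nearest-centroid check
  for (i in 1:30) {
    dd <- apply(rb$centers, 1, function(ct) sqrt(sum((e[i, ] - ct)^2)))
    expect_equal(rb$hard$cluster[i], which.min(dd))
  }
  # centroids inside the data box
  expect_true(all(rb$centers >= rep(apply(e, 2, min), each = 3)))
  expect_true(all(rb$centers <= rep(apply(e, 2, max), each = 3)))
  expect_identical(random_baseline(e, 3, seed = 13)$hard, rb$hard)
  expect_equal(unique(random_baseline(e, 1, seed = 2)$hard$cluster), 1L)
})

test_that("random baseline is worse than k-means on separated clusters", {
  worse <- 0
  for (seed in 1:5) {
    spec <- synthetic_spec(n_clusters = 3, d1 = 4, d2 = 4,
                           genes_per_cluster = 20, n_scatter = 0,
                           mean_range = c(0, 20), sd1 = 1, sd2 = 1)
    sim <- generate_paired_dataset(spec, seed = seed)
    km <- kmeans_baseline(sim$expr1, sim$expr2, 3, n_starts = 5,
                          seed = seed)
    r1 <- random_baseline(sim$expr1, 3, seed = seed, species = 1)
    r2 <- random_baseline(sim$expr2, 3, seed = seed + 100, species = 2)
    rnd <- structure(rbind(r1$hard, r2$hard),
                     class = c("scsc_hard", "data.frame"))
    worse <- worse +
      (misassignment_proportion(sim$truth, rnd) >
         misassignment_proportion(sim$truth, km$hard))
  }
  expect_gte(worse, 4)
})
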