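#' Average global scatter
#'
#' The average Euclidean distance between every non-scattered gene and the
#' center of the cluster it was assigned to, pooled across the two species:
#' the distance sum over both species divided by the total number of
#' non-scattered genes in both species. Scatter-flagged genes are excluded
#' and counted separately.
#'
#' @param data a [build_paired_dataset()] result supplying the profiles.
#' @param hard an [harden_assignment()] result (or any data frame with
#'   columns `gene_id`, `species`, `cluster`, `scatter`).
#' @param centers list with `centers1` (K x d1) and `centers2` (K x d2)
#'   cluster-center matrices.
#' @return list with `value` (the average distance), `n_used`, and
#'   `n_scatter_flagged`.
#' @export
average_global_scatter <- function(data, hard, centers) {
  profiles <- list(`1` = rbind(data$x1, data$u1),
                   `2` = rbind(data$x2, data$u2))
  cents <- list(`1` = rbind(centers$centers1), `2` = rbind(centers$centers2))
  hard <- as.data.frame(hard)
  if (is.null(hard$scatter)) hard$scatter <- is.na(hard$cluster)
  use <- !hard$scatter
  total <- 0
  for (s in c(1L, 2L)) {
    h <- hard[use & hard$species == s, , drop = FALSE]
    if (nrow(h) == 0L) next
    P <- profiles[[as.character(s)]]
    if (!all(h$gene_id %in% rownames(P))) {
      stop("assignment contains genes absent from the dataset")
    }
    if (any(h$cluster > nrow(cents[[as.character(s)]]))) {
      stop("cluster label without a center")
    }
    X <- P[h$gene_id, , drop = FALSE]
    total <- total +
      sum(sqrt(rowSums((X - cents[[as.character(s)]][h$cluster, ,
                                                     drop = FALSE])^2)))
  }
  n_used <- sum(use)
  list(value = if (n_used > 0L) total / n_used else 0,
       n_used = n_used, n_scatter_flagged = sum(hard$scatter))
}

#' Average center scatter
#'
#' The average Euclidean distance between true cluster centers and their
#' corresponding estimated centers. Within each species, estimated centers
#' are matched to true centers by the minimum-total-distance assignment;
#' matched distances are summed over both species and divided by the total
#' number of clusters in both species. Zero for perfect recovery.
#'
#' @param true_centers,est_centers lists with `centers1` and `centers2`
#'   matrices; cluster counts must agree per species between truth and
#'   estimate.
#' @return scalar average center scatter.
#' @export
average_center_scatter <- function(true_centers, est_centers) {
  one_species <- function(tc, ec) {
    tc <- rbind(tc); ec <- rbind(ec)
    if (nrow(tc) != nrow(ec)) {
      stop("true and estimated cluster counts differ")
    }
    ## direct differences (not the expanded quadratic form) so identical
    ## centers give an exact zero
    D <- matrix(0, nrow(tc), nrow(ec))
    for (i in seq_len(nrow(tc))) {
      D[i, ] <- sqrt(colSums((t(ec) - tc[i, ])^2))
    }
    p <- solve_assignment(D)
    sum(D[cbind(seq_len(nrow(tc)), p)])
  }
  s1 <- one_species(true_centers$centers1, est_centers$centers1)
  s2 <- one_species(true_centers$centers2, est_centers$centers2)
  (s1 + s2) / (nrow(rbind(true_centers$centers1)) +
                 nrow(rbind(true_centers$centers2)))
}

#' Misassignment proportion
#'
#' The proportion of genes assigned to wrong clusters, pooled over both
#' species. Within each species, estimated labels are mapped to true labels
#' by the agreement-maximizing assignment on the truth-by-estimate
#' contingency table (scattered genes are excluded from the matching). A
#' gene counts as wrong if its mapped label differs from its true label, or
#' if exactly one of truth and estimate marks it as scattered.
#'
#' @param truth a `synthetic_truth` object (or its `labels` data frame with
#'   columns `gene_id`, `species`, `true_label`).
#' @param hard an [harden_assignment()]-style data frame.
#' @return proportion in `[0, 1]`.
#' @export
misassignment_proportion <- function(truth, hard) {
  tl <- if (inherits(truth, "synthetic_truth")) truth$labels else
    as.data.frame(truth)
  hard <- as.data.frame(hard)
  if (is.null(hard$scatter)) hard$scatter <- is.na(hard$cluster)
  key_t <- paste(tl$species, tl$gene_id)
  key_h <- paste(hard$species, hard$gene_id)
  if (!all(key_h %in% key_t)) {
    stop("assignment contains genes unknown to the truth")
  }
  m <- match(key_h, key_t)
  truth_lab <- tl$true_label[m]
  est_lab <- hard$cluster
  est_lab[hard$scatter] <- NA_integer_
  wrong <- logical(nrow(hard))
  for (s in c(1L, 2L)) {
    idx <- which(hard$species == s)
    t_s <- truth_lab[idx]
    e_s <- est_lab[idx]
    both <- !is.na(t_s) & !is.na(e_s)
    ## scatter disagreement: exactly one side scattered
    wrong[idx[xor(is.na(t_s), is.na(e_s))]] <- TRUE
    if (!any(both)) next
    tv <- sort(unique(t_s[both]))
    ev <- sort(unique(e_s[both]))
    tab <- matrix(0, length(tv), length(ev))
    ti <- match(t_s[both], tv)
    ei <- match(e_s[both], ev)
    for (i in seq_along(ti)) tab[ti[i], ei[i]] <- tab[ti[i], ei[i]] + 1
    p <- solve_assignment(-tab)  # maximize agreement; est label per truth row
    mapped_est_of_truth <- rep(NA_integer_, length(tv))
    mapped_est_of_truth[!is.na(p)] <- ev[p[!is.na(p)]]
    cmp <- mapped_est_of_truth[ti] != ev[ei]
    cmp[is.na(cmp)] <- TRUE  # truth label matched to no estimated label
    wrong[idx[both][cmp]] <- TRUE
  }
  mean(wrong)
}

#' Biological homogeneity index (BHI)
#'
#' The average, over clusters containing at least two annotated genes, of
#' the proportion of annotated gene pairs in the cluster that share at least
#' one functional group label. Clusters are per-species entities (grouped by
#' species and cluster index); scattered genes are excluded. A greater BHI
#' reflects higher consistency between clusters and functional groups.
#'
#' @param hard an [harden_assignment()]-style data frame.
#' @param annot named list mapping gene identifiers to non-empty character
#'   vectors of functional group labels.
#' @return BHI in `[0, 1]`.
#' @export
bhi <- function(hard, annot) {
  hard <- as.data.frame(hard)
  if (is.null(hard$scatter)) hard$scatter <- is.na(hard$cluster)
  if (any(lengths(annot) == 0L)) stop("empty annotation label sets")
  h <- hard[!hard$scatter & hard$gene_id %in% names(annot), , drop = FALSE]
  groups <- split(h$gene_id, paste(h$species, h$cluster))
  groups <- groups[lengths(groups) >= 2L]
  if (length(groups) == 0L) {
    stop("no cluster contains two or more annotated genes")
  }
  per_cluster <- vapply(groups, function(g) {
    pairs <- utils::combn(length(g), 2L)
    share <- apply(pairs, 2L, function(ij) {
      length(intersect(annot[[g[ij[1L]]]], annot[[g[ij[2L]]]])) > 0L
    })
    mean(share)
  }, numeric(1L))
  mean(per_cluster)
}

#' Per-species K-means baseline
#'
#' Standard K-means (Euclidean, Lloyd iterations, k-means++ style seeding,
#' `n_starts` restarts keeping the lowest within-cluster sum of squares) run
#' independently on each species, as the uncoupled comparison point for the
#' cross-species model. Deterministic given `seed`.
#'
#' @param expr1,expr2 expression matrices.
#' @param K clusters per species.
#' @param n_starts number of seeding restarts.
#' @param seed integer RNG seed.
#' @return list with `hard` (an `scsc_hard`-style data frame covering both
#'   species; no scatter flags), `centers1`, `centers2`.
#' @export
kmeans_baseline <- function(expr1, expr2, K, n_starts = 10L, seed = 1L) {
  set.seed(seed)
  run_one <- function(X) {
    if (K > nrow(X)) stop("K exceeds the gene count of a species")
    best <- NULL
    for (r in seq_len(n_starts)) {
      c0 <- kmeanspp_centers(X, K)
      km <- tryCatch(
        suppressWarnings(stats::kmeans(X, c0, iter.max = 100L,
                                       algorithm = "Lloyd")),
        error = function(e) NULL
      )
      if (is.null(km)) next
      if (any(km$size == 0L)) {
        message("empty K-means cluster; re-seeding")
        next
      }
      if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    }
    if (is.null(best)) stop("K-means failed on every restart")
    best
  }
  km1 <- run_one(expr1)
  km2 <- run_one(expr2)
  hard <- rbind(
    data.frame(gene_id = rownames(expr1), species = 1L,
               cluster = as.integer(km1$cluster), scatter = FALSE,
               max_posterior = NA_real_, stringsAsFactors = FALSE),
    data.frame(gene_id = rownames(expr2), species = 2L,
               cluster = as.integer(km2$cluster), scatter = FALSE,
               max_posterior = NA_real_, stringsAsFactors = FALSE)
  )
  rownames(hard) <- NULL
  list(hard = structure(hard, class = c("scsc_hard", "data.frame")),
       centers1 = unname(km1$centers), centers2 = unname(km2$centers))
}

#' Random-centroid baseline
#'
#' Draws K centroids uniformly within the per-dimension min/max box of the
#' data and assigns each gene to its nearest centroid (Euclidean distance,
#' ties toward the lowest centroid index). The floor any informative
#' clusterer should beat.
#'
#' @param expr an expression matrix.
#' @param K number of centroids.
#' @param seed integer RNG seed.
#' @param species species index recorded in the assignment (1 or 2).
#' @return list with `hard` (assignment data frame for this species) and
#'   `centers`.
#' @export
random_baseline <- function(expr, K, seed = 1L, species = 1L) {
  stopifnot(K >= 1L)
  set.seed(seed)
  lo <- apply(expr, 2L, min)
  hi <- apply(expr, 2L, max)
  centers <- t(replicate(K, stats::runif(ncol(expr), lo, hi)))
  if (K == 1L) centers <- matrix(centers, 1L, ncol(expr))
  lab <- nearest_centroid(unclass(expr), centers)
  hard <- data.frame(gene_id = rownames(expr), species = as.integer(species),
                     cluster = as.integer(lab), scatter = FALSE,
                     max_posterior = NA_real_, stringsAsFactors = FALSE)
  list(hard = structure(hard, class = c("scsc_hard", "data.frame")),
       centers = centers)
}
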