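#' Specification of a synthetic paired two-species dataset
#'
#' Describes one benchmark design: `n_clusters` conserved co-expression
#' clusters whose per-species mean profiles are drawn independently and
#' uniformly per coordinate from `mean_range`, `genes_per_cluster` ortholog
#' pairs per cluster with isotropic Gaussian member noise (`sd1`, `sd2` per
#' species), and `n_scatter` scattered ortholog pairs drawn uniformly over
#' `mean_range` that belong to no cluster.
#'
#' @param n_clusters number of clusters (same in both species).
#' @param d1,d2 samples per species.
#' @param genes_per_cluster ortholog pairs per cluster.
#' @param n_scatter scattered ortholog pairs.
#' @param mean_range length-2 numeric `(lo, hi)` for cluster-mean
#'   coordinates.
#' @param sd1,sd2 member-noise standard deviations per species.
#' @param label free-text dataset name.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_clusters = 10L, d1 = 20L, d2 = 20L,
                           genes_per_cluster = 30L, n_scatter = 100L,
                           mean_range = c(0, 10), sd1 = 1, sd2 = 1,
                           label = "custom") {
  stopifnot(n_clusters >= 1L, d1 >= 1L, d2 >= 1L, genes_per_cluster >= 1L,
            n_scatter >= 0L, length(mean_range) == 2L,
            mean_range[1L] < mean_range[2L], sd1 > 0, sd2 > 0)
  structure(list(n_clusters = as.integer(n_clusters), d1 = as.integer(d1),
                 d2 = as.integer(d2),
                 genes_per_cluster = as.integer(genes_per_cluster),
                 n_scatter = as.integer(n_scatter),
                 mean_range = as.numeric(mean_range),
                 sd1 = sd1, sd2 = sd2, label = label),
            class = "synthetic_spec")
}

#' Packaged benchmark dataset designs
#'
#' Six designs spanning increasing cluster overlap: each has 10 clusters,
#' 20 samples per species, 30 ortholog pairs per cluster and 100 scattered
#' pairs. Designs 1-5 draw cluster means uniformly on (0, 10) with member
#' noise SD pairs (1,1), (1,2), (2,2), (2.5,2.5) and (1,3); design 6 draws
#' means on (0, 13) with SD 3 in both species. All fields can be overridden
#' by building a [synthetic_spec()] directly.
#'
#' @param dataset_id integer in 1..6.
#' @return a [synthetic_spec()].
#' @export
builtin_spec <- function(dataset_id) {
  if (length(dataset_id) != 1L || !dataset_id %in% 1:6) {
    stop("'dataset_id' must be a single integer in 1..6")
  }
  sds <- list(c(1, 1), c(1, 2), c(2, 2), c(2.5, 2.5), c(1, 3), c(3, 3))
  rng <- if (dataset_id == 6L) c(0, 13) else c(0, 10)
  s <- sds[[dataset_id]]
  synthetic_spec(mean_range = rng, sd1 = s[1L], sd2 = s[2L],
                 label = paste0("dataset", dataset_id))
}

#' Generate a paired two-species dataset with known truth
#'
#' Draws, for each cluster, independent per-species mean profiles uniform on
#' `mean_range`, then emits `genes_per_cluster` ortholog pairs per cluster
#' with coordinate-wise Gaussian noise, followed by `n_scatter` scattered
#' pairs whose coordinates are uniform on `mean_range` in both species. The
#' ortholog map pairs gene j of species 1 with gene j of species 2.
#' Identical `(spec, seed)` give bit-identical output.
#'
#' @param spec a [synthetic_spec()].
#' @param seed integer RNG seed.
#' @return list with `expr1`, `expr2` (expression matrices), `map`
#'   ([ortholog_map()]), and `truth` — a list with `labels` (data frame
#'   `gene_id`, `species`, `true_label`, `NA` for scattered genes),
#'   `centers1`, `centers2` (K x d mean matrices), and `map`.
#' @export
generate_paired_dataset <- function(spec, seed = 1L) {
  if (!inherits(spec, "synthetic_spec")) stop("'spec' must be a synthetic_spec")
  set.seed(seed)
  K <- spec$n_clusters
  lo <- spec$mean_range[1L]
  hi <- spec$mean_range[2L]
  centers1 <- matrix(stats::runif(K * spec$d1, lo, hi), K, spec$d1)
  centers2 <- matrix(stats::runif(K * spec$d2, lo, hi), K, spec$d2)
  n <- K * spec$genes_per_cluster + spec$n_scatter
  lab <- c(rep(seq_len(K), each = spec$genes_per_cluster),
           rep(NA_integer_, spec$n_scatter))
  x1 <- matrix(0, n, spec$d1)
  x2 <- matrix(0, n, spec$d2)
  memb <- !is.na(lab)
  x1[memb, ] <- centers1[lab[memb], , drop = FALSE] +
    stats::rnorm(sum(memb) * spec$d1, sd = spec$sd1)
  x2[memb, ] <- centers2[lab[memb], , drop = FALSE] +
    stats::rnorm(sum(memb) * spec$d2, sd = spec$sd2)
  if (spec$n_scatter > 0L) {
    x1[!memb, ] <- stats::runif(spec$n_scatter * spec$d1, lo, hi)
    x2[!memb, ] <- stats::runif(spec$n_scatter * spec$d2, lo, hi)
  }
  id1 <- sprintf("s1_g%04d", seq_len(n))
  id2 <- sprintf("s2_g%04d", seq_len(n))
  expr1 <- expression_matrix(x1, id1, sprintf("s1_smp%02d", seq_len(spec$d1)))
  expr2 <- expression_matrix(x2, id2, sprintf("s2_smp%02d", seq_len(spec$d2)))
  map <- ortholog_map(id1, id2)
  labels <- rbind(
    data.frame(gene_id = id1, species = 1L, true_label = lab,
               stringsAsFactors = FALSE),
    data.frame(gene_id = id2, species = 2L, true_label = lab,
               stringsAsFactors = FALSE)
  )
  list(expr1 = expr1, expr2 = expr2, map = map,
       truth = structure(list(labels = labels, centers1 = centers1,
                              centers2 = centers2, map = map),
                         class = "synthetic_truth"))
}

#' Rewire a fraction of ortholog links into wrong matches
#'
#' Selects `m = round(fraction * N)` pairs uniformly without replacement
#' (`m` is promoted to 2 when it would be 1, since a single link cannot be
#' made wrong on its own) and applies a uniformly random derangement to the
#' species-2 partners of the selected pairs, so that every selected link
#' becomes a wrong match while the map stays one-to-one and the partner
#' multiset is preserved. Unselected links are untouched.
#'
#' @param map an [ortholog_map()].
#' @param fraction proportion of links to rewire, in `[0, 1]`.
#' @param seed integer RNG seed.
#' @return the rewired [ortholog_map()].
#' @export
perturb_orthology <- function(map, fraction, seed = 1L) {
  stopifnot(fraction >= 0, fraction <= 1)
  if (!inherits(map, "ortholog_map")) map <- ortholog_map(map[[1L]], map[[2L]])
  N <- nrow(map)
  if (fraction == 0) return(map)
  if (N < 2L) stop("need at least 2 ortholog links to introduce errors")
  m <- round(fraction * N)
  if (m == 0L) return(map)
  if (m == 1L) m <- 2L
  set.seed(seed)
  sel <- sort(sample.int(N, m))
  perm <- random_derangement(m)
  map$id2[sel] <- map$id2[sel][perm]
  map
}

## Uniformly random derangement by rejection sampling (expected ~e tries).
random_derangement <- function(m) {
  stopifnot(m >= 2L)
  repeat {
    p <- sample.int(m)
    if (all(p != seq_len(m))) return(p)
  }
}
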