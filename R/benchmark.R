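#' Run the synthetic benchmark harness
#'
#' For every combination of dataset design, ortholog-map error fraction,
#' method and replicate: generate a dataset with known truth, rewire the
#' stated fraction of ortholog links, cluster with the method, and score the
#' result against the truth on the three metrics (global scatter, center
#' scatter, misassignment). Replicate r generates with seed
#' `base_seed + r`; all downstream randomness is derived from that seed, so
#' the whole table is reproducible. An individual run failure is recorded as
#' a missing row, not an error.
#'
#' @param spec_ids integer vector of packaged designs (see
#'   [builtin_spec()]); ignored when `specs` is supplied.
#' @param methods subset of `c("scsc", "kmeans", "random")`.
#' @param n_reps replicates per condition (the benchmark default is 20
#'   independent runs).
#' @param error_fractions proportions of ortholog links rewired.
#' @param base_seed integer base seed.
#' @param config an [scsc_config()] used for the model fits.
#' @param specs optional named list of [synthetic_spec()] objects replacing
#'   the packaged designs.
#' @return an object of class `scsc_benchmark`: list with `runs` (long
#'   table: dataset, error_fraction, method, rep, seed, global_scatter,
#'   center_scatter, misassignment, bhi) and `summary` (per-condition means
#'   and SDs).
#' @export
run_benchmark <- function(spec_ids = 1L,
                          methods = c("scsc", "kmeans", "random"),
                          n_reps = 20L, error_fractions = 0,
                          base_seed = 1L, config = scsc_config(),
                          specs = NULL) {
  stopifnot(n_reps >= 1L)
  methods <- match.arg(methods, c("scsc", "kmeans", "random"),
                       several.ok = TRUE)
  if (is.null(specs)) {
    specs <- lapply(spec_ids, builtin_spec)
    names(specs) <- vapply(specs, `[[`, character(1L), "label")
  } else if (is.null(names(specs))) {
    names(specs) <- paste0("spec", seq_along(specs))
  }
  rows <- list()
  for (sname in names(specs)) {
    spec <- specs[[sname]]
    for (rep_i in seq_len(n_reps)) {
      gen_seed <- base_seed + rep_i
      sim <- generate_paired_dataset(spec, seed = gen_seed)
      for (fr in error_fractions) {
        map_f <- perturb_orthology(sim$map, fr, seed = gen_seed + 10000L)
        for (method in methods) {
          res <- tryCatch(
            benchmark_one(sim, map_f, spec, method, gen_seed, config),
            error = function(e) {
              warning("run failed (", sname, ", fraction ", fr, ", ",
                      method, ", rep ", rep_i, "): ",
                      conditionMessage(e))
              NULL
            }
          )
          rows[[length(rows) + 1L]] <- data.frame(
            dataset = sname, error_fraction = fr, method = method,
            rep = rep_i, seed = gen_seed,
            global_scatter = if (is.null(res)) NA_real_ else res$gs,
            center_scatter = if (is.null(res)) NA_real_ else res$cs,
            misassignment = if (is.null(res)) NA_real_ else res$mis,
            bhi = NA_real_, stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  runs <- do.call(rbind, rows)
  agg <- stats::aggregate(
    runs[, c("global_scatter", "center_scatter", "misassignment")],
    by = runs[, c("dataset", "error_fraction", "method")],
    FUN = function(x) c(mean = mean(x, na.rm = TRUE),
                        sd = stats::sd(x, na.rm = TRUE))
  )
  summary <- do.call(data.frame, agg)
  structure(list(runs = runs, summary = summary), class = "scsc_benchmark")
}

benchmark_one <- function(sim, map_f, spec, method, gen_seed, config) {
  truth_centers <- list(centers1 = sim$truth$centers1,
                        centers2 = sim$truth$centers2)
  data_f <- build_paired_dataset(sim$expr1, sim$expr2, map_f)
  K <- spec$n_clusters
  if (method == "scsc") {
    cfg <- config
    cfg$seed <- gen_seed + 20000L
    fit <- fit_scsc(data_f, K, cfg)
    hard <- harden_assignment(fit$soft, cfg$scatter_threshold)
    centers <- list(centers1 = fit$params$mu1, centers2 = fit$params$mu2)
  } else if (method == "kmeans") {
    km <- kmeans_baseline(sim$expr1, sim$expr2, K,
                          n_starts = config$n_starts,
                          seed = gen_seed + 30000L)
    hard <- km$hard
    centers <- list(centers1 = km$centers1, centers2 = km$centers2)
  } else {
    r1 <- random_baseline(sim$expr1, K, seed = gen_seed + 40000L,
                          species = 1L)
    r2 <- random_baseline(sim$expr2, K, seed = gen_seed + 40001L,
                          species = 2L)
    hard <- structure(rbind(r1$hard, r2$hard),
                      class = c("scsc_hard", "data.frame"))
    centers <- list(centers1 = r1$centers, centers2 = r2$centers)
  }
  list(
    gs = average_global_scatter(data_f, hard, centers)$value,
    cs = average_center_scatter(truth_centers, centers),
    mis = misassignment_proportion(sim$truth, hard)
  )
}

#' @export
print.scsc_benchmark <- function(x, ...) {
  cat("scsc_benchmark:", nrow(x$runs), "runs\n")
  print(x$summary, ...)
  invisible(x)
}
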