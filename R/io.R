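#' Read an expression matrix from TSV
#'
#' Dialect: tab-separated, '.' decimal point, header row of sample
#' identifiers (optionally preceded by a gene-id column header), first
#' column gene identifiers. Duplicate gene ids, non-numeric cells and
#' ragged rows are rejected with the offending line number.
#'
#' @param path file path.
#' @return an [expression_matrix()].
#' @export
read_expression_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop("expression TSV needs a header and data rows")
  cells <- strsplit(lines, "\t", fixed = TRUE)
  header <- cells[[1L]]
  body <- cells[-1L]
  width <- length(body[[1L]])
  samples <- if (length(header) == width) header[-1L] else header
  if (length(samples) != width - 1L) {
    stop("header has ", length(header), " fields but data rows have ",
         width, " (line 2)")
  }
  n <- length(body)
  gene_ids <- character(n)
  vals <- matrix(NA_real_, n, width - 1L)
  for (i in seq_len(n)) {
    row <- body[[i]]
    if (length(row) != width) {
      stop("ragged row at line ", i + 1L, ": expected ", width,
           " fields, found ", length(row))
    }
    gene_ids[i] <- row[1L]
    v <- suppressWarnings(as.numeric(row[-1L]))
    if (anyNA(v)) {
      stop("non-numeric expression value at line ", i + 1L, " (gene ",
           row[1L], ")")
    }
    vals[i, ] <- v
  }
  if (anyDuplicated(gene_ids)) {
    dup <- gene_ids[duplicated(gene_ids)][1L]
    stop("duplicate gene id '", dup, "' at line ",
         which(gene_ids == dup)[2L] + 1L)
  }
  expression_matrix(vals, gene_ids, samples)
}

#' Write an expression matrix to TSV
#'
#' @param expr an [expression_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(expr, path) {
  expr <- expression_matrix(expr)
  header <- paste(c("gene_id", colnames(expr)), collapse = "\t")
  rows <- paste(rownames(expr),
                apply(expr, 1L, function(v)
                  paste(format(v, digits = 15, trim = TRUE,
                               scientific = FALSE), collapse = "\t")),
                sep = "\t")
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read a two-column ortholog map from TSV
#'
#' Two tab-separated columns (species-1 id, species-2 id); lines starting
#' with `#` are treated as headers/comments and skipped. The map must be
#' one-to-one.
#'
#' @param path file path.
#' @return an [ortholog_map()].
#' @export
read_ortholog_map_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) return(ortholog_map(character(0), character(0)))
  cells <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(cells) < 2L)
  if (length(bad)) {
    stop("ortholog map line ", bad[1L], " does not have two columns")
  }
  ortholog_map(vapply(cells, `[[`, character(1L), 1L),
               vapply(cells, `[[`, character(1L), 2L))
}

#' Write an ortholog map to TSV
#' @param map an [ortholog_map()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ortholog_map_tsv <- function(map, path) {
  writeLines(c("#id1\tid2", paste(map$id1, map$id2, sep = "\t")), path)
  invisible(path)
}

#' Serialize a fitted model to JSON
#'
#' The document holds K, the logit prior parameters, the correspondence
#' permutation, component means and variances, the log-likelihood trace,
#' the seed, and a verbatim echo of the configuration — everything needed
#' to reproduce or reload the fit.
#'
#' @param fit an `scsc_fit` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(fit, path) {
  p <- fit$params
  doc <- list(
    K = p$K, alpha = p$alpha, beta = p$beta, gamma = p$gamma,
    correspondence = p$correspondence,
    mu1 = p$mu1, var1 = p$var1, mu2 = p$mu2, var2 = p$var2,
    gamma_max = p$gamma_max,
    bg1 = p$bg1, bg2 = p$bg2,
    alpha_bg = p$alpha_bg, beta_bg = p$beta_bg,
    loglik_trace = fit$loglik_trace, converged = fit$converged,
    n_iter = fit$n_iter, seed = fit$seed,
    restart_index = fit$restart_index,
    config = fit$config[!vapply(fit$config, is.null, logical(1L))]
  )
  doc <- doc[!vapply(doc, is.null, logical(1L))]
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' Reload model parameters from JSON
#' @param path a file written by [write_model_json()].
#' @return list with `params` ([scsc_params()]), `loglik_trace`, `seed`,
#'   `config`.
#' @export
read_model_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- scsc_params(doc$K, doc$mu1, doc$var1, doc$mu2, doc$var2,
                        alpha = doc$alpha, beta = doc$beta,
                        gamma = doc$gamma,
                        correspondence = doc$correspondence,
                        gamma_max = doc$gamma_max,
                        bg1 = doc$bg1, bg2 = doc$bg2,
                        alpha_bg = if (is.null(doc$alpha_bg)) 0 else doc$alpha_bg,
                        beta_bg = if (is.null(doc$beta_bg)) 0 else doc$beta_bg)
  list(params = params, loglik_trace = doc$loglik_trace, seed = doc$seed,
       config = doc$config)
}

#' Write an assignment table to TSV
#'
#' Columns: gene_id, species, cluster (integer or the literal `SCATTER`),
#' max_posterior.
#'
#' @param hard an [harden_assignment()] result.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_assignment_tsv <- function(hard, path) {
  cl <- ifelse(hard$scatter, "SCATTER", as.character(hard$cluster))
  post <- ifelse(is.na(hard$max_posterior), "NA",
                 format(hard$max_posterior, digits = 15, trim = TRUE,
                        scientific = FALSE))
  writeLines(c("gene_id\tspecies\tcluster\tmax_posterior",
               paste(hard$gene_id, hard$species, cl, post, sep = "\t")),
             path)
  invisible(path)
}

#' Read an assignment table written by [write_assignment_tsv()]
#' @param path file path.
#' @return an `scsc_hard`-style data frame.
#' @export
read_assignment_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c("character", "integer",
                                         "character", "character"))
  scatter <- df$cluster == "SCATTER"
  cluster <- suppressWarnings(as.integer(df$cluster))
  out <- data.frame(gene_id = df$gene_id, species = df$species,
                    cluster = cluster, scatter = scatter,
                    max_posterior = suppressWarnings(
                      as.numeric(df$max_posterior)),
                    stringsAsFactors = FALSE)
  structure(out, class = c("scsc_hard", "data.frame"))
}

#' Write the artifacts of one fit to a directory
#'
#' Writes the assignment TSV (`assignment.tsv`), the model JSON
#' (`model.json`) and a short run log (`run.log`). Every artifact embeds
#' the seed and configuration needed to reproduce it.
#'
#' @param fit an `scsc_fit` object.
#' @param hard an [harden_assignment()] result.
#' @param config the [scsc_config()] used.
#' @param outdir output directory (created if needed).
#' @return named character vector of the written paths, invisibly.
#' @export
write_outputs <- function(fit, hard, config, outdir) {
  if (!dir.exists(outdir)) {
    ok <- dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", outdir)
  }
  paths <- c(assignment = file.path(outdir, "assignment.tsv"),
             model = file.path(outdir, "model.json"),
             log = file.path(outdir, "run.log"))
  write_assignment_tsv(hard, paths[["assignment"]])
  fit$config <- config
  write_model_json(fit, paths[["model"]])
  writeLines(c(
    paste0("scsclust fit; K = ", fit$params$K, "; seed = ", fit$seed),
    paste0("final loglik = ",
           format(fit$loglik_trace[length(fit$loglik_trace)], digits = 12)),
    paste0("iterations = ", fit$n_iter, "; converged = ", fit$converged,
           "; winning restart = ", fit$restart_index),
    paste0("config: ", paste(names(config), "=",
                             vapply(config, function(v)
                               paste(format(v), collapse = ","),
                               character(1L)),
                             collapse = "; "))
  ), paths[["log"]])
  invisible(paths)
}
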