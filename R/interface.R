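# File interchange: tab-separated, UTF-8, '.' decimal, no quoting; gzip by
# extension. Wide matrices for E, C and S_hat; long-format TSV for anything
# keyed by (gene, cell type). Output files carry '#' header comments with
# the package version and the seed so runs are auditable.

open_out <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
}

header_comment <- function(what, seed = NULL) {
  v <- as.character(utils::packageVersion("csdebench"))
  h <- paste0("# csdebench ", v, " ", what)
  if (!is.null(seed)) h <- c(h, paste0("# seed: ", seed))
  h
}

#' Write a labeled numeric matrix as TSV
#'
#' First column holds row identifiers (header `id`), remaining columns the
#' samples. A `.gz` extension writes gzip-compressed output.
#'
#' @param x Labeled numeric matrix.
#' @param path Output path.
#' @param what One-word content tag for the header comment.
#' @param seed Optional seed recorded in the header.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(x, path, what = "matrix", seed = NULL) {
  x <- as.matrix(x)
  if (is.null(rownames(x))) rownames(x) <- paste0("r", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- paste0("s", seq_len(ncol(x)))
  con <- open_out(path)
  on.exit(close(con))
  writeLines(header_comment(what, seed), con)
  writeLines(paste(c("id", colnames(x)), collapse = "\t"), con)
  body <- apply(x, 1, function(r) paste(sprintf("%.17g", r), collapse = "\t"))
  writeLines(paste(rownames(x), body, sep = "\t"), con)
  invisible(path)
}

#' Read a labeled numeric matrix from TSV
#'
#' Expects the layout written by [write_matrix()]: '#' comment lines, a
#' header row of sample identifiers, a first column of row identifiers and
#' a numeric body. Errors name the offending cell on non-numeric input and
#' reject duplicated row or sample identifiers.
#'
#' @param path Path to a TSV file, optionally gzip-compressed.
#' @return Labeled numeric matrix.
#' @export
read_matrix <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          comment.char = "#", check.names = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2) stop("matrix file needs an id column and data columns",
                         call. = FALSE)
  ids <- df[[1]]
  if (anyDuplicated(ids)) {
    stop("duplicated row id: ", ids[duplicated(ids)][1], call. = FALSE)
  }
  samples <- colnames(df)[-1]
  if (anyDuplicated(samples)) {
    stop("duplicated sample id: ", samples[duplicated(samples)][1],
         call. = FALSE)
  }
  body <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(body), dim = dim(body)))
  if (any(is.na(num))) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop("non-numeric value '", body[bad[1], bad[2]], "' at row '",
         ids[bad[1]], "', column '", samples[bad[2]], "'", call. = FALSE)
  }
  dimnames(num) <- list(ids, samples)
  num
}

#' Write / read the sample-to-group table
#'
#' Two-column TSV: `sample`, `group`.
#'
#' @param groups Character vector of labels named by sample (or unnamed).
#' @param path File path.
#' @param seed Optional seed recorded in the header.
#' @return `write_groups()` returns `path` invisibly; `read_groups()` a
#'   named character vector.
#' @export
write_groups <- function(groups, path, seed = NULL) {
  samples <- names(groups) %||% paste0("s", seq_along(groups))
  con <- open_out(path)
  on.exit(close(con))
  writeLines(header_comment("groups", seed), con)
  writeLines("sample\tgroup", con)
  writeLines(paste(samples, groups, sep = "\t"), con)
  invisible(path)
}

#' @rdname write_groups
#' @export
read_groups <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          comment.char = "#", check.names = FALSE,
                          colClasses = "character")
  stats::setNames(df$group, df$sample)
}

#' Write / read a detection table
#'
#' Long-format TSV with columns gene, cell_type, effect, statistic, p, fdr,
#' method; the number of permutations (when applicable) and the seed go
#' into the '#' header.
#'
#' @param table A detection table.
#' @param path File path.
#' @return `write_detection_table()` returns `path` invisibly;
#'   `read_detection_table()` a tibble.
#' @export
write_detection_table <- function(table, path) {
  con <- open_out(path)
  on.exit(close(con))
  h <- header_comment(paste0("detections method: ",
                             attr(table, "method") %||% "unknown"),
                      attr(table, "seed"))
  np <- attr(table, "n_perm")
  if (!is.null(np)) h <- c(h, paste0("# n_perm: ", np))
  writeLines(h, con)
  utils::write.table(as.data.frame(table), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_detection_table
#' @export
read_detection_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          comment.char = "#", check.names = FALSE)
  tibble::as_tibble(df)
}

#' Write / read a profile tensor as long-format TSV
#'
#' Columns: gene, cell_type, sample, value.
#'
#' @param S 3-d array genes x cell types x samples.
#' @param path File path (use `.gz`; tensors are large).
#' @param seed Optional seed recorded in the header.
#' @return `write_tensor()` returns `path` invisibly; `read_tensor()` the
#'   array.
#' @export
write_tensor <- function(S, path, seed = NULL) {
  stopifnot(length(dim(S)) == 3)
  dn <- dimnames(S)
  long <- data.frame(
    gene = rep(dn[[1]], times = dim(S)[2] * dim(S)[3]),
    cell_type = rep(rep(dn[[2]], each = dim(S)[1]), times = dim(S)[3]),
    sample = rep(dn[[3]], each = dim(S)[1] * dim(S)[2]),
    value = as.vector(S)
  )
  con <- open_out(path)
  on.exit(close(con))
  writeLines(header_comment("profile tensor", seed), con)
  utils::write.table(long, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tensor
#' @export
read_tensor <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          comment.char = "#", check.names = FALSE)
  genes <- unique(df$gene); cts <- unique(df$cell_type)
  samples <- unique(df$sample)
  S <- array(NA_real_, dim = c(length(genes), length(cts), length(samples)),
             dimnames = list(genes, cts, samples))
  S[cbind(match(df$gene, genes), match(df$cell_type, cts),
          match(df$sample, samples))] <- df$value
  S
}

#' Write a simulated dataset to a directory
#'
#' Writes `E.tsv`, `C.tsv`, `groups.tsv`, `truth.tsv` (long format: gene,
#' cell_type, is_csdeg) and `S.tsv.gz` (long-format tensor).
#'
#' @param dataset A [simulate_dataset()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "sim_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  colnames(dataset$E) <- colnames(dataset$C) <-
    paste0("s", seq_len(ncol(dataset$E)))
  dimnames(dataset$S)[[3]] <- colnames(dataset$E)
  write_matrix(dataset$E, file.path(dir, "E.tsv"), "bulk expression E",
               seed = dataset$seed)
  write_matrix(dataset$C, file.path(dir, "C.tsv"), "proportions C",
               seed = dataset$seed)
  write_groups(stats::setNames(dataset$groups, colnames(dataset$E)),
               file.path(dir, "groups.tsv"), seed = dataset$seed)
  truth_long <- data.frame(
    gene = rep(rownames(dataset$truth), times = ncol(dataset$truth)),
    cell_type = rep(colnames(dataset$truth), each = nrow(dataset$truth)),
    is_csdeg = as.vector(dataset$truth)
  )
  con <- open_out(file.path(dir, "truth.tsv"))
  writeLines(header_comment("csDEG truth mask", dataset$seed), con)
  utils::write.table(truth_long, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  close(con)
  write_tensor(dataset$S, file.path(dir, "S.tsv.gz"), seed = dataset$seed)
  invisible(dir)
}

#' Read a simulation configuration from YAML or JSON
#'
#' A flat key-value file whose keys mirror the [sim_config()] arguments;
#' unknown keys are rejected.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A [sim_config()].
#' @export
read_sim_config <- function(path) {
  vals <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  known <- names(formals(sim_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) {
    stop("unknown configuration keys: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(vals$fold_change_range)) {
    vals$fold_change_range <- as.numeric(unlist(vals$fold_change_range))
  }
  do.call(sim_config, vals)
}

#' Write a residual diagnostics report
#'
#' TSV with one row per sample (per-sample median relative residual and
#' outlier flag) preceded by '#' header lines carrying the dataset summary,
#' its reliability band and the number of genes used.
#'
#' @param summary A [median_relative_residual()] result.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_residual_report <- function(summary, path) {
  stopifnot(inherits(summary, "residual_summary"))
  con <- open_out(path)
  on.exit(close(con))
  writeLines(c(
    header_comment("residual diagnostics"),
    paste0("# median_relative_residual: ", summary$summary),
    paste0("# band: ", summary$band),
    paste0("# n_top_genes: ", summary$n_top_genes)
  ), con)
  writeLines("sample\tper_sample_residual\toutlier_flag", con)
  writeLines(paste(names(summary$per_sample),
                   format(summary$per_sample, digits = 15, trim = TRUE),
                   summary$flags, sep = "\t"), con)
  invisible(path)
}

#' Write an experiment grid as long-format TSV
#'
#' One row per grid cell x detector x cell type; optionally also writes the
#' per-level median summary (see [experiment_summary()]).
#'
#' @param result A `csde_experiment` tibble.
#' @param path Output path for the full grid.
#' @param summary_path Optional output path for the per-level summary.
#' @return `path`, invisibly.
#' @export
write_experiment <- function(result, path, summary_path = NULL) {
  stopifnot(inherits(result, "csde_experiment"))
  con <- open_out(path)
  writeLines(header_comment(paste0("experiment: ",
                                   attr(result, "experiment"))), con)
  utils::write.table(as.data.frame(result), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  close(con)
  if (!is.null(summary_path)) {
    con <- open_out(summary_path)
    writeLines(header_comment(paste0("experiment summary: ",
                                     attr(result, "experiment"))), con)
    utils::write.table(as.data.frame(experiment_summary(result)), con,
                       sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
  }
  invisible(path)
}
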