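# Residual-based reliability diagnostics: how well does S_hat * C
# reconstruct the observed bulk, relative to the bulk itself?

#' Median relative residual of a deconvolution
#'
#' Summarises reconstruction quality as
#' `median_G( median_R( |E_G - S_G * C| / E_G ) )`: the inner median runs
#' over samples, the outer over the `n_top` genes with the highest median
#' bulk expression. Residuals are taken relative to the bulk so the summary
#' is invariant to the overall expression magnitude (and hence to
#' normalisation scale); restricting to the top-expressed genes keeps
#' low-count noise from dominating. Entries with `E[i, j] = 0` are excluded
#' from the medians (division undefined); a selected gene whose whole row is
#' zero is dropped with a warning.
#'
#' @param E Bulk matrix, genes x samples.
#' @param S_hat Either a genes x cell types matrix (or `deconv_fit`), or a
#'   list with elements `case` and `control` for group-aware reconstruction
#'   (each sample reconstructed with its own group's estimate; requires
#'   `groups`).
#' @param C Proportion matrix, cell types x samples.
#' @param groups Per-sample labels, required when `S_hat` is group-wise.
#' @param n_top Number of top-expressed genes used (default 10000; clamped
#'   to the number of genes available).
#' @return An object of class `residual_summary`: `summary` (the median
#'   relative residual), `per_gene`, `per_sample`, `n_top_genes`, `flags`
#'   (per-sample outlier indicator, `NA` when fewer than 4 samples) and
#'   `band` (see [reliability_band()]).
#' @export
median_relative_residual <- function(E, S_hat, C, groups = NULL,
                                     n_top = 10000) {
  E <- as.matrix(E); C <- as.matrix(C)
  recon <- reconstruct_bulk(S_hat, C, groups, n_genes = nrow(E))
  stopifnot(all(dim(recon) == dim(E)))
  med_expr <- apply(E, 1, stats::median)
  gene_ids <- rownames(E) %||% sprintf("g%06d", seq_len(nrow(E)))
  n_top <- min(n_top, nrow(E))
  sel <- order(-med_expr, gene_ids)[seq_len(n_top)]
  rel <- abs(E[sel, , drop = FALSE] - recon[sel, , drop = FALSE]) /
    E[sel, , drop = FALSE]
  rel[E[sel, , drop = FALSE] == 0] <- NA_real_
  all_na <- rowSums(!is.na(rel)) == 0
  if (any(all_na)) {
    warning(sum(all_na), " selected gene(s) with all-zero bulk dropped",
            call. = FALSE)
    rel <- rel[!all_na, , drop = FALSE]
  }
  if (nrow(rel) < 1) stop("no usable genes for the residual summary",
                          call. = FALSE)
  per_gene <- apply(rel, 1, stats::median, na.rm = TRUE)
  names(per_gene) <- gene_ids[sel][!all_na]
  per_sample <- apply(rel, 2, stats::median, na.rm = TRUE)
  names(per_sample) <- colnames(E) %||% paste0("s", seq_len(ncol(E)))
  summary <- stats::median(per_gene)
  flags <- if (length(per_sample) >= 4) {
    flag_outlier_samples(per_sample)
  } else {
    rep(NA, length(per_sample))
  }
  structure(
    list(summary = summary, per_gene = per_gene, per_sample = per_sample,
         n_top_genes = nrow(rel), flags = flags,
         band = reliability_band(summary)),
    class = "residual_summary"
  )
}

# Rebuild the bulk from S_hat * C, group-aware when a case/control pair of
# estimates is supplied.
reconstruct_bulk <- function(S_hat, C, groups, n_genes) {
  as_mat <- function(x) {
    if (inherits(x, "deconv_fit")) x$S_hat else as.matrix(x)
  }
  if (is.list(S_hat) && !inherits(S_hat, "deconv_fit") &&
      all(c("case", "control") %in% names(S_hat))) {
    if (is.null(groups)) {
      stop("group-wise S_hat needs `groups`", call. = FALSE)
    }
    stopifnot(length(groups) == ncol(C))
    Sc <- as_mat(S_hat$case); S0 <- as_mat(S_hat$control)
    recon <- matrix(NA_real_, n_genes, ncol(C))
    is_case <- groups == "case"
    recon[, is_case] <- Sc %*% C[, is_case, drop = FALSE]
    recon[, !is_case] <- S0 %*% C[, !is_case, drop = FALSE]
    recon
  } else {
    as_mat(S_hat) %*% C
  }
}

#' @export
print.residual_summary <- function(x, ...) {
  cat("<residual_summary> median relative residual = ",
      signif(x$summary, 4), " (", x$band, "), ", x$n_top_genes,
      " genes, ", length(x$per_sample), " samples, ",
      sum(x$flags %in% TRUE), " flagged outlier(s)\n", sep = "")
  invisible(x)
}

#' Reliability band for a median relative residual
#'
#' Guidance bands, not hard gates: below 0.15 csDEG accuracy is typically
#' good ("reliable"); between 0.15 and 0.25 accuracy drops off sharply
#' ("degraded"); above 0.25 no cell type retains good accuracy
#' ("unreliable").
#'
#' @param summary Non-negative median relative residual.
#' @return One of `"reliable"`, `"degraded"`, `"unreliable"`.
#' @export
reliability_band <- function(summary) {
  stopifnot(length(summary) == 1, is.finite(summary))
  if (summary < 0) stop("residual summary cannot be negative", call. = FALSE)
  if (summary < 0.15) "reliable"
  else if (summary <= 0.25) "degraded"
  else "unreliable"
}

#' Flag outlier samples from per-sample residuals
#'
#' A sample is flagged when its per-sample median relative residual exceeds
#' `Q3 + 1.5 * IQR` of the per-sample residual vector (the same Tukey
#' convention used to construct outlier samples in the simulator). Samples
#' whose profiles deviate from the rest leave their mark in the residuals
#' even when their bulk profile looks unremarkable, so this flag can catch
#' outliers that bulk-level screening misses.
#'
#' @param per_sample Numeric vector of per-sample residual summaries
#'   (length >= 4).
#' @return Logical vector, `TRUE` = flagged.
#' @export
flag_outlier_samples <- function(per_sample) {
  if (length(per_sample) < 4) {
    stop("need at least 4 samples to flag outliers", call. = FALSE)
  }
  q <- stats::quantile(per_sample, c(0.25, 0.75), names = FALSE)
  per_sample > q[2] + 1.5 * (q[2] - q[1])
}
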