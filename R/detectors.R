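# csDEG detectors: the generic group-label permutation recipe around any
# deconvolution core, a Welch t-test on group-wise deconvolved profiles, and
# a proportion-by-group interaction linear model. All return one tidy row
# per (gene, cell type).

new_detection_table <- function(df, method, n_perm = NULL, seed = NULL) {
  df <- tibble::as_tibble(df)
  attr(df, "method") <- method
  if (!is.null(n_perm)) attr(df, "n_perm") <- as.integer(n_perm)
  if (!is.null(seed)) attr(df, "seed") <- as.integer(seed)
  class(df) <- c("csde_detection", class(df))
  df
}

# BH within each cell type (the default; pooling across cell types optional)
add_fdr <- function(df, pool_cell_types = FALSE) {
  if (pool_cell_types) {
    df$fdr <- bh_adjust(df$p)
  } else {
    df <- dplyr::mutate(dplyr::group_by(df, .data$cell_type),
                        fdr = bh_adjust(.data$p))
    df <- dplyr::ungroup(df)
  }
  df
}

#' Permutation csDEG detector around a deconvolution core
#'
#' Implements the generic recipe by which any expression deconvolution
#' method detects csDEGs: (1) estimate cell type-specific expression for
#' case and control samples separately, (2) take the absolute difference per
#' (gene, cell type), (3) repeat under `n_perm` random reshuffles of the
#' group labels (group sizes preserved), counting how often the permuted
#' difference exceeds the observed one (`m`), and (4) report `p = m / n`.
#' With `add_one = FALSE` (the default, faithful to the recipe) `p = 0` is
#' possible; `add_one = TRUE` applies the (m+1)/(n+1) correction.
#'
#' @inheritParams groupwise_deconv
#' @param n_perm Number of label permutations (the study used 1000).
#' @param seed Integer seed for the permutations.
#' @param add_one Use the (m+1)/(n+1) estimator instead of m/n.
#' @param pool_cell_types Apply BH across all cell types jointly instead of
#'   within each cell type.
#' @param ... Passed to the deconvolution core.
#' @return A detection table (tibble): `gene`, `cell_type`, `effect` (signed
#'   case - control difference), `statistic` (its absolute value), `p`,
#'   `fdr`, `method`.
#' @export
permutation_detector <- function(E, C, groups,
                                 method = c("ols", "nnls", "robust"),
                                 n_perm = 1000, seed = 1L, add_one = FALSE,
                                 pool_cell_types = FALSE, ...) {
  method <- match.arg(method)
  stopifnot(n_perm >= 1)
  E <- as.matrix(E); C <- as.matrix(C)
  groups <- as.character(groups)
  check_two_groups(groups, ncol(E), nrow(C))
  idx_case <- which(groups == "case")
  idx_ctrl <- which(groups == "control")
  diff_for <- function(case_idx, ctrl_idx) {
    fit_coefficients(E[, case_idx, drop = FALSE],
                     C[, case_idx, drop = FALSE], method, ...) -
      fit_coefficients(E[, ctrl_idx, drop = FALSE],
                       C[, ctrl_idx, drop = FALSE], method, ...)
  }
  obs <- diff_for(idx_case, idx_ctrl)
  obs_abs <- abs(obs)
  m <- matrix(0, nrow(obs), ncol(obs))
  n <- length(groups)
  n_case <- length(idx_case)
  # strictly-greater count; the relative slack keeps refits that differ only
  # by floating-point rounding (e.g. the observed labeling redrawn in another
  # column order) counted as ties, not exceedances
  tie_guard <- obs_abs * (1 + 1e-9)
  withr::with_seed(seed, {
    for (b in seq_len(n_perm)) {
      perm_case <- sample.int(n, n_case)
      perm_ctrl <- setdiff(seq_len(n), perm_case)
      m <- m + (abs(diff_for(perm_case, perm_ctrl)) > tie_guard)
    }
  })
  p <- if (add_one) (m + 1) / (n_perm + 1) else m / n_perm
  df <- tibble::tibble(
    gene = rep(rownames(E) %||% paste0("g", seq_len(nrow(E))),
               times = nrow(C)),
    cell_type = rep(rownames(C) %||% paste0("ct", seq_len(nrow(C))),
                    each = nrow(E)),
    effect = as.vector(obs),
    statistic = as.vector(obs_abs),
    p = as.vector(p)
  )
  df <- add_fdr(df, pool_cell_types)
  df$method <- paste0("perm-", method)
  new_detection_table(df, paste0("perm-", method), n_perm = n_perm,
                      seed = seed)
}

check_two_groups <- function(groups, n_samples, n_ct) {
  if (length(groups) != n_samples) {
    stop("`groups` length must match the number of samples", call. = FALSE)
  }
  if (!all(groups %in% c("case", "control"))) {
    stop('`groups` must contain only "case" and "control"', call. = FALSE)
  }
  for (g in c("case", "control")) {
    if (sum(groups == g) < n_ct) {
      stop("group '", g, "' has fewer samples than cell types", call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Welch t-test csDEG detector
#'
#' Deconvolves case and control samples separately by OLS and tests each
#' (gene, cell type) coefficient difference with Welch's two-sample t-test:
#' `t = (s_case - s_control) / sqrt(se_case^2 + se_control^2)`, degrees of
#' freedom by Welch-Satterthwaite using the coefficient standard errors and
#' the group residual degrees of freedom. Edge rule: when both standard
#' errors are zero the p-value is 1 for a zero difference and 0 otherwise.
#'
#' @inheritParams groupwise_deconv
#' @param pool_cell_types See [permutation_detector()].
#' @return A detection table (tibble), as in [permutation_detector()];
#'   `statistic` is the Welch t.
#' @export
welch_detector <- function(E, C, groups, pool_cell_types = FALSE) {
  E <- as.matrix(E); C <- as.matrix(C)
  groups <- as.character(groups)
  check_two_groups(groups, ncol(E), nrow(C))
  fits <- groupwise_deconv(E, C, groups, method = "ols")
  d <- fits$case$S_hat - fits$control$S_hat
  v1 <- fits$case$se^2
  v2 <- fits$control$se^2
  tstat <- d / sqrt(v1 + v2)
  df_w <- (v1 + v2)^2 / (v1^2 / fits$case$dof + v2^2 / fits$control$dof)
  p <- 2 * stats::pt(-abs(tstat), df_w)
  zero_se <- (v1 + v2) == 0
  tstat[zero_se] <- ifelse(d[zero_se] == 0, 0, sign(d[zero_se]) * Inf)
  p[zero_se] <- ifelse(d[zero_se] == 0, 1, 0)
  df <- tibble::tibble(
    gene = rep(rownames(E) %||% paste0("g", seq_len(nrow(E))),
               times = nrow(C)),
    cell_type = rep(rownames(C) %||% paste0("ct", seq_len(nrow(C))),
                    each = nrow(E)),
    effect = as.vector(d),
    statistic = as.vector(tstat),
    p = as.vector(p)
  )
  df <- add_fdr(df, pool_cell_types)
  df$method <- "welch"
  new_detection_table(df, "welch")
}

#' Proportion-by-group interaction csDEG detector
#'
#' Fits one linear model per gene over all samples with the cell type
#' proportions and their interactions with the case indicator as covariates
#' (no intercept): `E_j ~ sum_t s_t C_tj + sum_t d_t C_tj 1{case}`. A csDEG
#' call for cell type t is based on the t-test of the interaction
#' coefficient `d_t`, whose estimate is the case - control expression
#' difference in that cell type.
#'
#' @inheritParams groupwise_deconv
#' @param pool_cell_types See [permutation_detector()].
#' @return A detection table (tibble); `effect` is the interaction
#'   coefficient, `statistic` its t value.
#' @export
interaction_detector <- function(E, C, groups, pool_cell_types = FALSE) {
  E <- as.matrix(E); C <- as.matrix(C)
  groups <- as.character(groups)
  check_two_groups(groups, ncol(E), nrow(C))
  cts <- rownames(C) %||% paste0("ct", seq_len(nrow(C)))
  case_ind <- as.numeric(groups == "case")
  X <- cbind(t(C), t(C) * case_ind)
  colnames(X) <- c(cts, paste0(cts, ":case"))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[seq(qrX$rank + 1, ncol(X))]]
    stop("singular interaction design (", paste(bad, collapse = ", "),
         "); are both groups present with variable proportions?",
         call. = FALSE)
  }
  coefs <- qr.coef(qrX, t(E))                 # 2T x genes
  res <- t(E) - X %*% coefs
  dof <- nrow(X) - ncol(X)
  sigma2 <- colSums(res^2) / dof
  ord <- order(qrX$pivot)
  xtx_inv <- chol2inv(qr.R(qrX))[ord, ord, drop = FALSE]
  se <- sqrt(outer(diag(xtx_inv), sigma2))    # 2T x genes
  int_rows <- nrow(C) + seq_len(nrow(C))
  d <- t(coefs[int_rows, , drop = FALSE])     # genes x T
  se_int <- t(se[int_rows, , drop = FALSE])
  tstat <- d / se_int
  tstat[se_int == 0] <- ifelse(d[se_int == 0] == 0, 0,
                               sign(d[se_int == 0]) * Inf)
  p <- 2 * stats::pt(-abs(tstat), dof)
  p[se_int == 0] <- ifelse(d[se_int == 0] == 0, 1, 0)
  df <- tibble::tibble(
    gene = rep(rownames(E) %||% paste0("g", seq_len(nrow(E))),
               times = nrow(C)),
    cell_type = rep(cts, each = nrow(E)),
    effect = as.vector(d),
    statistic = as.vector(tstat),
    p = as.vector(p)
  )
  df <- add_fdr(df, pool_cell_types)
  df$method <- "interaction"
  new_detection_table(df, "interaction")
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate adjustment of a p-value vector (thin,
#' validated wrapper around [stats::p.adjust()]).
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted values in `[0, 1]`, never below the raw p.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Rank genes within a cell type
#'
#' Orders genes by ascending p-value, breaking ties by descending absolute
#' effect and then by gene identifier, and returns the first `k`.
#'
#' @param table A detection table.
#' @param cell_type Cell type to rank within.
#' @param k Number of genes to return.
#' @return Character vector of up to `k` gene identifiers.
#' @export
rank_genes <- function(table, cell_type, k) {
  stopifnot(k >= 0)
  sub <- table[table$cell_type == cell_type, , drop = FALSE]
  if (nrow(sub) == 0) {
    stop("cell type '", cell_type, "' not present in the table",
         call. = FALSE)
  }
  if (k > nrow(sub)) {
    warning("k = ", k, " exceeds the ", nrow(sub),
            " genes available; truncating", call. = FALSE)
    k <- nrow(sub)
  }
  ord <- order(sub$p, -abs(sub$effect), sub$gene)
  sub$gene[ord][seq_len(k)]
}

#' Run a named csDEG detector
#'
#' Dispatch by detector name: `"perm-ols"`, `"perm-nnls"`, `"perm-robust"`
#' (permutation recipe around the respective core), `"welch"` or
#' `"interaction"`.
#'
#' @inheritParams permutation_detector
#' @param detector Detector name.
#' @return A detection table.
#' @export
run_detector <- function(E, C, groups,
                         detector = c("perm-ols", "perm-nnls", "perm-robust",
                                      "welch", "interaction"),
                         n_perm = 1000, seed = 1L, ...) {
  detector <- match.arg(detector)
  switch(
    detector,
    "perm-ols" = permutation_detector(E, C, groups, "ols",
                                      n_perm = n_perm, seed = seed, ...),
    "perm-nnls" = permutation_detector(E, C, groups, "nnls",
                                       n_perm = n_perm, seed = seed, ...),
    "perm-robust" = permutation_detector(E, C, groups, "robust",
                                         n_perm = n_perm, seed = seed, ...),
    "welch" = welch_detector(E, C, groups, ...),
    "interaction" = interaction_detector(E, C, groups, ...)
  )
}
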