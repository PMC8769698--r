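# Per-gene expression deconvolution: estimate cell type-specific expression
# S_hat from bulk E and known proportions C. All genes share the design
# X = t(C) (no intercept: proportion columns sum to 1, an intercept would be
# collinear), so fits are vectorized across genes.

new_deconv_fit <- function(S_hat, se, dof, residual, method,
                           converged = NULL, se_approximate = FALSE) {
  structure(
    list(S_hat = S_hat, se = se, dof = dof, residual = residual,
         method = method, converged = converged,
         se_approximate = se_approximate),
    class = "deconv_fit"
  )
}

#' @export
print.deconv_fit <- function(x, ...) {
  cat("<deconv_fit method=", x$method, "> ", nrow(x$S_hat), " genes x ",
      ncol(x$S_hat), " cell types, ", x$dof, " residual dof\n", sep = "")
  invisible(x)
}

# validate inputs and return the shared design matrix (samples x cell types)
deconv_design <- function(E, C) {
  E <- as.matrix(E); C <- as.matrix(C)
  if (ncol(E) != ncol(C)) {
    stop("E and C must have the same samples (columns)", call. = FALSE)
  }
  if (ncol(E) < nrow(C)) {
    stop("need at least as many samples as cell types", call. = FALSE)
  }
  X <- t(C)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[seq(qrX$rank + 1, ncol(X))]]
    stop("singular design: collinear cell types (",
         paste(bad, collapse = ", "), ")", call. = FALSE)
  }
  list(E = E, X = X, qr = qrX)
}

#' Ordinary least squares deconvolution
#'
#' For every gene independently, minimises
#' `sum_j (E[i, j] - sum_t s_t C[t, j])^2` over the cell type-specific
#' expression levels `s`. Standard errors come from the usual linear-model
#' covariance `sigma_i^2 (X'X)^{-1}` with `dof = samples - cell types`.
#'
#' @param E Bulk matrix, genes x samples.
#' @param C Proportion matrix, cell types x samples (full row rank).
#' @return A `deconv_fit`: `S_hat` and `se` (genes x cell types), `dof`,
#'   `residual` (genes x samples), `method`.
#' @export
ols_fit <- function(E, C) {
  d <- deconv_design(E, C)
  coefs <- qr.coef(d$qr, t(d$E))              # cell types x genes
  fitted <- d$X %*% coefs                     # samples x genes
  res <- t(d$E) - fitted
  dof <- nrow(d$X) - ncol(d$X)
  rss <- colSums(res^2)
  sigma2 <- if (dof > 0) rss / dof else rep(NA_real_, length(rss))
  ord <- order(d$qr$pivot)
  xtx_inv <- chol2inv(qr.R(d$qr))[ord, ord, drop = FALSE]
  se <- sqrt(outer(sigma2, diag(xtx_inv)))    # genes x cell types
  S_hat <- t(coefs)
  dimnames(S_hat) <- dimnames(se) <- list(rownames(d$E), rownames(C))
  new_deconv_fit(S_hat, se, dof, t(res), "ols")
}

#' Non-negative least squares deconvolution
#'
#' Same per-gene objective as [ols_fit()] under the constraint `s_t >= 0`
#' (Lawson-Hanson active set in compiled code; only genes whose
#' unconstrained optimum violates the constraint are refit). Standard errors
#' are taken from the unconstrained fit restricted to the active (positive)
#' coordinates and are approximate (`se_approximate = TRUE`); zero-clamped
#' coordinates get `NA` standard errors.
#'
#' @inheritParams ols_fit
#' @return A `deconv_fit` with non-negative `S_hat`.
#' @export
nnls_fit <- function(E, C) {
  d <- deconv_design(E, C)
  fit <- ols_fit(d$E, C)
  viol <- which(apply(fit$S_hat < -1e-12, 1, any))
  S_hat <- fit$S_hat
  se <- fit$se
  if (length(viol)) {
    S_hat[viol, ] <- t(nnls_cpp(t(d$E[viol, , drop = FALSE]), d$X))
    for (i in viol) {
      y <- d$E[i, ]
      act <- which(S_hat[i, ] > 0)
      se_i <- rep(NA_real_, ncol(d$X))
      if (length(act) > 0 && nrow(d$X) > length(act)) {
        Xa <- d$X[, act, drop = FALSE]
        ra <- y - Xa %*% qr.coef(qr(Xa), y)
        s2 <- sum(ra^2) / (nrow(d$X) - length(act))
        se_i[act] <- sqrt(s2 * diag(chol2inv(chol(crossprod(Xa)))))
      }
      se[i, ] <- se_i
    }
  }
  S_hat[S_hat < 0] <- 0
  res <- d$E - S_hat %*% t(d$X)
  new_deconv_fit(S_hat, se, fit$dof, res, "nnls", se_approximate = TRUE)
}

#' Huber-robust deconvolution
#'
#' Per-gene M-estimation with the Huber loss, fitted by iteratively
#' reweighted least squares and vectorized across genes. The residual scale
#' is re-estimated every iteration as `median(|r|) / 0.6745`; a gene is
#' converged when the largest coefficient change drops below
#' `tol * max(1, max |coef|)`. Genes that have not converged after
#' `max_iter` iterations keep their final iterate and are flagged in
#' `converged` (with a warning). Downweighting of large residuals is what
#' buys tolerance to a few outlier samples.
#'
#' @inheritParams ols_fit
#' @param tuning Huber tuning constant `k` (default 1.345, the classical
#'   95%-efficiency choice under normal errors).
#' @param max_iter,tol IRLS iteration cap and relative convergence tolerance.
#' @return A `deconv_fit`; `se` uses the standard asymptotic M-estimation
#'   formula.
#' @export
robust_fit <- function(E, C, tuning = 1.345, max_iter = 50, tol = 1e-8) {
  stopifnot(tuning > 0)
  d <- deconv_design(E, C)
  cf <- huber_irls(d$E, d$X, tuning, max_iter, tol)
  b <- cf$coef                                # cell types x genes
  res <- t(d$E) - d$X %*% b                   # samples x genes
  n <- nrow(d$X); p <- ncol(d$X)
  dof <- n - p
  # asymptotic M-estimator covariance: s^2 * [E psi^2 / (E psi')^2] (X'X)^-1
  s <- pmax(cf$scale, .Machine$double.eps)
  u <- sweep(res, 2, s, "/")
  psi <- pmin(pmax(u, -tuning), tuning)
  psip <- abs(u) <= tuning
  v1 <- colSums(psi^2) / max(dof, 1)
  v2 <- (colMeans(psip))^2
  v2[v2 == 0] <- NA_real_
  xtx_inv_diag <- diag(chol2inv(chol(crossprod(d$X))))
  se <- sqrt(outer(s^2 * v1 / v2, xtx_inv_diag))
  if (!all(cf$converged)) {
    warning(sum(!cf$converged),
            " gene(s) did not reach the IRLS tolerance; final iterate kept",
            call. = FALSE)
  }
  S_hat <- t(b)
  dimnames(S_hat) <- dimnames(se) <- list(rownames(d$E), rownames(C))
  new_deconv_fit(S_hat, se, dof, t(res), "robust", converged = cf$converged)
}

# Huber IRLS across genes sharing one design (C++ core, see src/huber.cpp).
# E: genes x samples, X: samples x p. Returns p x genes coefficients,
# per-gene MAD scale and convergence flags.
huber_irls <- function(E, X, tuning, max_iter, tol) {
  out <- huber_irls_cpp(t(E), X, tuning, as.integer(max_iter), tol)
  b <- out$coef
  dimnames(b) <- list(colnames(X), rownames(E))
  list(coef = b, scale = as.vector(out$scale),
       converged = as.vector(out$converged) == 1L)
}

# Coefficient-only group fit used inside permutation loops (no se/residuals).
fit_coefficients <- function(E, C, method, tuning = 1.345,
                             max_iter = 50, tol = 1e-8) {
  E <- as.matrix(E); C <- as.matrix(C)
  X <- t(C)
  switch(
    method,
    ols = t(qr.coef(qr(X), t(E))),
    nnls = {
      S_hat <- t(nnls_cpp(t(E), X))
      rownames(S_hat) <- rownames(E)
      S_hat
    },
    robust = t(huber_irls(E, X, tuning, max_iter, tol)$coef),
    stop("unknown deconvolution method: ", method, call. = FALSE)
  )
}

#' Group-wise deconvolution
#'
#' Fits the chosen deconvolution core independently on the case and the
#' control samples — step 1 of the generic recipe by which any expression
#' deconvolution method yields csDEG candidates.
#'
#' @inheritParams ols_fit
#' @param groups Per-sample labels in `c("case", "control")`.
#' @param method One of `"ols"`, `"nnls"`, `"robust"`.
#' @param ... Passed to the core (e.g. `tuning` for `"robust"`).
#' @return List with elements `case` and `control`, each a `deconv_fit`.
#' @export
groupwise_deconv <- function(E, C, groups, method = c("ols", "nnls", "robust"),
                             ...) {
  method <- match.arg(method)
  E <- as.matrix(E); C <- as.matrix(C)
  stopifnot(length(groups) == ncol(E))
  fitter <- switch(method, ols = ols_fit, nnls = nnls_fit, robust = robust_fit)
  out <- list()
  for (g in c("case", "control")) {
    idx <- which(groups == g)
    if (length(idx) < nrow(C)) {
      stop("group '", g, "' has fewer samples (", length(idx),
           ") than cell types (", nrow(C), ")", call. = FALSE)
    }
    out[[g]] <- fitter(E[, idx, drop = FALSE], C[, idx, drop = FALSE], ...)
  }
  out
}
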