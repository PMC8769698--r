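# broom-style tidiers and ggplot2 autoplot methods for the package's
# result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a deconvolution fit
#'
#' @param x A `deconv_fit`.
#' @param ... Unused.
#' @return A tibble with one row per (gene, cell type): `estimate` and
#'   `std.error`.
#' @method tidy deconv_fit
#' @export
tidy.deconv_fit <- function(x, ...) {
  tibble::tibble(
    gene = rep(rownames(x$S_hat), times = ncol(x$S_hat)),
    cell_type = rep(colnames(x$S_hat), each = nrow(x$S_hat)),
    estimate = as.vector(x$S_hat),
    std.error = as.vector(x$se)
  )
}

#' @rdname tidy.deconv_fit
#' @return `glance()` returns a one-row tibble with fit-level facts.
#' @method glance deconv_fit
#' @export
glance.deconv_fit <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    n_genes = nrow(x$S_hat),
    n_cell_types = ncol(x$S_hat),
    n_samples = ncol(x$residual),
    df.residual = x$dof,
    se_approximate = isTRUE(x$se_approximate),
    n_not_converged = if (is.null(x$converged)) 0L else sum(!x$converged)
  )
}

#' Tidy a residual diagnostics summary
#'
#' @param x A `residual_summary`.
#' @param ... Unused.
#' @return One row per sample: residual and outlier flag.
#' @method tidy residual_summary
#' @export
tidy.residual_summary <- function(x, ...) {
  tibble::tibble(
    sample = names(x$per_sample),
    per_sample_residual = unname(x$per_sample),
    outlier_flag = unname(x$flags)
  )
}

#' @rdname tidy.residual_summary
#' @method glance residual_summary
#' @export
glance.residual_summary <- function(x, ...) {
  tibble::tibble(
    median_relative_residual = x$summary,
    band = x$band,
    n_top_genes = x$n_top_genes,
    n_samples = length(x$per_sample),
    n_flagged = sum(x$flags %in% TRUE)
  )
}

#' Tidy a gold standard
#'
#' @param x A `gold_standard`.
#' @param ... Unused.
#' @return The underlying per-(gene, cell type) tibble with an `in_gold`
#'   column.
#' @method tidy gold_standard
#' @export
tidy.gold_standard <- function(x, ...) {
  dplyr::mutate(x$table, in_gold = .data$fdr <= x$alpha)
}

#' Plot an experiment grid
#'
#' Per-level median top-list accuracy per detector, one panel per cell
#' type; the x-axis is the experiment's varied level (CV, mean proportion
#' or number of outliers).
#'
#' @param object A `csde_experiment`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot csde_experiment
#' @export
autoplot.csde_experiment <- function(object, ...) {
  s <- experiment_summary(object)
  level_col <- intersect(c("cv", "proportion", "n_outliers"), names(s))[1]
  ggplot2::ggplot(s, ggplot2::aes(x = .data[[level_col]],
                                  y = .data$accuracy,
                                  colour = .data$detector)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~cell_type) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = level_col, y = "top-list accuracy") +
    ggplot2::theme_bw()
}

#' Plot per-sample residual diagnostics
#'
#' Per-sample median relative residuals with flagged outliers highlighted
#' and the 0.15 / 0.25 reliability guides.
#'
#' @param object A `residual_summary`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot residual_summary
#' @export
autoplot.residual_summary <- function(object, ...) {
  d <- tidy(object)
  d$sample <- factor(d$sample, levels = d$sample)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$sample,
                                  y = .data$per_sample_residual,
                                  colour = .data$outlier_flag)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = c(0.15, 0.25), linetype = "dashed",
                        colour = "grey40") +
    ggplot2::labs(y = "per-sample median relative residual", x = NULL,
                  colour = "flagged") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   axis.ticks.x = ggplot2::element_blank())
}
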