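# Gold-standard construction, accuracy metrics and the benchmark experiment
# grids (heterogeneity, cell type abundance, outlier samples).

#' Gold-standard csDEGs from the known per-sample profiles
#'
#' Not every injected csDEG survives the randomness of the simulation, so
#' the reference set is re-derived from the generated per-sample profiles:
#' per cell type, a two-sided Wilcoxon rank-sum test compares each gene's
#' profiles between groups, p-values are BH-adjusted across genes within the
#' cell type, and genes with FDR <= `alpha` form the gold standard.
#'
#' @param S Profile tensor, genes x cell types x samples.
#' @param groups Per-sample labels in `c("case", "control")`.
#' @param alpha FDR cutoff (default 0.05).
#' @return An object of class `gold_standard`: named list `sets` (gene ids
#'   per cell type), the full `table` (tibble of gene, cell_type, p, fdr),
#'   `alpha` and `test`.
#' @export
gold_standard_csdegs <- function(S, groups, alpha = 0.05) {
  stopifnot(length(dim(S)) == 3, alpha > 0, alpha < 1)
  groups <- as.character(groups)
  stopifnot(length(groups) == dim(S)[3])
  if (sum(groups == "case") < 2 || sum(groups == "control") < 2) {
    stop("both groups need at least 2 samples", call. = FALSE)
  }
  genes <- dimnames(S)[[1]] %||% paste0("g", seq_len(dim(S)[1]))
  cts <- dimnames(S)[[2]] %||% paste0("ct", seq_len(dim(S)[2]))
  is_case <- groups == "case"
  tabs <- vector("list", length(cts))
  for (t in seq_along(cts)) {
    M <- matrix(S[, t, ], nrow = dim(S)[1])
    p <- vapply(seq_len(nrow(M)), function(i) {
      x <- M[i, is_case]; y <- M[i, !is_case]
      if (all(x == x[1]) && all(y == y[1]) && x[1] == y[1]) return(1)
      stats::wilcox.test(x, y, exact = FALSE)$p.value
    }, numeric(1))
    p[is.na(p)] <- 1
    tabs[[t]] <- tibble::tibble(gene = genes, cell_type = cts[t], p = p,
                                fdr = bh_adjust(p))
  }
  table <- dplyr::bind_rows(tabs)
  sets <- lapply(split(table, table$cell_type)[cts], function(d) {
    d$gene[d$fdr <= alpha]
  })
  structure(list(sets = sets, table = table, alpha = alpha,
                 test = "wilcoxon"),
            class = "gold_standard")
}

#' @export
print.gold_standard <- function(x, ...) {
  cat("<gold_standard> Wilcoxon+BH at FDR <= ", x$alpha, "; ",
      paste(names(x$sets), vapply(x$sets, length, integer(1)),
            sep = ": ", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Top-list overlap accuracy
#'
#' With `k` the size of the gold-standard set for the cell type, the
#' accuracy is the fraction of the detector's top-`k` ranked genes (see
#' [rank_genes()]) that belong to the gold standard. An empty gold standard
#' yields `NA` (undefined, never silently 0).
#'
#' @param table A detection table.
#' @param gold A [gold_standard_csdegs()] result.
#' @param cell_type Cell type to score.
#' @return A single number in `[0, 1]`, or `NA`.
#' @export
toplist_accuracy <- function(table, gold, cell_type) {
  gset <- gold_set(gold, cell_type)
  k <- length(gset)
  if (k == 0) return(NA_real_)
  top <- rank_genes(table, cell_type, min(k, sum(table$cell_type == cell_type)))
  length(intersect(top, gset)) / k
}

gold_set <- function(gold, cell_type) {
  stopifnot(inherits(gold, "gold_standard"))
  if (!cell_type %in% names(gold$sets)) {
    stop("cell type '", cell_type, "' absent from the gold standard",
         call. = FALSE)
  }
  gold$sets[[cell_type]]
}

#' Precision and recall at an FDR cutoff
#'
#' Detections are the table rows with `fdr <= q` for the cell type.
#' Precision is `NA` when there are no detections (dividing by zero, as in
#' an empty-findings cell of a benchmark table), recall is `NA` when the
#' gold standard is empty.
#'
#' @inheritParams toplist_accuracy
#' @param q FDR cutoff for calling detections (default 0.05).
#' @return A tibble with `cell_type`, `n_detected`, `precision`, `recall`.
#' @export
precision_recall <- function(table, gold, cell_type, q = 0.05) {
  gset <- gold_set(gold, cell_type)
  sub <- table[table$cell_type == cell_type, , drop = FALSE]
  if (nrow(sub) == 0) {
    stop("cell type '", cell_type, "' not present in the table",
         call. = FALSE)
  }
  detected <- sub$gene[sub$fdr <= q]
  hit <- length(intersect(detected, gset))
  tibble::tibble(
    cell_type = cell_type,
    n_detected = length(detected),
    precision = if (length(detected) == 0) NA_real_ else hit / length(detected),
    recall = if (length(gset) == 0) NA_real_ else hit / length(gset)
  )
}

# Shared worker: simulate one dataset, build the gold standard, run the
# detectors, score every cell type. Returns a long tibble.
score_one_dataset <- function(config, prop_model, prof_model, detectors,
                              n_perm, q = 0.05, gold_on_base = TRUE) {
  ds <- simulate_dataset(config, prop_model, prof_model)
  base <- if (gold_on_base) !ds$outlier else rep(TRUE, length(ds$groups))
  gold <- gold_standard_csdegs(ds$S[, , base, drop = FALSE],
                               ds$groups[base])
  fits <- groupwise_deconv(ds$E, ds$C, ds$groups, method = "ols")
  mrr <- median_relative_residual(ds$E, fits, ds$C, groups = ds$groups)
  rows <- list()
  for (det in detectors) {
    tab <- run_detector(ds$E, ds$C, ds$groups, det, n_perm = n_perm,
                        seed = config$seed)
    for (ct in dimnames(ds$S)[[2]]) {
      pr <- precision_recall(tab, gold, ct, q = q)
      rows[[length(rows) + 1]] <- tibble::tibble(
        detector = det, cell_type = ct,
        accuracy = toplist_accuracy(tab, gold, ct),
        precision = pr$precision, recall = pr$recall,
        gold_size = length(gold$sets[[ct]]),
        median_relative_residual = mrr$summary
      )
    }
  }
  dplyr::bind_rows(rows)
}

new_experiment <- function(df, type) {
  df <- tibble::as_tibble(df)
  attr(df, "experiment") <- type
  class(df) <- c("csde_experiment", class(df))
  df
}

#' Heterogeneity (coefficient of variation) experiment
#'
#' For each CV level and replicate, simulates a dataset whose profile
#' heterogeneity is pinned to the level (all cell types, or only
#' `target_cell` with the others keeping their model sds), runs the
#' detectors, and records top-list accuracy, precision, recall and the
#' median relative residual. The default grid is the benchmark's
#' `0.1, 0.5, 1, 1.5, 2, 2.5`; per-level aggregation (see
#' [experiment_summary()]) uses the median over replicates.
#'
#' @param prop_model,prof_model Generating models.
#' @param levels CV levels (> 0).
#' @param detectors Character vector of detector names (see
#'   [run_detector()]).
#' @param n_reps Replicates per level (the benchmark used 10).
#' @param config Base [sim_config()]; its `cv_override` and `seed` are
#'   overwritten per grid cell.
#' @param target_cell If non-NULL, only this cell type's CV is controlled.
#' @param n_perm Permutations for the permutation detectors.
#' @param seed Master seed; every grid cell derives its own seed from it.
#' @return A `csde_experiment` tibble: one row per level x replicate x
#'   detector x cell type.
#' @export
run_cv_experiment <- function(prop_model, prof_model,
                              levels = c(0.1, 0.5, 1, 1.5, 2, 2.5),
                              detectors = c("perm-ols", "welch",
                                            "interaction"),
                              n_reps = 10, config = sim_config(),
                              target_cell = NULL, n_perm = 200, seed = 1L) {
  stopifnot(all(levels > 0), n_reps >= 1)
  grid_seeds <- derive_seeds(seed, length(levels) * n_reps)
  rows <- list(); k <- 0
  for (li in seq_along(levels)) {
    cv <- if (is.null(target_cell)) levels[li] else
      stats::setNames(levels[li], target_cell)
    for (r in seq_len(n_reps)) {
      k <- k + 1
      cfg <- config
      cfg$cv_override <- cv
      cfg$seed <- as.integer(grid_seeds[k])
      sc <- score_one_dataset(cfg, prop_model, prof_model, detectors, n_perm)
      sc$cv <- levels[li]; sc$replicate <- r
      rows[[k]] <- sc
    }
  }
  new_experiment(dplyr::bind_rows(rows), "cv")
}

#' Cell type abundance experiment
#'
#' Varies the mean proportion of one target cell type over `mean_levels`,
#' redistributing the remaining mass proportionally among the other cell
#' types (their sds are rescaled with their means so each keeps its
#' proportion CV), and scores the detectors at each level.
#'
#' @inheritParams run_cv_experiment
#' @param target_cell Cell type whose abundance is varied.
#' @param mean_levels Mean proportion levels in (0, 1); the benchmark's
#'   focal level 0.2 is in the default grid.
#' @return A `csde_experiment` tibble with a `proportion` column.
#' @export
run_proportion_experiment <- function(prop_model, prof_model, target_cell,
                                      mean_levels = c(0.05, 0.1, 0.2, 0.4,
                                                      0.6, 0.9),
                                      detectors = c("perm-ols", "welch",
                                                    "interaction"),
                                      n_reps = 10, config = sim_config(),
                                      n_perm = 200, seed = 1L) {
  stopifnot(target_cell %in% prop_model$cell_types,
            all(mean_levels > 0), all(mean_levels < 1), n_reps >= 1)
  grid_seeds <- derive_seeds(seed + 1, length(mean_levels) * n_reps)
  rows <- list(); k <- 0
  for (li in seq_along(mean_levels)) {
    pm <- reweight_proportion_model(prop_model, target_cell, mean_levels[li])
    for (r in seq_len(n_reps)) {
      k <- k + 1
      cfg <- config
      cfg$seed <- as.integer(grid_seeds[k])
      sc <- score_one_dataset(cfg, pm, prof_model, detectors, n_perm)
      sc$proportion <- mean_levels[li]; sc$replicate <- r
      rows[[k]] <- sc
    }
  }
  new_experiment(dplyr::bind_rows(rows), "proportion")
}

# Set target's mean proportion to `level`, scale the others proportionally
# so means still sum to 1; sds follow their means (constant CV).
reweight_proportion_model <- function(model, target_cell, level) {
  mean <- model$mean; sd <- model$sd
  others <- setdiff(model$cell_types, target_cell)
  scale_t <- level / mean[target_cell]
  scale_o <- (1 - level) / sum(mean[others])
  cv <- ifelse(mean > 0, sd / mean, 0)
  mean[target_cell] <- level
  mean[others] <- mean[others] * scale_o
  proportion_model(model$cell_types, mean, cv * mean)
}

#' Outlier sample experiment
#'
#' For each outlier count, simulates a dataset with that many appended
#' IQR-limit outlier samples (split half case / half control, extra one to
#' case) and scores the detectors. The gold standard is always derived from
#' the non-outlier samples' profiles, so the scores isolate how much each
#' detector suffers from the contamination. The benchmark grid is
#' `1, 2, 4, 6, 8` added outliers (0 included here as the clean baseline).
#'
#' @inheritParams run_cv_experiment
#' @param counts Integer vector of outlier counts.
#' @return A `csde_experiment` tibble with an `n_outliers` column.
#' @export
run_outlier_experiment <- function(prop_model, prof_model,
                                   counts = c(0, 1, 2, 4, 6, 8),
                                   detectors = c("perm-ols", "perm-robust"),
                                   n_reps = 1, config = sim_config(),
                                   n_perm = 200, seed = 1L) {
  stopifnot(all(counts >= 0), n_reps >= 1)
  grid_seeds <- derive_seeds(seed + 2, length(counts) * n_reps)
  rows <- list(); k <- 0
  for (ci in seq_along(counts)) {
    for (r in seq_len(n_reps)) {
      k <- k + 1
      cfg <- config
      cfg$outlier_case <- as.integer(ceiling(counts[ci] / 2))
      cfg$outlier_control <- as.integer(floor(counts[ci] / 2))
      cfg$seed <- as.integer(grid_seeds[k])
      sc <- score_one_dataset(cfg, prop_model, prof_model, detectors, n_perm)
      sc$n_outliers <- counts[ci]; sc$replicate <- r
      rows[[k]] <- sc
    }
  }
  new_experiment(dplyr::bind_rows(rows), "outlier")
}

#' Per-level summary of an experiment grid
#'
#' Medians over replicates, per level x detector x cell type (the
#' benchmark's reported aggregate).
#'
#' @param result A `csde_experiment` tibble.
#' @return A tibble of per-level medians of accuracy and the residual
#'   summary.
#' @export
experiment_summary <- function(result) {
  stopifnot(inherits(result, "csde_experiment"))
  level_col <- intersect(c("cv", "proportion", "n_outliers"),
                         names(result))[1]
  dplyr::summarise(
    dplyr::group_by(result, .data[[level_col]], .data$detector,
                    .data$cell_type),
    accuracy = stats::median(.data$accuracy, na.rm = TRUE),
    median_relative_residual =
      stats::median(.data$median_relative_residual, na.rm = TRUE),
    n_reps = dplyr::n(),
    .groups = "drop"
  )
}

#' Rare cell type benchmark
#'
#' The package's headline configuration: four cell types with mean
#' proportions (0.2, 0.35, 0.25, 0.2) and proportion CV 0.5, the first cell
#' type being the low-abundance target; gene-wise profile CVs drawn
#' uniformly in `[0.4, 0.9]`; 10% injected csDEGs per cell type with fold
#' changes uniform in `[1.5, 3]`; two groups of 100 samples. Each replicate
#' simulates a dataset, derives the Wilcoxon+BH gold standard from the known
#' per-sample profiles, runs the detectors and records the target cell
#' type's top-list accuracy. Low abundance combined with realistic
#' heterogeneity caps what any detector can recover for the target cell
#' type.
#'
#' @param seed Master seed; replicate seeds derive from it.
#' @param n_genes Number of genes (default 2000).
#' @param n_perm Permutations for the permutation detectors (default 200).
#' @param n_reps Number of replicates (default 3).
#' @param detectors Detector names (see [run_detector()]).
#' @return A tibble with one row per replicate x detector: `replicate`,
#'   `detector`, `accuracy` (top-list accuracy for the 0.2-proportion cell
#'   type), `gold_size`.
#' @export
run_rare_cell_benchmark <- function(seed = 1L, n_genes = 2000,
                                    n_perm = 200, n_reps = 3,
                                    detectors = c("perm-ols", "perm-robust",
                                                  "welch", "interaction")) {
  cts <- c("ctA", "ctB", "ctC", "ctD")
  m <- c(0.2, 0.35, 0.25, 0.2)
  pm <- proportion_model(cts, mean = m, sd = m / 2)
  rep_seeds <- derive_seeds(seed, n_reps)
  rows <- list()
  for (r in seq_len(n_reps)) {
    s <- as.integer(rep_seeds[r])
    pf <- random_profile_model(n_genes, cts, cv_range = c(0.4, 0.9),
                               seed = s + 1L)
    cfg <- sim_config(n_case = 100, n_control = 100, csdeg_fraction = 0.1,
                      fold_change_range = c(1.5, 3), seed = s)
    ds <- simulate_dataset(cfg, pm, pf)
    gold <- gold_standard_csdegs(ds$S, ds$groups)
    for (det in detectors) {
      tab <- run_detector(ds$E, ds$C, ds$groups, det, n_perm = n_perm,
                          seed = s)
      rows[[length(rows) + 1]] <- tibble::tibble(
        replicate = r, detector = det,
        accuracy = toplist_accuracy(tab, gold, "ctA"),
        gold_size = length(gold$sets$ctA)
      )
    }
  }
  dplyr::bind_rows(rows)
}
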