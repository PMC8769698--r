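# Semi-simulation engine: bulk mixtures E = S * C with known per-sample
# cell type-specific profiles, controlled heterogeneity, injected csDEGs,
# outlier samples and unknown-cell noise.

#' Cell type proportion model
#'
#' Parametrises the distribution of cell type proportions across samples:
#' each sample's raw composition is drawn from independent normals
#' `N(mean_t, sd_t)` per cell type, negatives are clipped to zero, and the
#' column is rescaled to sum to one. Means are normalised to sum to one at
#' construction.
#'
#' @param cell_types Character vector of cell type names (at least 2).
#' @param mean Numeric vector of mean proportions, one per cell type;
#'   normalised to sum to 1.
#' @param sd Numeric vector of non-negative standard deviations on the raw
#'   (pre-normalisation) scale.
#' @return An object of class `proportion_model`.
#' @examples
#' proportion_model(c("T", "B"), mean = c(0.7, 0.3), sd = c(0.1, 0.05))
#' @export
proportion_model <- function(cell_types, mean, sd) {
  cell_types <- as.character(cell_types)
  stopifnot(length(cell_types) >= 2, !anyDuplicated(cell_types))
  if (length(mean) != length(cell_types) || length(sd) != length(cell_types)) {
    stop("`mean` and `sd` must have one entry per cell type", call. = FALSE)
  }
  if (any(mean < 0) || any(sd < 0)) {
    stop("proportion means and sds must be non-negative", call. = FALSE)
  }
  if (sum(mean) <= 0) {
    stop("invalid proportion model: all cell type means are zero", call. = FALSE)
  }
  mean <- mean / sum(mean)
  structure(
    list(cell_types = cell_types,
         mean = stats::setNames(as.numeric(mean), cell_types),
         sd = stats::setNames(as.numeric(sd), cell_types)),
    class = "proportion_model"
  )
}

#' @export
print.proportion_model <- function(x, ...) {
  cat("<proportion_model> ", length(x$cell_types), " cell types\n", sep = "")
  print(round(rbind(mean = x$mean, sd = x$sd), 4))
  invisible(x)
}

#' Cell type-specific expression profile model
#'
#' Holds gene-wise mean and standard deviation of expression for each cell
#' type; per-sample profiles are drawn as `N(mean_it, sd_it)` (clipped at 0
#' by default, expression being non-negative). An optional `case_mean` table
#' carries group-specific means: it differs from `mean` exactly at the
#' injected csDEGs (see [inject_csdegs()]).
#'
#' @param genes Character vector of gene identifiers.
#' @param mean,sd Numeric matrices, genes x cell types, non-negative;
#'   column names are the cell type names.
#' @param case_mean Optional genes x cell types matrix of case-group means;
#'   defaults to `mean` (no csDEGs).
#' @return An object of class `profile_model`.
#' @export
profile_model <- function(genes, mean, sd, case_mean = NULL) {
  genes <- as.character(genes)
  mean <- as.matrix(mean); sd <- as.matrix(sd)
  stopifnot(nrow(mean) == length(genes), all(dim(sd) == dim(mean)))
  if (is.null(colnames(mean))) {
    colnames(mean) <- paste0("ct", seq_len(ncol(mean)))
  }
  colnames(sd) <- colnames(mean)
  rownames(mean) <- rownames(sd) <- genes
  if (any(mean < 0) || any(sd < 0)) {
    stop("profile means and sds must be non-negative", call. = FALSE)
  }
  if (is.null(case_mean)) {
    case_mean <- mean
  } else {
    case_mean <- as.matrix(case_mean)
    stopifnot(all(dim(case_mean) == dim(mean)))
    dimnames(case_mean) <- dimnames(mean)
    if (any(case_mean < 0)) stop("case means must be non-negative", call. = FALSE)
  }
  structure(
    list(genes = genes, cell_types = colnames(mean),
         mean = mean, sd = sd, case_mean = case_mean),
    class = "profile_model"
  )
}

#' @export
print.profile_model <- function(x, ...) {
  n_de <- sum(x$case_mean != x$mean)
  cat("<profile_model> ", length(x$genes), " genes x ", length(x$cell_types),
      " cell types (", n_de, " csDEG entries)\n", sep = "")
  invisible(x)
}

#' Draw a random profile model emulating measured cell type profiles
#'
#' Gene-wise mean expression is drawn log-normally per cell type (so a few
#' genes dominate, as in real transcriptomes) and gene-wise coefficients of
#' variation are drawn uniformly from `cv_range`, emulating the spread of
#' between-sample heterogeneity observed in measured cell type profiles
#' (per-cell-type median CVs of roughly 0.4-0.95 in sorted blood data).
#'
#' @param n_genes Number of genes.
#' @param cell_types Character vector of cell type names.
#' @param meanlog,sdlog Parameters of the log-normal for mean expression.
#' @param cv_range Length-2 numeric: range of the uniform gene-wise CV draw.
#' @param seed Integer seed.
#' @return A [profile_model()].
#' @export
random_profile_model <- function(n_genes, cell_types,
                                 meanlog = 4, sdlog = 1,
                                 cv_range = c(0.4, 0.95), seed = 1L) {
  stopifnot(n_genes >= 1, length(cell_types) >= 2,
            length(cv_range) == 2, all(cv_range >= 0))
  genes <- sprintf("g%04d", seq_len(n_genes))
  withr::with_seed(seed, {
    mu <- matrix(stats::rlnorm(n_genes * length(cell_types), meanlog, sdlog),
                 nrow = n_genes, dimnames = list(genes, cell_types))
    cv <- matrix(stats::runif(n_genes * length(cell_types),
                              cv_range[1], cv_range[2]),
                 nrow = n_genes)
    profile_model(genes, mu, mu * cv)
  })
}

#' Simulation configuration
#'
#' Bundles the knobs of one semi-simulated dataset: group sizes, optional
#' fixed coefficients of variation, csDEG injection, outlier samples and
#' unknown-cell noise.
#'
#' @param n_case,n_control Samples per group (default 100 each, the study
#'   design emulated throughout).
#' @param cv_override `NULL`, a single number applied to every cell type, or
#'   a named list/vector mapping cell types to a fixed CV (sd = CV * mean for
#'   every gene of that cell type).
#' @param csdeg_fraction Fraction of genes injected as csDEGs per cell type.
#' @param fold_change_range Length-2 numeric >= 1: fold changes are drawn
#'   uniformly in this range, direction (up/down) symmetric.
#' @param outlier_case,outlier_control Number of outlier samples appended to
#'   each group (see [inject_outlier_samples()]).
#' @param noise_spec Optional list with elements `mean`, `sd` (gene-wise
#'   unknown-cell profile), `count_range` (integer pair, default c(10, 100))
#'   and `per_cell_scale` (default 1/500).
#' @param seed Integer seed; all randomness in [simulate_dataset()] derives
#'   from it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_case = 100L, n_control = 100L, cv_override = NULL,
                       csdeg_fraction = 0.1, fold_change_range = c(1.5, 3),
                       outlier_case = 0L, outlier_control = 0L,
                       noise_spec = NULL, seed = 1L) {
  stopifnot(n_case >= 1, n_control >= 1, n_case + n_control >= 4,
            csdeg_fraction >= 0, csdeg_fraction <= 1,
            length(fold_change_range) == 2,
            fold_change_range[1] >= 1,
            fold_change_range[1] <= fold_change_range[2],
            outlier_case >= 0, outlier_control >= 0)
  if (!is.null(cv_override) && any(unlist(cv_override) < 0)) {
    stop("cv_override must be non-negative", call. = FALSE)
  }
  structure(
    list(n_case = as.integer(n_case), n_control = as.integer(n_control),
         cv_override = cv_override, csdeg_fraction = csdeg_fraction,
         fold_change_range = as.numeric(fold_change_range),
         outlier_case = as.integer(outlier_case),
         outlier_control = as.integer(outlier_control),
         noise_spec = noise_spec, seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Generate a cell type proportion matrix
#'
#' Each sample is drawn independently: raw values `N(mean_t, sd_t)` per cell
#' type, negatives set to 0, then the column is scaled to sum to 1. A column
#' that is all zero after clipping is redrawn (at most 100 attempts).
#'
#' @param model A [proportion_model()].
#' @param n_samples Number of samples (columns).
#' @param seed Integer seed.
#' @return Numeric matrix, cell types x samples; columns sum to 1.
#' @export
generate_proportions <- function(model, n_samples, seed = 1L) {
  stopifnot(inherits(model, "proportion_model"), n_samples >= 1)
  n_ct <- length(model$cell_types)
  withr::with_seed(seed, {
    raw <- matrix(stats::rnorm(n_ct * n_samples, model$mean, model$sd),
                  nrow = n_ct)
    raw[raw < 0] <- 0
    tot <- colSums(raw)
    for (j in which(tot == 0)) {
      for (attempt in seq_len(100)) {
        col <- pmax(stats::rnorm(n_ct, model$mean, model$sd), 0)
        if (sum(col) > 0) break
      }
      if (sum(col) == 0) {
        stop("could not draw a non-degenerate proportion column", call. = FALSE)
      }
      raw[, j] <- col
      tot[j] <- sum(col)
    }
    C <- sweep(raw, 2, tot, "/")
    dimnames(C) <- list(model$cell_types, paste0("s", seq_len(n_samples)))
    C
  })
}

#' Generate the per-sample profile tensor S
#'
#' Draws `S[i, t, j] ~ N(mean_it[group(j)], sd_it)`, clipped at 0 by default.
#' Case samples use the model's `case_mean`, control samples its `mean`.
#' When `cv_override` sets cell type `t` to `v`, the sampling sd is
#' `v * mean_it` gene-wise (heterogeneity pinned to a fixed coefficient of
#' variation while the mean stays at its modelled level).
#'
#' @param model A [profile_model()].
#' @param groups Character vector of per-sample labels in
#'   `c("case", "control")`.
#' @param cv_override As in [sim_config()].
#' @param seed Integer seed.
#' @param clip_negative Clip negative draws to 0 (default TRUE).
#' @return 3-d array genes x cell types x samples.
#' @export
generate_profile_tensor <- function(model, groups, cv_override = NULL,
                                    seed = 1L, clip_negative = TRUE) {
  stopifnot(inherits(model, "profile_model"))
  groups <- as.character(groups)
  if (!all(groups %in% c("case", "control"))) {
    stop('`groups` must contain only "case" and "control"', call. = FALSE)
  }
  n <- length(groups)
  G <- length(model$genes); TT <- length(model$cell_types)
  sd_tab <- resolve_profile_sd(model, cv_override)
  withr::with_seed(seed, {
    S <- array(NA_real_, dim = c(G, TT, n),
               dimnames = list(model$genes, model$cell_types,
                               paste0("s", seq_len(n))))
    for (j in seq_len(n)) {
      mu <- if (groups[j] == "case") model$case_mean else model$mean
      draw <- matrix(stats::rnorm(G * TT, mu, sd_tab), nrow = G)
      if (clip_negative) draw[draw < 0] <- 0
      S[, , j] <- draw
    }
    S
  })
}

# Effective gene x cell type sd table after applying a CV override.
# cv_override: NULL, scalar, or named list/vector per cell type. For an
# overridden cell type the sd is tied to the *control* mean (the measured
# level); injected case fold changes do not inflate the noise.
resolve_profile_sd <- function(model, cv_override) {
  sd_tab <- model$sd
  if (is.null(cv_override)) return(sd_tab)
  if (any(unlist(cv_override) < 0)) {
    stop("cv_override must be non-negative", call. = FALSE)
  }
  if (is.null(names(cv_override)) && length(cv_override) == 1) {
    cv_override <- stats::setNames(rep(as.numeric(cv_override),
                                       length(model$cell_types)),
                                   model$cell_types)
  }
  bad <- setdiff(names(cv_override), model$cell_types)
  if (length(bad)) {
    stop("cv_override names unknown cell types: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  for (ct in names(cv_override)) {
    sd_tab[, ct] <- as.numeric(cv_override[[ct]]) * model$mean[, ct]
  }
  sd_tab
}

#' Inject cell type-specific differentially expressed genes
#'
#' For each cell type independently, `ceiling(fraction * G)` genes are chosen
#' uniformly at random; their case-group mean is the control mean times a
#' fold change drawn uniformly from `fold_range`, with direction (times f or
#' divided by f) chosen with probability 1/2.
#'
#' @param model A [profile_model()].
#' @param fraction Fraction of genes per cell type in `[0, 1]`.
#' @param fold_range Length-2 numeric >= 1.
#' @param seed Integer seed.
#' @return List with `model` (the input with `case_mean` set) and `truth`
#'   (logical genes x cell types mask of injected csDEGs).
#' @export
inject_csdegs <- function(model, fraction, fold_range = c(1.5, 3), seed = 1L) {
  stopifnot(inherits(model, "profile_model"))
  if (fraction < 0 || fraction > 1) {
    stop("`fraction` must be in [0, 1]", call. = FALSE)
  }
  stopifnot(length(fold_range) == 2, fold_range[1] >= 1,
            fold_range[1] <= fold_range[2])
  G <- length(model$genes); TT <- length(model$cell_types)
  truth <- matrix(FALSE, G, TT,
                  dimnames = list(model$genes, model$cell_types))
  case_mean <- model$mean
  n_pick <- as.integer(ceiling(fraction * G))
  if (n_pick > 0) {
    withr::with_seed(seed, {
      for (t in seq_len(TT)) {
        idx <- sample.int(G, n_pick)
        f <- stats::runif(n_pick, fold_range[1], fold_range[2])
        up <- stats::runif(n_pick) < 0.5
        fc <- ifelse(up, f, 1 / f)
        case_mean[idx, t] <- model$mean[idx, t] * fc
        truth[idx, t] <- TRUE
      }
    })
  }
  list(model = profile_model(model$genes, model$mean, model$sd, case_mean),
       truth = truth)
}

#' Compose bulk expression from profiles and proportions
#'
#' The bulk expression of gene i in sample j is the proportion-weighted sum
#' of that sample's cell type-specific profiles:
#' `E[i, j] = sum_t C[t, j] * S[i, t, j]`.
#'
#' @param S Profile tensor, genes x cell types x samples.
#' @param C Proportion matrix, cell types x samples.
#' @return Bulk matrix, genes x samples.
#' @export
compose_bulk <- function(S, C) {
  stopifnot(length(dim(S)) == 3)
  C <- as.matrix(C)
  if (dim(S)[2] != nrow(C) || dim(S)[3] != ncol(C)) {
    stop("dimension mismatch between S (", paste(dim(S), collapse = "x"),
         ") and C (", paste(dim(C), collapse = "x"), ")", call. = FALSE)
  }
  G <- dim(S)[1]
  E <- matrix(0, G, ncol(C), dimnames = list(dimnames(S)[[1]], colnames(C)))
  for (t in seq_len(nrow(C))) {
    St <- matrix(S[, t, ], nrow = G)
    E <- E + St * rep(C[t, ], each = G)
  }
  E
}

#' Append outlier samples whose profiles sit at the IQR limits
#'
#' For each appended sample and each cell type, one side (lower or upper) is
#' chosen at random; the outlier's profile for that cell type is drawn from a
#' normal whose gene-wise mean is the corresponding Tukey limit
#' (`Q1 - 1.5*IQR` or `Q3 + 1.5*IQR`, quartiles by linear interpolation over
#' the base samples' profiles, negative means clipped to 0) and whose sd is
#' the gene's model sd. Proportions come from the same proportion model as
#' the base samples.
#'
#' @param dataset A [simulate_dataset()] result.
#' @param prof_model,prop_model The models the base dataset was drawn from.
#' @param n_case,n_control Number of appended case / control outliers
#'   (defaults 1 and 5, the single-dataset benchmark setting).
#' @param cv_override As in [sim_config()]; must match the base dataset's.
#' @param seed Integer seed.
#' @return The dataset with outlier samples appended (E, C, S, groups grown;
#'   `outlier` logical marks appended columns).
#' @export
inject_outlier_samples <- function(dataset, prof_model, prop_model,
                                   n_case = 1L, n_control = 5L,
                                   cv_override = NULL, seed = 1L) {
  stopifnot(inherits(dataset, "sim_dataset"),
            inherits(prof_model, "profile_model"),
            inherits(prop_model, "proportion_model"),
            n_case >= 0, n_control >= 0)
  n_new <- n_case + n_control
  if (n_new == 0) return(dataset)
  if (dim(dataset$S)[3] < 2) {
    stop("need at least 2 base samples to compute quartiles", call. = FALSE)
  }
  genes <- dimnames(dataset$S)[[1]]
  cts <- dimnames(dataset$S)[[2]]
  keep <- match(genes, prof_model$genes)
  sd_tab <- resolve_profile_sd(prof_model, cv_override)[keep, , drop = FALSE]
  G <- length(genes); TT <- length(cts)
  # gene-wise Tukey limits per cell type over the base samples
  lo <- hi <- matrix(NA_real_, G, TT, dimnames = list(genes, cts))
  for (t in seq_len(TT)) {
    q <- apply(matrix(dataset$S[, t, ], nrow = G), 1, stats::quantile,
               probs = c(0.25, 0.75), names = FALSE)
    iqr <- q[2, ] - q[1, ]
    lo[, t] <- pmax(q[1, ] - 1.5 * iqr, 0)
    hi[, t] <- q[2, ] + 1.5 * iqr
  }
  new_groups <- c(rep("case", n_case), rep("control", n_control))
  withr::with_seed(seed, {
    C_new <- generate_proportions(prop_model, n_new,
                                  seed = sample.int(.Machine$integer.max, 1))
    S_new <- array(NA_real_, dim = c(G, TT, n_new))
    for (j in seq_len(n_new)) {
      for (t in seq_len(TT)) {
        upper <- stats::runif(1) < 0.5
        mu <- if (upper) hi[, t] else lo[, t]
        draw <- stats::rnorm(G, mu, sd_tab[, t])
        S_new[, t, j] <- pmax(draw, 0)
      }
    }
  })
  n0 <- dim(dataset$S)[3]
  ids <- paste0("o", seq_len(n_new))
  colnames(C_new) <- ids
  dimnames(S_new) <- list(genes, cts, ids)
  E_new <- compose_bulk(S_new, C_new)
  dataset$E <- cbind(dataset$E, E_new)
  dataset$C <- cbind(dataset$C, C_new)
  S_all <- array(NA_real_, dim = c(G, TT, n0 + n_new),
                 dimnames = list(genes, cts, c(dimnames(dataset$S)[[3]], ids)))
  S_all[, , seq_len(n0)] <- dataset$S
  S_all[, , n0 + seq_len(n_new)] <- S_new
  dataset$S <- S_all
  dataset$groups <- c(dataset$groups, new_groups)
  dataset$outlier <- c(rep(FALSE, n0), rep(TRUE, n_new))
  dataset
}

#' Add expression noise from cells of an unknown type
#'
#' Per sample, `k ~ Uniform{count_range}` unknown-cell expression vectors are
#' drawn from `N(mean, sd)` (clipped at 0), summed, scaled by
#' `per_cell_scale` and added to the bulk matrix. The proportion matrix is
#' deliberately not updated: the noise cell type stays invisible to the
#' detectors, as it would in a real analysis with an incomplete reference.
#'
#' @param E Bulk matrix, genes x samples.
#' @param noise_mean,noise_sd Gene-wise mean and sd of the unknown-cell
#'   profile (length = nrow(E)).
#' @param count_range Integer pair: inclusive range of the unknown-cell count
#'   per sample (default c(10, 100)).
#' @param per_cell_scale Scale applied to each unknown cell's contribution so
#'   that the added counts perturb rather than dominate; the default 1/500
#'   makes one unknown cell contribute like one cell of a nominal 500-cell
#'   sample.
#' @param seed Integer seed.
#' @return The bulk matrix with noise added.
#' @export
add_unknown_noise <- function(E, noise_mean, noise_sd,
                              count_range = c(10L, 100L),
                              per_cell_scale = 1 / 500, seed = 1L) {
  E <- as.matrix(E)
  stopifnot(length(noise_mean) == nrow(E), length(noise_sd) == nrow(E),
            length(count_range) == 2, count_range[1] >= 0,
            count_range[1] <= count_range[2], per_cell_scale >= 0)
  withr::with_seed(seed, {
    counts <- sample(seq(count_range[1], count_range[2]), ncol(E),
                     replace = TRUE)
    for (j in seq_len(ncol(E))) {
      k <- counts[j]
      if (k == 0) next
      cells <- matrix(stats::rnorm(nrow(E) * k, noise_mean, noise_sd),
                      nrow = nrow(E))
      cells[cells < 0] <- 0
      E[, j] <- E[, j] + per_cell_scale * rowSums(cells)
    }
  })
  attr(E, "noise_counts") <- counts
  E
}

#' Filter genes with zero median bulk expression in both groups
#'
#' @param E Bulk matrix, genes x samples.
#' @param groups Per-sample labels in `c("case", "control")`.
#' @return Logical vector over genes: TRUE = keep. A gene is dropped exactly
#'   when its within-group median bulk expression is 0 in the case group and
#'   in the control group.
#' @export
filter_zero_median_genes <- function(E, groups) {
  E <- as.matrix(E)
  stopifnot(length(groups) == ncol(E))
  if (!all(c("case", "control") %in% groups)) {
    stop("both groups must be present", call. = FALSE)
  }
  med_case <- apply(E[, groups == "case", drop = FALSE], 1, stats::median)
  med_ctrl <- apply(E[, groups == "control", drop = FALSE], 1, stats::median)
  !(med_case == 0 & med_ctrl == 0)
}

#' Simulate one semi-simulated benchmark dataset
#'
#' Orchestrates the generation steps in their natural order: csDEG injection
#' into the profile model, proportion generation, per-sample profile tensor,
#' bulk composition, optional outlier samples and unknown-cell noise, and a
#' final zero-median gene filter (recorded in `kept_genes`).
#'
#' @param config A [sim_config()].
#' @param prop_model A [proportion_model()].
#' @param prof_model A [profile_model()] (control means; case means are
#'   injected here according to `config`).
#' @return An object of class `sim_dataset`: list with `E`, `C`, `S`,
#'   `groups`, `truth`, `outlier`, `kept_genes`, `seed`, `config`.
#' @export
simulate_dataset <- function(config, prop_model, prof_model) {
  stopifnot(inherits(config, "sim_config"),
            inherits(prop_model, "proportion_model"),
            inherits(prof_model, "profile_model"))
  seeds <- derive_seeds(config$seed, 5)
  inj <- inject_csdegs(prof_model, config$csdeg_fraction,
                       config$fold_change_range, seed = seeds[1])
  groups <- c(rep("case", config$n_case), rep("control", config$n_control))
  n <- length(groups)
  C <- generate_proportions(prop_model, n, seed = seeds[2])
  S <- generate_profile_tensor(inj$model, groups,
                               cv_override = config$cv_override,
                               seed = seeds[3])
  E <- compose_bulk(S, C)
  ds <- structure(
    list(E = E, C = C, S = S, groups = groups, truth = inj$truth,
         outlier = rep(FALSE, n), kept_genes = NULL,
         seed = config$seed, config = config),
    class = "sim_dataset"
  )
  if (config$outlier_case + config$outlier_control > 0) {
    ds <- inject_outlier_samples(ds, inj$model, prop_model,
                                 n_case = config$outlier_case,
                                 n_control = config$outlier_control,
                                 cv_override = config$cv_override,
                                 seed = seeds[4])
  }
  if (!is.null(config$noise_spec)) {
    ns <- config$noise_spec
    ds$E <- add_unknown_noise(
      ds$E, ns$mean, ns$sd,
      count_range = ns$count_range %||% c(10L, 100L),
      per_cell_scale = ns$per_cell_scale %||% (1 / 500),
      seed = seeds[5]
    )
  }
  keep <- filter_zero_median_genes(ds$E, ds$groups)
  ds$kept_genes <- keep
  ds$E <- ds$E[keep, , drop = FALSE]
  ds$S <- ds$S[keep, , , drop = FALSE]
  ds$truth <- ds$truth[keep, , drop = FALSE]
  ds
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat("<sim_dataset> ", nrow(x$E), " genes x ", ncol(x$E), " samples (",
      sum(x$groups == "case"), " case / ", sum(x$groups == "control"),
      " control), ", dim(x$S)[2], " cell types, ", sum(x$truth),
      " true csDEG entries\n", sep = "")
  invisible(x)
}

# deterministic sub-seeds below 2^31 derived from one master seed
derive_seeds <- function(seed, n) {
  (as.numeric(seed) * 7919 + 104729 * seq_len(n)) %% 2147483647
}

`%||%` <- function(a, b) if (is.null(a)) b else a
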