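# Shared fixtures: the four-cell-type benchmark models (one rare-ish cell
# type at mean proportion 0.2, unequal means, proportion CV 0.5) and small
# profile models built in code.

bench_cell_types <- c("ctA", "ctB", "ctC", "ctD")

bench_prop_model <- function() {
  m <- c(0.2, 0.35, 0.25, 0.2)
  proportion_model(bench_cell_types, mean = m, sd = m / 2)
}

bench_prof_model <- function(n_genes = 300, seed = 42,
                             cv_range = c(0.4, 0.9)) {
  random_profile_model(n_genes, bench_cell_types, cv_range = cv_range,
                       seed = seed)
}

# hand-built profile model with explicit parameter matrices
flat_prof_model <- function(n_genes, cell_types, mean_value, cv) {
  mu <- matrix(mean_value, n_genes, length(cell_types),
               dimnames = list(sprintf("g%04d", seq_len(n_genes)),
                               cell_types))
  profile_model(rownames(mu), mu, mu * cv)
}

# minimal sim_dataset wrapper around explicit E, C, S for targeted tests
manual_dataset <- function(E, C, S, groups) {
  structure(
    list(E = E, C = C, S = S, groups = groups,
         truth = matrix(FALSE, nrow(E), nrow(C),
                        dimnames = list(rownames(E), rownames(C))),
         outlier = rep(FALSE, length(groups)), kept_genes = NULL,
         seed = 0L, config = NULL),
    class = "sim_dataset"
  )
}
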