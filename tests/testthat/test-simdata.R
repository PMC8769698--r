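test_that("proportion generation follows the draw-clip-normalize rule", {
  # zero variance: columns are exactly the (normalised) means
  pm <- proportion_model(c("x", "y"), mean = c(0.6, 0.4), sd = c(0, 0))
  C <- generate_proportions(pm, 3, seed = 1)
  expect_equal(unname(C), matrix(c(0.6, 0.4), 2, 3), tolerance = 1e-12)

  # rare cell type keeps its mean proportion on average
  pm2 <- proportion_model(c("rare", "bulk"), mean = c(0.03, 0.97),
                          sd = c(0.01, 0.05))
  C2 <- generate_proportions(pm2, 10000, seed = 7)
  expect_true(all(C2 >= 0))
  expect_equal(max(abs(colSums(C2) - 1)), 0, tolerance = 1e-9)
  expect_equal(mean(C2["rare", ]), 0.03, tolerance = 0.005)

  # literal re-execution oracle: draw -> clip at 0 -> scale to sum 1
  pm3 <- proportion_model(c("a", "b"), mean = c(0.1, 0.9), sd = c(0.3, 0.1))
  C3 <- generate_proportions(pm3, 25, seed = 11)
  oracle <- withr::with_seed(11, {
    sapply(1:25, function(j) {
      x <- stats::rnorm(2, pm3$mean, pm3$sd)
      x[x < 0] <- 0
      x / sum(x)
    })
  })
  expect_equal(unname(C3), unname(oracle), tolerance = 1e-15)
})

test_that("degenerate proportion models are rejected", {
  expect_error(proportion_model(c("a", "b"), c(0, 0), c(1, 1)),
               "all cell type means are zero")
  expect_error(proportion_model("a", 1, 0))
  expect_error(proportion_model(c("a", "b"), c(0.5, 0.5), c(-1, 0)))
})

test_that("profile tensor honours cv_override and matches re-execution", {
  # fixed CV: sampling sd is cv * mean; empirical CV over many samples
  pf <- flat_prof_model(1, c("u", "v"), mean_value = 10, cv = 0.1)
  groups <- rep("control", 10000)
  S <- generate_profile_tensor(pf, groups, cv_override = 0.5, seed = 3,
                               clip_negative = FALSE)
  x <- S[1, 1, ]
  expect_equal(stats::sd(x) / mean(x), 0.5, tolerance = 0.02)

  # zero mean gene: sd = cv * 0 = 0, all draws exactly 0
  mu <- matrix(c(0, 5), 2, 1, dimnames = list(c("g1", "g2"), "ct"))
  pf0 <- profile_model(c("g1", "g2"), mu, mu * 0.4)
  S0 <- generate_profile_tensor(pf0, rep("case", 50), cv_override = 2,
                                seed = 4)
  expect_true(all(S0["g1", , ] == 0))

  # entrywise re-execution oracle: per sample, draw N(mean, sd), clip at 0
  pf2 <- bench_prof_model(n_genes = 3)
  gr <- c("case", "control", "case", "control")
  S2 <- generate_profile_tensor(pf2, gr, seed = 9)
  oracle <- withr::with_seed(9, {
    out <- array(NA_real_, dim = c(3, 4, 4))
    for (j in 1:4) {
      mu_j <- if (gr[j] == "case") pf2$case_mean else pf2$mean
      d <- matrix(stats::rnorm(12, mu_j, pf2$sd), nrow = 3)
      d[d < 0] <- 0
      out[, , j] <- d
    }
    out
  })
  expect_equal(unname(S2[, , ]), oracle, tolerance = 1e-15)
  expect_error(generate_profile_tensor(pf2, gr, cv_override = -1, seed = 1),
               "non-negative")
})

test_that("csDEG injection marks the right number of entries", {
  pf <- bench_prof_model(n_genes = 1000)

  none <- inject_csdegs(pf, 0, c(2, 2), seed = 1)
  expect_identical(none$model$case_mean, none$model$mean)
  expect_false(any(none$truth))

  all_de <- inject_csdegs(pf, 1, c(2, 2), seed = 2)
  expect_true(all(all_de$truth))
  ratio <- all_de$model$case_mean / all_de$model$mean
  expect_true(all(abs(ratio - 2) < 1e-12 | abs(ratio - 0.5) < 1e-12))
  expect_true(any(ratio > 1) && any(ratio < 1))  # both directions occur

  tenth <- inject_csdegs(pf, 0.1, c(1.5, 3), seed = 3)
  expect_identical(unname(colSums(tenth$truth)), rep(100, 4))
  # non-selected entries untouched
  expect_equal(tenth$model$case_mean[!tenth$truth],
               tenth$model$mean[!tenth$truth])
  expect_error(inject_csdegs(pf, 1.2, c(2, 2)), "fraction")
})

test_that("bulk composition is the proportion-weighted sum", {
  # hand dot product: one sample, 2 genes, 2 cell types
  S <- array(c(10, 0, 2, 5), dim = c(2, 2, 1),
             dimnames = list(c("g1", "g2"), c("t1", "t2"), "s1"))
  C <- matrix(c(0.7, 0.3), 2, 1, dimnames = list(c("t1", "t2"), "s1"))
  expect_equal(unname(compose_bulk(S, C)[, 1]), c(7.6, 1.5))

  # identity mixture: single cell type with proportion 1
  S1 <- array(rnorm(20, 100, 10), dim = c(5, 1, 4))
  C1 <- matrix(1, 1, 4)
  expect_equal(unname(compose_bulk(S1, C1)), S1[, 1, ])

  # linearity in S and in C (randomized)
  withr::with_seed(5, {
    for (rep in 1:5) {
      S2 <- array(runif(24, 0, 50), dim = c(3, 2, 4))
      C2 <- matrix(runif(8), 2, 4)
      a <- runif(1, 0.1, 5)
      expect_equal(compose_bulk(S2 * a, C2), compose_bulk(S2, C2) * a)
      expect_equal(compose_bulk(S2, C2 * a), compose_bulk(S2, C2) * a)
    }
  })
  expect_error(compose_bulk(S1, matrix(1, 2, 4)), "dimension mismatch")
})

test_that("outlier samples sit at the Tukey limits of the base profiles", {
  # base values {1,2,3,4,5}: Q1 = 2, Q3 = 4, IQR = 2, limits (-1, 7);
  # lower limit clipped to 0. With model sd 0 the outlier draw IS the limit.
  genes <- "g0001"
  S <- array(NA_real_, dim = c(1, 2, 5),
             dimnames = list(genes, c("t1", "t2"), paste0("s", 1:5)))
  S[1, 1, ] <- 1:5
  S[1, 2, ] <- 10  # constant profile in the second cell type
  C <- matrix(0.5, 2, 5, dimnames = list(c("t1", "t2"), paste0("s", 1:5)))
  ds <- manual_dataset(compose_bulk(S, C), C, S,
                       groups = c("case", "case", "case", "control",
                                  "control"))
  mu <- matrix(c(3, 10), 1, 2, dimnames = list(genes, c("t1", "t2")))
  pf <- profile_model(genes, mu, mu * 0)
  pm <- proportion_model(c("t1", "t2"), c(0.5, 0.5), c(0, 0))
  grown <- inject_outlier_samples(ds, pf, pm, n_case = 3, n_control = 3,
                                  seed = 21)
  new_vals <- grown$S[1, 1, 6:11]
  expect_true(all(abs(new_vals - 0) < 1e-12 | abs(new_vals - 7) < 1e-12))
  # IQR = 0 in the constant cell type: both limits equal the value
  expect_equal(unname(grown$S[1, 2, 6:11]), rep(10, 6))
  expect_identical(grown$groups[6:11], rep(c("case", "control"), each = 3))
  expect_identical(grown$outlier, c(rep(FALSE, 5), rep(TRUE, 6)))

  # defaults: one outlier case sample and five outlier control samples
  def <- inject_outlier_samples(ds, pf, pm, seed = 22)
  expect_identical(sum(def$groups == "case") - 3L, 1L)
  expect_identical(sum(def$groups == "control") - 2L, 5L)
})

test_that("unknown-cell noise perturbs the bulk within the count range", {
  E <- matrix(100, 5, 8, dimnames = list(paste0("g", 1:5), paste0("s", 1:8)))
  nm <- rep(50, 5); nsd <- rep(5, 5)
  expect_equal(add_unknown_noise(E, nm, nsd, count_range = c(0, 0), seed = 1),
               E, ignore_attr = TRUE)
  noisy <- add_unknown_noise(E, nm, nsd, count_range = c(10, 100),
                             per_cell_scale = 1 / 500, seed = 2)
  counts <- attr(noisy, "noise_counts")
  expect_true(all(counts >= 10 & counts <= 100))
  expect_true(all(noisy >= E))   # non-negative noise only adds
  # deterministic under the seed
  noisy2 <- add_unknown_noise(E, nm, nsd, count_range = c(10, 100),
                              per_cell_scale = 1 / 500, seed = 2)
  expect_identical(noisy, noisy2)
})

test_that("zero-median filter drops genes silent in both groups", {
  E <- rbind(
    g1 = c(0, 0, 0, 0, 0, 0),     # silent everywhere -> dropped
    g2 = c(0, 0, 1, 0, 0, 0),     # case median 0, control median 0 -> dropped
    g3 = c(0, 0, 0, 3, 3, 3),     # control median 3 -> kept
    g4 = c(5, 5, 5, 5, 5, 5)      # expressed -> kept
  )
  groups <- rep(c("case", "control"), each = 3)
  keep <- filter_zero_median_genes(E, groups)
  expect_identical(unname(keep), c(FALSE, FALSE, TRUE, TRUE))
  expect_error(filter_zero_median_genes(E, rep("case", 6)), "both groups")
})

test_that("simulate_dataset is seed-deterministic and internally consistent", {
  pm <- bench_prop_model()
  pf <- bench_prof_model(n_genes = 120)
  cfg <- sim_config(n_case = 12, n_control = 12, csdeg_fraction = 0.1,
                    seed = 77)
  ds1 <- simulate_dataset(cfg, pm, pf)
  ds2 <- simulate_dataset(cfg, pm, pf)
  expect_identical(ds1$E, ds2$E)
  expect_identical(ds1$S, ds2$S)
  expect_identical(ds1$truth, ds2$truth)

  # mixture identity E = sum_t C_t * S_t (no noise cells added)
  expect_equal(max(abs(ds1$E - compose_bulk(ds1$S, ds1$C))), 0,
               tolerance = 1e-9)
  expect_true(all(ds1$E >= 0) && all(ds1$S >= 0))
  expect_equal(max(abs(colSums(ds1$C) - 1)), 0, tolerance = 1e-9)

  # no injection -> empty truth mask
  ds0 <- simulate_dataset(sim_config(n_case = 6, n_control = 6,
                                     csdeg_fraction = 0, seed = 1), pm, pf)
  expect_false(any(ds0$truth))

  # default group sizes: two groups of 100
  cfg_def <- sim_config(seed = 1)
  expect_identical(cfg_def$n_case, 100L)
  expect_identical(cfg_def$n_control, 100L)
})

test_that("all-zero-sd simulation is an exact deterministic mixture", {
  pf <- flat_prof_model(20, bench_cell_types, mean_value = 100, cv = 0)
  pm <- bench_prop_model()
  ds <- simulate_dataset(sim_config(n_case = 5, n_control = 5,
                                    csdeg_fraction = 0, seed = 3), pm, pf)
  manual <- 100 * colSums(ds$C)  # every gene: 100 * sum_t C_tj
  for (g in seq_len(nrow(ds$E))) {
    expect_equal(unname(ds$E[g, ]), unname(manual), tolerance = 1e-12)
  }
})
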