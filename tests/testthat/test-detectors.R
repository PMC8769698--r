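# exhaustive permutation oracle for small balanced designs: enumerate every
# way to assign n_case of the samples to "case" and compute the absolute
# group coefficient difference for each split
exhaustive_perm_p <- function(E, C, n_case, method = "ols") {
  n <- ncol(E)
  splits <- utils::combn(n, n_case)
  diffs <- apply(splits, 2, function(idx) {
    ctrl <- setdiff(seq_len(n), idx)
    abs(csdebench:::fit_coefficients(E[, idx, drop = FALSE],
                                     C[, idx, drop = FALSE], method) -
          csdebench:::fit_coefficients(E[, ctrl, drop = FALSE],
                                       C[, ctrl, drop = FALSE], method))
  })
  obs <- diffs[, 1]  # first split is the observed labeling 1..n_case
  rowMeans(diffs > obs)
}

test_that("permutation p-values are m/n with exact zeros possible", {
  # one cell type with C = 1: the group coefficient is the group mean, so a
  # noiseless 600-vs-100 gene attenuates under every mixed relabeling and
  # ties exactly under the label swap -> m = 0
  withr::with_seed(1, {
    E <- matrix(rnorm(5 * 12, 100, 2), 5, 12,
                dimnames = list(paste0("g", 1:5), paste0("s", 1:12)))
    E[1, ] <- c(rep(600, 6), rep(100, 6))
  })
  C <- matrix(1, 1, 12, dimnames = list("all", paste0("s", 1:12)))
  gr <- rep(c("case", "control"), each = 6)
  tab <- permutation_detector(E, C, gr, "ols", n_perm = 100, seed = 2)
  g1 <- tab[tab$gene == "g1", ]
  expect_equal(g1$p, 0)                        # m = 0 -> p exactly 0
  expect_equal(g1$effect, 500)
  expect_true(all(tab$p >= 0 & tab$p <= 1))
  expect_true(all(tab$fdr >= tab$p))
  expect_identical(attr(tab, "n_perm"), 100L)
  # optional (m+1)/(n+1) correction keeps p away from 0
  tab1 <- permutation_detector(E, C, gr, "ols", n_perm = 100, seed = 2,
                               add_one = TRUE)
  expect_equal(min(tab1$p), 1 / 101)
  # p-values in multiples of 1/n (uncorrected)
  expect_true(all(abs(tab$p * 100 - round(tab$p * 100)) < 1e-12))
})

test_that("sampled permutation p matches exhaustive enumeration on 3v3", {
  withr::with_seed(3, {
    C <- matrix(runif(2 * 6, 0.2, 0.8), 2, 6,
                dimnames = list(c("t1", "t2"), paste0("s", 1:6)))
    C <- sweep(C, 2, colSums(C), "/")
    E <- matrix(rnorm(4 * 6, 50, 10), 4, 6,
                dimnames = list(paste0("g", 1:4), paste0("s", 1:6)))
  })
  gr <- rep(c("case", "control"), each = 3)
  p_exact <- exhaustive_perm_p(E, C, 3)
  tab <- permutation_detector(E, C, gr, "ols", n_perm = 10000, seed = 4)
  p_sampled <- matrix(tab$p, nrow = 4)
  expect_equal(as.vector(p_sampled), as.vector(p_exact), tolerance = 0.02)
})

test_that("with one cell type the recipe is a two-sample permutation test", {
  # C identically 1: the OLS coefficient is the group mean, so the recipe
  # must agree with a plain permutation test of mean differences
  withr::with_seed(5, {
    E <- matrix(rnorm(3 * 8, 20, 5), 3, 8,
                dimnames = list(paste0("g", 1:3), paste0("s", 1:8)))
  })
  C <- matrix(1, 1, 8, dimnames = list("all", paste0("s", 1:8)))
  gr <- rep(c("case", "control"), each = 4)
  splits <- utils::combn(8, 4)
  p_direct <- apply(E, 1, function(y) {
    d <- apply(splits, 2, function(idx) {
      abs(mean(y[idx]) - mean(y[setdiff(1:8, idx)]))
    })
    mean(d > d[1])
  })
  tab <- permutation_detector(E, C, gr, "ols", n_perm = 20000, seed = 6)
  expect_equal(tab$p, unname(p_direct), tolerance = 0.02)
})

test_that("permutation p-values are invariant to rescaling the bulk", {
  withr::with_seed(7, {
    C <- matrix(runif(2 * 10, 0.2, 0.8), 2, 10)
    C <- sweep(C, 2, colSums(C), "/")
    rownames(C) <- c("t1", "t2")
    E <- matrix(rnorm(4 * 10, 100, 20), 4, 10)
  })
  gr <- rep(c("case", "control"), each = 5)
  t1 <- permutation_detector(E, C, gr, "ols", n_perm = 200, seed = 8)
  t2 <- permutation_detector(E * 37.5, C, gr, "ols", n_perm = 200, seed = 8)
  expect_equal(t1$p, t2$p)
})

test_that("welch detector computes the two-sample t on deconvolved groups", {
  withr::with_seed(9, {
    C <- matrix(runif(2 * 30, 0.2, 0.8), 2, 30,
                dimnames = list(c("t1", "t2"), paste0("s", 1:30)))
    C <- sweep(C, 2, colSums(C), "/")
    E <- matrix(rnorm(6 * 30, 200, 30), 6, 30,
                dimnames = list(paste0("g", 1:6), paste0("s", 1:30)))
  })
  gr <- rep(c("case", "control"), each = 15)
  tab <- welch_detector(E, C, gr)
  fits <- groupwise_deconv(E, C, gr, method = "ols")
  d <- fits$case$S_hat - fits$control$S_hat
  v1 <- fits$case$se^2; v2 <- fits$control$se^2
  t_manual <- d / sqrt(v1 + v2)
  df_manual <- (v1 + v2)^2 /
    (v1^2 / fits$case$dof + v2^2 / fits$control$dof)
  p_manual <- 2 * stats::pt(-abs(t_manual), df_manual)
  expect_equal(tab$statistic, as.vector(t_manual), tolerance = 1e-12)
  expect_equal(tab$p, as.vector(p_manual), tolerance = 1e-12)
  # equal-variance limit of the Welch dof: se1 = se2, equal dofs -> 2 * dof
  v <- 1.7
  df_lim <- (v + v)^2 / (v^2 / 13 + v^2 / 13)
  expect_equal(df_lim, 26)
  # diff 2 with unit standard errors gives t = sqrt(2)
  expect_equal(2 / sqrt(1 + 1), sqrt(2))

  # identical groups: t = 0, p = 1 (zero-se edge rule)
  E2 <- cbind(E[, 1:15], E[, 1:15])
  C2 <- cbind(C[, 1:15], C[, 1:15])
  tab2 <- welch_detector(E2, C2, gr)
  expect_equal(tab2$effect, rep(0, nrow(tab2)), tolerance = 1e-9)
})

test_that("interaction detector recovers injected shifts exactly at sd 0", {
  # duplicated identical blocks: every interaction coefficient is 0
  withr::with_seed(10, {
    C0 <- matrix(runif(2 * 10, 0.2, 0.8), 2, 10,
                 dimnames = list(c("t1", "t2"), NULL))
    C0 <- sweep(C0, 2, colSums(C0), "/")
    E0 <- matrix(rnorm(4 * 10, 100, 15), 4, 10,
                 dimnames = list(paste0("g", 1:4), NULL))
  })
  gr <- rep(c("case", "control"), each = 10)
  tab0 <- interaction_detector(cbind(E0, E0), cbind(C0, C0), gr)
  expect_equal(tab0$effect, rep(0, nrow(tab0)), tolerance = 1e-10)

  # noiseless single (gene, cell type) shift Delta is recovered exactly
  delta <- 42
  pf <- flat_prof_model(5, c("t1", "t2"), mean_value = 100, cv = 0)
  case_mean <- pf$mean; case_mean["g0003", "t2"] <- 100 + delta
  pf2 <- profile_model(pf$genes, pf$mean, pf$sd, case_mean)
  pm <- proportion_model(c("t1", "t2"), c(0.5, 0.5), c(0.2, 0.2))
  gr2 <- rep(c("case", "control"), each = 8)
  C2 <- generate_proportions(pm, 16, seed = 11)
  S2 <- generate_profile_tensor(pf2, gr2, seed = 12)
  E2 <- compose_bulk(S2, C2)
  tab <- interaction_detector(E2, C2, gr2)
  hit <- tab[tab$gene == "g0003" & tab$cell_type == "t2", ]
  expect_equal(hit$effect, delta, tolerance = 1e-6)
  others <- tab[!(tab$gene == "g0003" & tab$cell_type == "t2"), ]
  expect_equal(others$effect, rep(0, nrow(others)), tolerance = 1e-6)

  # relabeling case/control flips the sign of the effect only
  gr_flip <- ifelse(gr2 == "case", "control", "case")
  tab_flip <- interaction_detector(E2, C2, gr_flip)
  expect_equal(tab_flip$effect, -tab$effect, tolerance = 1e-9)
})

test_that("bh_adjust is the BH step-up with its standard properties", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.04, 0.05)),
               c(0.04, 0.04, 0.05, 0.05))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(0.1, -0.1)), "\\[0, 1\\]")
  withr::with_seed(13, {
    for (rep in 1:5) {
      p <- runif(50)
      q <- bh_adjust(p)
      expect_true(all(q >= p))
      expect_true(all(q >= 0 & q <= 1))
      # thresholding at a larger q returns a superset
      expect_true(all(which(q <= 0.05) %in% which(q <= 0.2)))
    }
  })
})

test_that("rank_genes orders by p, then |effect|, then gene id", {
  tab <- tibble::tibble(
    gene = c("gene1", "gene2", "gene3"),
    cell_type = "t1",
    effect = c(1, 5, -9),
    statistic = 0, p = c(0.2, 0.1, 0.1), fdr = 0.2, method = "x"
  )
  expect_identical(rank_genes(tab, "t1", 2), c("gene3", "gene2"))
  expect_identical(rank_genes(tab, "t1", 0), character(0))
  expect_setequal(rank_genes(tab, "t1", 3), tab$gene)
  expect_warning(out <- rank_genes(tab, "t1", 10), "truncating")
  expect_identical(length(out), 3L)
  expect_error(rank_genes(tab, "t9", 1), "t9")
})

test_that("detectors are calibrated on a small null simulation", {
  pm <- bench_prop_model()
  pf <- bench_prof_model(n_genes = 400, seed = 5)
  ds <- simulate_dataset(sim_config(n_case = 25, n_control = 25,
                                    csdeg_fraction = 0, seed = 19), pm, pf)
  for (det in c("welch", "interaction")) {
    tab <- run_detector(ds$E, ds$C, ds$groups, det)
    frac <- mean(tab$p <= 0.05)
    expect_gt(frac, 0.02)
    expect_lt(frac, 0.09)
  }
})

test_that("run_detector dispatches by name and records provenance", {
  pm <- bench_prop_model()
  pf <- bench_prof_model(n_genes = 40, seed = 6)
  ds <- simulate_dataset(sim_config(n_case = 8, n_control = 8, seed = 2),
                         pm, pf)
  tab <- run_detector(ds$E, ds$C, ds$groups, "perm-nnls", n_perm = 20,
                      seed = 3)
  expect_identical(attr(tab, "method"), "perm-nnls")
  expect_identical(unique(tab$method), "perm-nnls")
  expect_identical(nrow(tab), nrow(ds$E) * 4L)
  expect_error(run_detector(ds$E, ds$C, ds$groups, "no-such-detector"))
})
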