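test_that("Friedman test matches the rank-sum formula on clean grids", {
  # no rank variation at all
  flat <- matrix(5, 4, 4, dimnames = list(NULL, c("S", "A", "B", "C")))
  r <- friedman_phases(flat)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)

  # perfect monotone ladder, n = 9, k = 4: compare with the independent
  # rank-sum oracle
  ladder <- t(replicate(9, c(1, 2, 3, 4))) + rnorm(9, 0, 1e-6)
  colnames(ladder) <- c("S", "A", "B", "C")
  r2 <- friedman_phases(ladder)
  expect_equal(r2$statistic, oracle_friedman_stat(ladder), tolerance = 1e-8)
  expect_equal(r2$n_used, 9)
  expect_lt(r2$p_value, 0.001)

  # tie-free 3x3 hand grid
  g <- matrix(c(3, 1, 2,
                2, 3, 1,
                3, 2, 1), 3, byrow = TRUE,
              dimnames = list(NULL, c("S", "A", "B")))
  r3 <- friedman_phases(g)
  expect_equal(r3$statistic, oracle_friedman_stat(g), tolerance = 1e-10)

  set.seed(13)
  for (i in 1:10) {
    gg <- matrix(rnorm(5 * 4), 5, 4)  # continuous, tie-free a.s.
    expect_equal(friedman_phases(gg)$statistic, oracle_friedman_stat(gg),
                 tolerance = 1e-8)
  }
})

test_that("Friedman uses complete cases and is rank-invariant", {
  set.seed(2)
  g <- matrix(rnorm(36), 9, 4, dimnames = list(NULL, c("S", "A", "B", "C")))
  g[9, 4] <- NA
  r <- friedman_phases(g)
  expect_equal(r$n_used, 8)
  expect_equal(r$statistic, friedman_phases(g[1:8, ])$statistic)

  # strictly monotone transform of one subject's row leaves ranks unchanged
  g2 <- g[1:8, ]
  g3 <- g2
  g3[3, ] <- exp(g3[3, ])
  expect_equal(friedman_phases(g2)$statistic, friedman_phases(g3)$statistic)

  expect_error(friedman_phases(matrix(rnorm(4), 1, 4)), "2 complete")
  expect_error(friedman_phases(matrix(rnorm(4), 2, 2)), "3 conditions")
})

test_that("Wilcoxon post-hoc gives exact small-sample p-values", {
  # n = 8 all-positive differences: two-sided p = 2 / 2^8
  g <- cbind(A = 1:8 + (1:8) / 10, B = 1:8)  # distinct positive differences
  res <- wilcoxon_posthoc(g, pairs = list(c("A", "B")))
  expect_equal(res$p_value, 2 / 256)
  expect_match(res$method, "exact")

  # identical vectors: degenerate, flagged, p = 1
  g0 <- cbind(A = 1:6, B = 1:6)
  r0 <- wilcoxon_posthoc(g0, pairs = list(c("A", "B")))
  expect_true(r0$degenerate)
  expect_equal(r0$p_value, 1)

  # arbitrary tie-free example vs exhaustive sign-pattern enumeration
  set.seed(3)
  for (i in 1:10) {
    x <- rnorm(9)
    y <- rnorm(9)
    g1 <- cbind(A = x, B = y)
    res1 <- wilcoxon_posthoc(g1, pairs = list(c("A", "B")))
    expect_equal(res1$p_value, oracle_wilcoxon_exact(x - y),
                 tolerance = 1e-10)
  }
})

test_that("exact and approximate Wilcoxon p agree at the cutover size", {
  set.seed(6)
  for (i in 1:10) {
    d <- rnorm(15, mean = 0.4)
    exact_p <- wilcoxon_posthoc(cbind(A = d, B = 0), list(c("A", "B")),
                                exact_max_n = 15)$p_value
    approx_p <- wilcoxon_posthoc(cbind(A = d, B = 0), list(c("A", "B")),
                                 exact_max_n = 0)$p_value
    expect_lt(abs(exact_p - approx_p), 0.02)
  }
})

test_that("Spearman correlation handles monotone, tied and degenerate input", {
  x <- 1:10
  expect_equal(spearman_cor(x, x^3)$rho, 1)
  expect_equal(spearman_cor(x, rev(x))$rho, -1)

  # 6-point example with one tie vs the mid-rank arithmetic oracle
  a <- c(1.2, 3.4, 3.4, 5.0, 2.2, 7.7)
  b <- c(10, 14, 13, 22, 11, 21)
  expect_equal(spearman_cor(a, b)$rho, oracle_spearman_rho(a, b),
               tolerance = 1e-12)

  # symmetry and monotone-transform invariance
  set.seed(4)
  u <- rnorm(12)
  v <- rnorm(12)
  expect_equal(spearman_cor(u, v)$rho, spearman_cor(v, u)$rho)
  expect_equal(spearman_cor(u, v)$rho, spearman_cor(exp(u), v)$rho)
  expect_equal(spearman_cor(u, v)$p_value, spearman_cor(exp(u), v)$p_value)

  z <- rep(3, 8)
  expect_true(spearman_cor(z, rnorm(8))$undefined)
  expect_error(spearman_cor(1:2, 1:2), "at least 3")
})

test_that("correlation grid pools subject-phase observations", {
  set.seed(9)
  n <- 9
  obs <- expand.grid(subject = 1:n, phase = c("A", "B", "C"))
  # construct coupling: deeper suppression with lower occlusion HR
  obs$ocBSR <- c(A = 5, B = 20, C = 60)[obs$phase] + rnorm(nrow(obs), 0, 4)
  obs$ocHR <- 120 - 0.5 * obs$ocBSR + rnorm(nrow(obs), 0, 3)
  obs$pO2 <- rnorm(nrow(obs), 15, 1)          # uncoupled channel
  obs$self <- obs$ocBSR
  tab <- correlation_table(obs, qeeg_markers = c("ocBSR"),
                           physio_markers = c("ocHR", "pO2", "self"))
  expect_lt(tab$rho[tab$physio == "ocHR"], 0)
  expect_lt(tab$p_value[tab$physio == "ocHR"], 0.05)
  expect_gt(tab$p_value[tab$physio == "pO2"], 0.05)
  expect_equal(tab$rho[tab$physio == "self"], 1)
  expect_equal(tab$n, rep(27L, 3))

  # cells with too few complete pairs are marked missing
  obs$ocHR[4:nrow(obs)] <- NA
  tab2 <- correlation_table(obs, "ocBSR", "ocHR", min_n = 5)
  expect_true(is.na(tab2$rho))
})

test_that("summary-level generator is reproducible and calibratable", {
  means <- c(S = 6.3, A = 7.1, B = 6.0, C = 4.7)
  g1 <- simulate_summary_grid(9, means, subject_sd = 2, noise_sd = 0.8,
                              seed = 5L)
  g2 <- simulate_summary_grid(9, means, subject_sd = 2, noise_sd = 0.8,
                              seed = 5L)
  expect_identical(g1, g2)
  expect_equal(colnames(g1), names(means))

  big <- simulate_summary_grid(4000, means, subject_sd = 2, noise_sd = 0.8,
                               seed = 6L)
  cal <- calibrate_summary_generator(big)
  expect_equal(unname(cal$phase_means), unname(means), tolerance = 0.15)
  expect_equal(cal$subject_sd, 2, tolerance = 0.15)
  expect_equal(cal$noise_sd, 0.8, tolerance = 0.1)
})
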