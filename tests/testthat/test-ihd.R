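design_2x4 <- sample_design(c(paste0("t", 1:4), paste0("c", 1:4)),
                            rep(c("trt", "ctl"), each = 4), "ctl")

expr_mat <- function(trt_rows, ctl_rows) {
  m <- cbind(trt_rows, ctl_rows)
  rownames(m) <- sprintf("g%02d", seq_len(nrow(m)))
  colnames(m) <- c(paste0("t", 1:4), paste0("c", 1:4))
  m
}

test_that("per-gene t-test handles degenerate and symmetric inputs", {
  m <- expr_mat(rbind(rep(2, 4), 1:4), rbind(rep(2, 4), 1:4))
  res <- ttest_per_gene(m, design_2x4, "trt", "ctl")
  expect_identical(res$t_stat[1], 0)   # identical constant values
  expect_identical(res$p_t[1], 1)
  expect_identical(res$t_stat[2], 0)   # same values in both groups
  expect_identical(res$p_t[2], 1)
})

test_that("per-gene t-test equals the pooled-variance closed form and t.test", {
  x <- c(2.1, 2.3, 1.9, 2.2)
  y <- c(1.1, 1.0, 1.3, 0.9)
  m <- expr_mat(matrix(x, 1), matrix(y, 1))
  res <- ttest_per_gene(m, design_2x4, "trt", "ctl")
  # textbook pooled-SD formula
  sp <- sqrt((3 * var(x) + 3 * var(y)) / 6)
  t_manual <- (mean(x) - mean(y)) / (sp * sqrt(1 / 4 + 1 / 4))
  expect_equal(res$t_stat[1], t_manual, tolerance = 1e-12)
  expect_equal(res$p_t[1], 2 * pt(abs(t_manual), 6, lower.tail = FALSE),
               tolerance = 1e-12)

  # property: matches stats::t.test row-wise, Student and Welch
  set.seed(4)
  mm <- expr_mat(matrix(rnorm(40, 1), 10), matrix(rnorm(40), 10))
  for (welch in c(FALSE, TRUE)) {
    res <- ttest_per_gene(mm, design_2x4, "trt", "ctl", welch = welch)
    for (g in seq_len(nrow(mm))) {
      tt <- t.test(mm[g, 1:4], mm[g, 5:8], var.equal = !welch)
      expect_equal(res$t_stat[g], unname(tt$statistic), tolerance = 1e-10)
      expect_equal(res$p_t[g], tt$p.value, tolerance = 1e-10)
    }
  }
})

test_that("t-test rejects unknown groups and tiny groups", {
  m <- expr_mat(matrix(rnorm(4), 1), matrix(rnorm(4), 1))
  expect_error(ttest_per_gene(m, design_2x4, "nope", "ctl"), "absent")
})

test_that("exact median null enumerates all 70 splits of a 4-vs-4 design", {
  set.seed(10)
  m <- expr_mat(matrix(rnorm(12), 3), matrix(rnorm(12), 3))
  null <- median_null(m, design_2x4, "trt", "ctl", comparison_config())
  expect_identical(attr(null, "n_splits"), 70L)       # C(8,4)
  expect_identical(attr(null, "mode"), "exact")
  expect_length(null, 70L * 3L)                       # pooled across genes

  # matches the independent exhaustive enumeration oracle (as multisets)
  oracle <- median_null_oracle(m[, 1:4, drop = FALSE], m[, 5:8, drop = FALSE])
  expect_equal(sort(null), sort(as.vector(oracle)), tolerance = 1e-12)

  # a constant gene contributes only zeros
  m2 <- expr_mat(matrix(5, 1, 4), matrix(5, 1, 4))
  null2 <- median_null(m2, design_2x4, "trt", "ctl", comparison_config())
  expect_true(all(null2 == 0))
})

test_that("median-difference p-values match exhaustive enumeration", {
  set.seed(17)
  m <- expr_mat(matrix(rnorm(12, 1), 3), matrix(rnorm(12), 3))
  cfg <- comparison_config()
  null <- median_null(m, design_2x4, "trt", "ctl", cfg)
  res <- median_diff_p(m, design_2x4, "trt", "ctl", null)
  oracle_null <- sort(as.vector(median_null_oracle(m[, 1:4], m[, 5:8])))
  for (g in 1:3) {
    obs <- median(m[g, 1:4]) - median(m[g, 5:8])
    expect_equal(res$median_diff[g], obs, tolerance = 1e-12)
    p_oracle <- (1 + sum(oracle_null >= abs(obs))) / (1 + length(oracle_null))
    expect_equal(res$p_m[g], p_oracle, tolerance = 1e-12)
  }
})

test_that("median-difference p boundaries behave as specified", {
  # observed 0 -> every null value >= 0 -> p = 1
  m <- expr_mat(rbind(c(1, 2, 3, 4), c(9, 9, 9, 9)),
                rbind(c(4, 3, 2, 1), c(1, 1, 1, 1)))
  null <- median_null(m, design_2x4, "trt", "ctl", comparison_config())
  res <- median_diff_p(m, design_2x4, "trt", "ctl", null)
  expect_identical(res$p_m[1], 1)
  # per-gene null, observed exceeding every permuted value -> 1/(1+N)
  cfgpg <- comparison_config(pooled_null = FALSE)
  nullpg <- median_null(m, design_2x4, "trt", "ctl", cfgpg)
  respg <- median_diff_p(m, design_2x4, "trt", "ctl", nullpg)
  # gene 2: |obs| = 8 is the max attainable, attained by 2 of 70 splits
  expect_equal(respg$p_m[2], (1 + sum(nullpg[2, ] >= 8)) / 71, tolerance = 1e-12)
})

test_that("sampled and exact median nulls give close p-values", {
  set.seed(30)
  G <- 50
  m <- expr_mat(matrix(rnorm(4 * G, 0.3), G), matrix(rnorm(4 * G), G))
  p_exact <- median_diff_p(m, design_2x4, "trt", "ctl",
                           median_null(m, design_2x4, "trt", "ctl",
                                       comparison_config(mode = "exact")))$p_m
  cfg_s <- comparison_config(mode = "sampled", n_perm = 10000, seed = 99)
  p_samp <- median_diff_p(m, design_2x4, "trt", "ctl",
                          median_null(m, design_2x4, "trt", "ctl", cfg_s))$p_m
  expect_lt(mean(abs(p_exact - p_samp)), 0.01)
  # sampled mode is seed-reproducible
  p_samp2 <- median_diff_p(m, design_2x4, "trt", "ctl",
                           median_null(m, design_2x4, "trt", "ctl", cfg_s))$p_m
  expect_identical(p_samp, p_samp2)
})

test_that("Stouffer combination matches normal-quantile arithmetic", {
  r <- stouffer_combine(1, 1, 1, 1)
  expect_identical(r$z_combined, 0)
  expect_identical(r$p_combined, 1)

  r <- stouffer_combine(0.05, 0.05, 1, 1)
  expect_equal(r$z_combined, 2 * qnorm(0.975) / sqrt(2), tolerance = 1e-12)
  expect_equal(r$p_combined, 2 * pnorm(-2 * qnorm(0.975) / sqrt(2)),
               tolerance = 1e-12)
  # agreement with the values at their printed precision
  expect_equal(r$z_combined, 2.771808, tolerance = 1e-6)
  expect_equal(r$p_combined, 0.005574, tolerance = 1e-3)

  # opposite effect directions cancel
  r <- stouffer_combine(0.05, 0.05, 1, -1)
  expect_identical(r$z_combined, 0)
  expect_identical(r$p_combined, 1)
})

test_that("Stouffer combination is symmetric and monotone", {
  set.seed(6)
  p1 <- runif(50); p2 <- runif(50)
  a <- stouffer_combine(p1, p2, 1, 1)
  b <- stouffer_combine(p2, p1, 1, 1)
  expect_equal(a$p_combined, b$p_combined, tolerance = 1e-12)
  # decreasing one p (same signs) never increases the combined p
  a2 <- stouffer_combine(p1 / 2, p2, 1, 1)
  expect_true(all(a2$p_combined <= a$p_combined + 1e-15))
  expect_error(stouffer_combine(0, 0.5, 1, 1), "0, 1")
  expect_error(stouffer_combine(0.5, 1.2, 1, 1), "0, 1")
})

test_that("BH adjustment equals the quadratic step-up oracle exactly", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_identical(bh_adjust(0.37), 0.37)
  set.seed(12)
  for (i in 1:100) {
    m <- sample(1:200, 1)
    p <- runif(m)^sample(1:3, 1)
    p <- pmin(pmax(p, 1e-12), 1)
    q <- bh_adjust(p)
    expect_identical(q, bh_oracle(p))
    expect_true(all(q[order(p)] == cummax(q[order(p)])))  # order-preserving
  }
  expect_error(bh_adjust(c(0.5, NaN)), "finite")
})

test_that("DEG gating uses inclusive thresholds and signed direction", {
  tab <- data.frame(q_fdr = c(0.05, 0.051, 0.01),
                    log2fc = c(0.58, 3, -0.6))
  out <- call_degs(tab, comparison_config())
  expect_identical(out$is_deg, c(TRUE, FALSE, TRUE))
  expect_identical(out$direction, c("up", "none", "down"))
})

test_that("full comparisons are deterministic and tally correctly", {
  sim <- small_sim(n_genes = 120, seed = 31, de_fraction = 0.15)
  cfg <- comparison_config(seed = 7)
  t1 <- run_comparison(sim$counts, sim$design, "T1", "control", cfg)
  t2 <- run_comparison(sim$counts, sim$design, "T1", "control", cfg)
  expect_identical(t1, t2)
  s <- attr(t1, "summary")
  expect_identical(s$n_deg, sum(t1$is_deg))
  expect_identical(s$n_up + s$n_down, s$n_deg)
  expect_match(deg_summary(t1), "up-regulated and .* down-regulated")
  # q never below its combined p after step-up
  expect_true(all(t1$q_fdr >= t1$p_combined - 1e-15))
})

test_that("component p-values are approximately uniform under a pure null", {
  sim <- simulate_null(sim_config(n_genes = 5000,
                                  groups = c(control = 4, T1 = 4), seed = 11))
  f <- filter_low_counts(sim$counts)
  tab <- run_comparison(sim$counts, sim$design, "T1", "control",
                        comparison_config(seed = 2),
                        norm = normalize_counts(f))
  ks <- function(p) suppressWarnings(ks.test(p, "punif")$statistic)
  expect_lt(ks(tab$p_t), 0.05)
  expect_lt(ks(tab$p_m), 0.05)
})
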