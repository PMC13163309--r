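test_that("RNA QC gate applies the acceptance thresholds as written", {
  expect_true(qc_gate(9.3, 2.4, 85)$pass)
  # boundary semantics: RINe inclusive, the other two strict
  expect_true(qc_gate(7.0, 2.01, 70.1)$pass)
  expect_false(qc_gate(7.0, 2.0, 85)$pass)
  expect_false(qc_gate(7.0, 2.4, 70)$pass)
  bad <- qc_gate(6.9, 2.5, 90)
  expect_false(bad$pass)
  expect_identical(bad$failed, "rine")
  expect_error(qc_gate(NA_real_, 2, 80), "rine")
  expect_error(qc_gate(8, 2.4, 150), "dv200")
})

test_that("FPKM follows the count * 1e9 / (library * length) formula", {
  expect_equal(compute_fpkm(100, 1000, 1e6), 100)
  expect_equal(compute_fpkm(0, 1000, 1e6), 0)
  expect_equal(compute_fpkm(50, 500, 2e6), 50)
  m <- matrix(c(10, 20, 30, 60), 2)
  f <- compute_fpkm(m, c(1000, 2000), c(1e6, 1e6))
  expect_equal(f[1, 1], 10 * 1e9 / (1e6 * 1000))
  expect_error(compute_fpkm(5, 1000, 0), "library")
  expect_error(compute_fpkm(5, 0, 1e6), "length")
})

test_that("log-CPM is the damped log2 counts-per-million", {
  expect_equal(log_cpm(0, 999999, prior_count = 0.5), -1)
  # (count + prior) / (lib + 2 prior) = 1e-6 gives exactly zero
  expect_equal(log_cpm(0.5, 999999, prior_count = 0.5), 0)
  x <- log_cpm(c(1, 5, 50), library_sizes = 1e6)
  expect_true(all(diff(x) > 0))  # monotone in the count
  expect_error(log_cpm(5, 1e6, prior_count = 0), "prior_count")
  expect_error(log_cpm(-1, 1e6), "non-negative")
})

test_that("moderated t with zero prior df is the classical pooled t-test", {
  m <- rbind(g1 = c(1, 2, 3, 4, 5, 6))
  grp <- rep(c("control", "treated"), each = 3)
  res <- moderated_ttest(m, grp, prior_df = 0)
  expect_equal(res$log2fc, 3)
  expect_equal(res$df, 4)
  expect_equal(res$t, 3.674235, tolerance = 1e-6)
  expect_equal(res$p_value, 0.02131164, tolerance = 1e-6)

  # oracle equivalence on random matrices, tolerance 1e-10
  set.seed(101)
  X <- matrix(rnorm(50 * 8), 50)
  res <- moderated_ttest(X, rep(c("a", "b"), each = 4), prior_df = 0)
  for (i in c(1, 7, 23, 50)) {
    tt <- t.test(X[i, 5:8], X[i, 1:4], var.equal = TRUE)
    expect_equal(res$t[i], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(res$p_value[i], tt$p.value, tolerance = 1e-10)
  }
})

test_that("moderated t handles priors and degenerate genes", {
  m <- rbind(flat = c(2, 2, 2, 2, 2, 2))
  grp <- rep(c("a", "b"), each = 3)
  res <- moderated_ttest(m, grp, prior_df = 0)
  expect_true(res$degenerate)
  expect_equal(res$p_value, 1)
  expect_equal(res$t, 0)

  # infinite prior df fixes the variance at prior_var (z-like limit)
  set.seed(11)
  X <- matrix(rnorm(20 * 6), 20)
  res_inf <- moderated_ttest(X, grp, prior_df = Inf, prior_var = 1)
  lfc <- rowMeans(X[, 4:6]) - rowMeans(X[, 1:3])
  z <- lfc / sqrt(1 * (1 / 3 + 1 / 3))
  expect_equal(res_inf$t, z, tolerance = 1e-12)
  expect_equal(res_inf$p_value, 2 * pnorm(-abs(z)), tolerance = 1e-12)

  expect_error(moderated_ttest(X, rep("a", 6)), "two groups")
  expect_error(moderated_ttest(X[, 1:3], c("a", "b", "b")), "at least 2")
})

test_that("BH adjustment matches hand-enumerated step-up examples", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(c(0.005, 0.5)), c(0.01, 0.5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(0.5, NA)))
})

test_that("BH adjustment is permutation-equivariant and within [0,1]", {
  set.seed(21)
  for (i in 1:20) {
    p <- runif(sample(2:30, 1))
    adj <- bh_adjust(p)
    expect_true(all(adj >= 0 & adj <= 1))
    perm <- sample(length(p))
    expect_equal(bh_adjust(p[perm]), adj[perm], tolerance = 1e-15)
    expect_equal(adj, bh_oracle(p), tolerance = 1e-12)
  }
})

test_that("DEG filter applies inclusive fold-change and strict FDR bounds", {
  rec <- data.frame(
    gene_id = c("a", "b", "c", "d", "e"),
    log2fc = c(0.5, 0.49, -0.8, 1.2, -2),
    fdr = c(0.049, 0.001, 0.01, 0.05, 0.2)
  )
  sets <- filter_degs(rec)
  expect_identical(sets$up, "a")       # |lfc| >= 0.5 inclusive, fdr < 0.05
  expect_identical(sets$down, "c")     # d fails strict fdr, e fails fdr
  expect_length(intersect(sets$up, sets$down), 0)
})
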