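toy_xy <- function(seed = 1, p = 4, n = 8) {
  set.seed(seed)
  X <- matrix(rnorm(p * n, sd = 1), nrow = p,
              dimnames = list(sprintf("f%02d", 1:p), NULL))
  cls <- factor(rep(c("control", "treated"), each = n / 2))
  X[1, cls == "treated"] <- X[1, cls == "treated"] + 2
  X[2, cls == "treated"] <- X[2, cls == "treated"] - 1
  list(X = X, cls = cls)
}

test_that("PLS-DA extraction is deterministic with unit-norm weights", {
  d <- toy_xy()
  m1 <- fit_plsda(d$X, d$cls, n_components = 2)
  m2 <- fit_plsda(d$X, d$cls, n_components = 2)
  expect_identical(m1, m2)
  expect_equal(colSums(m1$weights^2), c(1, 1), tolerance = 1e-12)
  expect_true(all(m1$ssy >= 0))
  # single feature: weight vector is forced to [1]
  single <- fit_plsda(d$X[1, , drop = FALSE], d$cls, n_components = 1)
  expect_equal(abs(as.vector(single$weights)), 1, tolerance = 1e-12)
  expect_error(fit_plsda(d$X, d$cls, n_components = 50), "rank")
  expect_warning(
    fit_plsda(rbind(d$X, const = rep(3, 8)), d$cls, n_components = 1),
    "constant")
})

test_that("first PLS weight follows the X'y covariance direction", {
  # noiseless separable 2-feature toy: weight must align with cov(X, y)
  cls <- factor(rep(c("a", "b"), each = 4))
  X <- rbind(f1 = c(0, 0, 0, 0, 2, 2, 2, 2),
             f2 = c(1, 1, 1, 1, 1, 1, 1, 1) + rep(c(0, 1), each = 4) * 0.5)
  m <- fit_plsda(X, cls, n_components = 1, scale = "none")
  y <- rep(c(-1, 1), each = 4)
  w_closed <- crossprod(scale(t(X), TRUE, FALSE), y)
  w_closed <- w_closed / sqrt(sum(w_closed^2))
  expect_equal(as.vector(m$weights), as.vector(w_closed), tolerance = 1e-10)
})

test_that("VIP satisfies its algebraic identity and matches the oracle", {
  d <- toy_xy()
  m <- fit_plsda(d$X, d$cls, n_components = 2)
  v <- vip_scores(m)
  expect_equal(mean(v^2), 1, tolerance = 1e-10)
  # p = 1 forces VIP = 1
  v1 <- vip_scores(fit_plsda(d$X[1, , drop = FALSE], d$cls, 1))
  expect_equal(unname(v1), 1, tolerance = 1e-12)
  # independent closed-form-per-component oracle, several seeds
  for (s in c(2, 5, 9)) {
    dd <- toy_xy(seed = s, p = 6, n = 10)
    m <- fit_plsda(dd$X, dd$cls, n_components = 2)
    expect_equal(unname(vip_scores(m)),
                 pls_vip_oracle(dd$X, dd$cls, 2), tolerance = 1e-8)
  }
})

test_that("fold change is the raw-scale treated/control mean ratio", {
  X <- rbind(up = c(2, 2, 2, 4, 4, 4), flat = c(3, 3, 3, 3, 3, 3))
  cls <- factor(rep(c("control", "treated"), each = 3))
  fc <- fold_change(X, cls)
  expect_equal(unname(fc["up"]), 2)
  expect_equal(unname(fc["flat"]), 1)
  expect_error(fold_change(X - 2, cls), "positive")
  # planted multiplicative effect is recovered within sampling error
  mt <- simulate_metabolite_table(sim_config(seed = 12))
  fc <- fold_change(mt$intensities, mt$classes)
  disc <- mt$truth$discriminant_feature_ids
  expect_equal(median(fc[disc]), 3.0, tolerance = 0.2)
})

test_that("the univariate test is the Welch t on log2 intensities", {
  X <- rbind(a = 2^c(1, 2, 3, 4, 5, 6))
  cls <- factor(rep(c("c", "t"), each = 3))
  res <- univariate_test(X, cls)
  oracle <- t.test(c(4, 5, 6), c(1, 2, 3))  # Welch on the logged values
  expect_equal(res$p_value, oracle$p.value, tolerance = 1e-10)
  # identical groups: degenerate, p = 1
  flat <- univariate_test(rbind(z = rep(4, 6)), cls)
  expect_true(flat$degenerate)
  expect_equal(flat$p_value, 1)
  # random-data oracle equivalence
  set.seed(33)
  X <- matrix(2^rnorm(20 * 10), 20)
  res <- univariate_test(X, rep(c("c", "t"), each = 5))
  for (i in c(3, 11, 20)) {
    o <- t.test(log2(X[i, 6:10]), log2(X[i, 1:5]))
    expect_equal(res$p_value[i], o$p.value, tolerance = 1e-10)
  }
})

test_that("metabolite selection applies all four thresholds strictly", {
  f <- data.frame(vip = c(1.6, 1.5, 2.0, 2.0, 1.8),
                  p_value = c(0.01, 0.01, 0.01, 0.01, 0.06),
                  fdr = c(0.03, 0.03, 0.03, 0.03, 0.03),
                  fold_change = c(2.5, 2.5, 2.0, 2.1, 2.5))
  sel <- select_metabolites(f)
  expect_identical(sel$selected, c(TRUE, FALSE, FALSE, TRUE, FALSE))
  # two-sided option admits strong down-regulation
  g <- data.frame(vip = 2, p_value = 0.01, fdr = 0.01, fold_change = 0.3)
  expect_false(select_metabolites(g)$selected)
  expect_true(select_metabolites(g, mode = "two_sided")$selected)
  expect_error(select_metabolites(f[, -1]), "missing statistic")
})

test_that("tightening any selection threshold never adds features", {
  set.seed(44)
  f <- data.frame(vip = runif(200, 0, 3), p_value = runif(200),
                  fdr = runif(200), fold_change = runif(200, 0, 5))
  base <- select_metabolites(f)$selected
  expect_true(all(select_metabolites(f, vip_min = 2)$selected <= base))
  expect_true(all(select_metabolites(f, p_max = 0.01)$selected <= base))
  expect_true(all(select_metabolites(f, fdr_max = 0.01)$selected <= base))
  expect_true(all(select_metabolites(f, fc_min = 3)$selected <= base))
})

test_that("redundant features merge under the ppm and RT rules", {
  f <- data.frame(feature_id = c("a", "b"), mz = c(500.0, 500.0),
                  rt_min = c(3, 3), mean_intensity = c(10, 99))
  out <- dedup_features(f)
  expect_identical(out$feature_id, "b")  # the brighter survives
  expect_identical(out$n_merged, 2L)
  # 500.0000 vs 500.0024 is 4.8 ppm: inside the 5 ppm window
  f2 <- data.frame(feature_id = c("a", "b"), mz = c(500.0000, 500.0024),
                   rt_min = c(3.0, 3.1), mean_intensity = c(5, 1))
  expect_identical(nrow(dedup_features(f2)), 1L)
  # 50 ppm apart stays separate, as does an RT mismatch
  f3 <- data.frame(feature_id = c("a", "b"), mz = c(500, 500.025),
                   rt_min = c(3, 3), mean_intensity = c(5, 1))
  expect_identical(nrow(dedup_features(f3)), 2L)
  f4 <- data.frame(feature_id = c("a", "b"), mz = c(500, 500.001),
                   rt_min = c(3, 9), mean_intensity = c(5, 1))
  expect_identical(nrow(dedup_features(f4)), 2L)
})

test_that("planted discriminant features pass the full selection filter", {
  mt <- simulate_metabolite_table(sim_config(seed = 7))
  sel <- metab_analysis(mt$intensities, mt$features, mt$classes)
  truth <- mt$truth$discriminant_feature_ids
  hits <- sel$feature_id[sel$selected]
  expect_gte(mean(truth %in% hits), 0.7)
})
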