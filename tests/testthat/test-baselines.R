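test_that("logistic comparator reproduces the 2x2 closed form and an IRLS oracle", {
  df <- data.frame(a = rep(c(1, 1, 0, 0), c(10, 90, 20, 80)),
                   y = rep(c(1, 0, 1, 0), c(10, 90, 20, 80)),
                   z1 = 0, w1 = 0)
  s <- tnd_sample(df)
  fit <- estimate_ve_logistic(s)
  expect_equal(unname(fit$beta[1]), log((10 * 80) / (90 * 20)), tolerance = 1e-6)

  # hand-rolled iteratively reweighted least squares as an independent check
  X <- cbind(1, s$a)
  b <- c(0, 0)
  for (i in 1:50) {
    p <- plogis(drop(X %*% b))
    W <- p * (1 - p)
    b <- b + solve(t(X) %*% (W * X), t(X) %*% (s$y - p))
  }
  expect_equal(unname(fit$beta[1]), b[2], tolerance = 1e-6)
})

test_that("oracle substitution: NC with a fixed oracle bridge equals the oracle estimator", {
  s <- quick_binary_sample(seed = 17)
  cfg <- binary_dgp_config(beta0 = -0.693)
  orc <- oracle_bridge_binary(cfg)
  f1 <- estimate_ve_nc_oracle(s, cfg)
  f2 <- estimate_ve(s, bridge = orc, tau_fixed = TRUE)
  expect_identical(unname(f1$beta[1]), unname(f2$beta[1]))
  expect_identical(unname(f1$se[1]), unname(f2$se[1]))
})

test_that("IPTW with constant propensity reduces to the crude case ratio", {
  cfg <- binary_dgp_config(p_a = c(0.5, 0.5), confounding_ratio = 1, n_pop = 2e5)
  pop <- simulate_population(cfg, seed = 19)
  fit <- estimate_ve_iptw(pop)
  sel <- pop[pop$s == 1, ]
  expect_equal(unname(fit$beta[1]),
               log(sum(sel$a * sel$y) / sum((1 - sel$a) * sel$y)))
})

test_that("negative-control regressions detect confounding and stay null without it", {
  s <- quick_binary_sample(seed = 23)
  tt <- nce_bias_tests(s)
  expect_named(tt, c("outcome", "term", "estimate", "std.error", "p.value", "model"))
  expect_identical(nrow(tt), 2L)
  expect_true(all(tt$p.value < 0.05))

  cfg_null <- binary_dgp_config(beta0 = -0.693, confounding_ratio = 1,
                                z_coef = c(qlogis(0.3), 0, 0.3),
                                p_w = c(0.3, 0.3), p_d = c(0.08, 0.08))
  p_null <- unlist(lapply(1:5, function(r) {
    s0 <- select_tnd_sample(simulate_population(cfg_null, seed = 8000 + r))
    nce_bias_tests(s0)$p.value
  }))
  # under the null the Z coefficients are noise: large p-values dominate
  expect_lte(sum(p_null < 0.05), 3)
  expect_gt(mean(p_null), 0.2)
})

test_that("Hausman comparison matches hand arithmetic and handles degeneracy", {
  same <- hausman_test(list(beta = -2, se = 0.2), list(beta = -2, se = 0.1))
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)

  ht <- hausman_test(list(beta = -2.80, se = 0.1378), list(beta = -3.18, se = 0.0867))
  expect_equal(ht$statistic, 0.38^2 / (0.1378^2 - 0.0867^2), tolerance = 1e-10)
  expect_equal(ht$statistic, 12.59, tolerance = 0.01)
  expect_lt(ht$p.value, 1e-3)

  expect_warning(bad <- hausman_test(list(beta = -2, se = 0.1),
                                     list(beta = -2.5, se = 0.3)),
                 "not positive")
  expect_true(is.na(bad$statistic))
})

test_that("bootstrap resampling returns per-draw estimates", {
  s <- quick_binary_sample(seed = 29, n_pop = 5e5)
  bs <- bootstrap_ve(s, draws = 10, seed = 30)
  expect_lte(nrow(bs), 10)
  expect_gte(nrow(bs), 8)
  expect_true(all(is.finite(bs$beta)))
})
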