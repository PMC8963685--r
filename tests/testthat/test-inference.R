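test_that("the closed-form log risk ratio reduces to the case ratio and is scale invariant", {
  df <- data.frame(a = rep(c(1, 0), c(10, 20)), y = 1,
                   z1 = rbinom(30, 1, 0.5), w1 = 0)
  s <- tnd_sample(df)
  expect_equal(estimate_log_rr(s, rep(1, 30)), log(0.5))
  q <- runif(30, 1, 3)
  expect_identical(estimate_log_rr(s, 7 * q), estimate_log_rr(s, q))

  hand <- tnd_sample(data.frame(a = c(1, 0, 0), y = 1, z1 = 0, w1 = 0))
  expect_equal(estimate_log_rr(hand, c(2.0, 1.5, 2.5)), log(2.0 / 4.0))

  no_vax <- tnd_sample(data.frame(a = c(0, 0), y = c(1, 1), z1 = 0:1, w1 = 0:1))
  expect_error(estimate_log_rr(no_vax, c(1, 1)), "no vaccinated cases")
  no_unvax <- tnd_sample(data.frame(a = c(1, 1), y = c(1, 1), z1 = 0:1, w1 = 0:1))
  expect_error(estimate_log_rr(no_unvax, c(1, 1)), "no unvaccinated cases")
})

test_that("stacked moments vanish at the fit and match analytic derivatives", {
  s <- quick_binary_sample(seed = 5150)
  fit <- suppressWarnings(estimate_ve(s))
  infl <- fit$influence
  expect_lte(max(abs(colMeans(infl$G))), 1e-8)

  # first component is exactly zero for controls
  expect_true(all(infl$G[s$y == 0, 1] == 0))

  # d/d beta of the first mean component has the analytic form
  q <- evaluate_bridge(fit$bridge, s$a, s$z1)
  beta <- unname(fit$beta[1])
  expect_equal(infl$Omega[1, 1], -mean(q * s$a * s$y * exp(-beta * s$a)),
               tolerance = 1e-6)
})

test_that("sandwich covariance is symmetric PSD and flags rank deficiency", {
  s <- quick_binary_sample(seed = 660)
  fit <- suppressWarnings(estimate_ve(s))
  Sig <- fit$cov
  expect_equal(Sig, t(Sig), tolerance = 1e-12)
  expect_true(all(diag(Sig) >= 0))
  expect_true(all(eigen(Sig, symmetric = TRUE, only.values = TRUE)$values > -1e-12))

  infl <- fit$influence
  infl$Omega[, 3] <- infl$Omega[, 2]   # duplicate a parameter direction
  expect_error(sandwich_covariance(infl), "rank-deficient")
})

test_that("VE interval transforms beta endpoints as printed", {
  ci <- wald_ci_ve((-3.08 - 2.54) / 2, (3.08 - 2.54) / (2 * qnorm(0.975)))
  expect_equal(round(100 * ci[["lower"]], 1), 92.1)
  expect_equal(round(100 * ci[["upper"]], 1), 95.4)
  expect_equal(wald_ci_ve(0, 0), c(lower = 0, upper = 0))
  # monotone: larger beta -> smaller VE, endpoints ordered
  expect_lt(1 - exp(-0.5), 1 - exp(-1.5))
  ci2 <- wald_ci_ve(-1, 0.2)
  expect_lt(ci2[["lower"]], ci2[["upper"]])
})

test_that("an intercept-only effect-modification design reproduces the scalar fit", {
  s <- quick_binary_sample(seed = 8)
  fit <- suppressWarnings(estimate_ve(s))
  fit_em <- suppressWarnings(estimate_ve(s, bridge = fit$bridge, tau_fixed = TRUE,
                                         effect_modifiers = character(0)))
  fit_sc <- suppressWarnings(estimate_ve(s, bridge = fit$bridge, tau_fixed = TRUE))
  expect_equal(unname(fit_em$beta[1]), unname(fit_sc$beta[1]), tolerance = 1e-9)
})

test_that("effect-modification coefficients recover a heterogeneous effect", {
  ests <- purrr::compact(lapply(1:5, function(r) {
    cfg <- continuous_dgp_config(beta0 = -0.7, beta_x = 0.3, n_pop = 2e6)
    s <- select_tnd_sample(simulate_population(cfg, seed = 4400 + r))
    tryCatch(suppressWarnings(estimate_ve(s, family = "logistic",
                                          effect_modifiers = "x1"))$beta,
             error = function(e) NULL)
  }))[1:3]
  ests <- do.call(rbind, ests)
  expect_lt(abs(mean(ests[, 1]) - (-0.7)), 0.15)
  expect_lt(abs(mean(ests[, 2]) - 0.3), 0.15)
})

test_that("null interaction is centred at zero", {
  ests <- unlist(purrr::compact(lapply(1:5, function(r) {
    cfg <- continuous_dgp_config(beta0 = -0.7, n_pop = 2e6)
    s <- select_tnd_sample(simulate_population(cfg, seed = 5500 + r))
    tryCatch(suppressWarnings(estimate_ve(s, family = "logistic",
                                          effect_modifiers = "x1"))$beta[2],
             error = function(e) NULL)
  })))[1:3]
  expect_lt(abs(mean(ests)), 0.12)
})

test_that("tidy and glance return the documented shapes", {
  s <- quick_binary_sample(seed = 12)
  fit <- suppressWarnings(estimate_ve(s))
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "std.error", "conf.low", "conf.high"))
  expect_identical(nrow(td), 1L)
  td_all <- tidy(fit, components = "all")
  expect_identical(nrow(td_all), 1L + length(fit$tau))
  gl <- glance(fit)
  expect_identical(nrow(gl), 1L)
  expect_equal(gl$ve, 1 - exp(gl$beta))
  expect_lt(gl$ve_low, gl$ve_high)
  expect_s3_class(autoplot(fit), "ggplot")
})
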