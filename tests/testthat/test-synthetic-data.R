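test_that("selection triggers only through outcome, NCO or auxiliary illness", {
  pop <- simulate_population(binary_dgp_config(beta0 = -0.693, n_pop = 2e5), seed = 1)
  expect_true(all(pop$s[pop$y == 0 & pop$w1 == 0 & pop$d == 0] == 0))
  popc <- simulate_population(continuous_dgp_config(beta0 = -0.693, n_pop = 2e5), seed = 2)
  expect_true(all(popc$s[popc$y == 0 & popc$d == 0] == 0))
})

test_that("the analytic sample masks latent columns and counts selected rows", {
  pop <- simulate_population(binary_dgp_config(n_pop = 3e5), seed = 3)
  s <- select_tnd_sample(pop)
  expect_false(any(c("u", "d", "s") %in% names(s)))
  expect_identical(nrow(s), sum(pop$s == 1))
  # outcome-dependent sampling concentrates cases
  expect_gt(mean(s$y), mean(pop$y))
})

test_that("population draws are reproducible from config plus seed", {
  cfg <- binary_dgp_config(beta0 = -0.357, n_pop = 1e5)
  expect_identical(simulate_population(cfg, seed = 11),
                   simulate_population(cfg, seed = 11))
  cfgc <- continuous_dgp_config(n_pop = 1e5)
  expect_identical(simulate_population(cfgc, seed = 12),
                   simulate_population(cfgc, seed = 12))
})

test_that("calibrated defaults reproduce the target prevalences", {
  pop <- simulate_population(binary_dgp_config(beta0 = -1.609, n_pop = 2e6), seed = 21)
  prev0 <- mean(pop$y[pop$a == 0])
  se0 <- sqrt(0.0075 * (1 - 0.0075) / sum(pop$a == 0))
  expect_lt(abs(prev0 - 0.0075), 4 * se0)
  # overall infection prevalence at RR = 0.2 matches the printed 0.55%
  expect_lt(abs(mean(pop$y) - 0.0055), 4 * sqrt(0.0055 / 2e6) + 2e-4)

  popc <- simulate_population(continuous_dgp_config(beta0 = 0, n_pop = 2e6), seed = 22)
  prev0c <- mean(popc$y[popc$a == 0])
  expect_lt(abs(prev0c - 0.0034), 4 * sqrt(0.0034 / sum(popc$a == 0)))

  popn <- simulate_population(dgp_preset("binary-nonrare", beta0 = 0, n_pop = 5e5), seed = 23)
  expect_lt(abs(mean(popn$y[popn$a == 0]) - 0.10), 0.005)
})

test_that("invalid risk configurations error at construction or simulation", {
  expect_error(binary_dgp_config(beta0 = 3, prev_unvax = 0.10), "invalid risk model")
  cfg_bad <- continuous_dgp_config(outcome = c(muuy = 3, muxy = 0.2, muuxy = 0.05),
                                   prev_unvax = 0.05, n_pop = 2e5)
  expect_error(simulate_population(cfg_bad, seed = 5), "risk > 1")
})

test_that("binary oracle bridge satisfies its defining identity exactly", {
  cfg <- binary_dgp_config(beta0 = -0.693)
  expect_lt(bridge_identity_check(cfg), 1e-12)
  # generic random configs against an independent linear solve
  for (sd0 in 1:3) {
    set.seed(sd0)
    cfg2 <- binary_dgp_config(p_u = runif(1, 0.2, 0.5),
                              p_a = sort(runif(2, 0.1, 0.9)),
                              z_coef = c(rnorm(1), runif(1, 0.5, 2), rnorm(1, 0, 0.3)))
    p <- tndnc:::oracle_cell_probabilities(cfg2)
    for (a in 0:1) {
      M <- rbind(p[, a + 1, 1], p[, a + 1, 2])
      expect_equal(unname(closed_form_binary_bridge(p, a)),
                   unname(solve(M, c(1, 1))), tolerance = 1e-10)
    }
  }
})

test_that("a perfect proxy reduces the oracle bridge to the inverse propensity", {
  cfg <- binary_dgp_config(z_coef = c(-30, 60, 0))  # Z = U almost surely
  q_tab <- attr(oracle_bridge_binary(cfg), "q_table")
  expect_equal(q_tab["1", "0"], 1 / cfg$p_a[1], tolerance = 1e-6)
  expect_equal(q_tab["1", "1"], 1 / cfg$p_a[2], tolerance = 1e-6)
  expect_equal(q_tab["0", "0"], 1 / (1 - cfg$p_a[1]), tolerance = 1e-6)
  expect_equal(q_tab["0", "1"], 1 / (1 - cfg$p_a[2]), tolerance = 1e-6)
})

test_that("continuous oracle bridge passes quadrature verification", {
  cfg <- continuous_dgp_config()
  expect_lt(bridge_identity_check(cfg), 1e-8)

  # no confounding: bridge is the marginal inverse propensity
  cfg0 <- continuous_dgp_config(treat = c(mu0a = -0.6, muua = 0, muxa = 0))
  orc0 <- oracle_bridge_continuous(cfg0)
  expect_equal(orc0$tau, c(-0.6, 0, 0, 0))
  expect_equal(evaluate_bridge(orc0, 1, 2.3, 0.7), unname(1 / plogis(-0.6)))

  expect_error(oracle_bridge_continuous(
    continuous_dgp_config(nce = c(mu0z = 0, muaz = 0.2, muuz = 1e-14,
                                  muxz = 0.3, sigmaz = 1))),
    "must be nonzero")
})

test_that("continuous NCE draws reflect their model moments", {
  cfg <- continuous_dgp_config(n_pop = 4e5)
  pop <- simulate_population(cfg, seed = 14)
  resid <- pop$z1 - (cfg$nce[["mu0z"]] + cfg$nce[["muaz"]] * pop$a +
                       cfg$nce[["muuz"]] * pop$u + cfg$nce[["muxz"]] * pop$x1)
  expect_equal(stats::var(resid), cfg$nce[["sigmaz"]]^2, tolerance = 0.02)
  # E[Z | A] contrast carries the direct treatment effect plus confounder tilt
  fit <- stats::lm(z1 ~ a + u + x1, data = pop)
  expect_equal(unname(coef(fit)["a"]), cfg$nce[["muaz"]], tolerance = 0.02)
})

test_that("true inverse propensities behave like inverse probabilities", {
  cfg <- binary_dgp_config(n_pop = 1e4)
  pop <- simulate_population(cfg, seed = 9)
  q <- true_inverse_propensity(pop)
  expect_true(all(q >= 1))
  # hand computation from the configuration
  i1 <- which(pop$u == 1 & pop$a == 1)[1]
  expect_equal(q[i1], 1 / cfg$p_a[2])
  i0 <- which(pop$u == 0 & pop$a == 0)[1]
  expect_equal(q[i0], 1 / (1 - cfg$p_a[1]))

  popc <- simulate_population(continuous_dgp_config(n_pop = 1e4), seed = 10)
  qc <- true_inverse_propensity(popc)
  q_other <- true_inverse_propensity(dplyr::mutate(popc, a = 1L - a))
  expect_equal(1 / qc + 1 / q_other, rep(1, nrow(popc)))
})

test_that("prevalence report gives arm prevalences and a dominating delta", {
  pop <- simulate_population(binary_dgp_config(beta0 = -1.609, n_pop = 5e5), seed = 30)
  rep0 <- prevalence_report(pop)
  expect_gte(rep0$delta_hat, rep0$overall)
  expect_identical(nrow(rep0$by_arm), 2L)

  pop$y <- 0L
  rep_null <- prevalence_report(pop)
  expect_equal(rep_null$by_arm$prevalence, c(0, 0))
  expect_equal(rep_null$delta_hat, 0)
})

test_that("treatment-independent sampling holds in the generated population", {
  pop <- simulate_population(binary_dgp_config(beta0 = -0.693, n_pop = 1e6), seed = 77)
  elig <- pop[pop$y == 1 | pop$w1 == 1 | pop$d == 1, ]
  fit <- glm(s ~ a + y + u + w1 + d, family = binomial(), data = elig)
  ca <- summary(fit)$coefficients["a", ]
  expect_lt(abs(ca["Estimate"]), 4 * ca["Std. Error"])
})
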