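test_that("bridge evaluation matches its parametric forms", {
  sat <- bridge_model("saturated", c(1, 0, 0, 0))
  expect_equal(evaluate_bridge(sat, c(0, 1, 0, 1), c(0, 0, 1, 1)), rep(1, 4))
  sat2 <- bridge_model("saturated", c(0.5, 2, -1, 3))
  expect_equal(evaluate_bridge(sat2, 1, 1), 0.5 + 2 - 1 + 3)

  lgs <- bridge_model("logistic", c(0, 0, 0, 0), dz = 1, dx = 1)
  expect_equal(evaluate_bridge(lgs, c(0, 1), c(0, 0), c(0, 0)), c(2, 2))
  # coefficient on the NCE is the ratio of confounder effects
  cfg <- continuous_dgp_config(treat = c(mu0a = -0.6, muua = 0.5, muxa = 0.3))
  expect_equal(oracle_bridge_continuous(cfg)$tau[3], 0.5 / 1.0)
  expect_error(evaluate_bridge(lgs, c(0, 1), c(0, 0)), "x.*column")
})

test_that("closed-form binary bridge solves the 2x2 system", {
  # Z = U exactly: bridge is the true inverse propensity 1/P(A=1|U=z)
  p <- array(0, c(2, 2, 2))
  p[, 2, 1] <- c(0.4, 0)   # u = 0: P(Z=0,A=1)=0.4
  p[, 1, 1] <- c(0.6, 0)
  p[, 2, 2] <- c(0, 0.8)   # u = 1: P(Z=1,A=1)=0.8
  p[, 1, 2] <- c(0, 0.2)
  expect_equal(unname(closed_form_binary_bridge(p, 1)), c(2.5, 1.25))

  # generic table checked against an independent linear solve
  p2 <- array(c(0.5, 0.1, 0.2, 0.2, 0.2, 0.3, 0.3, 0.2), c(2, 2, 2))
  q <- closed_form_binary_bridge(p2, 0)
  expect_equal(unname(q), c(0.2 / 0.13, 0.3 / 0.13), tolerance = 1e-12)
  M <- rbind(p2[1:2, 1, 1], p2[1:2, 1, 2])
  expect_equal(unname(q), solve(M, c(1, 1)), tolerance = 1e-12)

  # identical rows across the conditioning variable: unidentified
  p3 <- array(rep(c(0.25, 0.25, 0.25, 0.25), 2), c(2, 2, 2))
  expect_error(closed_form_binary_bridge(p3, 1),
               class = "tndnc_identification_error")
})

test_that("moment residuals cancel cases and match a term-by-term oracle", {
  s <- hand_sample()
  mm <- default_moment_spec("saturated", dw = 1)
  const2 <- bridge_model("saturated", c(2, 0, 0, 0))
  expect_equal(moment_residuals(s, const2, mm, c(2, 0, 0, 0)), rep(0, 4))

  all_cases <- tnd_sample(data.frame(a = c(0, 1), y = c(1, 1),
                                     z1 = c(0, 1), w1 = c(1, 0)))
  expect_error(moment_residuals(all_cases, const2, mm, c(2, 0, 0, 0)),
               "no test-negative controls")

  # independent summation oracle on the six-row sample
  tau <- c(0.8, 0.4, 1.1, -0.2)
  mod <- bridge_model("saturated", tau)
  mm <- default_moment_spec("saturated", dw = 1)
  expected <- rep(0, 4)
  for (i in seq_len(nrow(s))) {
    qi <- tau[1] + tau[2] * s$z1[i] + tau[3] * s$a[i] + tau[4] * s$z1[i] * s$a[i]
    m_at <- function(a) c(1, s$w1[i], a, s$w1[i] * a)
    expected <- expected +
      (1 - s$y[i]) * (m_at(s$a[i]) * qi - m_at(1) - m_at(0)) / nrow(s)
  }
  expect_equal(moment_residuals(s, mod, mm, tau), expected, tolerance = 1e-12)
})

test_that("with no treatment confounding the fit reduces to inverse vaccination frequencies", {
  # A independent of U (and Z): the unique bridge is flat in Z because the
  # NCE-NCO association through U pins the Z-slope at zero
  cfg <- binary_dgp_config(beta0 = -0.693, p_a = c(0.4, 0.4),
                           confounding_ratio = 1,
                           z_coef = c(qlogis(0.1), qlogis(0.85) - qlogis(0.1), 0),
                           n_pop = 2e6)
  s <- select_tnd_sample(simulate_population(cfg, seed = 314))
  fit <- suppressWarnings(fit_bridge(s, family = "saturated"))
  ctrl <- s[s$y == 0, ]
  # z-slopes are centred at zero; arm-averaged bridge values hit the
  # empirical inverse vaccination frequencies among controls
  expect_equal(fit$tau[2], 0, tolerance = 0.6)
  expect_equal(fit$tau[4], 0, tolerance = 0.6)
  q_ctrl <- evaluate_bridge(fit, ctrl$a, ctrl$z1)
  expect_equal(mean(q_ctrl[ctrl$a == 0]), 1 / mean(ctrl$a == 0), tolerance = 0.05)
  expect_equal(mean(q_ctrl[ctrl$a == 1]), 1 / mean(ctrl$a == 1), tolerance = 0.05)
  expect_true(fit$convergence$converged)
  expect_lte(max(abs(moment_residuals(s, fit, fit$moment, fit$tau))), 1e-8)
})

test_that("case rows never influence the fitted bridge", {
  s <- quick_binary_sample(seed = 99)
  fit1 <- suppressWarnings(fit_bridge(s))
  cases <- s[s$y == 1, ]
  reordered <- dplyr::bind_rows(s[s$y == 0, ], cases[rev(seq_len(nrow(cases))), ],
                                cases[1:50, ])
  fit2 <- suppressWarnings(fit_bridge(as_tnd_sample(reordered)))
  expect_equal(fit1$tau, fit2$tau, tolerance = 1e-8)
})

test_that("saturated moment fit is algebraically the closed-form control-cell solution", {
  s <- quick_binary_sample(seed = 2024)
  fit <- suppressWarnings(fit_bridge(s))
  p <- control_cell_probabilities(s)
  q_cf <- rbind(closed_form_binary_bridge(p, 0), closed_form_binary_bridge(p, 1))
  q_fit <- rbind(evaluate_bridge(fit, c(0, 0), c(0, 1)),
                 evaluate_bridge(fit, c(1, 1), c(0, 1)))
  expect_equal(q_fit, q_cf, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("a redundant moment component leaves the over-identified fit at the exact root", {
  s <- quick_binary_sample(seed = 31)
  just <- suppressWarnings(fit_bridge(s))
  over_m <- moment_spec(function(W, a, X) cbind(1, W, a, W * a, 1 + W), d = 5)
  over <- suppressWarnings(fit_bridge(s, moment = over_m))
  expect_equal(over$tau, just$tau, tolerance = 1e-6)
})
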