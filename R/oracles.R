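#' Oracle bridge function for the binary setting
#'
#' Computes the cell probabilities `p[z, a | u] = P(Z = z, A = a | U = u)`
#' analytically from a binary DGP configuration and solves the 2x2 linear
#' system for each treatment level, yielding the true treatment confounding
#' bridge `q(a, z)` expressed as a saturated-family `tnd_bridge`. The fitted
#' table satisfies `E[q(a, Z) | A = a, U = u] P(A = a | U = u) = 1` exactly.
#'
#' @param config A [binary_dgp_config()].
#' @return A `tnd_bridge` (family `"saturated"`) with attribute `q_table`
#'   (2x2 matrix indexed `[a + 1, z + 1]`).
#' @export
oracle_bridge_binary <- function(config) {
  stopifnot(inherits(config, "binary_dgp"))
  p <- oracle_cell_probabilities(config)
  q_table <- rbind(closed_form_binary_bridge(p, a = 0),
                   closed_form_binary_bridge(p, a = 1))
  dimnames(q_table) <- list(a = 0:1, z = 0:1)
  tau <- c(q_table[1, 1],
           q_table[1, 2] - q_table[1, 1],
           q_table[2, 1] - q_table[1, 1],
           q_table[2, 2] - q_table[2, 1] - q_table[1, 2] + q_table[1, 1])
  model <- bridge_model("saturated", tau = tau, dz = 1L, dx = 0L)
  model$oracle <- TRUE
  attr(model, "q_table") <- q_table
  model
}

# p[z, a | u] from the binary configuration (exact arithmetic)
oracle_cell_probabilities <- function(config) {
  p <- array(NA_real_, c(2, 2, 2), dimnames = list(z = 0:1, a = 0:1, u = 0:1))
  for (u in 0:1) for (a in 0:1) {
    pa <- if (a == 1) config$p_a[u + 1] else 1 - config$p_a[u + 1]
    pz1 <- expit(config$z_coef[1] + config$z_coef[2] * u + config$z_coef[3] * a)
    p[, a + 1, u + 1] <- pa * c(1 - pz1, pz1)
  }
  p
}

#' Cell probabilities estimated from test-negative controls
#'
#' Empirical `p'[z, a | w] = P(Z = z, A = a | W = w, Y = 0)` among the
#' controls of a TND sample; plugging this table into
#' [closed_form_binary_bridge()] gives the control-sample closed-form bridge
#' estimate, algebraically identical to fitting the saturated model by its
#' moment equations.
#'
#' @param sample A [tnd_sample()] with binary scalar `z1`, `w1`.
#' @return A 2x2x2 array indexed `[z + 1, a + 1, w + 1]`.
#' @export
control_cell_probabilities <- function(sample) {
  s <- as_tnd_sample(sample)
  ctrl <- s[s$y == 0, ]
  if (nrow(ctrl) == 0) abort("sample contains no test-negative controls (Y = 0)")
  if (!all(ctrl$z1 %in% 0:1) || !all(ctrl$w1 %in% 0:1)) {
    abort("control cell probabilities require binary z1 and w1")
  }
  p <- array(NA_real_, c(2, 2, 2), dimnames = list(z = 0:1, a = 0:1, w = 0:1))
  for (w in 0:1) {
    sub <- ctrl[ctrl$w1 == w, ]
    if (nrow(sub) == 0) abort(sprintf("no controls with W = %d", w))
    for (z in 0:1) for (a in 0:1) {
      p[z + 1, a + 1, w + 1] <- mean(sub$z1 == z & sub$a == a)
    }
  }
  p
}

#' Oracle bridge function for the continuous setting
#'
#' Under the logistic treatment model and Gaussian NCE model the bridge
#' admits the closed form
#' `q(A, Z, X) = 1 + exp((-1)^A (tau0 + tau1 A + tau2 Z + tau3 X))` with
#' coefficients obtained by matching exponential moments of the Gaussian
#' NCE against the inverse logistic treatment probability (via the normal
#' moment generating function):
#' \deqn{\tau_2 = \mu_{UA}/\mu_{UZ}, \quad
#'       \tau_3 = \mu_{XA} - \mu_{XZ}\,\tau_2, \quad
#'       \tau_0 = \mu_{0A} - \tau_2\,\mu_{0Z} - \sigma_Z^2\tau_2^2/2, \quad
#'       \tau_1 = \sigma_Z^2\tau_2^2 - \tau_2\,\mu_{AZ}.}
#' Existence requires `muuz != 0`: the NCE must respond to the confounder.
#'
#' @param config A [continuous_dgp_config()].
#' @return A `tnd_bridge` (family `"logistic"`, `dz = dx = 1`).
#' @export
oracle_bridge_continuous <- function(config) {
  stopifnot(inherits(config, "continuous_dgp"))
  nce <- config$nce; tr <- config$treat
  if (abs(nce[["muuz"]]) < 1e-12) {
    abort("bridge function does not exist: muuz = 0 (NCE uninformative about the confounder)")
  }
  tau2 <- tr[["muua"]] / nce[["muuz"]]
  tau3 <- tr[["muxa"]] - nce[["muxz"]] * tau2
  tau0 <- tr[["mu0a"]] - tau2 * nce[["mu0z"]] - nce[["sigmaz"]]^2 * tau2^2 / 2
  tau1 <- nce[["sigmaz"]]^2 * tau2^2 - tau2 * nce[["muaz"]]
  model <- bridge_model("logistic", tau = c(tau0, tau1, tau2, tau3),
                        dz = 1L, dx = 1L)
  model$oracle <- TRUE
  model
}

#' Verify the defining bridge identity on a grid
#'
#' Checks `E[q(a, Z, X) | A = a, U = u, X = x] * P(A = a | U = u, X = x) = 1`
#' for a bridge function against a DGP configuration: exactly (finite sum)
#' in the binary setting, by Gauss-Hermite quadrature over the Gaussian NCE
#' in the continuous setting.
#'
#' @param config A DGP configuration.
#' @param bridge A `tnd_bridge` (defaults to the analytic oracle bridge).
#' @param u_grid,x_grid Grid of confounder/covariate values (continuous
#'   setting only).
#' @param n_nodes Number of quadrature nodes.
#' @return Maximum absolute deviation of the identity from 1 over the grid.
#' @export
bridge_identity_check <- function(config, bridge = NULL,
                                  u_grid = c(-1.5, 0, 1.5),
                                  x_grid = c(-1.5, 0, 1.5), n_nodes = 40) {
  if (inherits(config, "binary_dgp")) {
    bridge <- bridge %||% oracle_bridge_binary(config)
    p <- oracle_cell_probabilities(config)
    err <- 0
    for (u in 0:1) for (a in 0:1) {
      q_az <- evaluate_bridge(bridge, c(a, a), c(0, 1))
      err <- max(err, abs(sum(p[, a + 1, u + 1] * q_az) - 1))
    }
    err
  } else {
    bridge <- bridge %||% oracle_bridge_continuous(config)
    nce <- config$nce; tr <- config$treat
    err <- 0
    for (a in 0:1) for (u in u_grid) for (x in x_grid) {
      mz <- nce[["mu0z"]] + nce[["muaz"]] * a + nce[["muuz"]] * u + nce[["muxz"]] * x
      Eq <- gauss_hermite_mean(function(z) evaluate_bridge(bridge, rep(a, length(z)), z,
                                                           rep(x, length(z))),
                               mean = mz, sd = nce[["sigmaz"]], n_nodes = n_nodes)
      p1 <- expit(tr[["mu0a"]] + tr[["muua"]] * u + tr[["muxa"]] * x)
      pa <- if (a == 1) p1 else 1 - p1
      err <- max(err, abs(Eq * pa - 1))
    }
    err
  }
}
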