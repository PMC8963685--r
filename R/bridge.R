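#' Treatment confounding bridge models
#'
#' A treatment confounding bridge function `q(A, Z, X)` is a function of the
#' treatment, the negative control exposure and measured covariates whose
#' conditional expectation given `(A, U, X)` equals the inverse treatment
#' probability `1 / P(A | U, X)`, where `U` is the unmeasured confounder.
#' Two parametric families are supported:
#'
#' * `"saturated"`: `q = tau0 + tau_z' Z + tau_a A + tau_za' (Z A)`, the
#'   saturated model for binary NCEs (linear in `tau`, values may fall below
#'   1, which is flagged since an inverse probability cannot);
#' * `"logistic"`: `q = 1 + exp((-1)^A (tau0 + tau1 A + tau2' Z + tau3' X))`,
#'   the closed form implied by a logistic treatment model with Gaussian NCE
#'   (always > 1 by construction).
#'
#' @param family `"saturated"` or `"logistic"`.
#' @param tau Numeric parameter vector: length `2 * (1 + dz)` for
#'   `"saturated"`, `2 + dz + dx` for `"logistic"`.
#' @param dz,dx Number of NCE components and covariates the model applies to.
#' @return An object of class `tnd_bridge`.
#' @seealso [fit_bridge()], [evaluate_bridge()]
#' @export
bridge_model <- function(family = c("saturated", "logistic"), tau,
                         dz = 1L, dx = 0L) {
  family <- match.arg(family)
  p <- bridge_npar(family, dz, dx)
  if (length(tau) != p) {
    abort(sprintf("`tau` must have length %d for family '%s' with dz=%d, dx=%d (got %d)",
                  p, family, dz, dx, length(tau)))
  }
  structure(
    list(family = family, tau = as.numeric(tau), dz = as.integer(dz),
         dx = as.integer(dx), convergence = NULL, validity = NULL),
    class = "tnd_bridge"
  )
}

bridge_npar <- function(family, dz, dx) {
  switch(family, saturated = 2L * (1L + dz), logistic = 2L + dz + dx)
}

#' Evaluate a treatment confounding bridge function
#'
#' @param model A `tnd_bridge` object.
#' @param a Binary treatment value(s).
#' @param z NCE value(s): vector or matrix with one row per subject.
#' @param x Covariate row(s); `NULL` when the model has none.
#' @param tau Optional parameter vector overriding `model$tau`.
#' @return Numeric vector of bridge values, one per subject.
#' @export
evaluate_bridge <- function(model, a, z, x = NULL, tau = NULL) {
  tau <- tau %||% model$tau
  n <- length(a)
  Z <- as_matrix(z, n, "z")
  X <- as_matrix(x, n, "x")
  if (ncol(Z) != model$dz) abort(sprintf("`z` has %d column(s); model expects %d", ncol(Z), model$dz))
  if (ncol(X) != model$dx) abort(sprintf("`x` has %d column(s); model expects %d", ncol(X), model$dx))
  dz <- model$dz
  if (model$family == "saturated") {
    tau0 <- tau[1]
    tau_z <- tau[1 + seq_len(dz)]
    tau_a <- tau[2 + dz]
    tau_za <- tau[2 + dz + seq_len(dz)]
    drop(tau0 + Z %*% tau_z + tau_a * a + (Z * a) %*% tau_za)
  } else {
    lin <- tau[1] + tau[2] * a + drop(Z %*% tau[2 + seq_len(dz)])
    if (model$dx > 0) lin <- lin + drop(X %*% tau[2 + dz + seq_len(model$dx)])
    1 + exp((-1)^a * lin)
  }
}

#' Closed-form bridge function for binary confounder and binary NCE
#'
#' With a binary conditioning variable (the latent confounder `U` in the
#' oracle version, or the observed NCO `W` in the control-sample version)
#' and binary NCE `Z`, the defining integral equation reduces to a 2x2
#' linear system `sum_z p[z, a | u] q(a, z) = 1` for `u = 0, 1`, solved here
#' directly.
#'
#' @param p A `2 x 2 x 2` array of conditional joint cell probabilities
#'   `p[z, a | u]`, indexed `[z + 1, a + 1, u + 1]`; each `p[, , u]` slice
#'   must be a probability table over `(z, a)`.
#' @param a Treatment level (0 or 1) whose bridge values are required.
#' @param kappa_max Condition-number threshold above which the system is
#'   declared unidentified (the NCE then carries no information about the
#'   conditioning variable).
#' @return Named numeric vector `c(q0, q1)` holding `q(a, 0)` and `q(a, 1)`.
#' @examples
#' p <- array(0, c(2, 2, 2))
#' p[, 1, 1] <- c(0.5, 0.4); p[, 2, 1] <- c(0.06, 0.04)
#' p[, 1, 2] <- c(0.1, 0.4); p[, 2, 2] <- c(0.2, 0.3)
#' closed_form_binary_bridge(p, a = 1)
#' @export
closed_form_binary_bridge <- function(p, a, kappa_max = 1e8) {
  stopifnot(is.array(p), all(dim(p) == c(2, 2, 2)))
  if (!a %in% c(0, 1)) abort("`a` must be 0 or 1")
  sums <- apply(p, 3, sum)
  if (any(p < -1e-12) || any(abs(sums - 1) > 1e-8)) {
    abort("each p[, , u] slice must be a probability table over (z, a)")
  }
  # rows: conditioning level u (or w); columns: z
  M <- rbind(p[c(1, 2), a + 1, 1], p[c(1, 2), a + 1, 2])
  kap <- tryCatch(kappa(M, exact = TRUE), error = function(e) Inf)
  if (!is.finite(kap) || kap > kappa_max) {
    abort(sprintf(paste0("bridge function not identified for treatment level a=%d: ",
                         "cell-probability matrix is singular or ill-conditioned ",
                         "(condition number %.3g); the NCE carries no information ",
                         "about the conditioning variable"), a, kap),
          class = "tndnc_identification_error")
  }
  q <- solve(M, c(1, 1))
  stats::setNames(q, c("q0", "q1"))
}

#' Moment specifications for bridge estimation
#'
#' The bridge parameters are estimated from the test-negative controls by
#' solving moment equations built from a user-chosen function `m(W, A, X)`
#' whose dimension must be at least `dim(tau)`. `moment_spec()` wraps an
#' arbitrary vectorised function; `default_moment_spec()` returns the
#' conventional bases: `(1, W, A, W*A)` for the saturated family and
#' `(1, W, A, X)` for the logistic family (NCO components enter with their
#' treatment interactions in the saturated case).
#'
#' @param fn A function `(W, a, X) -> matrix` taking the NCO matrix, the
#'   treatment vector and the covariate matrix for `n` subjects and returning
#'   an `n x d` matrix. It must be evaluable at `a = 0` and `a = 1` for every
#'   subject, because the estimating equation evaluates `m` at both
#'   treatment levels.
#' @param d Output dimension of `fn`.
#' @return An object of class `tnd_moment_spec`.
#' @export
moment_spec <- function(fn, d) {
  stopifnot(is.function(fn), d >= 1)
  structure(list(fn = fn, d = as.integer(d)), class = "tnd_moment_spec")
}

#' @rdname moment_spec
#' @param family Bridge family the basis is intended for.
#' @param dw,dx Number of NCO and covariate columns.
#' @export
default_moment_spec <- function(family = c("saturated", "logistic"),
                                dw = 1L, dx = 0L) {
  family <- match.arg(family)
  if (family == "saturated") {
    moment_spec(function(W, a, X) cbind(1, W, a, W * a), d = 2L * (1L + dw))
  } else {
    moment_spec(function(W, a, X) cbind(1, W, a, X), d = 2L + dw + dx)
  }
}

#' Bridge estimating-equation residuals
#'
#' Empirical mean of the control-restricted moment conditions
#' `(1 - Y) * (m(W, A, X) q(A, Z, X; tau) - m(W, 1, X) - m(W, 0, X))`.
#' Test-positive rows contribute exactly zero; the bridge is identified from
#' the test-negative controls alone.
#'
#' @param sample A [tnd_sample()].
#' @param model A `tnd_bridge` (its family/dimensions are used).
#' @param moment A `tnd_moment_spec`.
#' @param tau Parameter vector at which to evaluate the residuals.
#' @return Numeric vector of length `moment$d`.
#' @export
moment_residuals <- function(sample, model, moment, tau) {
  s <- sample_arrays(as_tnd_sample(sample))
  if (!any(s$y == 0)) abort("sample contains no test-negative controls (Y = 0)")
  if (moment$d < length(tau)) {
    abort(sprintf("moment dimension (%d) is smaller than dim(tau) (%d)", moment$d, length(tau)))
  }
  q <- evaluate_bridge(model, s$a, s$Z, if (model$dx > 0) s$X, tau = tau)
  M_a <- moment$fn(s$W, s$a, s$X)
  M_1 <- moment$fn(s$W, rep(1, s$n), s$X)
  M_0 <- moment$fn(s$W, rep(0, s$n), s$X)
  unname(colMeans((1 - s$y) * (M_a * q - M_1 - M_0)))
}

#' Estimate a treatment confounding bridge function from TND controls
#'
#' Solves the moment equations for `tau`. With a just-identified moment
#' specification (`d == dim(tau)`) an exact root is found by damped Newton
#' iteration with a numerically differentiated Jacobian; with an
#' over-identified specification the identity-weighted quadratic form
#' `g(tau)' g(tau)` is minimised by Gauss-Newton (this matches the
#' projection form used by the sandwich variance; no optimal reweighting is
#' applied). Bridge values below 1 at the solution are reported as a
#' validity warning since an inverse probability cannot be less than 1.
#'
#' @inheritParams moment_residuals
#' @param family Bridge family to fit when `model` is not supplied.
#' @param moment A `tnd_moment_spec`, defaulting to [default_moment_spec()]
#'   for the chosen family.
#' @param tau_init Optional starting values (defaults: `(1, 0, ...)` for
#'   saturated, i.e. the constant bridge `q == 1`; all zero for logistic,
#'   i.e. `q == 2`).
#' @param tol,max_iter Convergence tolerance (max-norm of the residual) and
#'   iteration cap.
#' @param floor_at_one If `TRUE`, evaluated bridge values are floored at 1
#'   downstream (off by default; violations only warn).
#' @return A fitted `tnd_bridge` with `convergence` and `validity` fields.
#' @export
fit_bridge <- function(sample, family = c("saturated", "logistic"),
                       moment = NULL, tau_init = NULL,
                       tol = 1e-10, max_iter = 200, floor_at_one = FALSE) {
  family <- match.arg(family)
  sample <- as_tnd_sample(sample)
  s <- sample_arrays(sample)
  if (!any(s$y == 0)) abort("sample contains no test-negative controls (Y = 0)")
  dz <- ncol(s$Z); dw <- ncol(s$W); dx <- ncol(s$X)
  model_dx <- if (family == "logistic") dx else 0L
  p <- bridge_npar(family, dz, model_dx)
  moment <- moment %||% default_moment_spec(family, dw = dw, dx = dx)
  if (moment$d < p) {
    abort(sprintf("moment dimension (%d) is smaller than dim(tau) (%d)", moment$d, p))
  }
  model <- bridge_model(family, tau = rep(0, p), dz = dz, dx = model_dx)
  # default starts: q == 1 (saturated); the no-residual-confounding solution
  # 1/P(A = a | Z, X) from a logistic fit among controls (logistic family)
  tau_init <- tau_init %||% if (family == "saturated") {
    c(1, rep(0, p - 1))
  } else {
    ctrl <- sample[sample$y == 0, ]
    cf <- tryCatch({
      sc <- sample_arrays(as_tnd_sample(ctrl))
      des <- cbind(sc$Z, sc$X)
      coef(stats::glm.fit(cbind(1, des), sc$a, family = binomial()))
    }, error = function(e) NULL)
    if (is.null(cf) || anyNA(cf)) rep(0, p) else c(cf[1], 0, cf[-1])
  }

  g_fn <- function(tau) moment_residuals(sample, model, moment, tau)
  fit <- solve_estimating_eq(g_fn, tau_init, tol = tol, max_iter = max_iter)
  if (!fit$converged && moment$d == p) {
    abort(sprintf("bridge estimation did not converge (last residual max-norm %.3g)",
                  fit$residual_norm), class = "tndnc_convergence_error")
  }
  model$tau <- fit$theta
  q_hat <- evaluate_bridge(model, s$a, s$Z, if (model_dx > 0) s$X)
  frac_invalid <- mean(q_hat < 1)
  if (frac_invalid > 0) {
    warn(sprintf("%.1f%% of fitted bridge values are < 1 (an inverse probability cannot be); interpret with care",
                 100 * frac_invalid))
  }
  model$convergence <- list(converged = fit$converged,
                            iterations = fit$iterations,
                            residual_norm = fit$residual_norm)
  model$validity <- list(fraction_below_one = frac_invalid,
                         floored = isTRUE(floor_at_one))
  model$moment <- moment
  model$floor_at_one <- isTRUE(floor_at_one)
  model
}

# internal: evaluate a fitted bridge on a tnd_sample (honours flooring)
bridge_values <- function(model, sample) {
  s <- sample_arrays(sample)
  q <- evaluate_bridge(model, s$a, s$Z, if (model$dx > 0) s$X)
  if (isTRUE(model$floor_at_one)) q <- pmax(q, 1)
  q
}

#' @export
print.tnd_bridge <- function(x, ...) {
  cat(sprintf("<tnd_bridge> family = %s, dim(tau) = %d\n", x$family, length(x$tau)))
  cat("tau:", paste(format(x$tau, digits = 5), collapse = " "), "\n")
  if (!is.null(x$convergence)) {
    cat(sprintf("converged: %s (residual max-norm %.2e, %d iterations)\n",
                x$convergence$converged, x$convergence$residual_norm,
                x$convergence$iterations))
  }
  if (!is.null(x$validity) && x$validity$fraction_below_one > 0) {
    cat(sprintf("note: %.1f%% of in-sample bridge values < 1\n",
                100 * x$validity$fraction_below_one))
  }
  invisible(x)
}

#' @export
tidy.tnd_bridge <- function(x, ...) {
  tibble::tibble(term = paste0("tau", seq_along(x$tau) - 1), estimate = x$tau)
}
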