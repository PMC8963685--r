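#' @importFrom stats rbinom rnorm plogis qlogis qnorm pnorm pchisq cov glm
#'   binomial coef vcov quantile complete.cases
#' @importFrom rlang abort warn .data
NULL

expit <- stats::plogis

`%||%` <- function(a, b) if (is.null(a)) b else a

# numeric Jacobian of a vector-valued function by central differences,
# step 1e-6 * (1 + |theta|) per coordinate
num_jacobian <- function(fn, theta, eps = 1e-6) {
  f0 <- fn(theta)
  J <- matrix(NA_real_, length(f0), length(theta))
  for (j in seq_along(theta)) {
    h <- eps * (1 + abs(theta[j]))
    tp <- tm <- theta
    tp[j] <- theta[j] + h
    tm[j] <- theta[j] - h
    J[, j] <- (fn(tp) - fn(tm)) / (2 * h)
  }
  J
}

# Damped Newton (square systems) / Gauss-Newton (over-identified systems)
# root finder for estimating equations. Deterministic quasi-random
# multi-start perturbations (golden-angle sequence) on failure.
solve_estimating_eq <- function(g_fn, theta_init, tol = 1e-10, max_iter = 200,
                                n_restart = 8) {
  p <- length(theta_init)
  d <- length(g_fn(theta_init))
  starts <- list(theta_init)
  for (k in seq_len(n_restart)) {
    starts[[k + 1]] <- theta_init + 0.5 * k / n_restart *
      sin(2.39996323 * k * seq_len(p))
  }
  best <- NULL
  for (th0 in starts) {
    res <- newton_once(g_fn, th0, tol, max_iter, square = (d == p))
    if (is.null(best) || res$residual_norm < best$residual_norm) best <- res
    if (best$converged) break
  }
  best
}

newton_once <- function(g_fn, theta, tol, max_iter, square) {
  safe_norm <- function(g) {
    v <- suppressWarnings(max(abs(g)))
    if (!is.finite(v)) Inf else v
  }
  g <- g_fn(theta)
  gnorm <- safe_norm(g)
  if (!is.finite(gnorm)) {
    return(list(theta = theta, converged = FALSE, iterations = 0L,
                residual_norm = Inf))
  }
  for (it in seq_len(max_iter)) {
    crit <- gnorm
    J <- num_jacobian(g_fn, theta)
    if (anyNA(J)) break
    if (square) {
      step <- tryCatch(-solve(J, g), error = function(e) NULL)
    } else {
      JtJ <- crossprod(J)
      grad <- drop(crossprod(J, g))
      crit <- safe_norm(grad) # g = 0 may be unattainable; require stationarity
      step <- tryCatch(-solve(JtJ, grad), error = function(e) NULL)
    }
    if (crit <= tol) {
      return(list(theta = theta, converged = TRUE, iterations = it - 1L,
                  residual_norm = gnorm))
    }
    if (is.null(step) || anyNA(step)) break
    # step halving until the residual norm decreases
    lambda <- 1
    repeat {
      g_new <- g_fn(theta + lambda * step)
      gn_new <- safe_norm(g_new)
      if (gn_new < gnorm || lambda < 1e-8) break
      lambda <- lambda / 2
    }
    if (lambda < 1e-8 && gn_new >= gnorm) break
    theta <- theta + lambda * step
    g <- g_new
    gnorm <- gn_new
  }
  converged <- if (square) gnorm <= tol else FALSE
  list(theta = theta, converged = converged, iterations = max_iter,
       residual_norm = gnorm)
}

# Gauss-Hermite expectation of f(Z) for Z ~ N(mean, sd^2)
gauss_hermite_mean <- function(f, mean, sd, n_nodes = 40) {
  gh <- pracma::gaussHermite(n_nodes)
  z <- sqrt(2) * sd * gh$x + mean
  sum(gh$w * f(z)) / sqrt(pi)
}

as_matrix <- function(x, n, what) {
  if (is.null(x)) return(matrix(numeric(0), n, 0))
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x)) x <- matrix(x, ncol = 1)
  if (nrow(x) == 1 && n > 1) x <- x[rep(1, n), , drop = FALSE]
  if (nrow(x) != n) abort(sprintf("`%s` must have %d rows, got %d", what, n, nrow(x)))
  x
}
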