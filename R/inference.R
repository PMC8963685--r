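#' Estimate vaccine effectiveness from a TND sample via negative controls
#'
#' Runs the full double negative control procedure: estimate the treatment
#' confounding bridge function from the test-negative controls (unless a
#' fitted or oracle bridge is supplied), plug it into the closed-form
#' inverse-weighted estimator of the causal log risk ratio
#' \deqn{\hat\beta = \log \frac{\sum_i \hat q_i A_i Y_i}{\sum_i \hat q_i (1-A_i) Y_i},}
#' and compute joint sandwich (stacked M-estimation) inference for
#' `(beta, tau)` with a Wald interval for `VE = 1 - exp(beta)`.
#'
#' With `effect_modifiers`, the log risk ratio is modelled as
#' `beta0(X) = d(X)' b` with `d(X) = (1, X_modifiers)` and `b` is found by
#' solving the `d(X)`-weighted vector extension of the scalar estimating
#' equation by Newton iteration.
#'
#' Under treatment-independent sampling the estimand is the log causal risk
#' ratio for a rare infection; under treatment-induced selection the same
#' computation retains validity on the odds ratio scale (set
#' `scale = "OR"` to record that reading; the numbers are identical).
#'
#' @param data A [tnd_sample()] (or a data frame with standardised columns).
#' @param bridge Optional `tnd_bridge`; when supplied with
#'   `tau_fixed = TRUE` it is treated as known (oracle inference on `beta`
#'   alone).
#' @param family,moment Passed to [fit_bridge()] when `bridge` is `NULL`.
#' @param effect_modifiers Optional character vector of covariate columns
#'   (`"x1"`, ...) modifying the log risk ratio.
#' @param alpha Two-sided level for the Wald interval (default 0.05).
#' @param tau_fixed Treat the supplied bridge parameters as known constants.
#' @param scale `"RR"` (rare-disease reading, default) or `"OR"`
#'   (treatment-induced selection reading).
#' @return An object of class `tnd_ve`; see [tidy.tnd_ve()] and
#'   [glance.tnd_ve()].
#' @examples
#' pop <- simulate_population(dgp_preset("binary-rare", beta0 = -0.693), seed = 7)
#' fit <- estimate_ve(select_tnd_sample(pop))
#' glance(fit)
#' @export
estimate_ve <- function(data, bridge = NULL,
                        family = c("saturated", "logistic"), moment = NULL,
                        effect_modifiers = NULL, alpha = 0.05,
                        tau_fixed = FALSE, scale = c("RR", "OR")) {
  scale <- match.arg(scale)
  stopifnot(alpha > 0, alpha < 1)
  sample <- as_tnd_sample(data)
  s <- sample_arrays(sample)
  if (is.null(bridge)) {
    bridge <- fit_bridge(sample, family = family, moment = moment)
    tau_fixed <- FALSE
  }
  q_hat <- bridge_values(bridge, sample)

  dmat <- em_design(s, effect_modifiers)
  if (is.null(dmat)) {
    beta <- log_rr_closed_form(s, q_hat)
    bnames <- "beta"
  } else {
    beta <- log_rr_modified(s, q_hat, dmat)
    bnames <- paste0("beta_", colnames(dmat))
  }
  k <- length(beta)

  infl <- stacked_moments(sample, bridge, beta = beta, tau = bridge$tau,
                          moment = bridge$moment, effect_modifiers = effect_modifiers,
                          tau_fixed = tau_fixed)
  Sigma <- sandwich_covariance(infl)
  se <- sqrt(diag(Sigma)[seq_len(k)])

  zq <- qnorm(1 - alpha / 2)
  b1 <- beta[1]; se1 <- se[1]
  structure(list(
    beta = stats::setNames(beta, bnames),
    se = stats::setNames(se, bnames),
    cov = Sigma,
    tau = bridge$tau,
    bridge = bridge,
    ve = 1 - exp(b1),
    ve_ci = wald_ci_ve(b1, se1, alpha),
    beta_ci = c(lower = b1 - zq * se1, upper = b1 + zq * se1),
    alpha = alpha,
    n = s$n,
    n_cases = sum(s$y),
    tau_fixed = tau_fixed,
    method = if (tau_fixed) "NC-Oracle" else "NC",
    scale_note = if (scale == "RR") "RR (rare-disease reading)"
                 else "OR (treatment-induced selection reading)",
    convergence = bridge$convergence,
    influence = infl
  ), class = "tnd_ve")
}

#' Closed-form log risk ratio for a given bridge function
#'
#' The point estimator alone: plugs bridge values into
#' `log(sum q A Y / sum q (1 - A) Y)`. Multiplying the bridge by any
#' positive constant leaves the estimate unchanged; with `q == 1` it reduces
#' to the log vaccinated:unvaccinated case ratio.
#'
#' @param data A [tnd_sample()].
#' @param bridge A `tnd_bridge`, or a numeric vector of per-subject bridge
#'   values.
#' @return The scalar log risk ratio estimate.
#' @export
estimate_log_rr <- function(data, bridge) {
  sample <- as_tnd_sample(data)
  s <- sample_arrays(sample)
  q_hat <- if (inherits(bridge, "tnd_bridge")) bridge_values(bridge, sample)
           else rep_len(as.numeric(bridge), s$n)
  log_rr_closed_form(s, q_hat)
}

em_design <- function(s, effect_modifiers) {
  if (is.null(effect_modifiers)) return(NULL)
  if (length(effect_modifiers) == 0) {
    return(matrix(1, s$n, 1, dimnames = list(NULL, "0")))
  }
  idx <- match(effect_modifiers, paste0("x", seq_len(ncol(s$X))))
  if (anyNA(idx)) abort("`effect_modifiers` must name covariate columns x1, x2, ...")
  d <- cbind(1, s$X[, idx, drop = FALSE])
  colnames(d) <- c("0", effect_modifiers)
  d
}

log_rr_closed_form <- function(s, q_hat) {
  num <- sum(q_hat * s$a * s$y)
  den <- sum(q_hat * (1 - s$a) * s$y)
  if (num <= 0) abort("no vaccinated cases: the log risk ratio estimate is undefined")
  if (den <= 0) abort("no unvaccinated cases: the log risk ratio estimate is undefined")
  log(num / den)
}

log_rr_modified <- function(s, q_hat, dmat) {
  if (sum(s$a * s$y) == 0) abort("no vaccinated cases: the log risk ratio estimate is undefined")
  if (sum((1 - s$a) * s$y) == 0) abort("no unvaccinated cases: the log risk ratio estimate is undefined")
  sgn <- (-1)^(1 - s$a)
  g_fn <- function(b) {
    colMeans(sgn * q_hat * s$y * exp(-drop(dmat %*% b) * s$a) * dmat)
  }
  fit <- solve_estimating_eq(g_fn, rep(0, ncol(dmat)))
  if (!fit$converged) {
    abort(sprintf("effect-modification estimating equation did not converge (residual %.3g)",
                  fit$residual_norm), class = "tndnc_convergence_error")
  }
  fit$theta
}

#' Stacked estimating functions and their Jacobian
#'
#' Per-subject values of the joint estimating function for `(beta, tau)`:
#' the inverse-weighted risk-ratio component(s)
#' `(-1)^(1-A) q(A,Z,X; tau) Y exp(-beta(X) A)` stacked over the bridge
#' moment components `(1-Y) (m(W,A,X) q - m(W,1,X) - m(W,0,X))`, together
#' with the Jacobian `Omega` of the mean estimating function with respect to
#' the parameters (central finite differences).
#'
#' @inheritParams estimate_ve
#' @param bridge A `tnd_bridge` whose family/parameters define `q`.
#' @param beta Log risk ratio value (scalar, or vector for effect
#'   modification) at which to evaluate.
#' @param tau Bridge parameters at which to evaluate.
#' @param moment The moment specification used for the bridge block.
#' @return A list with components `G` (n x (k + d) matrix), `Omega`
#'   ((k + d) x n_par Jacobian) and bookkeeping dimensions.
#' @export
stacked_moments <- function(data, bridge, beta, tau, moment = NULL,
                            effect_modifiers = NULL, tau_fixed = FALSE) {
  sample <- as_tnd_sample(data)
  s <- sample_arrays(sample)
  moment <- moment %||% bridge$moment %||%
    default_moment_spec(bridge$family, dw = ncol(s$W), dx = ncol(s$X))
  dmat <- em_design(s, effect_modifiers)
  if (is.null(dmat)) dmat <- matrix(1, s$n, 1, dimnames = list(NULL, "0"))
  k <- ncol(dmat)
  stopifnot(length(beta) == k)
  sgn <- (-1)^(1 - s$a)
  Xarg <- if (bridge$dx > 0) s$X

  G_beta <- function(b, tv) {
    q <- evaluate_bridge(bridge, s$a, s$Z, Xarg, tau = tv)
    if (isTRUE(bridge$floor_at_one)) q <- pmax(q, 1)
    sgn * q * s$y * exp(-drop(dmat %*% b) * s$a) * dmat
  }
  G_tau <- function(tv) {
    q <- evaluate_bridge(bridge, s$a, s$Z, Xarg, tau = tv)
    M_a <- moment$fn(s$W, s$a, s$X)
    M_1 <- moment$fn(s$W, rep(1, s$n), s$X)
    M_0 <- moment$fn(s$W, rep(0, s$n), s$X)
    (1 - s$y) * (M_a * q - M_1 - M_0)
  }

  if (tau_fixed) {
    G <- G_beta(beta, tau)
    mean_fn <- function(theta) colMeans(G_beta(theta, tau))
    Omega <- num_jacobian(mean_fn, beta)
  } else {
    G <- cbind(G_beta(beta, tau), G_tau(tau))
    mean_fn <- function(theta) {
      b <- theta[seq_len(k)]; tv <- theta[-seq_len(k)]
      c(colMeans(G_beta(b, tv)), colMeans(G_tau(tv)))
    }
    Omega <- num_jacobian(mean_fn, c(beta, tau))
  }
  list(G = G, Omega = Omega, n = s$n, k = k, tau_fixed = tau_fixed)
}

#' Sandwich covariance of the stacked estimator
#'
#' Computes the M-estimation (sandwich) covariance
#' `(Omega' Omega)^-1 Omega' Var(G) Omega (Omega' Omega)^-1 / n`
#' from the per-subject stacked estimating-function values and their
#' Jacobian. The projection form accommodates over-identified bridge moment
#' specifications. The output is symmetrised.
#'
#' @param infl Output of [stacked_moments()].
#' @return Symmetric positive semi-definite covariance matrix for the
#'   estimated parameters (`beta` block first).
#' @export
sandwich_covariance <- function(infl) {
  Omega <- infl$Omega
  qr_O <- qr(Omega)
  if (qr_O$rank < ncol(Omega)) {
    deficient <- setdiff(seq_len(ncol(Omega)), sort(qr_O$pivot[seq_len(qr_O$rank)]))
    abort(sprintf("Jacobian of the stacked moments is rank-deficient in parameter direction(s): %s",
                  paste(deficient, collapse = ", ")))
  }
  B <- cov(infl$G)
  bread <- solve(crossprod(Omega), t(Omega))
  Sigma <- bread %*% B %*% t(bread) / infl$n
  (Sigma + t(Sigma)) / 2
}

#' Wald confidence interval for vaccine effectiveness
#'
#' Transforms the endpoints of the Wald interval for the log risk ratio to
#' the VE scale, `VE = 1 - exp(beta)`; the interval order is swapped so the
#' lower VE bound comes from the upper `beta` bound.
#'
#' @param beta_hat Estimated log risk ratio.
#' @param se Its standard error (must be non-negative).
#' @param alpha Two-sided level (default 0.05).
#' @return Named vector `c(lower, upper)` on the VE scale.
#' @examples
#' wald_ci_ve(-2.80, 0.1378)
#' @export
wald_ci_ve <- function(beta_hat, se, alpha = 0.05) {
  stopifnot(se >= 0, alpha > 0, alpha < 1)
  zq <- qnorm(1 - alpha / 2)
  c(lower = 1 - exp(beta_hat + zq * se),
    upper = 1 - exp(beta_hat - zq * se))
}

#' @export
print.tnd_ve <- function(x, ...) {
  cat(sprintf("<tnd_ve> %s estimate from %d subjects (%d cases)\n",
              x$method, x$n, x$n_cases))
  cat(sprintf("  log RR: %.4f (SE %.4f)\n", x$beta[1], x$se[1]))
  cat(sprintf("  VE: %.1f%% (%d%% CI: %.1f%%, %.1f%%)\n",
              100 * x$ve, round(100 * (1 - x$alpha)),
              100 * x$ve_ci[1], 100 * x$ve_ci[2]))
  if (length(x$beta) > 1) {
    cat("  effect-modification terms:\n")
    print(stats::setNames(round(x$beta, 4), names(x$beta)))
  }
  cat(" ", x$scale_note, "\n")
  invisible(x)
}

#' Tidy a fitted VE estimate
#'
#' @param x A `tnd_ve` object.
#' @param components `"beta"` (default) for the log-risk-ratio term(s), or
#'   `"all"` to append the bridge parameters.
#' @param ... Unused.
#' @return A tibble with one row per term: estimate, standard error and
#'   Wald limits on the log risk ratio scale.
#' @export
tidy.tnd_ve <- function(x, components = c("beta", "all"), ...) {
  components <- match.arg(components)
  zq <- qnorm(1 - x$alpha / 2)
  out <- tibble::tibble(
    term = names(x$beta),
    estimate = unname(x$beta),
    std.error = unname(x$se),
    conf.low = unname(x$beta - zq * x$se),
    conf.high = unname(x$beta + zq * x$se)
  )
  if (components == "all" && !x$tau_fixed && !is.null(x$cov)) {
    kk <- length(x$beta)
    tau_se <- sqrt(diag(x$cov))[-seq_len(kk)]
    out <- dplyr::bind_rows(out, tibble::tibble(
      term = paste0("tau", seq_along(x$tau) - 1),
      estimate = x$tau,
      std.error = tau_se,
      conf.low = x$tau - zq * tau_se,
      conf.high = x$tau + zq * tau_se
    ))
  }
  out
}

#' One-row summary of a fitted VE estimate
#'
#' @param x A `tnd_ve` object.
#' @param ... Unused.
#' @export
glance.tnd_ve <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    beta = unname(x$beta[1]),
    se = unname(x$se[1]),
    ve = x$ve,
    ve_low = unname(x$ve_ci[1]),
    ve_high = unname(x$ve_ci[2]),
    alpha = x$alpha,
    n = x$n,
    n_cases = x$n_cases,
    converged = is.null(x$convergence) || isTRUE(x$convergence$converged),
    scale = x$scale_note
  )
}
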