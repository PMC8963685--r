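#' Oracle negative-control estimator
#'
#' Runs the closed-form log risk ratio estimator with the true (analytic)
#' treatment confounding bridge, treating its parameters as known; variance
#' comes from the `beta` block of the sandwich with `tau` fixed. Available
#' in simulation only, as a benchmark isolating the cost of estimating the
#' bridge from the test-negative controls.
#'
#' @param data A [tnd_sample()].
#' @param oracle_bridge A `tnd_bridge` from [oracle_bridge_binary()] or
#'   [oracle_bridge_continuous()] (or the generating configuration itself).
#' @param alpha Interval level.
#' @return A `tnd_ve` object with `method = "NC-Oracle"`.
#' @export
estimate_ve_nc_oracle <- function(data, oracle_bridge, alpha = 0.05) {
  if (inherits(oracle_bridge, "tnd_dgp")) {
    oracle_bridge <- if (inherits(oracle_bridge, "binary_dgp")) {
      oracle_bridge_binary(oracle_bridge)
    } else {
      oracle_bridge_continuous(oracle_bridge)
    }
  }
  estimate_ve(data, bridge = oracle_bridge, alpha = alpha, tau_fixed = TRUE)
}

#' Infeasible IPTW estimator using the latent confounder
#'
#' The inverse-probability-of-treatment-weighted log risk ratio over the
#' selected sample, using the exact inverse treatment probabilities from the
#' latent confounder: `log(sum Q A Y / sum Q (1 - A) Y)` over rows with
#' `S = 1`. Infeasible outside simulation; a positivity/selection benchmark.
#'
#' @param pop A `tnd_population` (the latent confounder is required).
#' @param config Generating configuration (defaults to the attached one).
#' @param alpha Interval level.
#' @return A `tnd_ve` object with `method = "IPTW-Oracle"`.
#' @export
estimate_ve_iptw <- function(pop, config = attr(pop, "config"), alpha = 0.05) {
  stopifnot(inherits(pop, "tnd_population"))
  q_all <- true_inverse_propensity(pop, config)
  sel <- pop$s == 1
  a <- pop$a[sel]; y <- pop$y[sel]; q <- q_all[sel]
  num <- sum(q * a * y); den <- sum(q * (1 - a) * y)
  if (num <= 0) abort("no vaccinated cases: the log risk ratio estimate is undefined")
  if (den <= 0) abort("no unvaccinated cases: the log risk ratio estimate is undefined")
  beta <- log(num / den)
  # one-dimensional sandwich with Q known
  G <- (-1)^(1 - a) * q * y * exp(-beta * a)
  omega <- -mean(q * a * y * exp(-beta * a))
  se <- sqrt(stats::var(G) / omega^2 / length(a))
  zq <- qnorm(1 - alpha / 2)
  structure(list(
    beta = c(beta = beta), se = c(beta = se),
    cov = matrix(se^2, 1, 1), tau = NULL, bridge = NULL,
    ve = 1 - exp(beta), ve_ci = wald_ci_ve(beta, se, alpha),
    beta_ci = c(lower = beta - zq * se, upper = beta + zq * se),
    alpha = alpha, n = sum(sel), n_cases = sum(y),
    tau_fixed = TRUE, method = "IPTW-Oracle",
    scale_note = "RR (latent-confounder IPTW)",
    convergence = NULL, influence = NULL
  ), class = "tnd_ve")
}

#' Logistic regression comparator
#'
#' Maximum-likelihood logistic regression of the test result on vaccination
#' (and selected covariates) within the TND sample: the conventional
#' covariate-adjusted TND analysis. The coefficient on vaccination is a log
#' odds ratio; it ignores both unmeasured confounding and the collider
#' structure of outcome-dependent selection.
#'
#' @param data A [tnd_sample()].
#' @param covariates Character vector of covariate columns (`"x1"`, ...) to
#'   adjust for; `NULL` for the unadjusted model.
#' @param alpha Interval level.
#' @return A `tnd_ve` object with `method = "Logistic"`, on the log
#'   odds-ratio scale.
#' @export
estimate_ve_logistic <- function(data, covariates = NULL, alpha = 0.05) {
  sample <- as_tnd_sample(data)
  rhs <- paste(c("a", covariates), collapse = " + ")
  fit <- glm(stats::as.formula(paste("y ~", rhs)), data = sample,
             family = binomial())
  if (!fit$converged) abort("logistic regression did not converge (separation?)")
  if (anyNA(coef(fit))) abort("singular design in logistic regression")
  beta <- unname(coef(fit)["a"])
  se <- sqrt(vcov(fit)["a", "a"])
  zq <- qnorm(1 - alpha / 2)
  structure(list(
    beta = c(beta = beta), se = c(beta = se),
    cov = matrix(se^2, 1, 1), tau = NULL, bridge = NULL,
    ve = 1 - exp(beta), ve_ci = wald_ci_ve(beta, se, alpha),
    beta_ci = c(lower = beta - zq * se, upper = beta + zq * se),
    alpha = alpha, n = nrow(sample), n_cases = sum(sample$y),
    tau_fixed = TRUE, method = "Logistic",
    scale_note = "OR (logistic regression, no latent-confounder adjustment)",
    convergence = list(converged = fit$converged), influence = NULL,
    glm = fit
  ), class = "tnd_ve")
}

#' Negative-control bias-detection regressions
#'
#' If the negative controls are valid and there is no residual confounding,
#' the NCE should be conditionally unassociated with both the test result
#' and the NCO given treatment and covariates. Fits (i) a logistic
#' regression of `Y` on `Z` adjusting for `(A, X)` and (ii) a regression of
#' `W` on `Z` adjusting for `(A, X)` (logistic when `W` is binary, linear
#' otherwise); significant `Z` coefficients flag hidden bias.
#'
#' @param data A [tnd_sample()].
#' @return A tibble with one row per test: outcome, estimate, std.error,
#'   p.value and the model used.
#' @export
nce_bias_tests <- function(data) {
  sample <- as_tnd_sample(data)
  nm <- names(sample)
  xs <- grep("^x[0-9]+$", nm, value = TRUE)
  zs <- grep("^z[0-9]+$", nm, value = TRUE)
  ws <- grep("^w[0-9]+$", nm, value = TRUE)
  adj <- paste(c(zs, "a", xs), collapse = " + ")
  one_fit <- function(outcome, family_name) {
    f <- stats::as.formula(paste(outcome, "~", adj))
    fit <- if (family_name == "logistic") glm(f, sample, family = binomial())
           else stats::lm(f, sample)
    if (anyNA(coef(fit))) abort(sprintf("collinear design in the %s regression", outcome))
    sm <- summary(fit)$coefficients
    tibble::tibble(outcome = outcome, term = zs,
                   estimate = sm[zs, 1], std.error = sm[zs, 2],
                   p.value = sm[zs, 4], model = family_name)
  }
  w_binary <- all(unlist(sample[ws]) %in% 0:1)
  dplyr::bind_rows(
    one_fit("y", "logistic"),
    one_fit(ws[1], if (w_binary) "logistic" else "linear")
  )
}

#' Hausman comparison of two estimators
#'
#' Classical scalar Hausman chi-squared statistic
#' `T = (b1 - b2)^2 / (V1 - V2)` comparing an estimator consistent under
#' weaker assumptions (the negative-control estimator, assumed less
#' efficient, first argument) with one requiring stronger assumptions
#' (e.g. logistic regression), referred to a chi-square distribution with
#' one degree of freedom. Both estimates must be on the same log scale.
#' When the variance difference is not positive the statistic is undefined
#' and `NA` is returned with a warning.
#'
#' @param fit1,fit2 `tnd_ve` objects (or lists with `beta` and `se`).
#' @return A tibble with `statistic`, `df`, `p.value`.
#' @examples
#' hausman_test(list(beta = -2.80, se = 0.1378), list(beta = -3.18, se = 0.0867))
#' @export
hausman_test <- function(fit1, fit2) {
  b1 <- unname(fit1$beta[1]); b2 <- unname(fit2$beta[1])
  v1 <- unname(fit1$se[1])^2; v2 <- unname(fit2$se[1])^2
  dv <- v1 - v2
  if (dv <= 0) {
    warn("variance difference is not positive; Hausman statistic undefined")
    return(tibble::tibble(statistic = NA_real_, df = 1L, p.value = NA_real_))
  }
  stat <- (b1 - b2)^2 / dv
  tibble::tibble(statistic = stat, df = 1L,
                 p.value = pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Nonparametric bootstrap of the negative-control VE estimator
#'
#' Resamples subjects with replacement and refits the full pipeline (bridge
#' estimation plus log risk ratio); a direct check on the sandwich variance.
#'
#' @param data A [tnd_sample()].
#' @param draws Number of bootstrap resamples.
#' @param seed Optional seed.
#' @param ... Passed to [estimate_ve()].
#' @return A tibble with one row per successful resample (`beta`, `ve`).
#' @export
bootstrap_ve <- function(data, draws = 500, seed = NULL, ...) {
  sample <- as_tnd_sample(data)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(sample)
  res <- purrr::map(seq_len(draws), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    fit <- tryCatch(
      suppressWarnings(estimate_ve(sample[idx, ], ...)),
      error = function(e) NULL
    )
    if (is.null(fit)) NULL else tibble::tibble(draw = b, beta = unname(fit$beta[1]), ve = fit$ve)
  })
  dplyr::bind_rows(res)
}
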