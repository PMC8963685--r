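#' Binary-setting data-generating configuration
#'
#' Configures a target population with a binary unmeasured confounder `U`,
#' binary NCE `Z`, binary NCO `W`, an auxiliary flu-like illness indicator
#' `D`, a log-linear infection risk model
#' `Y | A, U ~ Bernoulli(exp(eta0y + beta0 A + etauy U))`, and
#' outcome-dependent selection that can only trigger when at least one of
#' `Y`, `W`, `D` equals one. Selection depends on `(Y, W, D)` alone, so
#' treatment-independent sampling holds by construction.
#'
#' The outcome coefficients are calibrated rather than set directly: given
#' the target prevalence among the unvaccinated (`prev_unvax`) and the
#' confounding ratio `c = E[g(U) | A = 1] / E[g(U) | A = 0]` (the
#' multiplicative bias a naive prevalence comparison would suffer in the
#' target population), `etauy` and `eta0y` are solved in closed form. The
#' defaults reproduce an unvaccinated prevalence of 0.75% and an overall
#' infection prevalence of about 0.55% at `beta0 = log(0.2)`.
#'
#' @param beta0 True log causal risk ratio of infection under vaccination.
#' @param n_pop Target population size per draw.
#' @param p_u `P(U = 1)`.
#' @param p_a Length-2 vector `P(A = 1 | U = 0)`, `P(A = 1 | U = 1)`.
#' @param z_coef Logistic coefficients `(intercept, u, a)` for
#'   `P(Z = 1 | A, U)`.
#' @param p_w,p_d Length-2 vectors `P(W = 1 | U)` and `P(D = 1 | U)`.
#' @param prev_unvax Target `P(Y = 1 | A = 0)` in the population.
#' @param confounding_ratio Target `E[g(U)|A=1] / E[g(U)|A=0]`.
#' @param sel_case `P(S = 1 | Y = 1)`.
#' @param sel_ctrl `P(S = 1 | Y = 0, W = 1 or D = 1)`.
#' @return An object of class `c("binary_dgp", "tnd_dgp")`.
#' @export
binary_dgp_config <- function(beta0 = 0, n_pop = 1e6,
                              p_u = 0.3, p_a = c(0.15, 0.80),
                              z_coef = c(qlogis(0.1), qlogis(0.85) - qlogis(0.1), 0.3),
                              p_w = c(0.10, 0.70), p_d = c(0.05, 0.12),
                              prev_unvax = 0.0075, confounding_ratio = 1.25,
                              sel_case = 0.15, sel_ctrl = 0.024) {
  probs <- c(p_u, p_a, p_w, p_d, sel_case, sel_ctrl, prev_unvax)
  stopifnot(all(probs >= 0), all(probs <= 1), confounding_ratio > 0)
  # P(U = 1 | A = a) implied by the treatment model
  pi0 <- p_u * (1 - p_a[2]) / (p_u * (1 - p_a[2]) + (1 - p_u) * (1 - p_a[1]))
  pi1 <- p_u * p_a[2] / (p_u * p_a[2] + (1 - p_u) * p_a[1])
  # c = (1 + k pi1) / (1 + k pi0) with k = exp(etauy) - 1
  denom <- pi1 - confounding_ratio * pi0
  if (abs(confounding_ratio - 1) < 1e-12) {
    k <- 0
  } else {
    if (denom <= 0) abort("confounding_ratio is unattainable for this treatment model")
    k <- (confounding_ratio - 1) / denom
  }
  if (k <= -1) abort("confounding_ratio is unattainable for this treatment model")
  etauy <- log1p(k)
  eta0y <- log(prev_unvax / (1 + k * pi0))
  max_risk <- exp(eta0y + max(beta0, 0) + max(etauy, 0))
  if (max_risk > 1) {
    abort(sprintf("invalid risk model: maximal stratum risk exp(eta0y + max(beta0,0) + etauy) = %.3f > 1",
                  max_risk))
  }
  structure(list(
    setting = "binary", beta0 = beta0, n_pop = n_pop,
    p_u = p_u, p_a = p_a, z_coef = z_coef, p_w = p_w, p_d = p_d,
    eta0y = eta0y, etauy = etauy,
    prev_unvax = prev_unvax, confounding_ratio = confounding_ratio,
    sel_case = sel_case, sel_ctrl = sel_ctrl
  ), class = c("binary_dgp", "tnd_dgp"))
}

#' Continuous-setting data-generating configuration
#'
#' Standard-normal covariate `X` and unmeasured confounder `U`; logistic
#' treatment `A | U, X`; Gaussian NCE `Z | A, U, X` and NCO `W | U, X`;
#' log-linear infection risk
#' `Y | A, U, X ~ Bernoulli(exp(mu0y + beta0 A + muuy U + muxy X + muuxy U X))`;
#' auxiliary illness `D | U, X` (logistic); selection triggers only when
#' `Y` or `D` is nonzero. `mu0y` is calibrated by Gauss-Hermite quadrature
#' so that the unvaccinated prevalence matches `prev_unvax` (default 0.34%).
#'
#' @param beta0,n_pop As in [binary_dgp_config()].
#' @param treat Named coefficients `(mu0a, muua, muxa)` of the logistic
#'   treatment model.
#' @param nce Named coefficients `(mu0z, muaz, muuz, muxz, sigmaz)` of the
#'   Gaussian NCE model; `muuz` must be nonzero for a bridge to exist.
#' @param nco Named coefficients `(mu0w, muuw, muxw, sigmaw)` of the
#'   Gaussian NCO model (independent of `A`, `Z` given `U`, `X`).
#' @param outcome Named coefficients `(muuy, muxy, muuxy)` of the risk model.
#' @param aux Named logistic coefficients `(d0, du, dx)` for `D`.
#' @param prev_unvax Target `P(Y = 1 | A = 0)`.
#' @param sel_case `P(S = 1 | Y = 1)`; `sel_ctrl` is `P(S = 1 | Y = 0, D = 1)`.
#' @param sel_ctrl See `sel_case`.
#' @param beta_x Effect-modification slope: the log risk ratio at covariate
#'   value `x` is `beta0 + beta_x * x` (0 for a homogeneous effect).
#' @return An object of class `c("continuous_dgp", "tnd_dgp")`.
#' @export
continuous_dgp_config <- function(beta0 = 0, n_pop = 1e6,
                                  treat = c(mu0a = -0.6, muua = 0.4, muxa = 0.3),
                                  nce = c(mu0z = 0, muaz = 0.2, muuz = 1, muxz = 0.3, sigmaz = 1),
                                  nco = c(mu0w = 0, muuw = 0.8, muxw = 0.3, sigmaw = 1),
                                  outcome = c(muuy = 0.3, muxy = 0.2, muuxy = 0.05),
                                  aux = c(d0 = -2.6, du = 0.5, dx = 0.3),
                                  prev_unvax = 0.0034,
                                  sel_case = 0.3, sel_ctrl = 0.06,
                                  beta_x = 0) {
  if (abs(nce[["muuz"]]) < 1e-12) {
    abort("`muuz` must be nonzero: the NCE must respond to the confounder for a bridge function to exist")
  }
  # calibrate mu0y: E[exp(muuy U + muxy X + muuxy U X) | A = 0] exp(mu0y) = prev_unvax
  gh <- pracma::gaussHermite(40)
  grid_u <- sqrt(2) * gh$x
  ww <- outer(gh$w, gh$w) / pi
  uu <- matrix(grid_u, 40, 40)
  xx <- t(uu)
  p_a0 <- 1 - expit(treat[["mu0a"]] + treat[["muua"]] * uu + treat[["muxa"]] * xx)
  gfun <- exp(outcome[["muuy"]] * uu + outcome[["muxy"]] * xx + outcome[["muuxy"]] * uu * xx)
  mu0y <- log(prev_unvax * sum(ww * p_a0) / sum(ww * gfun * p_a0))
  structure(list(
    setting = "continuous", beta0 = beta0, n_pop = n_pop,
    treat = treat, nce = nce, nco = nco, outcome = outcome, aux = aux,
    mu0y = mu0y, prev_unvax = prev_unvax,
    sel_case = sel_case, sel_ctrl = sel_ctrl, beta_x = beta_x
  ), class = c("continuous_dgp", "tnd_dgp"))
}

#' Named data-generating presets
#'
#' `"binary-rare"` and `"continuous-rare"` are the calibrated rare-infection
#' settings (unvaccinated prevalence 0.75% and 0.34%); `"binary-nonrare"`
#' raises the unvaccinated prevalence to 10% (with selection scaled down to
#' keep sample sizes comparable) to probe sensitivity to the rare-disease
#' approximation, under which the control-estimated bridge is biased except
#' under the null of no vaccine effect.
#'
#' @param name Preset name.
#' @param beta0 True log risk ratio.
#' @param n_pop Population size per draw.
#' @return A DGP configuration object.
#' @export
dgp_preset <- function(name = c("binary-rare", "continuous-rare", "binary-nonrare"),
                       beta0 = 0, n_pop = 1e6) {
  switch(match.arg(name),
    "binary-rare" = binary_dgp_config(beta0 = beta0, n_pop = n_pop),
    "binary-nonrare" = binary_dgp_config(beta0 = beta0, n_pop = n_pop,
                                         prev_unvax = 0.10,
                                         sel_case = 0.012, sel_ctrl = 0.012),
    "continuous-rare" = continuous_dgp_config(beta0 = beta0, n_pop = n_pop)
  )
}

#' Simulate a target population
#'
#' Draws the full latent-variable population (confounder `U`, treatment,
#' negative controls, auxiliary illness, infection outcome and selection
#' indicator) from a DGP configuration. The latent columns `u`, `d`, `s`
#' are present in the population frame but are never exported to the
#' analytic sample by [select_tnd_sample()].
#'
#' @param config A DGP configuration from [binary_dgp_config()],
#'   [continuous_dgp_config()] or [dgp_preset()].
#' @param seed Optional integer seed for reproducibility.
#' @param n Population size (defaults to `config$n_pop`).
#' @return A tibble of class `tnd_population` with attribute `config`.
#' @export
simulate_population <- function(config, seed = NULL, n = config$n_pop) {
  UseMethod("simulate_population")
}

#' @export
simulate_population.binary_dgp <- function(config, seed = NULL, n = config$n_pop) {
  if (!is.null(seed)) set.seed(seed)
  cf <- config
  u <- rbinom(n, 1, cf$p_u)
  a <- rbinom(n, 1, cf$p_a[u + 1])
  z <- rbinom(n, 1, expit(cf$z_coef[1] + cf$z_coef[2] * u + cf$z_coef[3] * a))
  w <- rbinom(n, 1, cf$p_w[u + 1])
  d <- rbinom(n, 1, cf$p_d[u + 1])
  y <- rbinom(n, 1, exp(cf$eta0y + cf$beta0 * a + cf$etauy * u))
  p_s <- ifelse(y == 1, cf$sel_case, ifelse(w == 1 | d == 1, cf$sel_ctrl, 0))
  s <- rbinom(n, 1, p_s)
  out <- tibble::tibble(u = u, a = a, z1 = z, w1 = w, d = d, y = y, s = s)
  attr(out, "config") <- config
  class(out) <- c("tnd_population", class(out))
  out
}

#' @export
simulate_population.continuous_dgp <- function(config, seed = NULL, n = config$n_pop) {
  if (!is.null(seed)) set.seed(seed)
  cf <- config
  u <- rnorm(n)
  x <- rnorm(n)
  a <- rbinom(n, 1, expit(cf$treat[["mu0a"]] + cf$treat[["muua"]] * u + cf$treat[["muxa"]] * x))
  z <- rnorm(n, cf$nce[["mu0z"]] + cf$nce[["muaz"]] * a + cf$nce[["muuz"]] * u +
               cf$nce[["muxz"]] * x, cf$nce[["sigmaz"]])
  w <- rnorm(n, cf$nco[["mu0w"]] + cf$nco[["muuw"]] * u + cf$nco[["muxw"]] * x,
             cf$nco[["sigmaw"]])
  risk <- exp(cf$mu0y + (cf$beta0 + (cf$beta_x %||% 0) * x) * a +
                cf$outcome[["muuy"]] * u +
                cf$outcome[["muxy"]] * x + cf$outcome[["muuxy"]] * u * x)
  n_bad <- sum(risk > 1)
  if (n_bad > 0) {
    abort(sprintf("invalid risk model: %d subject(s) have model risk > 1; rescale the outcome coefficients",
                  n_bad))
  }
  y <- rbinom(n, 1, risk)
  dd <- rbinom(n, 1, expit(cf$aux[["d0"]] + cf$aux[["du"]] * u + cf$aux[["dx"]] * x))
  p_s <- ifelse(y == 1, cf$sel_case, ifelse(dd == 1, cf$sel_ctrl, 0))
  s <- rbinom(n, 1, p_s)
  out <- tibble::tibble(u = u, x1 = x, a = a, z1 = z, w1 = w, d = dd, y = y, s = s)
  attr(out, "config") <- config
  class(out) <- c("tnd_population", class(out))
  out
}

#' Select the test-negative design sample from a population
#'
#' Keeps the rows with `S = 1` and exports only the observable columns
#' (treatment, test result, negative controls, measured covariates): the
#' latent confounder, the auxiliary illness indicator and the selection
#' indicator are masked.
#'
#' @param pop A `tnd_population`.
#' @return A [tnd_sample()] with attributes `n_selected` and
#'   `case_fraction`.
#' @export
select_tnd_sample <- function(pop) {
  stopifnot(inherits(pop, "tnd_population"))
  sel <- pop[pop$s == 1, , drop = FALSE]
  if (nrow(sel) == 0) abort("no subjects were selected (S = 1) in this population")
  has_x <- "x1" %in% names(sel)
  out <- tnd_sample(as.data.frame(sel), a = "a", y = "y", z = "z1", w = "w1",
                    x = if (has_x) "x1")
  attr(out, "n_selected") <- nrow(out)
  attr(out, "case_fraction") <- mean(out$y)
  out
}

#' Exact inverse treatment probabilities from the latent confounder
#'
#' Returns `Q(A_i, U_i, X_i) = 1 / P(A = A_i | U_i, X_i)` for every subject,
#' using the generating configuration and the latent confounder. Available
#' in simulation only; used by the infeasible IPTW comparator.
#'
#' @param pop A `tnd_population`.
#' @param config Its generating configuration (defaults to the attached one).
#' @return Numeric vector of per-subject inverse probabilities (all >= 1).
#' @export
true_inverse_propensity <- function(pop, config = attr(pop, "config")) {
  stopifnot(inherits(pop, "tnd_population"))
  if (config$setting == "binary") {
    p1 <- config$p_a[pop$u + 1]
  } else {
    p1 <- expit(config$treat[["mu0a"]] + config$treat[["muua"]] * pop$u +
                  config$treat[["muxa"]] * pop$x1)
  }
  1 / ifelse(pop$a == 1, p1, 1 - p1)
}

#' Population prevalence and rare-disease diagnostics
#'
#' Reports infection prevalence by vaccination arm and an empirical upper
#' bound `delta_hat` on the stratum-specific infection risk, the quantity
#' controlling the quality of the rare-disease approximation used when the
#' bridge function is estimated from test-negative controls. Strata are the
#' coarse cells of treatment, NCO, confounder and covariate (continuous
#' variables are cut at their tertiles); cells with fewer than `min_cell`
#' subjects are ignored.
#'
#' @param pop A `tnd_population`.
#' @param min_cell Minimum stratum size entering the maximum.
#' @return A list of class `tnd_prevalence` with elements `by_arm`
#'   (tibble), `overall` and `delta_hat`.
#' @export
prevalence_report <- function(pop, min_cell = 200) {
  stopifnot(inherits(pop, "tnd_population"))
  by_arm <- pop |>
    dplyr::group_by(.data$a) |>
    dplyr::summarise(n = dplyr::n(), prevalence = mean(.data$y), .groups = "drop")
  coarse <- function(v) {
    if (length(unique(v)) <= 2) return(v)
    cut(v, breaks = unique(quantile(v, c(0, 1/3, 2/3, 1))), include.lowest = TRUE)
  }
  strata <- interaction(pop$a, coarse(pop$w1), coarse(pop$u),
                        if ("x1" %in% names(pop)) coarse(pop$x1) else 0,
                        drop = TRUE)
  risks <- tapply(pop$y, strata, mean)
  sizes <- tapply(pop$y, strata, length)
  eligible <- risks[sizes >= min_cell]
  delta_hat <- if (length(eligible)) max(eligible) else max(risks)
  structure(list(by_arm = by_arm, overall = mean(pop$y), delta_hat = delta_hat),
            class = "tnd_prevalence")
}

#' @export
print.tnd_prevalence <- function(x, ...) {
  cat("<tnd_prevalence>\n")
  print(x$by_arm)
  cat(sprintf("overall prevalence: %.4f%%; max coarse-stratum risk (delta_hat): %.4f\n",
              100 * x$overall, x$delta_hat))
  invisible(x)
}
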