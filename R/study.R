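#' Specify a Monte Carlo simulation study
#'
#' Describes a bias/coverage experiment over a grid of true log risk
#' ratios: per replicate a target population is simulated, the TND sample
#' selected, and each requested estimator run; per-replicate estimates and
#' nominal-95% interval coverage are aggregated.
#'
#' @param setting `"binary"` or `"continuous"` (selects the preset family),
#'   or a full DGP configuration to be used as template.
#' @param beta0 Grid of true log risk ratios.
#' @param n_pop Population size per replicate.
#' @param replicates Number of Monte Carlo replicates per `beta0`.
#' @param estimators Subset of `"NC"`, `"NC-Oracle"`, `"IPTW-Oracle"`,
#'   `"Logistic"`.
#' @param preset Preset name used when `setting` is a string (default the
#'   rare preset of the chosen setting).
#' @param seed Master seed; per-replicate seeds are split off
#'   deterministically.
#' @return An object of class `tnd_study_spec`.
#' @export
study_spec <- function(setting = c("binary", "continuous"),
                       beta0 = c(-1.609, -0.693, -0.357, 0),
                       n_pop = 1e6, replicates = 300,
                       estimators = c("NC", "NC-Oracle", "Logistic"),
                       preset = NULL, seed = 1) {
  stopifnot(replicates >= 1, length(estimators) >= 1)
  estimators <- match.arg(estimators,
                          c("NC", "NC-Oracle", "IPTW-Oracle", "Logistic"),
                          several.ok = TRUE)
  if (!inherits(setting, "tnd_dgp")) {
    setting <- match.arg(setting)
    preset <- preset %||% paste0(setting, "-rare")
    config <- dgp_preset(preset, n_pop = n_pop)
  } else {
    config <- setting
    config$n_pop <- n_pop
  }
  structure(list(config = config, beta0 = beta0, n_pop = n_pop,
                 replicates = as.integer(replicates), estimators = estimators,
                 seed = seed),
            class = "tnd_study_spec")
}

with_beta0 <- function(config, beta0) {
  config$beta0 <- beta0
  if (inherits(config, "binary_dgp")) {
    max_risk <- exp(config$eta0y + max(beta0, 0) + max(config$etauy, 0))
    if (max_risk > 1) abort("invalid risk model for this beta0")
  }
  config
}

run_estimator <- function(est, pop, sample, config, oracle) {
  switch(est,
    "NC" = estimate_ve(sample,
                       family = if (config$setting == "binary") "saturated" else "logistic"),
    "NC-Oracle" = estimate_ve_nc_oracle(sample, oracle),
    "IPTW-Oracle" = estimate_ve_iptw(pop, config),
    "Logistic" = estimate_ve_logistic(
      sample, covariates = if (config$setting == "continuous") "x1")
  )
}

#' Run a Monte Carlo simulation study
#'
#' Executes the experiment described by a [study_spec()]: per replicate and
#' per true `beta0`, simulate the population, select the TND sample, apply
#' every requested estimator, and record the estimate, its standard error
#' and whether the nominal-95% Wald interval covers the truth. Replicate
#' failures (non-convergence, empty treatment arms) are counted and
#' excluded from the aggregates rather than propagated.
#'
#' @param spec A [study_spec()].
#' @param progress Print a line per scenario.
#' @return A tibble of class `tnd_study` with one row per
#'   `beta0 x estimator`: mean bias, empirical SD, mean estimated SE,
#'   empirical 95% coverage and failure count. The per-replicate draws are
#'   attached as attribute `draws`.
#' @export
run_simulation_study <- function(spec, progress = FALSE) {
  stopifnot(inherits(spec, "tnd_study_spec"))
  set.seed(spec$seed)
  rep_seeds <- matrix(sample.int(2147483646L, spec$replicates * length(spec$beta0)),
                      nrow = spec$replicates)
  draws <- list()
  for (ib in seq_along(spec$beta0)) {
    b0 <- spec$beta0[ib]
    config <- with_beta0(spec$config, b0)
    oracle <- if (inherits(config, "binary_dgp")) oracle_bridge_binary(config)
              else oracle_bridge_continuous(config)
    for (r in seq_len(spec$replicates)) {
      pop <- simulate_population(config, seed = rep_seeds[r, ib])
      sample <- select_tnd_sample(pop)
      for (est in spec$estimators) {
        fit <- tryCatch(
          suppressWarnings(run_estimator(est, pop, sample, config, oracle)),
          error = function(e) NULL
        )
        draws[[length(draws) + 1]] <- if (is.null(fit)) {
          tibble::tibble(beta0 = b0, estimator = est, replicate = r,
                         estimate = NA_real_, se = NA_real_, covered = NA)
        } else {
          tibble::tibble(beta0 = b0, estimator = est, replicate = r,
                         estimate = unname(fit$beta[1]), se = unname(fit$se[1]),
                         covered = b0 >= fit$beta_ci[1] && b0 <= fit$beta_ci[2])
        }
      }
    }
    if (progress) {
      message(sprintf("beta0 = %.3f done (%d replicates)", b0, spec$replicates))
    }
  }
  draws <- dplyr::bind_rows(draws)
  out <- draws |>
    dplyr::group_by(.data$beta0, .data$estimator) |>
    dplyr::summarise(
      replicates = dplyr::n(),
      failures = sum(is.na(.data$estimate)),
      bias = mean(.data$estimate - .data$beta0, na.rm = TRUE),
      sd = stats::sd(.data$estimate, na.rm = TRUE),
      mean_se = mean(.data$se, na.rm = TRUE),
      coverage = mean(.data$covered, na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::mutate(mc_se = .data$sd / sqrt(.data$replicates - .data$failures))
  attr(out, "draws") <- draws
  attr(out, "spec") <- spec
  class(out) <- c("tnd_study", class(out))
  out
}

#' Plot bias and coverage of a simulation study
#'
#' Two-panel display: mean bias of each estimator (with 2 Monte Carlo SE
#' error bars) and empirical coverage of the nominal-95% interval (with the
#' binomial Monte Carlo band around 0.95), across the `beta0` grid.
#'
#' @param object A `tnd_study`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tnd_study <- function(object, ...) {
  R <- max(object$replicates - object$failures)
  band <- 3 * sqrt(0.95 * 0.05 / R)
  long <- dplyr::bind_rows(
    dplyr::transmute(object, .data$beta0, .data$estimator, metric = "bias",
                     value = .data$bias, low = .data$bias - 2 * .data$mc_se,
                     high = .data$bias + 2 * .data$mc_se, ref = 0),
    dplyr::transmute(object, .data$beta0, .data$estimator, metric = "coverage",
                     value = .data$coverage, low = NA_real_, high = NA_real_,
                     ref = 0.95)
  )
  ggplot2::ggplot(long, ggplot2::aes(x = factor(round(.data$beta0, 3)),
                                     y = .data$value,
                                     colour = .data$estimator,
                                     group = .data$estimator)) +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$ref), linetype = 2,
                        colour = "grey40") +
    ggplot2::geom_rect(
      data = tibble::tibble(metric = "coverage"),
      ggplot2::aes(xmin = -Inf, xmax = Inf, ymin = 0.95 - band, ymax = 0.95 + band),
      inherit.aes = FALSE, alpha = 0.15, fill = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$low, ymax = .data$high),
                             position = ggplot2::position_dodge(width = 0.4),
                             na.rm = TRUE) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "true log risk ratio", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' @export
print.tnd_study <- function(x, ...) {
  cat("<tnd_study> Monte Carlo bias/coverage summary\n")
  NextMethod()
}
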