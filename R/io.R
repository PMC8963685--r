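#' Read a TND sample from CSV
#'
#' Reads a comma-separated file with a header and builds a validated
#' [tnd_sample()] from an explicit column mapping. Negative-control roles
#' are analyst-declared: nothing is inferred from column names. Rows with
#' missing values in mapped columns are dropped with a warning; non-binary
#' values in the treatment or test-result columns are an error.
#'
#' @param path CSV file path.
#' @param a,y,z,w,x Column mapping, as in [tnd_sample()].
#' @return A [tnd_sample()].
#' @export
read_tnd_csv <- function(path, a = "a", y = "y", z = "z1", w = "w1", x = NULL) {
  if (!file.exists(path)) abort(sprintf("input file not found: %s", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  latent <- intersect(names(df), c("u", "d", "s"))
  if (length(latent)) {
    warn(paste0("latent column(s) present in input and ignored: ",
                paste(latent, collapse = ", ")))
  }
  tnd_sample(df, a = a, y = y, z = z, w = w, x = x)
}

#' Write a sample or population to CSV
#'
#' @param data A [tnd_sample()] or `tnd_population` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tnd_csv <- function(data, path) {
  readr::write_csv(tibble::as_tibble(data), path, progress = FALSE)
  invisible(path)
}

#' Serialize an estimation result to JSON
#'
#' Versioned schema holding the point estimate, sandwich standard error,
#' VE with its Wald interval, bridge parameters, convergence report, scale
#' note, sample size and seed/configuration provenance. Floats are written
#' at full precision.
#'
#' @param fit A `tnd_ve` object.
#' @param path Output path.
#' @param seed Seed used to produce the input, if any (provenance).
#' @param config Optional configuration list to embed (hashed).
#' @param timestamp Include a creation timestamp field.
#' @return `path`, invisibly.
#' @export
write_result_json <- function(fit, path, seed = NULL, config = NULL,
                              timestamp = TRUE) {
  stopifnot(inherits(fit, "tnd_ve"))
  doc <- list(
    schema = "tndnc/result/v1",
    method = fit$method,
    beta = unname(fit$beta),
    se = unname(fit$se),
    beta_ci = as.list(fit$beta_ci),
    ve = fit$ve,
    ve_ci = as.list(fit$ve_ci),
    alpha = fit$alpha,
    tau = fit$tau,
    convergence = fit$convergence,
    scale = fit$scale_note,
    n = fit$n,
    n_cases = fit$n_cases,
    seed = seed,
    config = config,
    config_hash = if (!is.null(config)) rlang::hash(config)
  )
  if (timestamp) doc$created <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Assemble a run configuration
#'
#' @param command One of `"estimate"`, `"simulate"`, `"study"`,
#'   `"diagnose"`.
#' @param input Input CSV path (estimate/diagnose).
#' @param out Output path stem for artifacts.
#' @param mapping Named list of column names (`a`, `y`, `z`, `w`, `x`).
#' @param bridge Bridge family: `"saturated"` or `"logistic"`.
#' @param alpha Interval level in (0, 1).
#' @param seed Integer seed.
#' @param preset DGP preset name (simulate/study).
#' @param beta0 True log risk ratio (simulate) or grid (study).
#' @param n_pop Population size (simulate/study).
#' @param replicates Replicates (study).
#' @param estimators Estimator list (study).
#' @return A list of class `tnd_run_config`.
#' @export
run_config <- function(command = c("estimate", "simulate", "study", "diagnose"),
                       input = NULL, out = "tndnc_result.json",
                       mapping = list(a = "a", y = "y", z = "z1", w = "w1", x = NULL),
                       bridge = c("saturated", "logistic"), alpha = 0.05,
                       seed = 1, preset = "binary-rare", beta0 = -0.693,
                       n_pop = 1e6, replicates = 100,
                       estimators = c("NC", "NC-Oracle", "Logistic")) {
  command <- match.arg(command)
  bridge <- match.arg(bridge)
  stopifnot(alpha > 0, alpha < 1)
  structure(list(command = command, input = input, out = out,
                 mapping = utils::modifyList(list(a = "a", y = "y", z = "z1",
                                                  w = "w1", x = NULL),
                                             mapping %||% list()),
                 bridge = bridge, alpha = alpha, seed = as.integer(seed),
                 preset = preset, beta0 = beta0, n_pop = n_pop,
                 replicates = replicates, estimators = estimators),
            class = "tnd_run_config")
}

#' Read a run configuration from a YAML file
#'
#' Keys mirror the arguments of [run_config()].
#'
#' @param path YAML file path.
#' @return A `tnd_run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(run_config, cfg)
}

#' Execute a run configuration
#'
#' * `estimate`: read the input CSV, fit the bridge on the test-negative
#'   controls, compute the log risk ratio, sandwich interval and VE, and
#'   write the JSON result;
#' * `simulate`: draw a population from the preset and write population and
#'   sample CSVs;
#' * `study`: run the Monte Carlo study and write a CSV summary plus JSON;
#' * `diagnose`: run the negative-control bias-detection regressions and a
#'   sample summary, written as JSON.
#'
#' Every artifact embeds the seed and a hash of the configuration.
#'
#' @param config A `tnd_run_config` (or path to a YAML file).
#' @return Invisibly, a list with `status` (0 on success) and the artifact
#'   paths.
#' @export
run_command <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "tnd_run_config"))
  cfg_public <- unclass(config)
  switch(config$command,
    estimate = {
      m <- config$mapping
      sample <- read_tnd_csv(config$input, a = m$a, y = m$y, z = m$z, w = m$w, x = m$x)
      fit <- estimate_ve(sample, family = config$bridge, alpha = config$alpha)
      write_result_json(fit, config$out, seed = config$seed, config = cfg_public,
                        timestamp = FALSE)
      invisible(list(status = 0L, artifacts = config$out, result = fit))
    },
    simulate = {
      dgp <- dgp_preset(config$preset, beta0 = config$beta0, n_pop = config$n_pop)
      pop <- simulate_population(dgp, seed = config$seed)
      paths <- paste0(sub("\\.csv$", "", config$out), c("_population.csv", "_sample.csv"))
      write_tnd_csv(pop, paths[1])
      write_tnd_csv(select_tnd_sample(pop), paths[2])
      invisible(list(status = 0L, artifacts = paths))
    },
    study = {
      setting <- if (grepl("^continuous", config$preset)) "continuous" else "binary"
      spec <- study_spec(setting, beta0 = config$beta0, n_pop = config$n_pop,
                         replicates = config$replicates,
                         estimators = config$estimators, preset = config$preset,
                         seed = config$seed)
      res <- run_simulation_study(spec)
      csv_path <- paste0(sub("\\.json$|\\.csv$", "", config$out), ".csv")
      json_path <- paste0(sub("\\.json$|\\.csv$", "", config$out), ".json")
      readr::write_csv(tibble::as_tibble(res), csv_path, progress = FALSE)
      jsonlite::write_json(
        list(schema = "tndnc/study/v1", seed = config$seed,
             config_hash = rlang::hash(cfg_public),
             summary = tibble::as_tibble(res)),
        json_path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
      invisible(list(status = 0L, artifacts = c(csv_path, json_path), result = res))
    },
    diagnose = {
      m <- config$mapping
      sample <- read_tnd_csv(config$input, a = m$a, y = m$y, z = m$z, w = m$w, x = m$x)
      tests <- nce_bias_tests(sample)
      doc <- list(schema = "tndnc/diagnose/v1", seed = config$seed,
                  config_hash = rlang::hash(cfg_public),
                  n = nrow(sample), case_fraction = mean(sample$y),
                  nce_bias_tests = tests)
      jsonlite::write_json(doc, config$out, auto_unbox = TRUE, digits = NA,
                           dataframe = "rows")
      invisible(list(status = 0L, artifacts = config$out, result = tests))
    }
  )
}
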