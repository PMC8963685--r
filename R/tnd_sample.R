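#' Construct a test-negative design sample
#'
#' Validates and standardises a rectangular dataset of tested individuals:
#' a binary vaccination indicator, the binary test result (1 = test-positive
#' case, 0 = test-negative control), one or more negative control exposures
#' (NCE), one or more negative control outcomes (NCO), and optional measured
#' covariates. Every row is implicitly a selected (tested) subject; the
#' selection indicator itself is never part of the analytic sample.
#'
#' Rows with missing values in any mapped column are dropped with a warning.
#' Internally columns are renamed to `a`, `y`, `z1..`, `w1..`, `x1..` so that
#' downstream estimators are agnostic to the original names.
#'
#' @param data A data frame of tested individuals.
#' @param a,y Names of the vaccination and test-result columns (both must be
#'   coded 0/1).
#' @param z,w Character vectors naming the NCE and NCO columns (binary or
#'   continuous, at least one each).
#' @param x Optional character vector naming measured covariate columns.
#' @return A tibble of class `tnd_sample` with standardised columns.
#' @examples
#' df <- data.frame(vax = c(1, 0, 1, 0), pos = c(0, 0, 1, 1),
#'                  flu_last_year = c(1, 0, 1, 0), sprain = c(0, 1, 0, 0))
#' tnd_sample(df, a = "vax", y = "pos", z = "flu_last_year", w = "sprain")
#' @export
tnd_sample <- function(data, a = "a", y = "y", z = "z1", w = "w1", x = NULL) {
  stopifnot(is.data.frame(data))
  mapped <- c(a, y, z, w, x)
  missing_cols <- setdiff(mapped, names(data))
  if (length(missing_cols)) {
    abort(paste0("column(s) not found in data: ",
                 paste(missing_cols, collapse = ", ")))
  }
  keep <- complete.cases(data[mapped])
  if (!all(keep)) {
    warn(sprintf("dropped %d row(s) with missing values in mapped columns",
                 sum(!keep)))
    data <- data[keep, , drop = FALSE]
  }
  if (nrow(data) < 1) abort("no complete rows in `data`")
  check_binary <- function(v, nm) {
    bad <- which(!(v %in% c(0, 1)))
    if (length(bad)) {
      abort(sprintf("column `%s` must be coded 0/1; first offending row: %d (value %s)",
                    nm, bad[1], format(v[bad[1]])))
    }
    as.integer(v)
  }
  out <- tibble::tibble(
    a = check_binary(data[[a]], a),
    y = check_binary(data[[y]], y)
  )
  for (j in seq_along(z)) out[[paste0("z", j)]] <- as.numeric(data[[z[j]]])
  for (j in seq_along(w)) out[[paste0("w", j)]] <- as.numeric(data[[w[j]]])
  for (j in seq_along(x)) out[[paste0("x", j)]] <- as.numeric(data[[x[j]]])
  attr(out, "dims") <- c(z = length(z), w = length(w), x = length(x %||% character(0)))
  class(out) <- c("tnd_sample", class(out))
  out
}

is_tnd_sample <- function(x) inherits(x, "tnd_sample")

as_tnd_sample <- function(data, ...) {
  if (is_tnd_sample(data)) return(data)
  nm <- names(data)
  tnd_sample(data,
             a = "a", y = "y",
             z = grep("^z[0-9]+$", nm, value = TRUE),
             w = grep("^w[0-9]+$", nm, value = TRUE),
             x = if (any(grepl("^x[0-9]+$", nm))) grep("^x[0-9]+$", nm, value = TRUE))
}

# internal: split a tnd_sample into component arrays
sample_arrays <- function(s) {
  nm <- names(s)
  list(
    a = s$a,
    y = s$y,
    Z = as.matrix(s[grep("^z[0-9]+$", nm, value = TRUE)]),
    W = as.matrix(s[grep("^w[0-9]+$", nm, value = TRUE)]),
    X = as.matrix(s[grep("^x[0-9]+$", nm, value = TRUE)]),
    n = nrow(s)
  )
}

#' @export
print.tnd_sample <- function(x, ...) {
  nm <- names(x)
  d <- c(z = sum(grepl("^z[0-9]+$", nm)), w = sum(grepl("^w[0-9]+$", nm)),
         x = sum(grepl("^x[0-9]+$", nm)))
  cat(sprintf("<tnd_sample> %d subjects (%d cases, %d controls); %d NCE, %d NCO, %d covariate(s)\n",
              nrow(x), sum(x$y == 1), sum(x$y == 0), d[["z"]], d[["w"]], d[["x"]]))
  NextMethod()
}
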