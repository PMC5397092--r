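#' Upper-tail probability of the standard normal (Q function)
#'
#' `q_gauss(eta)` is the probability that a standard normal random variable
#' exceeds `eta`, i.e. \eqn{Q(\eta) = (2\pi)^{-1/2}\int_\eta^\infty
#' e^{-u^2/2}\,du}. All closed-form false-alarm and miss probabilities in the
#' package are expressed through this function.
#'
#' @param eta Numeric vector of finite quantiles.
#' @return Numeric vector of tail probabilities in `[0, 1]`, strictly
#'   decreasing in `eta`, with `q_gauss(eta) + q_gauss(-eta) == 1`.
#' @examples
#' q_gauss(0)      # 0.5
#' q_gauss(1.96)   # ~0.025
#' @export
q_gauss <- function(eta) {
  if (!is.numeric(eta) || length(eta) == 0L || anyNA(eta) || any(!is.finite(eta))) {
    stop_cd("`eta` must be finite numeric.", "domain_error")
  }
  stats::pnorm(eta, lower.tail = FALSE)
}

#' Gaussian response model for one hypothesis
#'
#' A single-condition response distribution: the level of the readout (for
#' example nuclear NF-kB, arbitrary units) measured across cells exposed to
#' one stimulus level at one time point is modeled as
#' \eqn{N(\mu, \sigma^2)}.
#'
#' @param mean Mean response level (response units).
#' @param variance Response variance (response units squared); must be
#'   strictly positive.
#' @return An object of class `gaussian_model` with fields `mean`,
#'   `variance` and `sd`.
#' @seealso [fit_gaussian()] to estimate a model from samples.
#' @export
gaussian_model <- function(mean, variance) {
  check_scalar_number(mean, "mean")
  check_scalar_number(variance, "variance")
  if (variance <= 0) {
    stop_cd("`variance` must be strictly positive.", "domain_error")
  }
  structure(
    list(mean = as.numeric(mean), variance = as.numeric(variance),
         sd = sqrt(as.numeric(variance))),
    class = "gaussian_model"
  )
}

#' @export
print.gaussian_model <- function(x, ...) {
  cat(sprintf("<gaussian_model> mean = %g, variance = %g (sd = %g)\n",
              x$mean, x$variance, x$sd))
  n <- attr(x, "n", exact = TRUE)
  if (!is.null(n)) cat(sprintf("  fitted from %d samples\n", n))
  invisible(x)
}

# Density of a gaussian_model, vectorized over x.
dens_gaussian <- function(model, x) stats::dnorm(x, model$mean, model$sd)

#' Fit a Gaussian response model to single-cell samples
#'
#' Estimates mean and variance of the response distribution under one
#' condition. The variance uses the unbiased (n - 1 denominator) estimator;
#' with the hundreds of cells typical of single-cell experiments the
#' difference from the maximum-likelihood estimator is negligible, but the
#' choice is fixed here for reproducibility.
#'
#' @param samples Numeric vector of per-cell response levels (at least two
#'   distinct finite values).
#' @return A [gaussian_model()] with attribute `n`, the sample count.
#' @examples
#' fit_gaussian(c(0.8, 1.1, 1.3, 0.9))
#' @export
fit_gaussian <- function(samples) {
  if (!is.numeric(samples)) {
    stop_cd("`samples` must be numeric.", "domain_error")
  }
  samples <- samples[is.finite(samples)]
  n <- length(samples)
  if (n < 2L) {
    stop_cd("Need at least 2 finite samples to fit a Gaussian model.",
            "degenerate_data")
  }
  v <- stats::var(samples)
  if (!is.finite(v) || v <= 0) {
    stop_cd("Samples have zero spread; variance must be positive.",
            "degenerate_data")
  }
  out <- gaussian_model(mean(samples), v)
  attr(out, "n") <- n
  out
}

#' Fit Gaussian models to every experimental condition in a table
#'
#' Groups a long-format measurement table by condition and fits a Gaussian
#' response model per group, returning one row per condition.
#'
#' @param data A measurement table (see [read_measurements()]) with a
#'   `response` column.
#' @param ... Grouping columns (tidy-select); defaults to
#'   `genotype`, `dose_ng_ml`, `time_min` when present.
#' @return A tibble with the grouping columns plus `n`, `mean`, `variance`.
#' @examples
#' tbl <- generate_dataset(paperlike_scenario(cells_per_condition = 50))
#' fit_conditions(tbl)
#' @export
fit_conditions <- function(data, ...) {
  stopifnot(is.data.frame(data), "response" %in% names(data))
  groups <- rlang::enquos(...)
  if (length(groups) == 0L) {
    default <- intersect(c("genotype", "dose_ng_ml", "time_min"), names(data))
    groups <- rlang::syms(default)
  }
  data |>
    dplyr::group_by(!!!groups) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$response),
      variance = stats::var(.data$response),
      .groups = "drop"
    )
}
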