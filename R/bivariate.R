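#' Bivariate Gaussian model for joint early/late responses
#'
#' Joint model for the response measured in the same cell at an early and a
#' late time point (for example nuclear NF-kB at 30 minutes and 4 hours),
#' with marginal means and variances and an inter-time-point correlation
#' `rho`. The implied covariance matrix must be positive definite, which is
#' guaranteed by positive variances and `|rho| < 1`.
#'
#' @param mean_early,mean_late Marginal means (response units).
#' @param var_early,var_late Marginal variances (> 0).
#' @param correlation Correlation between the two time points, in (-1, 1).
#' @return An object of class `bivariate_model` with the fields above plus
#'   `mu` (length-2 mean vector) and `sigma` (2x2 covariance matrix).
#' @export
bivariate_model <- function(mean_early, mean_late, var_early, var_late,
                            correlation) {
  check_scalar_number(mean_early, "mean_early")
  check_scalar_number(mean_late, "mean_late")
  check_scalar_number(var_early, "var_early")
  check_scalar_number(var_late, "var_late")
  check_scalar_number(correlation, "correlation")
  if (var_early <= 0 || var_late <= 0) {
    stop_cd("Variances must be strictly positive.", "domain_error")
  }
  if (abs(correlation) >= 1) {
    stop_cd("`correlation` must lie strictly inside (-1, 1).", "domain_error")
  }
  cov_xy <- correlation * sqrt(var_early * var_late)
  structure(
    list(mean_early = mean_early, mean_late = mean_late,
         var_early = var_early, var_late = var_late,
         correlation = correlation,
         mu = c(mean_early, mean_late),
         sigma = matrix(c(var_early, cov_xy, cov_xy, var_late), 2, 2)),
    class = "bivariate_model"
  )
}

#' @export
print.bivariate_model <- function(x, ...) {
  cat(sprintf(
    "<bivariate_model> mean = (%g, %g), var = (%g, %g), rho = %g\n",
    x$mean_early, x$mean_late, x$var_early, x$var_late, x$correlation))
  invisible(x)
}

# log density, vectorized over (x, y); kept separate for numerical
# stability in the Monte-Carlo decision rule.
bivariate_log_density <- function(model, x, y) {
  sx <- sqrt(model$var_early)
  sy <- sqrt(model$var_late)
  rho <- model$correlation
  zx <- (x - model$mean_early) / sx
  zy <- (y - model$mean_late) / sy
  -log(2 * pi * sx * sy * sqrt(1 - rho^2)) -
    (zx^2 - 2 * rho * zx * zy + zy^2) / (2 * (1 - rho^2))
}

#' Bivariate Gaussian density
#'
#' Evaluates the joint Normal density with correlation `rho` at points
#' `(x, y)` (vectorized).
#'
#' @param model A [bivariate_model()].
#' @param x,y Numeric vectors of early and late response levels.
#' @return Numeric vector of densities.
#' @examples
#' m <- bivariate_model(0, 0, 1, 1, 0.6)
#' bivariate_density(m, 0, 0)  # 1 / (2 pi sqrt(1 - 0.36))
#' @export
bivariate_density <- function(model, x, y) {
  stopifnot(inherits(model, "bivariate_model"))
  exp(bivariate_log_density(model, x, y))
}

#' Pearson correlation between paired early and late responses
#'
#' Estimates the inter-time-point correlation from per-cell paired
#' measurements, for use when the correlation is not supplied externally.
#'
#' @param early,late Numeric vectors of equal length (>= 3 pairs) with
#'   nonzero spread in both coordinates.
#' @return The Pearson correlation coefficient.
#' @export
estimate_correlation <- function(early, late) {
  if (!is.numeric(early) || !is.numeric(late) || length(early) != length(late)) {
    stop_cd("`early` and `late` must be numeric vectors of equal length.",
            "domain_error")
  }
  keep <- is.finite(early) & is.finite(late)
  early <- early[keep]; late <- late[keep]
  if (length(early) < 3L) {
    stop_cd("Need at least 3 complete (early, late) pairs.", "degenerate_data")
  }
  if (stats::sd(early) == 0 || stats::sd(late) == 0) {
    stop_cd("Zero spread in one coordinate; correlation undefined.",
            "degenerate_data")
  }
  stats::cor(early, late)
}

#' Monte-Carlo settings for bivariate error estimation
#'
#' @param seed Integer seed; mandatory so that estimates are reproducible
#'   (the package keeps no hidden random state).
#' @param n_samples Draws per hypothesis (>= 1e4). The default 1e6 puts the
#'   binomial standard error near 5e-4, i.e. well inside the second decimal
#'   at which probabilities are typically reported.
#' @param batch_size Draws per batch (memory control).
#' @return An object of class `mc_settings`.
#' @export
mc_settings <- function(seed, n_samples = 1e6, batch_size = 1e5) {
  check_scalar_number(seed, "seed")
  check_scalar_number(n_samples, "n_samples")
  check_scalar_number(batch_size, "batch_size")
  if (n_samples < 1e4) {
    stop_cd("`n_samples` must be at least 1e4.", "domain_error")
  }
  if (batch_size < 1) stop_cd("`batch_size` must be positive.", "domain_error")
  structure(list(seed = as.integer(seed),
                 n_samples = as.integer(n_samples),
                 batch_size = as.integer(min(batch_size, n_samples))),
            class = "mc_settings")
}

draw_bivariate <- function(model, n) {
  MASS::mvrnorm(n, mu = model$mu, Sigma = model$sigma)
}

#' Monte-Carlo false-alarm and miss probabilities for the joint decision
#'
#' The joint maximum-likelihood rule decides H1 at `(x, y)` when
#' `P(H1) p(x, y | H1) > P(H0) p(x, y | H0)` (ties decide H0). The
#' decide-H1 set is bounded by a threshold curve in the plane and its
#' probability masses have no convenient closed form, so they are estimated
#' by Monte-Carlo integration: `P_FA` is the fraction of draws from the H0
#' model that land in the decide-H1 set, `P_M` the fraction of H1 draws
#' that land outside it. Binomial standard errors `sqrt(p (1 - p) / n)`
#' accompany the estimates; a fixed seed gives identical output.
#'
#' @param model0,model1 [bivariate_model()] objects for H0 and H1.
#' @param priors A [decision_priors()] object.
#' @param settings An [mc_settings()] object (seed mandatory).
#' @return A `decision_result` with `method = "monte_carlo"` and
#'   `mc_standard_error`.
#' @export
mc_error_probabilities <- function(model0, model1, priors = decision_priors(),
                                   settings) {
  stopifnot(inherits(model0, "bivariate_model"),
            inherits(model1, "bivariate_model"),
            inherits(settings, "mc_settings"))
  priors <- as_priors(priors)
  lp0 <- log(priors$p_h0)
  lp1 <- log(priors$p_h1)
  decide_h1 <- function(xy) {
    lp1 + bivariate_log_density(model1, xy[, 1], xy[, 2]) >
      lp0 + bivariate_log_density(model0, xy[, 1], xy[, 2])
  }
  n <- settings$n_samples
  counts <- withr::with_seed(settings$seed, {
    fa <- 0; miss <- 0; done <- 0
    while (done < n) {
      b <- min(settings$batch_size, n - done)
      fa <- fa + sum(decide_h1(draw_bivariate(model0, b)))
      miss <- miss + sum(!decide_h1(draw_bivariate(model1, b)))
      done <- done + b
    }
    c(fa = fa, miss = miss)
  })
  p_fa <- counts[["fa"]] / n
  p_m <- counts[["miss"]] / n
  se <- c(p_fa = sqrt(p_fa * (1 - p_fa) / n),
          p_m = sqrt(p_m * (1 - p_m) / n))
  new_decision_result(
    threshold = NA_real_,
    p_fa = p_fa, p_m = p_m,
    p_e = overall_error(p_fa, p_m, priors),
    method = "monte_carlo",
    mc_standard_error = se,
    provenance = list(model0 = model0, model1 = model1, priors = priors,
                      settings = settings)
  )
}

#' Grid of the joint log-odds surface (threshold-curve utility)
#'
#' The joint decision boundary is the zero contour of
#' `log[P(H1) p(x,y|H1)] - log[P(H0) p(x,y|H0)]`. This utility evaluates
#' that log-odds surface (and both densities) on a rectangular grid for
#' contour plotting; the decision itself never extracts the curve.
#'
#' @inheritParams mc_error_probabilities
#' @param xlim,ylim Plot ranges; default spans both models' means +/- 4 sd.
#' @param n Grid points per axis.
#' @return A tibble with columns `x`, `y`, `log_odds`, `dens0`, `dens1`.
#' @export
threshold_curve <- function(model0, model1, priors = decision_priors(),
                            xlim = NULL, ylim = NULL, n = 201) {
  priors <- as_priors(priors)
  if (is.null(xlim)) {
    xlim <- range(model0$mean_early + c(-4, 4) * sqrt(model0$var_early),
                  model1$mean_early + c(-4, 4) * sqrt(model1$var_early))
  }
  if (is.null(ylim)) {
    ylim <- range(model0$mean_late + c(-4, 4) * sqrt(model0$var_late),
                  model1$mean_late + c(-4, 4) * sqrt(model1$var_late))
  }
  grid <- tidyr::expand_grid(x = seq(xlim[1], xlim[2], length.out = n),
                             y = seq(ylim[1], ylim[2], length.out = n))
  grid |>
    dplyr::mutate(
      log_odds = log(priors$p_h1) +
        bivariate_log_density(model1, .data$x, .data$y) -
        log(priors$p_h0) -
        bivariate_log_density(model0, .data$x, .data$y),
      dens0 = bivariate_density(model0, .data$x, .data$y),
      dens1 = bivariate_density(model1, .data$x, .data$y)
    )
}
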