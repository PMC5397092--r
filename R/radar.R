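#' Radar reference scenario: constant signal in Gaussian noise
#'
#' The textbook detection problem the cell analysis mirrors: decide whether
#' a constant-amplitude signal `A` is present in `N` samples of zero-mean
#' Gaussian noise with standard deviation `sigma`. The optimal detector
#' compares the sample mean with a threshold, `A/2` for equal priors. The
#' closed forms serve as an analytic oracle for the general decision
#' machinery.
#'
#' @param amplitude Signal amplitude `A`.
#' @param noise_sd Noise standard deviation `sigma` (> 0).
#' @param n_samples Number of observations `N` (>= 1).
#' @param threshold Decision threshold on the sample mean; defaults to the
#'   optimal `A/2`.
#' @return An object of class `radar_scenario`.
#' @export
radar_scenario <- function(amplitude, noise_sd, n_samples,
                           threshold = amplitude / 2) {
  check_scalar_number(amplitude, "amplitude")
  check_scalar_number(noise_sd, "noise_sd")
  check_scalar_number(n_samples, "n_samples")
  check_scalar_number(threshold, "threshold")
  if (noise_sd <= 0) stop_cd("`noise_sd` must be positive.", "domain_error")
  if (n_samples < 1 || n_samples != round(n_samples)) {
    stop_cd("`n_samples` must be a positive integer.", "domain_error")
  }
  structure(list(amplitude = amplitude, noise_sd = noise_sd,
                 n_samples = as.integer(n_samples), threshold = threshold),
            class = "radar_scenario")
}

#' @export
print.radar_scenario <- function(x, ...) {
  cat(sprintf(
    "<radar_scenario> A = %g, sigma = %g, N = %d, threshold = %g\n",
    x$amplitude, x$noise_sd, x$n_samples, x$threshold))
  invisible(x)
}

#' Decide signal presence from observed samples
#'
#' Declares H1 (signal present) when the sample mean exceeds the scenario
#' threshold; an exact tie decides H0.
#'
#' @param observations Numeric vector of length `scenario$n_samples`.
#' @param scenario A [radar_scenario()].
#' @return `"H1"` or `"H0"`.
#' @export
radar_decide <- function(observations, scenario) {
  stopifnot(inherits(scenario, "radar_scenario"))
  if (!is.numeric(observations) ||
      length(observations) != scenario$n_samples) {
    stop_cd(sprintf("Expected %d observations, got %d.",
                    scenario$n_samples, length(observations)),
            "domain_error")
  }
  if (mean(observations) > scenario$threshold) "H1" else "H0"
}

#' Closed-form error probabilities of the radar detector
#'
#' The sample mean is Gaussian with variance `sigma^2 / N` under either
#' hypothesis, so `P_FA = Q(sqrt(N) threshold / sigma)`,
#' `P_M = Q(sqrt(N) (A - threshold) / sigma)` and, with equal priors,
#' `P_e` is their average — which at the optimal threshold `A/2` collapses
#' to `Q(sqrt(N) A / (2 sigma))`.
#'
#' @param scenario A [radar_scenario()].
#' @return A `decision_result` with `method = "closed_form"`.
#' @examples
#' radar_error_probabilities(radar_scenario(2, 1, 4))  # P_e = Q(2)
#' @export
radar_error_probabilities <- function(scenario) {
  stopifnot(inherits(scenario, "radar_scenario"))
  rootN <- sqrt(scenario$n_samples)
  p_fa <- q_gauss(rootN * scenario$threshold / scenario$noise_sd)
  p_m <- q_gauss(rootN * (scenario$amplitude - scenario$threshold) /
                   scenario$noise_sd)
  new_decision_result(
    threshold = scenario$threshold,
    p_fa = p_fa, p_m = p_m, p_e = (p_fa + p_m) / 2,
    method = "closed_form",
    provenance = list(scenario = scenario, priors = decision_priors())
  )
}

#' Monte-Carlo check of the radar closed forms
#'
#' Simulates the detector under each hypothesis and reports the empirical
#' false-alarm and miss rates. The sample mean is drawn directly from its
#' `N(0, sigma^2/N)` / `N(A, sigma^2/N)` law.
#'
#' @param scenario A [radar_scenario()].
#' @param n_trials Trials per hypothesis (>= 1e4).
#' @param seed Integer seed; results are reproducible under a fixed seed.
#' @return Named numeric `c(p_fa = , p_m = )`.
#' @export
radar_monte_carlo <- function(scenario, n_trials = 1e6, seed) {
  stopifnot(inherits(scenario, "radar_scenario"))
  check_scalar_number(n_trials, "n_trials")
  check_scalar_number(seed, "seed")
  if (n_trials < 1e4) stop_cd("`n_trials` must be at least 1e4.", "domain_error")
  sd_mean <- scenario$noise_sd / sqrt(scenario$n_samples)
  withr::with_seed(as.integer(seed), {
    xbar0 <- stats::rnorm(n_trials, 0, sd_mean)
    xbar1 <- stats::rnorm(n_trials, scenario$amplitude, sd_mean)
    c(p_fa = mean(xbar0 > scenario$threshold),
      p_m = mean(xbar1 <= scenario$threshold))
  })
}
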