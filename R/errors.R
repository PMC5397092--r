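#' Closed-form false-alarm and miss probabilities at a threshold
#'
#' With Gaussian response models and the decide-H1-above-threshold
#' convention, the false-alarm probability is the upper tail of the H0
#' model beyond the threshold, `Q((threshold - mu0)/sigma0)`, and the miss
#' probability is the lower tail of the H1 model, `Q((mu1 - threshold)/sigma1)`.
#'
#' @param model0,model1 [gaussian_model()] objects; `model1` must have the
#'   larger (or equal) mean — otherwise an orientation error asks the
#'   caller to relabel the hypotheses.
#' @param threshold Decision threshold (response units); `-Inf`/`Inf`
#'   allowed as limits.
#' @return Named numeric vector `c(p_fa = , p_m = )`.
#' @examples
#' error_probabilities(gaussian_model(0, 1), gaussian_model(2, 1), 1)
#' @export
error_probabilities <- function(model0, model1, threshold) {
  stopifnot(inherits(model0, "gaussian_model"), inherits(model1, "gaussian_model"))
  if (model1$mean < model0$mean) {
    stop_cd(paste0(
      "`model1` must have the higher mean (H1 = stimulus high). ",
      "Relabel the hypotheses and call again."), "orientation_error")
  }
  if (!is.numeric(threshold) || length(threshold) != 1L || is.na(threshold)) {
    stop_cd("`threshold` must be a single number.", "domain_error")
  }
  p_fa <- stats::pnorm(threshold, model0$mean, model0$sd, lower.tail = FALSE)
  p_m <- stats::pnorm(threshold, model1$mean, model1$sd)
  c(p_fa = p_fa, p_m = p_m)
}

#' Overall (prior-weighted) decision error probability
#'
#' `P_e = P(H0) P_FA + P(H1) P_M`; under equal priors this is the plain
#' average of the false-alarm and miss probabilities.
#'
#' @param p_fa,p_m False-alarm and miss probabilities in `[0, 1]`.
#' @param priors A [decision_priors()] object.
#' @return The overall error probability.
#' @examples
#' overall_error(0.04, 0.1)  # 0.07
#' @export
overall_error <- function(p_fa, p_m, priors = decision_priors()) {
  check_probability(p_fa, "p_fa")
  check_probability(p_m, "p_m")
  priors <- as_priors(priors)
  priors$p_h0 * p_fa + priors$p_h1 * p_m
}

#' Overall error probability along a grid of candidate thresholds
#'
#' Evaluates the closed-form false-alarm, miss and overall error
#' probabilities at each candidate threshold. The curve is minimized at the
#' maximum-likelihood threshold; sweeping it shows how sensitive the error
#' is to a suboptimal decision boundary.
#'
#' @inheritParams error_probabilities
#' @param priors A [decision_priors()] object.
#' @param thresholds Sorted finite numeric vector of candidate thresholds.
#' @return A tibble (class `error_curve`) with columns `threshold`, `p_fa`,
#'   `p_m`, `p_e`.
#' @export
error_vs_threshold <- function(model0, model1, priors = decision_priors(),
                               thresholds) {
  stopifnot(inherits(model0, "gaussian_model"), inherits(model1, "gaussian_model"))
  priors <- as_priors(priors)
  if (missing(thresholds) || length(thresholds) == 0L) {
    stop_cd("`thresholds` must be a non-empty grid.", "domain_error")
  }
  if (!is.numeric(thresholds) || any(!is.finite(thresholds))) {
    stop_cd("`thresholds` must be finite numeric.", "domain_error")
  }
  if (is.unsorted(thresholds)) {
    stop_cd("`thresholds` must be sorted increasing.", "domain_error")
  }
  p_fa <- stats::pnorm(thresholds, model0$mean, model0$sd, lower.tail = FALSE)
  p_m <- stats::pnorm(thresholds, model1$mean, model1$sd)
  out <- tibble::tibble(
    threshold = as.numeric(thresholds),
    p_fa = p_fa,
    p_m = p_m,
    p_e = priors$p_h0 * p_fa + priors$p_h1 * p_m
  )
  class(out) <- c("error_curve", class(out))
  out
}

#' Full univariate decision analysis for a pair of Gaussian models
#'
#' Combines threshold solution and error probabilities into a
#' [decision result][tidy.decision_result]. Two modes are available:
#'
#' * `"single_threshold"` (default): the between-means density crossing
#'   from [ml_threshold()] with the closed-form tail probabilities — the
#'   conventional treatment, under which `P_e = P(H0) P_FA + P(H1) P_M`
#'   holds exactly.
#' * `"exact_region"`: the exact Bayes rule. With unequal variances the
#'   decide-H1 set `{x : P(H1) p(x|H1) > P(H0) p(x|H0)}` can be an interval
#'   or the complement of one; its error probabilities are computed as
#'   Gaussian masses over the exact region.
#'
#' @inheritParams error_vs_threshold
#' @param mode `"single_threshold"` or `"exact_region"`.
#' @return A `decision_result` object.
#' @examples
#' decision_analysis(gaussian_model(1, 0.12), gaussian_model(3.4, 1))
#' @export
decision_analysis <- function(model0, model1, priors = decision_priors(),
                              mode = c("single_threshold", "exact_region")) {
  mode <- match.arg(mode)
  stopifnot(inherits(model0, "gaussian_model"), inherits(model1, "gaussian_model"))
  priors <- as_priors(priors)
  if (model1$mean < model0$mean) {
    rlang::warn(paste0(
      "`model1` mean is below `model0` mean; relabeling hypotheses so that ",
      "H1 has the higher mean response."), class = "celldecide_orientation")
    tmp <- model0; model0 <- model1; model1 <- tmp
  }
  if (mode == "single_threshold") {
    th <- ml_threshold(model0, model1, priors)
    pp <- error_probabilities(model0, model1, th)
    new_decision_result(
      threshold = th,
      p_fa = pp[["p_fa"]], p_m = pp[["p_m"]],
      p_e = overall_error(pp[["p_fa"]], pp[["p_m"]], priors),
      method = "closed_form",
      provenance = list(model0 = model0, model1 = model1, priors = priors,
                        mode = mode)
    )
  } else {
    reg <- h1_region(model0, model1, priors)
    p_fa <- if (nrow(reg)) sum(gauss_mass(model0$mean, model0$sd, reg[, 1], reg[, 2])) else 0
    p_m <- 1 - (if (nrow(reg)) sum(gauss_mass(model1$mean, model1$sd, reg[, 1], reg[, 2])) else 0)
    new_decision_result(
      threshold = NA_real_,
      p_fa = p_fa, p_m = p_m,
      p_e = overall_error(p_fa, p_m, priors),
      method = "closed_form",
      provenance = list(model0 = model0, model1 = model1, priors = priors,
                        mode = mode, region = reg,
                        region_label = region_label(reg))
    )
  }
}
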