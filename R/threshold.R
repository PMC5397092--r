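# Coefficients of the log prior-weighted likelihood-ratio
#   g(x) = log[P(H1) p(x|H1)] - log[P(H0) p(x|H0)] = a x^2 + b x + c
# The decide-H1 region is {x : g(x) > 0}; g(x) = 0 recovers the threshold
# quadratic for two Gaussians with (possibly) unequal variances.
log_odds_coefs <- function(model0, model1, priors) {
  s0 <- model0$variance
  s1 <- model1$variance
  a <- 1 / (2 * s0) - 1 / (2 * s1)
  b <- model1$mean / s1 - model0$mean / s0
  cc <- model0$mean^2 / (2 * s0) - model1$mean^2 / (2 * s1) +
    log(priors$p_h1 / priors$p_h0) + 0.5 * log(s0 / s1)
  list(a = a, b = b, c = cc)
}

# Numerically stable real roots of a x^2 + b x + c = 0 (a != 0).
quad_roots <- function(a, b, cc) {
  disc <- b^2 - 4 * a * cc
  if (disc < 0) return(numeric(0))
  q <- -(b + sign(b + (b == 0)) * sqrt(disc)) / 2
  r <- if (q == 0) 0 else c(q / a, cc / q)
  sort(unique(r))
}

#' Maximum-likelihood decision threshold for two Gaussian response models
#'
#' Solves `P(H0) p(x|H0) = P(H1) p(x|H1)` for the response level at which
#' the prior-weighted densities cross. For unequal variances this is a
#' quadratic in `x` with up to two real roots; the conventional
#' single-threshold treatment (the one under which the closed-form
#' false-alarm and miss formulas hold) takes the crossing that lies
#' strictly between the two means. With equal variances the quadratic term
#' vanishes and the linear equation is solved directly: the midpoint of the
#' means shifted by the prior log-ratio term.
#'
#' @param model0,model1 [gaussian_model()] objects for H0 (stimulus low)
#'   and H1 (stimulus high). If `model1` has the smaller mean the two are
#'   relabeled with a warning so that H1 sits above the threshold.
#' @param priors A [decision_priors()] object; equal priors by default.
#' @return The threshold (response units). At the returned value the
#'   prior-weighted densities agree to ~1e-9 relative.
#' @examples
#' ml_threshold(gaussian_model(0, 1), gaussian_model(2, 1))  # 1
#' @export
ml_threshold <- function(model0, model1, priors = decision_priors()) {
  stopifnot(inherits(model0, "gaussian_model"), inherits(model1, "gaussian_model"))
  priors <- as_priors(priors)
  same_mean <- isTRUE(all.equal(model0$mean, model1$mean, tolerance = 1e-12))
  same_var <- isTRUE(all.equal(model0$variance, model1$variance, tolerance = 1e-12))
  if (same_mean && same_var) {
    stop_cd("Models are identical; no decision threshold exists.", "no_threshold")
  }
  if (model1$mean < model0$mean) {
    rlang::warn(paste0(
      "`model1` mean is below `model0` mean; relabeling hypotheses so that ",
      "H1 has the higher mean response."), class = "celldecide_orientation")
    tmp <- model0; model0 <- model1; model1 <- tmp
  }
  if (same_mean) {
    stop_cd(paste0(
      "Models share a mean and differ only in variance: the decide-H1 region ",
      "is not a single between-means threshold. Use decision_analysis(mode = ",
      "\"exact_region\") for the exact Bayes regions."), "degenerate_threshold")
  }
  k <- log_odds_coefs(model0, model1, priors)
  rel_a <- abs(k$a) * max(model0$mean^2, model1$mean^2, 1)
  if (rel_a < 1e-12 * abs(k$b)) {
    th <- -k$c / k$b
  } else {
    roots <- quad_roots(k$a, k$b, k$c)
    lo <- model0$mean
    hi <- model1$mean
    inside <- roots[roots > lo & roots < hi]
    if (length(inside) == 0L) {
      stop_cd(paste0(
        "The prior-weighted densities do not cross between the means ",
        sprintf("(%g and %g): ", lo, hi),
        "the decide-H1 region is not a single between-means threshold ",
        "(this happens with strongly unequal variances or extreme priors). ",
        "Use decision_analysis(mode = \"exact_region\")."),
        "degenerate_threshold")
    }
    th <- inside[[1]]
  }
  d0 <- priors$p_h0 * dens_gaussian(model0, th)
  d1 <- priors$p_h1 * dens_gaussian(model1, th)
  if (abs(d0 - d1) > 1e-9 * max(d0, d1)) {
    stop_cd("Internal error: densities do not agree at the computed threshold.",
            "internal")
  }
  th
}

# Decide-H1 region {x : g(x) > 0} as a two-column matrix of disjoint
# intervals (rows, possibly infinite endpoints), for the exact Bayes rule.
h1_region <- function(model0, model1, priors = decision_priors()) {
  priors <- as_priors(priors)
  k <- log_odds_coefs(model0, model1, priors)
  scale <- max(abs(k$b) * max(abs(model0$mean), abs(model1$mean), 1), abs(k$c), 1)
  if (abs(k$a) * max(model0$mean^2, model1$mean^2, 1) < 1e-12 * scale) {
    # effectively linear
    if (k$b > 0) return(matrix(c(-k$c / k$b, Inf), 1)) # g > 0 above
    if (k$b < 0) return(matrix(c(-Inf, -k$c / k$b), 1))
    if (k$c > 0) return(matrix(c(-Inf, Inf), 1))
    return(matrix(numeric(0), 0, 2))
  }
  roots <- quad_roots(k$a, k$b, k$c)
  if (length(roots) < 2L) {
    # no sign change: sign of g is the sign of the leading coefficient
    if (k$a > 0) return(matrix(c(-Inf, Inf), 1))
    return(matrix(numeric(0), 0, 2))
  }
  if (k$a < 0) {
    matrix(c(roots[1], roots[2]), 1)
  } else {
    matrix(c(-Inf, roots[1], roots[2], Inf), 2, 2, byrow = TRUE)
  }
}

region_label <- function(region) {
  if (nrow(region) == 0L) return("H1 region: empty")
  paste0("H1 region: ", paste(
    sprintf("(%s, %s)", formatC(region[, 1], digits = 6, format = "g"),
            formatC(region[, 2], digits = 6, format = "g")),
    collapse = " U "))
}
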