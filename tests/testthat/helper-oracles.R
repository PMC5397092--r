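# Independent numerical oracles used to cross-check the closed forms.
# These deliberately avoid the package's own solution paths: thresholds by
# bisection on the density difference, tail probabilities by adaptive
# quadrature of the Gaussian density, bivariate masses by dense midpoint
# quadrature with densities from mvtnorm.

# Plain bisection on the prior-weighted density difference.
bisect_threshold <- function(model0, model1, priors = decision_priors(),
                             lower, upper, tol = 1e-10) {
  f <- function(x) {
    priors$p_h1 * dnorm(x, model1$mean, model1$sd) -
      priors$p_h0 * dnorm(x, model0$mean, model0$sd)
  }
  fl <- f(lower)
  stopifnot(fl * f(upper) < 0)
  while (upper - lower > tol) {
    mid <- (lower + upper) / 2
    if (f(mid) * fl <= 0) upper <- mid else {
      lower <- mid
      fl <- f(lower)
    }
  }
  (lower + upper) / 2
}

# Tail probabilities by adaptive quadrature of the Gaussian density.
quad_tail_probs <- function(model0, model1, threshold) {
  p_fa <- integrate(function(x) dnorm(x, model0$mean, model0$sd),
                    threshold, Inf, rel.tol = 1e-12, abs.tol = 1e-13)$value
  p_m <- integrate(function(x) dnorm(x, model1$mean, model1$sd),
                   -Inf, threshold, rel.tol = 1e-12, abs.tol = 1e-13)$value
  c(p_fa = p_fa, p_m = p_m)
}

# Decide-H1 intervals located by sign scanning + uniroot (independent of
# the package's quadratic-root path), then error masses by quadrature.
oracle_region_error <- function(model0, model1, priors = decision_priors()) {
  g <- function(x) {
    priors$p_h1 * dnorm(x, model1$mean, model1$sd) -
      priors$p_h0 * dnorm(x, model0$mean, model0$sd)
  }
  lim <- range(model0$mean + c(-12, 12) * model0$sd,
               model1$mean + c(-12, 12) * model1$sd)
  xs <- seq(lim[1], lim[2], length.out = 8001)
  gx <- g(xs)
  sgn <- sign(gx)
  flips <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  roots <- vapply(flips, function(i) {
    uniroot(g, c(xs[i], xs[i + 1]), tol = 1e-12)$root
  }, numeric(1))
  bounds <- c(-Inf, roots, Inf)
  p_fa <- 0
  p_m <- 0
  for (i in seq_len(length(bounds) - 1)) {
    probe <- if (is.infinite(bounds[i]) && is.infinite(bounds[i + 1])) {
      (model0$mean + model1$mean) / 2
    } else if (is.infinite(bounds[i])) {
      bounds[i + 1] - 1
    } else if (is.infinite(bounds[i + 1])) {
      bounds[i] + 1
    } else {
      (bounds[i] + bounds[i + 1]) / 2
    }
    mass0 <- pnorm(bounds[i + 1], model0$mean, model0$sd) -
      pnorm(bounds[i], model0$mean, model0$sd)
    mass1 <- pnorm(bounds[i + 1], model1$mean, model1$sd) -
      pnorm(bounds[i], model1$mean, model1$sd)
    if (g(probe) > 0) p_fa <- p_fa + mass0 else p_m <- p_m + mass1
  }
  c(p_fa = p_fa, p_m = p_m)
}

# Dense midpoint quadrature of the bivariate error integrals; densities
# from mvtnorm, region by direct density comparison.
quad2d_error <- function(model0, model1, priors = decision_priors(),
                         xlim = c(-6, 8), ylim = c(-6, 8), dx = 0.005) {
  xs <- seq(xlim[1] + dx / 2, xlim[2], by = dx)
  ys <- seq(ylim[1] + dx / 2, ylim[2], by = dx)
  p_fa <- 0
  p_m <- 0
  for (chunk in split(xs, ceiling(seq_along(xs) / 120))) {
    grid <- as.matrix(expand.grid(x = chunk, y = ys))
    d0 <- mvtnorm::dmvnorm(grid, model0$mu, model0$sigma)
    d1 <- mvtnorm::dmvnorm(grid, model1$mu, model1$sigma)
    h1 <- priors$p_h1 * d1 > priors$p_h0 * d0
    p_fa <- p_fa + sum(d0[h1])
    p_m <- p_m + sum(d1[!h1])
  }
  c(p_fa = p_fa * dx^2, p_m = p_m * dx^2)
}

# Random well-posed Gaussian model pair with mu1 >= mu0.
random_model_pair <- function() {
  means <- sort(runif(2, 0, 5))
  vars <- runif(2, 0.1, 4)
  list(model0 = gaussian_model(means[1], vars[1]),
       model1 = gaussian_model(means[2], vars[2]))
}
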