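test_that("bivariate density matches factorization and matrix-form oracle", {
  m <- bivariate_model(1, 2, 0.8, 1.5, 0.6)
  # peak value has the closed form 1 / (2 pi sx sy sqrt(1 - rho^2))
  expect_equal(bivariate_density(m, 1, 2),
               1 / (2 * pi * sqrt(0.8) * sqrt(1.5) * sqrt(1 - 0.36)))
  # rho = 0 factorizes into the product of the univariate densities
  m_ind <- bivariate_model(1, 2, 0.8, 1.5, 0)
  withr::with_seed(3, {
    xs <- rnorm(20, 1, 2)
    ys <- rnorm(20, 2, 2)
    expect_equal(bivariate_density(m_ind, xs, ys),
                 dnorm(xs, 1, sqrt(0.8)) * dnorm(ys, 2, sqrt(1.5)),
                 tolerance = 1e-12)
  })
  # general rho against an independent matrix-form implementation
  pts <- expand.grid(x = c(0, 1 + sqrt(0.8), 2.5), y = c(1, 2 + sqrt(1.5), 4))
  expect_equal(bivariate_density(m, pts$x, pts$y),
               mvtnorm::dmvnorm(as.matrix(pts), m$mu, m$sigma),
               tolerance = 1e-12)
  expect_error(bivariate_model(0, 0, 1, 1, 1), class = "celldecide_domain_error")
  expect_error(bivariate_model(0, 0, -1, 1, 0), class = "celldecide_domain_error")
})

test_that("bivariate density integrates to one on a wide grid", {
  m <- bivariate_model(0.5, 1, 1.2, 0.7, 0.4)
  dx <- 0.02
  xs <- seq(0.5 - 6 * sqrt(1.2) + dx / 2, 0.5 + 6 * sqrt(1.2), by = dx)
  ys <- seq(1 - 6 * sqrt(0.7) + dx / 2, 1 + 6 * sqrt(0.7), by = dx)
  grid <- expand.grid(x = xs, y = ys)
  total <- sum(bivariate_density(m, grid$x, grid$y)) * dx^2
  expect_equal(total, 1, tolerance = 1e-4)
})

test_that("correlation estimation recovers linear, anti-linear and null cases", {
  x <- seq(-2, 2, length.out = 25)
  expect_equal(estimate_correlation(x, 2 * x + 1), 1)
  expect_equal(estimate_correlation(x, -x), -1)
  withr::with_seed(7, {
    expect_lt(abs(estimate_correlation(rnorm(1e5), rnorm(1e5))), 0.01)
  })
  expect_error(estimate_correlation(1:2, 2:3), class = "celldecide_degenerate_data")
  expect_error(estimate_correlation(rep(1, 10), rnorm(10)),
               class = "celldecide_degenerate_data")
})

test_that("Monte-Carlo error estimation is seeded, calibrated and consistent", {
  m0 <- bivariate_model(0, 0, 1, 1, 0.3)
  m1 <- bivariate_model(2, 1.5, 1, 1.3, 0.3)
  s <- mc_settings(seed = 21, n_samples = 1e5)
  r1 <- mc_error_probabilities(m0, m1, settings = s)
  r2 <- mc_error_probabilities(m0, m1, settings = s)
  expect_identical(tidy(r1), tidy(r2))  # same seed, identical output
  r3 <- mc_error_probabilities(m0, m1, settings = mc_settings(seed = 22, n_samples = 1e5))
  comb <- sqrt(r1$mc_standard_error^2 + r3$mc_standard_error^2)
  expect_lt(abs(r1$p_fa - r3$p_fa), 5 * comb[["p_fa"]])
  expect_lt(abs(r1$p_m - r3$p_m), 5 * comb[["p_m"]])
  # overwhelming separation: both error rates essentially zero
  far <- bivariate_model(20, 20, 1, 1, 0)
  r_far <- mc_error_probabilities(bivariate_model(0, 0, 1, 1, 0), far,
                                  settings = mc_settings(seed = 1, n_samples = 1e4))
  expect_lte(r_far$p_fa, 1e-6)
  expect_lte(r_far$p_m, 1e-6)
  # indistinguishable hypotheses: ties decide H0, so P_FA + P_M ~ 1
  same <- bivariate_model(1, 1, 1, 1, 0.2)
  r_same <- mc_error_probabilities(same, same,
                                   settings = mc_settings(seed = 2, n_samples = 1e5))
  # the log-odds is identically zero, so ties (decided H0) are certain:
  # P_FA = 0, P_M = 1 and P_e = 1/2 hold exactly
  se_sum <- sqrt(sum(r_same$mc_standard_error^2))
  expect_lte(abs(r_same$p_fa + r_same$p_m - 1), 3 * se_sum)
  expect_lte(abs(r_same$p_e - 0.5), 3 * se_sum)
  expect_error(mc_settings(seed = 1, n_samples = 100),
               class = "celldecide_domain_error")
})

test_that("joint analysis reduces to the univariate rule when late is uninformative", {
  # identical late marginals + rho = 0: only the early coordinate matters
  early0 <- gaussian_model(0, 1)
  early1 <- gaussian_model(2, 1.7)
  m0 <- bivariate_model(0, 5, 1, 2, 0)
  m1 <- bivariate_model(2, 5, 1.7, 2, 0)
  joint <- mc_error_probabilities(m0, m1,
                                  settings = mc_settings(seed = 13, n_samples = 4e5))
  uni <- decision_analysis(early0, early1, mode = "exact_region")
  expect_lt(abs(joint$p_fa - uni$p_fa), 3 * joint$mc_standard_error[["p_fa"]])
  expect_lt(abs(joint$p_m - uni$p_m), 3 * joint$mc_standard_error[["p_m"]])
})

test_that("quadrature-oracle P_e never increases with mean separation", {
  seps <- c(0.5, 1, 1.5, 2, 3)
  pes <- vapply(seps, function(d) {
    m0 <- bivariate_model(0, 0, 1, 1, 0.4)
    m1 <- bivariate_model(d, d, 1, 1, 0.4)
    pp <- quad2d_error(m0, m1, xlim = c(-5, 8), ylim = c(-5, 8), dx = 0.02)
    mean(pp)
  }, numeric(1))
  expect_true(all(diff(pes) <= 1e-6))
})

test_that("threshold curve grid marks the decision boundary", {
  m0 <- bivariate_model(0, 0, 1, 1, 0)
  m1 <- bivariate_model(2, 2, 1, 1, 0)
  grid <- threshold_curve(m0, m1, n = 41)
  # equal covariances: boundary is the line x + y = 2
  expect_true(all(sign(grid$log_odds[abs(grid$x + grid$y - 2) > 0.2]) ==
                    sign(grid$x[abs(grid$x + grid$y - 2) > 0.2] +
                           grid$y[abs(grid$x + grid$y - 2) > 0.2] - 2)))
})
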