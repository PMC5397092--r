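test_that("Q function matches its defining integral and identities", {
  expect_identical(q_gauss(0), 0.5)
  expect_equal(q_gauss(0.7) + q_gauss(-0.7), 1)
  # frozen from numerical quadrature of the upper-tail integrand
  quad <- integrate(function(u) exp(-u^2 / 2) / sqrt(2 * pi), 1.96, Inf,
                    rel.tol = 1e-12)$value
  expect_equal(quad, 0.0249979, tolerance = 1e-5)
  expect_equal(q_gauss(1.96), quad, tolerance = 1e-6)
  eta <- seq(-4, 4, by = 0.25)
  expect_true(all(diff(q_gauss(eta)) < 0))
  expect_error(q_gauss(Inf), class = "celldecide_domain_error")
  expect_error(q_gauss(NA_real_), class = "celldecide_domain_error")
})

test_that("fit_gaussian estimates mean/variance and rejects degenerate data", {
  m <- fit_gaussian(c(0, 2))
  expect_equal(m$mean, 1)
  expect_equal(m$variance, 2)  # unbiased, n - 1 denominator
  expect_error(fit_gaussian(rep(1.3, 50)), class = "celldecide_degenerate_data")
  expect_error(fit_gaussian(3), class = "celldecide_degenerate_data")
  withr::with_seed(11, {
    x <- rnorm(1e5, mean = 3, sd = 2)
    f <- fit_gaussian(x)
    expect_lt(abs(f$mean - 3), 0.05)
    expect_lt(abs(f$variance - 4), 0.15)
  })
})

test_that("ml_threshold solves the density-crossing equation", {
  # equal variances, equal priors: symmetric midpoint
  expect_equal(ml_threshold(gaussian_model(0, 1), gaussian_model(2, 1)), 1)
  # radar-equivalent scenario: threshold A/2
  expect_equal(ml_threshold(gaussian_model(0, 1), gaussian_model(2, 1),
                            decision_priors(0.5)), 1)
  # unequal variances: agree with an independent bisection oracle
  m0 <- gaussian_model(0, 1)
  m1 <- gaussian_model(3, 4)
  th <- ml_threshold(m0, m1)
  expect_equal(th, bisect_threshold(m0, m1, lower = 0, upper = 3),
               tolerance = 1e-6)
  # prior-weighted crossing under unequal priors
  pr <- decision_priors(0.8)
  th_pr <- ml_threshold(m0, m1, pr)
  d0 <- pr$p_h0 * dnorm(th_pr, 0, 1)
  d1 <- pr$p_h1 * dnorm(th_pr, 3, 2)
  expect_lt(abs(d0 - d1), 1e-9 * max(d0, d1))
  expect_error(ml_threshold(m0, gaussian_model(0, 1)),
               class = "celldecide_no_threshold")
  expect_warning(ml_threshold(m1, m0), class = "celldecide_orientation")
  # same mean, different variance: no single between-means threshold
  expect_error(ml_threshold(gaussian_model(1, 1), gaussian_model(1, 3)),
               class = "celldecide_degenerate_threshold")
})

test_that("closed-form error probabilities match quadrature of the tails", {
  m0 <- gaussian_model(0, 1)
  m1 <- gaussian_model(2, 1)
  pp <- error_probabilities(m0, m1, 1)
  oracle <- quad_tail_probs(m0, m1, 1)
  expect_equal(pp[["p_fa"]], oracle[["p_fa"]], tolerance = 1e-4)
  expect_equal(pp[["p_m"]], oracle[["p_m"]], tolerance = 1e-4)
  expect_equal(pp[["p_fa"]], pp[["p_m"]])  # symmetric case
  expect_equal(unname(error_probabilities(m0, m1, Inf)), c(0, 1))
  expect_error(error_probabilities(m1, m0, 1),
               class = "celldecide_orientation_error")
  withr::with_seed(5, {
    for (i in 1:20) {
      pair <- random_model_pair()
      th <- runif(1, pair$model0$mean, pair$model1$mean)
      pp <- error_probabilities(pair$model0, pair$model1, th)
      oracle <- quad_tail_probs(pair$model0, pair$model1, th)
      expect_lt(max(abs(pp - oracle)), 1e-8)
    }
  })
})

test_that("overall error is the prior-weighted mixture and linear in priors", {
  expect_equal(overall_error(0.2, 0.29), 0.245)
  expect_equal(overall_error(0.04, 0.1), 0.07)
  expect_equal(overall_error(0, 0, decision_priors(0.3)), 0)
  # linearity in the prior weight; p_h0 -> 1 limit recovers p_fa
  w <- c(0.1, 0.25, 0.5, 0.75, 0.9, 0.999)
  pe <- vapply(w, function(p) overall_error(0.3, 0.08, decision_priors(p)),
               numeric(1))
  expect_equal(pe, w * 0.3 + (1 - w) * 0.08)
  expect_equal(overall_error(0.3, 0.08, decision_priors(0.999)), 0.3,
               tolerance = 1e-3)
  expect_error(overall_error(1.2, 0), class = "celldecide_domain_error")
})

test_that("error-vs-threshold curve is minimized at the ML threshold", {
  m0 <- gaussian_model(1, 0.5)
  m1 <- gaussian_model(3.2, 1.4)
  grid <- seq(m0$mean - 4 * m0$sd, m1$mean + 4 * m1$sd, length.out = 2000)
  curve <- error_vs_threshold(m0, m1, thresholds = grid)
  expect_true(all(curve$p_e >= 0 & curve$p_e <= 1))
  th <- ml_threshold(m0, m1)
  step <- diff(grid[1:2])
  expect_lt(abs(curve$threshold[which.min(curve$p_e)] - th), step + 1e-12)
  # symmetric models: curve symmetric about the midpoint of the means
  sym <- error_vs_threshold(gaussian_model(0, 1), gaussian_model(2, 1),
                            thresholds = seq(-1, 3, length.out = 401))
  expect_equal(sym$p_e, rev(sym$p_e), tolerance = 1e-12)
  expect_error(error_vs_threshold(m0, m1, thresholds = numeric(0)),
               class = "celldecide_domain_error")
  expect_error(error_vs_threshold(m0, m1, thresholds = c(2, 1)),
               class = "celldecide_domain_error")
})

test_that("ML threshold is optimal and errors vanish with separation", {
  withr::with_seed(42, {
    for (i in 1:50) {
      pair <- random_model_pair()
      if (pair$model1$mean - pair$model0$mean < 0.05) next
      th <- tryCatch(ml_threshold(pair$model0, pair$model1),
                     celldecide_degenerate_threshold = function(e) NULL)
      if (is.null(th)) next
      grid <- seq(pair$model0$mean - 4 * pair$model0$sd,
                  pair$model1$mean + 4 * pair$model1$sd, length.out = 500)
      curve <- error_vs_threshold(pair$model0, pair$model1, thresholds = grid)
      pe_opt <- overall_error(
        error_probabilities(pair$model0, pair$model1, th)[["p_fa"]],
        error_probabilities(pair$model0, pair$model1, th)[["p_m"]])
      expect_lte(pe_opt, min(curve$p_e) + 1e-12)
      expect_lte(pe_opt, 0.5)
    }
  })
  # degenerate limit: errors shrink monotonically to zero with separation
  seps <- seq(1, 20, by = 1)
  res <- vapply(seps, function(d) {
    m0 <- gaussian_model(0, 1)
    m1 <- gaussian_model(d, 2.25)
    error_probabilities(m0, m1, ml_threshold(m0, m1))
  }, numeric(2))
  expect_true(all(diff(res[1, ]) < 0))
  expect_true(all(diff(res[2, ]) < 0))
  expect_lt(res[1, length(seps)], 1e-9)
})

test_that("exact-region mode integrates the true Bayes regions", {
  withr::with_seed(99, {
    for (i in 1:10) {
      pair <- random_model_pair()
      pr <- decision_priors(runif(1, 0.2, 0.8))
      res <- decision_analysis(pair$model0, pair$model1, pr,
                               mode = "exact_region")
      oracle <- oracle_region_error(pair$model0, pair$model1, pr)
      expect_lt(abs(res$p_fa - oracle[["p_fa"]]), 1e-8)
      expect_lt(abs(res$p_m - oracle[["p_m"]]), 1e-8)
    }
  })
  # exact region handles the equal-mean case the single threshold rejects
  res <- decision_analysis(gaussian_model(1, 1), gaussian_model(1, 3),
                           mode = "exact_region")
  oracle <- oracle_region_error(gaussian_model(1, 1), gaussian_model(1, 3))
  expect_equal(res$p_fa, oracle[["p_fa"]], tolerance = 1e-8)
})

test_that("decision_result tidiers expose estimates and provenance", {
  res <- decision_analysis(gaussian_model(1, 0.2), gaussian_model(3, 1))
  td <- tidy(res)
  expect_equal(td$term, c("p_fa", "p_m", "p_e"))
  expect_equal(td$estimate[3],
               overall_error(td$estimate[1], td$estimate[2]))
  gl <- glance(res)
  expect_equal(gl$method, "closed_form")
  expect_equal(gl$threshold, res$threshold)
  # p_e identity holds to near machine precision for closed form
  expect_lt(abs(res$p_e - 0.5 * res$p_fa - 0.5 * res$p_m), 1e-12)
})
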