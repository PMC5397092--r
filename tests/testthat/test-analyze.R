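sep_sweep_spec <- function(cells = 2000, seed = 9) {
  # separation between reference and test dose grows strictly with dose,
  # at fixed variances, so the closed-form P_e must fall with dose
  doses <- c(0.01, 0.1, 0.5, 2, 8)
  conditions <- dplyr::bind_rows(
    tibble::tibble(genotype = "WT", dose_ng_ml = doses, time_min = 30,
                   mean = c(1, 1.8, 2.6, 3.4, 4.2), variance = 0.5),
    tibble::tibble(genotype = "WT", dose_ng_ml = doses, time_min = 240,
                   mean = c(1, 1.4, 1.8, 2.2, 2.6), variance = 0.5)
  )
  correlations <- tibble::tibble(genotype = "WT", dose_ng_ml = doses,
                                 correlation = 0.5)
  scenario_spec(conditions, correlations, cells_per_condition = cells,
                seed = seed)
}

test_that("condition-pair analysis recovers the true closed-form errors", {
  spec <- sep_sweep_spec(cells = 5000)
  tbl <- generate_dataset(spec)
  fitted <- analyze_condition_pair(tbl, 0.01, 8, time = 30)
  truth <- decision_analysis(gaussian_model(1, 0.5), gaussian_model(4.2, 0.5))
  expect_lt(abs(fitted$p_fa - truth$p_fa), 0.01)
  expect_lt(abs(fitted$p_m - truth$p_m), 0.01)
  expect_equal(fitted$provenance$n0, 5000)
  # empirical mode lands near the same answer on well-sampled data
  emp <- analyze_condition_pair(tbl, 0.01, 8, time = 30, method = "empirical")
  expect_lt(abs(emp$p_e - truth$p_e), 0.02)
  expect_error(analyze_condition_pair(tbl, 0.01, 8, time = 99),
               class = "celldecide_missing_condition")
})

test_that("threshold policies: optimal, literal fixed, and borrowed", {
  tbl <- generate_dataset(paperlike_scenario(cells_per_condition = 300))
  opt <- analyze_condition_pair(tbl, 0.0021, 8, time = 30)
  fixed <- analyze_condition_pair(tbl, 0.0021, 8, time = 30,
                                  policy = threshold_policy("fixed", fixed_value = 2.5))
  expect_equal(fixed$threshold, 2.5)
  expect_gte(fixed$p_e, opt$p_e)  # optimal threshold minimizes P_e
  borrowed <- analyze_condition_pair(
    tbl, 0.0021, 8, time = 30, genotype = "A20KO",
    policy = threshold_policy("fixed", source_condition = list(
      genotype = "WT", dose_low = 0.0021, dose_high = 8, time = 30)))
  expect_equal(borrowed$threshold, opt$threshold)
  expect_error(threshold_policy("fixed"), class = "celldecide_domain_error")
})

test_that("identical low/high response distributions give P_e near one half", {
  conditions <- tibble::tibble(
    genotype = "WT", dose_ng_ml = rep(c(0.01, 8), each = 2),
    time_min = rep(c(30, 240), 2), mean = 2, variance = 0.5)
  correlations <- tibble::tibble(genotype = "WT", dose_ng_ml = c(0.01, 8),
                                 correlation = 0.3)
  tbl <- generate_dataset(scenario_spec(conditions, correlations,
                                        cells_per_condition = 2000, seed = 12))
  res <- suppressWarnings(analyze_condition_pair(tbl, 0.01, 8, time = 30))
  expect_equal(res$p_e, 0.5, tolerance = 0.05)
})

test_that("dose sweep orders doses and falls with growing separation", {
  spec <- sep_sweep_spec()
  tbl <- generate_dataset(spec)
  sweep <- dose_sweep(tbl, reference_dose = 0.01, time = 30)
  expect_equal(sweep$dose_ng_ml, c(0.1, 0.5, 2, 8))
  expect_true(all(diff(sweep$p_e) < 0))
  expect_true(all(sweep$p_e >= 0 & sweep$p_e <= 1))
  expect_error(dose_sweep(tbl, reference_dose = 99, time = 30),
               class = "celldecide_missing_condition")
  single <- dplyr::filter(tbl, dose_ng_ml == 0.01)
  expect_error(dose_sweep(single, reference_dose = 0.01, time = 30),
               class = "celldecide_missing_condition")
})

test_that("joint analysis matches the quadrature oracle on known parameters", {
  spec <- sep_sweep_spec(cells = 5000, seed = 21)
  tbl <- generate_dataset(spec)
  res <- joint_analysis(tbl, 0.01, 0.5, settings = mc_settings(seed = 31, n_samples = 2e5))
  # oracle uses the *fitted* models so only MC error separates the two
  m0 <- res$provenance$model0
  m1 <- res$provenance$model1
  oracle <- quad2d_error(m0, m1, xlim = c(-4, 7), ylim = c(-4, 7), dx = 0.01)
  expect_lt(abs(res$p_fa - oracle[["p_fa"]]),
            3 * res$mc_standard_error[["p_fa"]] + 2e-3)
  expect_lt(abs(res$p_m - oracle[["p_m"]]),
            3 * res$mc_standard_error[["p_m"]] + 2e-3)
  expect_equal(res$provenance$rho_source, "estimated_from_paired_data")
  # user-supplied rho takes precedence and is recorded
  res_rho <- joint_analysis(tbl, 0.01, 0.5, rho = 0.5,
                            settings = mc_settings(seed = 31, n_samples = 1e4))
  expect_equal(res_rho$provenance$rho_source, "user_supplied")
})

test_that("joint analysis without rho or paired cells asks for the correlation", {
  tbl <- generate_dataset(sep_sweep_spec(cells = 100, seed = 2))
  # break the pairing: distinct cell ids per time point
  unpaired <- dplyr::mutate(
    tbl, cell_id = paste0(cell_id, "_t", time_min))
  expect_error(joint_analysis(unpaired, 0.01, 8,
                              settings = mc_settings(seed = 1, n_samples = 1e4)),
               class = "celldecide_missing_rho")
  # supplying rho rescues the unpaired table
  res <- joint_analysis(unpaired, 0.01, 8, rho = 0.4,
                        settings = mc_settings(seed = 1, n_samples = 1e4))
  expect_s3_class(res, "decision_result")
})

test_that("rho sensitivity sweeps the assumed correlation", {
  tbl <- generate_dataset(sep_sweep_spec(cells = 500, seed = 4))
  sens <- rho_sensitivity(tbl, 0.01, 2, rhos = c(0, 0.45, 0.9),
                          settings = mc_settings(seed = 8, n_samples = 1e4))
  expect_equal(sens$rho, c(0, 0.45, 0.9))
  expect_true(all(sens$p_fa >= 0 & sens$p_fa <= 1))
  expect_true(all(is.finite(sens$se_p_fa)))
})

test_that("identical inputs produce byte-identical run reports", {
  tbl <- generate_dataset(paperlike_scenario(cells_per_condition = 100))
  res1 <- joint_analysis(tbl, 0.0021, 8, settings = mc_settings(seed = 3, n_samples = 1e4))
  res2 <- joint_analysis(tbl, 0.0021, 8, settings = mc_settings(seed = 3, n_samples = 1e4))
  f1 <- withr::local_tempfile()
  f2 <- withr::local_tempfile()
  write_report(res1, f1)
  write_report(res2, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_true(any(grepl("rho_source", readLines(f1))))
  expect_true(any(grepl("seed", readLines(f1))))
})
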