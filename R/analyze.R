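#' Threshold policy for condition-pair analysis
#'
#' Decides how the decision threshold is chosen: `"optimal"` computes the
#' maximum-likelihood threshold from the analyzed pair itself, while
#' `"fixed"` imposes an external one — either a literal value or the
#' optimal threshold of another condition pair (for example the wild-type
#' threshold applied to deficient cells, which do not "know" their
#' response distributions have shifted).
#'
#' @param mode `"optimal"` or `"fixed"`.
#' @param fixed_value Literal threshold for `mode = "fixed"`.
#' @param source_condition Alternative for `mode = "fixed"`: a named list
#'   `list(genotype =, dose_low =, dose_high =, time =)` identifying the
#'   condition pair whose optimal threshold is borrowed.
#' @return An object of class `threshold_policy`.
#' @export
threshold_policy <- function(mode = c("optimal", "fixed"), fixed_value = NULL,
                             source_condition = NULL) {
  mode <- match.arg(mode)
  if (mode == "fixed" && is.null(fixed_value) && is.null(source_condition)) {
    stop_cd("Fixed policy needs `fixed_value` or `source_condition`.",
            "domain_error")
  }
  structure(list(mode = mode, fixed_value = fixed_value,
                 source_condition = source_condition),
            class = "threshold_policy")
}

condition_samples <- function(table, genotype, dose, time) {
  table$response[table$genotype == genotype &
                   table$dose_ng_ml == dose & table$time_min == time]
}

#' Decision analysis for a low/high dose pair at one time point
#'
#' The full pipeline for one comparison: extracts the two conditions from a
#' measurement table, fits response models (Gaussian by default, or
#' empirical histograms), resolves the decision threshold per the policy
#' (optimal for the pair, or a fixed/borrowed one), and returns the
#' false-alarm, miss and overall error probabilities with full provenance.
#'
#' @param table A validated measurement table (see [read_measurements()]).
#' @param dose_low,dose_high Doses defining H0 (stimulus low) and H1
#'   (stimulus high), in ng/mL.
#' @param time Time point in minutes.
#' @param genotype Genotype label to analyze (default `"WT"`).
#' @param priors A [decision_priors()] object.
#' @param policy A [threshold_policy()].
#' @param method `"gaussian"` (fitted models + closed forms) or
#'   `"empirical"` (histogram threshold, raw-sample tail fractions).
#' @return A `decision_result` whose provenance records models, sample
#'   counts, priors, policy and condition labels.
#' @examples
#' tbl <- generate_dataset(paperlike_scenario(cells_per_condition = 200))
#' analyze_condition_pair(tbl, 0.0021, 8, time = 30)
#' @export
analyze_condition_pair <- function(table, dose_low, dose_high, time,
                                   genotype = "WT",
                                   priors = decision_priors(),
                                   policy = threshold_policy("optimal"),
                                   method = c("gaussian", "empirical")) {
  method <- match.arg(method)
  priors <- as_priors(priors)
  stopifnot(inherits(policy, "threshold_policy"))
  table <- validate_measurements(table)
  x0 <- condition_samples(table, genotype, dose_low, time)
  x1 <- condition_samples(table, genotype, dose_high, time)
  for (pair in list(list(x0, dose_low), list(x1, dose_high))) {
    if (length(pair[[1]]) < 2L) {
      stop_cd(sprintf(
        "Condition (genotype %s, dose %g ng/mL, %g min) has %d cells; need >= 2.",
        genotype, pair[[2]], time, length(pair[[1]])), "missing_condition")
    }
  }
  cond_label <- sprintf("%s %g vs %g ng/mL at %g min (%s)",
                        genotype, dose_low, dose_high, time, method)

  resolve_fixed <- function() {
    if (!is.null(policy$fixed_value)) return(policy$fixed_value)
    src <- policy$source_condition
    ref <- analyze_condition_pair(
      table, src$dose_low, src$dose_high, src$time,
      genotype = src$genotype %||% "WT",
      priors = priors, policy = threshold_policy("optimal"), method = method)
    ref$threshold
  }

  if (method == "gaussian") {
    m0 <- fit_gaussian(x0)
    m1 <- fit_gaussian(x1)
    if (m1$mean < m0$mean) {
      rlang::warn(sprintf(
        "High-dose condition has the lower fitted mean at %s; relabeling.",
        cond_label), class = "celldecide_orientation")
      tmp <- m0; m0 <- m1; m1 <- tmp
    }
    th <- if (policy$mode == "optimal") {
      # near-identical conditions may have no between-means density
      # crossing; fall back to the exact Bayes regions in that case
      tryCatch(ml_threshold(m0, m1, priors),
               celldecide_degenerate_threshold = function(e) NA_real_,
               celldecide_no_threshold = function(e) NA_real_)
    } else {
      resolve_fixed()
    }
    res <- if (is.na(th)) {
      decision_analysis(m0, m1, priors, mode = "exact_region")
    } else {
      pp <- error_probabilities(m0, m1, th)
      new_decision_result(
        threshold = th, p_fa = pp[["p_fa"]], p_m = pp[["p_m"]],
        p_e = overall_error(pp[["p_fa"]], pp[["p_m"]], priors),
        method = "closed_form",
        provenance = list(model0 = m0, model1 = m1, priors = priors)
      )
    }
    res$provenance <- c(res$provenance,
                        list(policy = policy, condition = cond_label,
                             n0 = length(x0), n1 = length(x1)))
    res
  } else {
    h0 <- build_histogram(x0)
    h1 <- build_histogram(x1)
    th <- if (policy$mode == "optimal") {
      as.numeric(empirical_threshold(h0, h1, priors))
    } else {
      resolve_fixed()
    }
    res <- empirical_error_rates(x0, x1, th, priors)
    res$provenance <- c(res$provenance,
                        list(model0 = h0, model1 = h1, policy = policy,
                             condition = cond_label))
    res
  }
}

#' Overall decision error as a function of stimulus dose
#'
#' Sweeps every dose present at the chosen time point against a fixed
#' reference (low) dose, running [analyze_condition_pair()] for each and
#' collecting the error probabilities. Quantifies how much easier the
#' low-versus-high decision becomes as the high dose grows.
#'
#' @inheritParams analyze_condition_pair
#' @param reference_dose The low (H0) dose, which must be present.
#' @return A tibble (class `dose_sweep`) with one row per non-reference
#'   dose: `dose_ng_ml`, `threshold`, `p_fa`, `p_m`, `p_e`, sorted by dose.
#' @export
dose_sweep <- function(table, reference_dose, time, genotype = "WT",
                       priors = decision_priors(),
                       policy = threshold_policy("optimal"),
                       method = c("gaussian", "empirical")) {
  method <- match.arg(method)
  table <- validate_measurements(table)
  at_time <- table |>
    dplyr::filter(.data$genotype == .env$genotype, .data$time_min == .env$time)
  doses <- sort(unique(at_time$dose_ng_ml))
  if (!reference_dose %in% doses) {
    stop_cd(sprintf("Reference dose %g ng/mL absent at %g min for %s.",
                    reference_dose, time, genotype), "missing_condition")
  }
  others <- setdiff(doses, reference_dose)
  if (length(others) == 0L) {
    stop_cd("Need at least two doses at the chosen time point.",
            "missing_condition")
  }
  rows <- purrr::map(others, function(d) {
    res <- analyze_condition_pair(table, reference_dose, d, time,
                                  genotype = genotype, priors = priors,
                                  policy = policy, method = method)
    tibble::tibble(dose_ng_ml = d,
                   threshold = if (is.numeric(res$threshold)) res$threshold else NA_real_,
                   p_fa = res$p_fa, p_m = res$p_m, p_e = res$p_e)
  })
  out <- dplyr::bind_rows(rows) |> dplyr::arrange(.data$dose_ng_ml)
  attr(out, "reference_dose") <- reference_dose
  attr(out, "time_min") <- time
  attr(out, "genotype") <- genotype
  class(out) <- c("dose_sweep", class(out))
  out
}

#' Pair early and late responses per cell
#'
#' Pivots a long measurement table to one row per cell with `early` and
#' `late` response columns; cells missing either time point are dropped.
#'
#' @inheritParams analyze_condition_pair
#' @param dose Dose to extract.
#' @param time_early,time_late The two time points (minutes).
#' @return A tibble with columns `cell_id`, `early`, `late`.
#' @export
pair_timepoints <- function(table, dose, genotype = "WT", time_early = 30,
                            time_late = 240) {
  table |>
    dplyr::filter(.data$genotype == .env$genotype,
                  .data$dose_ng_ml == .env$dose,
                  .data$time_min %in% c(time_early, time_late)) |>
    dplyr::mutate(when = ifelse(.data$time_min == time_early, "early", "late")) |>
    dplyr::select("cell_id", "when", "response") |>
    tidyr::pivot_wider(names_from = "when", values_from = "response") |>
    tidyr::drop_na()
}

#' Joint early/late decision analysis for a dose pair
#'
#' Builds a bivariate Gaussian response model per hypothesis from paired
#' per-cell (early, late) measurements and estimates the joint decision's
#' false-alarm and miss probabilities by Monte-Carlo integration. The
#' correlation is resolved in order of precedence: a user-supplied `rho`
#' (scalar, or named `c(low =, high =)` per hypothesis), else the Pearson
#' correlation of the paired data, else an error instructing the caller to
#' supply it.
#'
#' @inheritParams analyze_condition_pair
#' @param time_early,time_late The two time points (minutes).
#' @param rho Optional correlation override (see above).
#' @param settings An [mc_settings()] object (seed mandatory).
#' @return A `decision_result` with `method = "monte_carlo"`, recording the
#'   correlation source and Monte-Carlo standard errors.
#' @export
joint_analysis <- function(table, dose_low, dose_high, genotype = "WT",
                           time_early = 30, time_late = 240,
                           priors = decision_priors(), rho = NULL,
                           settings) {
  priors <- as_priors(priors)
  table <- validate_measurements(table)
  rho_for <- function(which) {
    if (is.null(rho)) return(NULL)
    if (length(rho) == 1L && is.null(names(rho))) return(as.numeric(rho))
    if (!is.null(names(rho)) && which %in% names(rho)) {
      return(as.numeric(rho[[which]]))
    }
    stop_cd("`rho` must be a single number or named c(low =, high =).",
            "domain_error")
  }
  models <- purrr::imap(list(low = dose_low, high = dose_high), function(d, nm) {
    x_e <- condition_samples(table, genotype, d, time_early)
    x_l <- condition_samples(table, genotype, d, time_late)
    if (length(x_e) < 2L || length(x_l) < 2L) {
      stop_cd(sprintf("Dose %g ng/mL lacks measurements at both time points.",
                      d), "missing_condition")
    }
    r <- rho_for(nm)
    if (is.null(r)) {
      paired <- pair_timepoints(table, d, genotype, time_early, time_late)
      if (nrow(paired) < 3L) {
        stop_cd(sprintf(
          paste0("Dose %g ng/mL has no paired per-cell (early, late) data and ",
                 "no `rho` was supplied; provide the inter-time-point ",
                 "correlation explicitly."), d), "missing_rho")
      }
      r <- estimate_correlation(paired$early, paired$late)
    }
    m_e <- fit_gaussian(x_e)
    m_l <- fit_gaussian(x_l)
    bivariate_model(m_e$mean, m_l$mean, m_e$variance, m_l$variance, r)
  })
  res <- mc_error_probabilities(models$low, models$high, priors, settings)
  res$provenance$rho_source <- if (is.null(rho)) "estimated_from_paired_data" else "user_supplied"
  res$provenance$condition <- sprintf(
    "%s %g vs %g ng/mL, joint (%g, %g) min", genotype, dose_low, dose_high,
    time_early, time_late)
  res
}

#' Sensitivity of joint error probabilities to the correlation
#'
#' Re-runs [joint_analysis()] across a grid of assumed inter-time-point
#' correlations (applied to both hypotheses), reporting how the joint
#' false-alarm, miss and overall error probabilities respond. Useful when
#' the true correlation is uncertain, e.g. when it would otherwise come
#' from an external simulator.
#'
#' @inheritParams joint_analysis
#' @param rhos Correlation grid (each in (-1, 1)).
#' @return A tibble with columns `rho`, `p_fa`, `p_m`, `p_e`, `se_p_fa`,
#'   `se_p_m`.
#' @export
rho_sensitivity <- function(table, dose_low, dose_high, genotype = "WT",
                            time_early = 30, time_late = 240,
                            priors = decision_priors(),
                            rhos = seq(0, 0.9, by = 0.1), settings) {
  purrr::map_dfr(rhos, function(r) {
    res <- joint_analysis(table, dose_low, dose_high, genotype,
                          time_early, time_late, priors, rho = r,
                          settings = settings)
    tibble::tibble(rho = r, p_fa = res$p_fa, p_m = res$p_m, p_e = res$p_e,
                   se_p_fa = res$mc_standard_error[["p_fa"]],
                   se_p_m = res$mc_standard_error[["p_m"]])
  })
}
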