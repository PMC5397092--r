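#' Scenario specification for the synthetic single-cell generator
#'
#' Declares, per experimental condition, the Gaussian response parameters
#' the generator should emulate: one row of `conditions` per
#' (genotype, dose, time point) with a mean and variance, plus one row of
#' `correlations` per (genotype, dose) giving the inter-time-point
#' correlation of the per-cell (early, late) pair. Each (genotype, dose)
#' group must contain exactly two time points, since cells are drawn from
#' the implied bivariate Gaussian.
#'
#' @param conditions Data frame with columns `genotype`, `dose_ng_ml`,
#'   `time_min`, `mean`, `variance` (variances > 0).
#' @param correlations Data frame with columns `genotype`, `dose_ng_ml`,
#'   `correlation` (each in (-1, 1)).
#' @param cells_per_condition Cells per (genotype, dose) group (>= 10);
#'   hundreds of cells mirrors typical single-cell experiments.
#' @param seed Integer seed making generation deterministic.
#' @return An object of class `scenario_spec`.
#' @seealso [generate_dataset()], [paperlike_scenario()]
#' @export
scenario_spec <- function(conditions, correlations, cells_per_condition = 500,
                          seed) {
  conditions <- tibble::as_tibble(conditions)
  correlations <- tibble::as_tibble(correlations)
  need_c <- c("genotype", "dose_ng_ml", "time_min", "mean", "variance")
  if (!all(need_c %in% names(conditions))) {
    stop_cd(paste("`conditions` needs columns:", paste(need_c, collapse = ", ")),
            "domain_error")
  }
  if (!all(c("genotype", "dose_ng_ml", "correlation") %in% names(correlations))) {
    stop_cd("`correlations` needs columns genotype, dose_ng_ml, correlation.",
            "domain_error")
  }
  if (any(conditions$variance <= 0)) {
    stop_cd("All variances must be strictly positive.", "domain_error")
  }
  if (any(abs(correlations$correlation) >= 1)) {
    stop_cd("All correlations must lie strictly inside (-1, 1).", "domain_error")
  }
  check_scalar_number(cells_per_condition, "cells_per_condition")
  if (cells_per_condition < 10) {
    stop_cd("`cells_per_condition` must be at least 10.", "domain_error")
  }
  check_scalar_number(seed, "seed")
  tp <- conditions |>
    dplyr::count(.data$genotype, .data$dose_ng_ml)
  if (any(tp$n != 2L)) {
    stop_cd("Each (genotype, dose) group must have exactly two time points.",
            "domain_error")
  }
  structure(
    list(conditions = conditions, correlations = correlations,
         cells_per_condition = as.integer(cells_per_condition),
         seed = as.integer(seed)),
    class = "scenario_spec"
  )
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf(
    "<scenario_spec> %d conditions, %d cells/condition, seed %d\n",
    nrow(x$conditions), x$cells_per_condition, x$seed))
  print(x$conditions, n = Inf)
  invisible(x)
}

#' Generate a synthetic long-format single-cell dataset
#'
#' For every (genotype, dose) group, draws `cells_per_condition` cells from
#' the bivariate Gaussian implied by the group's two (time point, mean,
#' variance) rows and its correlation, and returns the measurements in
#' long format: one row per (cell, time point). Generation is deterministic
#' under the spec's seed.
#'
#' @param spec A [scenario_spec()].
#' @return A tibble with columns `cell_id`, `genotype`, `dose_ng_ml`,
#'   `time_min`, `response`.
#' @examples
#' tbl <- generate_dataset(paperlike_scenario(cells_per_condition = 20))
#' dplyr::count(tbl, genotype, dose_ng_ml, time_min)
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  groups <- spec$conditions |>
    dplyr::arrange(.data$genotype, .data$dose_ng_ml, .data$time_min) |>
    dplyr::group_split(.data$genotype, .data$dose_ng_ml)
  n <- spec$cells_per_condition
  withr::with_seed(spec$seed, {
    purrr::map_dfr(groups, function(g) {
      rho_row <- spec$correlations |>
        dplyr::filter(.data$genotype == g$genotype[1],
                      .data$dose_ng_ml == g$dose_ng_ml[1])
      if (nrow(rho_row) != 1L) {
        stop_cd(sprintf("No correlation entry for genotype %s, dose %g.",
                        g$genotype[1], g$dose_ng_ml[1]), "domain_error")
      }
      model <- bivariate_model(g$mean[1], g$mean[2], g$variance[1],
                               g$variance[2], rho_row$correlation)
      draws <- draw_bivariate(model, n)
      ids <- sprintf("%s_d%g_c%04d", g$genotype[1], g$dose_ng_ml[1], seq_len(n))
      tibble::tibble(
        cell_id = rep(ids, 2L),
        genotype = g$genotype[1],
        dose_ng_ml = g$dose_ng_ml[1],
        time_min = rep(g$time_min, each = n),
        response = c(draws[, 1], draws[, 2])
      )
    })
  })
}

#' Packaged synthetic scenario mimicking TNF--NF-kB response structure
#'
#' A documented fixture whose parameter values are synthetic — they are
#' chosen to reproduce the qualitative structure of published TNF--NF-kB
#' single-cell response histograms, not the (unpublished) means and
#' variances behind them, so its output must not be mistaken for a
#' reproduction of measured data. The construction encodes:
#'
#' * well-separated low/high-dose response distributions at 30 minutes and
#'   heavily overlapping ones at 4 hours (negative feedback attenuates the
#'   high-dose response late), so the early decision error is smaller than
#'   the late one;
#' * an "A20-deficient" (`A20KO`) variant whose low-dose response is
#'   shifted upward and broadened (no feedback to switch the response off),
#'   inflating the false-alarm rate — especially when such cells keep
#'   using the wild-type decision threshold;
#' * six stimulus doses with response means increasing and then saturating
#'   in dose, so the overall error falls with dose before flattening;
#' * positive inter-time-point correlation within each cell.
#'
#' @param cells_per_condition Cells per (genotype, dose); default 500.
#' @param seed Integer seed.
#' @return A [scenario_spec()] covering genotypes `WT` and `A20KO`, doses
#'   0.0021--8 ng/mL, time points 30 and 240 minutes.
#' @export
paperlike_scenario <- function(cells_per_condition = 500, seed = 7041705) {
  doses <- c(0.0021, 0.05, 0.2, 0.51, 2, 8)
  wt_early_mean <- c(1.00, 1.45, 1.95, 2.45, 3.05, 3.35)
  wt_early_sd   <- c(0.35, 0.45, 0.55, 0.65, 0.80, 1.00)
  wt_late_mean  <- c(1.20, 1.40, 1.60, 1.80, 2.05, 2.20)
  wt_late_sd    <- c(0.50, 0.55, 0.65, 0.75, 0.85, 0.90)
  ko_early_mean <- c(2.00, 2.25, 2.50, 2.75, 3.10, 3.40)
  ko_early_sd   <- c(0.90, 0.92, 0.95, 0.97, 1.00, 1.05)
  ko_late_mean  <- c(2.60, 2.70, 2.80, 2.90, 3.00, 3.10)
  ko_late_sd    <- c(0.95, 0.95, 1.00, 1.00, 1.05, 1.05)
  conditions <- dplyr::bind_rows(
    tibble::tibble(genotype = "WT", dose_ng_ml = doses, time_min = 30,
                   mean = wt_early_mean, variance = wt_early_sd^2),
    tibble::tibble(genotype = "WT", dose_ng_ml = doses, time_min = 240,
                   mean = wt_late_mean, variance = wt_late_sd^2),
    tibble::tibble(genotype = "A20KO", dose_ng_ml = doses, time_min = 30,
                   mean = ko_early_mean, variance = ko_early_sd^2),
    tibble::tibble(genotype = "A20KO", dose_ng_ml = doses, time_min = 240,
                   mean = ko_late_mean, variance = ko_late_sd^2)
  )
  correlations <- dplyr::bind_rows(
    tibble::tibble(genotype = "WT", dose_ng_ml = doses, correlation = 0.5),
    tibble::tibble(genotype = "A20KO", dose_ng_ml = doses, correlation = 0.6)
  )
  scenario_spec(conditions, correlations,
                cells_per_condition = cells_per_condition, seed = seed)
}
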