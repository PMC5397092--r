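#' Plot a decision result: densities, threshold, error regions
#'
#' For univariate Gaussian results, draws the two fitted response
#' densities, the decision threshold, and shades the false-alarm region
#' (H0 density above the threshold) and miss region (H1 density below it).
#' Empirical results draw the histograms as step densities. Bivariate
#' Monte-Carlo results delegate to [plot_threshold_curve()].
#'
#' @param object A `decision_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.decision_result <- function(object, ...) {
  prov <- object$provenance
  m0 <- prov$model0
  m1 <- prov$model1
  if (inherits(m0, "bivariate_model")) {
    return(plot_threshold_curve(m0, m1, prov$priors %||% decision_priors()))
  }
  th <- object$threshold
  if (inherits(m0, "gaussian_model")) {
    xr <- range(m0$mean + c(-4, 4) * m0$sd, m1$mean + c(-4, 4) * m1$sd)
    x <- seq(xr[1], xr[2], length.out = 512)
    dens <- dplyr::bind_rows(
      tibble::tibble(x = x, density = dens_gaussian(m0, x), hypothesis = "H0 (low)"),
      tibble::tibble(x = x, density = dens_gaussian(m1, x), hypothesis = "H1 (high)")
    )
    fa <- dens |> dplyr::filter(.data$hypothesis == "H0 (low)", .data$x > th)
    miss <- dens |> dplyr::filter(.data$hypothesis == "H1 (high)", .data$x <= th)
    p <- ggplot2::ggplot(dens, ggplot2::aes(x = .data$x, y = .data$density)) +
      ggplot2::geom_area(data = fa, fill = "#d66a6a", alpha = 0.5) +
      ggplot2::geom_area(data = miss, fill = "#8a8a8a", alpha = 0.5) +
      ggplot2::geom_line(ggplot2::aes(color = .data$hypothesis), linewidth = 0.8)
  } else if (inherits(m0, "empirical_model")) {
    step_df <- function(m, lab) tibble::tibble(
      x = m$bin_edges,
      density = c(m$bin_masses / diff(m$bin_edges), 0),
      hypothesis = lab)
    dens <- dplyr::bind_rows(step_df(m0, "H0 (low)"), step_df(m1, "H1 (high)"))
    p <- ggplot2::ggplot(dens, ggplot2::aes(x = .data$x, y = .data$density,
                                            color = .data$hypothesis)) +
      ggplot2::geom_step(linewidth = 0.8)
  } else {
    stop_cd("No plottable models recorded in the result's provenance.",
            "domain_error")
  }
  if (is.numeric(th) && is.finite(th)) {
    p <- p + ggplot2::geom_vline(xintercept = th, color = "#3465a4",
                                 linewidth = 0.9)
  }
  p +
    ggplot2::labs(
      x = "response level (a.u.)", y = "density",
      title = sprintf("P_FA = %.3f, P_M = %.3f, P_e = %.3f",
                      object$p_fa, object$p_m, object$p_e),
      subtitle = prov$condition %||% NULL, color = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the overall error along a threshold grid
#'
#' @param object An `error_curve` tibble from [error_vs_threshold()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.error_curve <- function(object, ...) {
  long <- object |>
    tidyr::pivot_longer(c("p_fa", "p_m", "p_e"), names_to = "metric",
                        values_to = "probability")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$threshold,
                                     y = .data$probability,
                                     color = .data$metric)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::geom_vline(xintercept = object$threshold[which.min(object$p_e)],
                        linetype = "dashed", color = "grey40") +
    ggplot2::labs(x = "decision threshold (a.u.)", y = "probability",
                  color = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a dose sweep of the overall decision error
#'
#' @param object A `dose_sweep` tibble from [dose_sweep()].
#' @param ... Unused.
#' @return A ggplot object (log-scaled dose axis).
#' @export
autoplot.dose_sweep <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$dose_ng_ml, y = .data$p_e)) +
    ggplot2::geom_line(color = "#3465a4") +
    ggplot2::geom_point(color = "#3465a4") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "high dose (ng/mL)", y = "overall error probability P_e",
      title = sprintf("Decisions vs reference dose %g ng/mL at %g min (%s)",
                      attr(object, "reference_dose"), attr(object, "time_min"),
                      attr(object, "genotype"))) +
    ggplot2::theme_minimal()
}

#' Contour plot of the joint decision boundary
#'
#' Density contours of the two bivariate response models with the joint
#' decision boundary (zero contour of the prior-weighted log-odds) overlaid.
#'
#' @inheritParams mc_error_probabilities
#' @param xlim,ylim,n Passed to [threshold_curve()].
#' @return A ggplot object.
#' @export
plot_threshold_curve <- function(model0, model1, priors = decision_priors(),
                                 xlim = NULL, ylim = NULL, n = 201) {
  grid <- threshold_curve(model0, model1, priors, xlim, ylim, n)
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_contour(ggplot2::aes(z = .data$dens0), color = "#4e9a06",
                          bins = 6, linewidth = 0.4) +
    ggplot2::geom_contour(ggplot2::aes(z = .data$dens1), color = "#cc0000",
                          bins = 6, linewidth = 0.4) +
    ggplot2::geom_contour(ggplot2::aes(z = .data$log_odds), breaks = 0,
                          color = "#3465a4", linewidth = 1) +
    ggplot2::labs(x = "early response (a.u.)", y = "late response (a.u.)",
                  title = "Joint decision boundary (blue): H1 decided where prior-weighted H1 density wins") +
    ggplot2::theme_minimal()
}
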