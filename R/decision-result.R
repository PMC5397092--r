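#' @rdname tidy.decision_result
#' @param threshold Decision threshold (or `NA` for region/bivariate rules).
#' @param p_fa,p_m,p_e False-alarm, miss and overall error probabilities.
#' @param method One of `"closed_form"`, `"monte_carlo"`, `"empirical"`.
#' @param mc_standard_error Optional named numeric `c(p_fa =, p_m =)` of
#'   binomial standard errors for Monte-Carlo estimates.
#' @param provenance List recording the models, priors, threshold policy,
#'   seeds etc. that produced the result.
#' @export
new_decision_result <- function(threshold, p_fa, p_m, p_e,
                                method = c("closed_form", "monte_carlo", "empirical"),
                                mc_standard_error = NULL,
                                provenance = list()) {
  method <- match.arg(method)
  check_probability(p_fa, "p_fa")
  check_probability(p_m, "p_m")
  check_probability(p_e, "p_e")
  structure(
    list(threshold = threshold, p_fa = p_fa, p_m = p_m, p_e = p_e,
         method = method, mc_standard_error = mc_standard_error,
         provenance = provenance),
    class = "decision_result"
  )
}

#' @export
print.decision_result <- function(x, ...) {
  writeLines(format_report(x))
  invisible(x)
}

#' Tidy and summarize decision results
#'
#' `tidy()` returns one row per error metric (`p_fa`, `p_m`, `p_e`) with
#' its estimate and, for Monte-Carlo results, the binomial standard error.
#' `glance()` returns a one-row summary including the threshold and method.
#' `new_decision_result()` is the low-level constructor used by the
#' analysis functions.
#'
#' @param x A `decision_result` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.decision_result <- function(x, ...) {
  se <- rep(NA_real_, 3)
  if (!is.null(x$mc_standard_error)) {
    pr <- x$provenance$priors %||% decision_priors()
    se_fa <- x$mc_standard_error[["p_fa"]]
    se_m <- x$mc_standard_error[["p_m"]]
    se <- c(se_fa, se_m, sqrt((pr$p_h0 * se_fa)^2 + (pr$p_h1 * se_m)^2))
  }
  tibble::tibble(
    term = c("p_fa", "p_m", "p_e"),
    estimate = c(x$p_fa, x$p_m, x$p_e),
    std.error = se
  )
}

#' @rdname tidy.decision_result
#' @export
glance.decision_result <- function(x, ...) {
  prov <- x$provenance
  tibble::tibble(
    threshold = if (is.numeric(x$threshold)) x$threshold else NA_real_,
    p_fa = x$p_fa, p_m = x$p_m, p_e = x$p_e,
    method = x$method,
    n_mc = prov$settings$n_samples %||% NA_integer_,
    seed = prov$settings$seed %||% NA_integer_
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Key-value run report with full provenance; numbers formatted at fixed
# precision so identical inputs give byte-identical reports.
format_report <- function(x) {
  stopifnot(inherits(x, "decision_result"))
  fmt <- function(v) formatC(v, digits = 6, format = "g")
  prov <- x$provenance
  lines <- c(
    "celldecide decision report",
    sprintf("method: %s", x$method),
    sprintf("threshold: %s",
            if (is.numeric(x$threshold) && is.finite(x$threshold)) fmt(x$threshold)
            else prov$region_label %||% "density-comparison rule (no scalar threshold)"),
    sprintf("p_fa: %s", fmt(x$p_fa)),
    sprintf("p_m: %s", fmt(x$p_m)),
    sprintf("p_e: %s", fmt(x$p_e))
  )
  if (!is.null(x$mc_standard_error)) {
    lines <- c(lines,
      sprintf("mc_se_p_fa: %s", fmt(x$mc_standard_error[["p_fa"]])),
      sprintf("mc_se_p_m: %s", fmt(x$mc_standard_error[["p_m"]])))
  }
  if (!is.null(prov$priors)) {
    lines <- c(lines, sprintf("priors: P(H0)=%s P(H1)=%s",
                              fmt(prov$priors$p_h0), fmt(prov$priors$p_h1)))
  }
  for (nm in c("model0", "model1")) {
    m <- prov[[nm]]
    if (inherits(m, "gaussian_model")) {
      lines <- c(lines, sprintf("%s: gaussian mean=%s variance=%s n=%s",
                                nm, fmt(m$mean), fmt(m$variance),
                                attr(m, "n", exact = TRUE) %||% "NA"))
    } else if (inherits(m, "bivariate_model")) {
      lines <- c(lines, sprintf(
        "%s: bivariate mean=(%s,%s) var=(%s,%s) rho=%s",
        nm, fmt(m$mean_early), fmt(m$mean_late),
        fmt(m$var_early), fmt(m$var_late), fmt(m$correlation)))
    }
  }
  if (!is.null(prov$policy)) {
    lines <- c(lines, sprintf("threshold_policy: %s", prov$policy$mode))
  }
  if (!is.null(prov$condition)) {
    lines <- c(lines, sprintf("condition: %s", prov$condition))
  }
  if (!is.null(prov$rho_source)) {
    lines <- c(lines, sprintf("rho_source: %s", prov$rho_source))
  }
  if (!is.null(prov$settings)) {
    lines <- c(lines, sprintf("mc_samples: %d", prov$settings$n_samples),
               sprintf("seed: %d", prov$settings$seed))
  }
  lines
}

#' Write a structured run report for a decision result
#'
#' Writes a key-value text report carrying the estimate together with its
#' full provenance (models, priors, threshold policy, Monte-Carlo seed and
#' standard errors), so a result can be audited and re-derived. The same
#' input always produces a byte-identical report.
#'
#' @param x A `decision_result`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path) {
  writeLines(format_report(x), path)
  invisible(path)
}
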