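#' Normalized histogram of single-cell responses
#'
#' Distribution-free response model: a normalized histogram whose bin
#' masses sum to one. Used when the Gaussian assumption is not wanted and
#' thresholds/error probabilities are read directly off the data.
#'
#' `build_histogram()` bins raw samples (default binning: the
#' Freedman-Diaconis rule, robust to heavy tails); `empirical_model()`
#' wraps pre-binned input.
#'
#' @param samples Numeric vector (>= 10 finite values).
#' @param binning A binning policy: a rule name accepted by
#'   [graphics::hist()] (`"FD"`, `"Sturges"`, `"Scott"`), a single bin
#'   count, or an explicit vector of break points. Recorded in the model.
#' @return An `empirical_model`: list with `bin_edges`, `bin_masses`,
#'   `n_source_samples`, `binning`.
#' @export
build_histogram <- function(samples, binning = "FD") {
  if (!is.numeric(samples)) stop_cd("`samples` must be numeric.", "domain_error")
  samples <- samples[is.finite(samples)]
  if (length(samples) < 10L) {
    stop_cd("Need at least 10 finite samples to build a histogram.",
            "degenerate_data")
  }
  h <- graphics::hist(samples, breaks = binning, plot = FALSE,
                      include.lowest = TRUE, right = TRUE)
  empirical_model(h$breaks, h$counts / sum(h$counts),
                  n_source_samples = length(samples), binning = binning)
}

#' @rdname build_histogram
#' @param bin_edges Strictly increasing numeric vector of bin boundaries.
#' @param bin_masses Probability mass per bin; must sum to 1 (tol 1e-12
#'   after normalization of counts).
#' @param n_source_samples Number of samples the histogram was built from.
#' @export
empirical_model <- function(bin_edges, bin_masses, n_source_samples,
                            binning = "supplied") {
  if (any(diff(bin_edges) <= 0)) {
    stop_cd("`bin_edges` must be strictly increasing.", "domain_error")
  }
  if (length(bin_masses) != length(bin_edges) - 1L) {
    stop_cd("`bin_masses` must have one entry per bin.", "domain_error")
  }
  if (any(bin_masses < 0) || abs(sum(bin_masses) - 1) > 1e-12) {
    stop_cd("`bin_masses` must be nonnegative and sum to 1.", "domain_error")
  }
  structure(
    list(bin_edges = as.numeric(bin_edges),
         bin_masses = as.numeric(bin_masses),
         n_source_samples = as.integer(n_source_samples),
         binning = binning),
    class = "empirical_model"
  )
}

#' @export
print.empirical_model <- function(x, ...) {
  cat(sprintf(
    "<empirical_model> %d bins on [%g, %g], from %d samples (binning: %s)\n",
    length(x$bin_masses), min(x$bin_edges), max(x$bin_edges),
    x$n_source_samples, paste(format(x$binning), collapse = ",")))
  invisible(x)
}

# Mass at or below q; thresholds inside a bin split its mass by linear
# interpolation, removing bin-width discontinuities. Vectorized over q.
empirical_cdf <- function(model, q) {
  edges <- model$bin_edges
  cum <- c(0, cumsum(model$bin_masses))
  vapply(q, function(qi) {
    if (qi <= edges[1]) return(0)
    if (qi >= edges[length(edges)]) return(1)
    i <- findInterval(qi, edges, rightmost.closed = TRUE)
    frac <- (qi - edges[i]) / (edges[i + 1] - edges[i])
    cum[i] + frac * model$bin_masses[i]
  }, numeric(1))
}

#' Error probabilities read directly off empirical histograms
#'
#' `P_FA` is the mass of the H0 histogram above the threshold; `P_M` is the
#' mass of the H1 histogram at or below it (ties decide H0). A threshold
#' inside a bin splits the bin mass by linear interpolation.
#'
#' @param model0,model1 `empirical_model` objects for H0 and H1.
#' @param threshold Finite decision threshold.
#' @param priors A [decision_priors()] object.
#' @return A `decision_result` with `method = "empirical"`.
#' @export
empirical_error <- function(model0, model1, threshold,
                            priors = decision_priors()) {
  stopifnot(inherits(model0, "empirical_model"),
            inherits(model1, "empirical_model"))
  check_scalar_number(threshold, "threshold")
  priors <- as_priors(priors)
  p_fa <- 1 - empirical_cdf(model0, threshold)
  p_m <- empirical_cdf(model1, threshold)
  new_decision_result(
    threshold = threshold, p_fa = p_fa, p_m = p_m,
    p_e = overall_error(p_fa, p_m, priors),
    method = "empirical",
    provenance = list(model0 = model0, model1 = model1, priors = priors)
  )
}

#' Empirical decision threshold minimizing the overall error
#'
#' Scans the union of both histograms' bin edges and returns the edge with
#' the smallest prior-weighted overall error (ties broken toward the lowest
#' edge). With disjoint supports any separating edge gives zero error; the
#' returned threshold then carries attribute `disjoint_support = TRUE` and
#' a message is emitted.
#'
#' @inheritParams empirical_error
#' @return The threshold (numeric scalar).
#' @export
empirical_threshold <- function(model0, model1, priors = decision_priors()) {
  stopifnot(inherits(model0, "empirical_model"),
            inherits(model1, "empirical_model"))
  priors <- as_priors(priors)
  candidates <- sort(unique(c(model0$bin_edges, model1$bin_edges)))
  p_fa <- 1 - empirical_cdf(model0, candidates)
  p_m <- empirical_cdf(model1, candidates)
  p_e <- priors$p_h0 * p_fa + priors$p_h1 * p_m
  th <- candidates[which.min(p_e)]
  if (min(p_e) == 0) {
    message("Supports are separable: returned threshold achieves zero ",
            "empirical error.")
    attr(th, "disjoint_support") <- TRUE
  }
  th
}

#' Error rates from raw samples at a fixed threshold
#'
#' When raw per-cell samples are available the tail fractions are computed
#' on the samples themselves, avoiding binning loss; histograms are for
#' pre-binned input. Ties at the threshold decide H0.
#'
#' @param samples0,samples1 Numeric response vectors under H0 and H1.
#' @inheritParams empirical_error
#' @return A `decision_result` with `method = "empirical"`.
#' @export
empirical_error_rates <- function(samples0, samples1, threshold,
                                  priors = decision_priors()) {
  check_scalar_number(threshold, "threshold")
  priors <- as_priors(priors)
  samples0 <- samples0[is.finite(samples0)]
  samples1 <- samples1[is.finite(samples1)]
  if (length(samples0) == 0L || length(samples1) == 0L) {
    stop_cd("Both sample sets must be non-empty.", "degenerate_data")
  }
  p_fa <- mean(samples0 > threshold)
  p_m <- mean(samples1 <= threshold)
  new_decision_result(
    threshold = threshold, p_fa = p_fa, p_m = p_m,
    p_e = overall_error(p_fa, p_m, priors),
    method = "empirical",
    provenance = list(n0 = length(samples0), n1 = length(samples1),
                      priors = priors)
  )
}
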