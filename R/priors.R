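#' Prior probabilities of the two hypotheses
#'
#' Priors for the binary hypothesis test: H0, the stimulus is low, versus
#' H1, the stimulus is high. Equal priors (the default) encode the absence
#' of a priori knowledge about the input and make the optimal rule the
#' plain maximum-likelihood decision; unequal priors tilt the rule to
#' compare `P(H1) p(x|H1)` against `P(H0) p(x|H0)`.
#'
#' @param p_h0 Prior probability of H0, in (0, 1).
#' @param p_h1 Prior probability of H1; defaults to `1 - p_h0` and the two
#'   must sum to one.
#' @return An object of class `decision_priors` with fields `p_h0`, `p_h1`.
#' @export
decision_priors <- function(p_h0 = 0.5, p_h1 = 1 - p_h0) {
  check_scalar_number(p_h0, "p_h0")
  check_scalar_number(p_h1, "p_h1")
  if (p_h0 <= 0 || p_h0 >= 1 || p_h1 <= 0 || p_h1 >= 1) {
    stop_cd("Priors must lie strictly inside (0, 1).", "domain_error")
  }
  if (abs(p_h0 + p_h1 - 1) > 1e-8) {
    stop_cd("Priors must sum to 1.", "domain_error")
  }
  structure(list(p_h0 = as.numeric(p_h0), p_h1 = as.numeric(p_h1)),
            class = "decision_priors")
}

#' @export
print.decision_priors <- function(x, ...) {
  cat(sprintf("<decision_priors> P(H0) = %g, P(H1) = %g (cutoff gamma = %g)\n",
              x$p_h0, x$p_h1, likelihood_ratio_cutoff(x)))
  invisible(x)
}

#' Likelihood-ratio cutoff implied by the priors
#'
#' The optimal rule decides H1 when the likelihood ratio
#' `L(x) = p(x|H1)/p(x|H0)` exceeds `gamma = P(H0)/P(H1)`.
#'
#' @param priors A [decision_priors()] object.
#' @return The scalar cutoff `gamma`.
#' @export
likelihood_ratio_cutoff <- function(priors) {
  stopifnot(inherits(priors, "decision_priors"))
  priors$p_h0 / priors$p_h1
}

as_priors <- function(priors) {
  if (inherits(priors, "decision_priors")) return(priors)
  if (is.numeric(priors) && length(priors) == 2L) {
    return(decision_priors(priors[[1]], priors[[2]]))
  }
  stop_cd("`priors` must be a decision_priors object or a length-2 numeric.",
          "domain_error")
}
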