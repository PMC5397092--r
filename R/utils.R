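stop_cd <- function(msg, class, ...) {
  rlang::abort(msg, class = paste0("celldecide_", class), ...)
}

check_scalar_number <- function(x, name, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop_cd(sprintf("`%s` must be a single number.", name), "domain_error")
  }
  if (finite && !is.finite(x)) {
    stop_cd(sprintf("`%s` must be finite.", name), "domain_error")
  }
  invisible(as.numeric(x))
}

check_probability <- function(x, name) {
  check_scalar_number(x, name)
  if (x < 0 || x > 1) {
    stop_cd(sprintf("`%s` must lie in [0, 1], got %g.", name, x), "domain_error")
  }
  invisible(as.numeric(x))
}

# Gaussian interval mass; handles infinite endpoints.
gauss_mass <- function(mean, sd, lower, upper) {
  stats::pnorm(upper, mean, sd) - stats::pnorm(lower, mean, sd)
}
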