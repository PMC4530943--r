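#' Default prior specification for the trend model
#'
#' Returns the vague priors used in the study, recorded with their original
#' parameterizations: normal priors carry a mean and a precision
#' (1/variance), lognormal priors the natural log of the median and the
#' precision of the log, the gamma prior its shape and rate, and the uniform
#' its bounds. Two readings are ambiguous in the source material and are
#' resolved by explicit switches in [build_config()]: the site-intercept
#' family (lognormal by default) and whether the Gamma(0.01, 0.01) residual
#' prior sits on the precision (default) or the variance.
#'
#' @return A list of class `murre_priors`, one entry per parameter class.
#' @export
default_priors <- function() {
  structure(list(
    a        = list(dist = "normal",    mean = 0,    precision = 10000),
    c        = list(dist = "normal",    mean = 0,    precision = 0.01),
    resid    = list(dist = "gamma",     shape = 0.01, rate = 0.01),
    t        = list(dist = "normal",    mean = 0,    precision = 1),
    sigma_Y  = list(dist = "lognormal", logmedian = 2.303, logprecision = 1.5625),
    mu_b0    = list(dist = "uniform",   lower = 1,   upper = 2000),
    sigma_b0 = list(dist = "lognormal", logmedian = 3.91, logprecision = 1.5625),
    mu_b1    = list(dist = "normal",    mean = 0,    precision = 0.0001),
    sigma_b1 = list(dist = "lognormal", logmedian = 2.30, logprecision = 1.5625)
  ), class = "murre_priors")
}

# sd implied by a precision parameterization
prec_sd <- function(precision) 1 / sqrt(precision)

# log-density of a residual SD under Gamma(shape, rate) placed on the
# precision 1/sigma^2 (default BUGS idiom) or on the variance sigma^2;
# includes the change-of-variables Jacobian so the density is in sigma.
dsigma_resid <- function(sigma, shape, rate, on = c("precision", "variance")) {
  on <- match.arg(on)
  out <- rep(-Inf, length(sigma))
  ok <- is.finite(sigma) & sigma > 0
  if (on == "precision") {
    tau <- sigma[ok]^-2
    out[ok] <- dgamma(tau, shape = shape, rate = rate, log = TRUE) +
      log(2) - 3 * log(sigma[ok])
  } else {
    v <- sigma[ok]^2
    out[ok] <- dgamma(v, shape = shape, rate = rate, log = TRUE) +
      log(2 * sigma[ok])
  }
  out
}
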