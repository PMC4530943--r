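#' Predicted radar count for surveys under a parameter vector
#'
#' Evaluates the trend model's mean structure for one or more survey rows:
#' a site-level linear trend referenced to the site's mean survey year,
#' multiplied by the region-year effect, the quadratic day-of-year detection
#' curve, and the linear radar-tilt detection factor,
#' \deqn{\hat C = (b_{0,s} + b_{1,s}(y-\bar y_s))(1+Y_{R,y})
#'   (1+a_R(D-c_R)^2)(1+tT).}
#' Non-positive values are returned as-is; the likelihood layer treats them
#' as impossible (the lognormal has positive support).
#'
#' @param theta named parameter vector (see [theta_template()]).
#' @param rec a data.frame of survey rows (`region`, `site`, `year`, `doy`,
#'   `tilt_deg`) or a [murre_data] object.
#' @param cfg a `murre_config`.
#' @return numeric vector of expected counts, one per row.
#' @export
predicted_count <- function(theta, rec, cfg) {
  if (inherits(rec, "murre_data")) rec <- rec$records
  unknown <- setdiff(rec$site, cfg$sites)
  if (length(unknown) > 0) {
    stop("key error: site not in model configuration: ", unknown[1])
  }
  b0 <- theta[sprintf("b0[%s]", rec$site)]
  b1 <- theta[sprintf("b1[%s]", rec$site)]
  ybar <- cfg$site_mean_year[rec$site]
  Y <- year_effect_value(theta, rec$region, rec$year, cfg)
  a <- theta[sprintf("a[%s]", rec$region)]
  cc <- theta[sprintf("c[%s]", rec$region)]
  D <- rec$doy - cfg$doy_center
  tt <- theta["t"]
  unname((b0 + b1 * (rec$year - ybar)) * (1 + Y) *
           (1 + a * (D - cc)^2) * (1 + tt * rec$tilt_deg))
}

#' Lognormal log-likelihood of observed counts
#'
#' Sum over surveys of the lognormal log-density of the observed count with
#' location \eqn{\log\hat C} and region-specific scale \eqn{\sigma_R}.
#' Returns `-Inf` whenever any predicted count is non-positive (outside the
#' lognormal support). Counts must be >= 1, i.e. post-[filter_surveys()].
#'
#' @inheritParams predicted_count
#' @param data a [murre_data] object (filtered).
#' @return scalar log-likelihood.
#' @export
log_likelihood <- function(theta, data, cfg) {
  rec <- if (inherits(data, "murre_data")) data$records else data
  chat <- predicted_count(theta, rec, cfg)
  if (any(chat <= 0)) return(-Inf)
  sig <- theta[sprintf("sigma_R[%s]", rec$region)]
  if (any(sig <= 0)) return(-Inf)
  C <- rec$count_in
  sum(-log(C) - log(sig) - 0.5 * log(2 * pi) -
        (log(C / chat))^2 / (2 * sig^2))
}

#' Log prior density of a parameter vector
#'
#' Sum of log prior densities over all parameters, including the
#' hierarchical terms: site intercepts given (mu_b0, sigma_b0), site slopes
#' given (mu_b1, sigma_b1), estimated year effects given sigma_Y, and the
#' hyperpriors of the five hyperparameters. Fixed-at-zero year effects are
#' constants and contribute nothing. Support violations (non-positive SDs,
#' mean intercept outside its uniform bounds, non-positive intercepts under
#' the lognormal family) give `-Inf`.
#'
#' @inheritParams predicted_count
#' @return scalar log prior density.
#' @export
log_prior <- function(theta, cfg) {
  idx <- cfg$param_index
  pr <- cfg$priors
  mu_b0 <- theta["mu_b0"]; sigma_b0 <- theta["sigma_b0"]
  mu_b1 <- theta["mu_b1"]; sigma_b1 <- theta["sigma_b1"]
  sigma_Y <- theta["sigma_Y"]

  if (sigma_b0 <= 0 || sigma_b1 <= 0 || sigma_Y <= 0) return(-Inf)
  if (mu_b0 < pr$mu_b0$lower || mu_b0 > pr$mu_b0$upper) return(-Inf)

  b0 <- theta[idx$type == "b0"]
  b1 <- theta[idx$type == "b1"]
  Y <- theta[idx$type == "Y"]
  a <- theta[idx$type == "a"]
  cc <- theta[idx$type == "c"]
  sig_R <- theta[idx$type == "sigma_R"]
  tt <- theta["t"]

  lp_b0 <- if (cfg$b0_prior == "lognormal") {
    if (any(b0 <= 0)) return(-Inf)
    sum(dlnorm(b0, meanlog = log(mu_b0), sdlog = sigma_b0, log = TRUE))
  } else {
    sum(dnorm(b0, mean = mu_b0, sd = sigma_b0, log = TRUE))
  }

  lp <- lp_b0 +
    sum(dnorm(b1, mu_b1, sigma_b1, log = TRUE)) +
    sum(dnorm(Y, 0, sigma_Y, log = TRUE)) +
    sum(dnorm(a, pr$a$mean, prec_sd(pr$a$precision), log = TRUE)) +
    sum(dnorm(cc, pr$c$mean, prec_sd(pr$c$precision), log = TRUE)) +
    sum(dsigma_resid(sig_R, pr$resid$shape, pr$resid$rate, cfg$resid_prior_on)) +
    dnorm(tt, pr$t$mean, prec_sd(pr$t$precision), log = TRUE) +
    dunif(mu_b0, pr$mu_b0$lower, pr$mu_b0$upper, log = TRUE) +
    dlnorm(sigma_b0, pr$sigma_b0$logmedian, prec_sd(pr$sigma_b0$logprecision), log = TRUE) +
    dnorm(mu_b1, pr$mu_b1$mean, prec_sd(pr$mu_b1$precision), log = TRUE) +
    dlnorm(sigma_b1, pr$sigma_b1$logmedian, prec_sd(pr$sigma_b1$logprecision), log = TRUE) +
    dlnorm(sigma_Y, pr$sigma_Y$logmedian, prec_sd(pr$sigma_Y$logprecision), log = TRUE)
  unname(lp)
}

#' Log posterior density (unnormalized)
#'
#' [log_likelihood()] plus [log_prior()]; `-Inf` propagates.
#'
#' @inheritParams log_likelihood
#' @return scalar.
#' @export
log_posterior <- function(theta, data, cfg) {
  lp <- log_prior(theta, cfg)
  if (!is.finite(lp)) return(-Inf)
  lp + log_likelihood(theta, data, cfg)
}
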