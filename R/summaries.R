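#' Per-draw proportional rate of change at a site
#'
#' The site trend expressed as proportional change per year: slope divided
#' by intercept, where the intercept is the expected count in the site's
#' mean survey year. Computed draw by draw, so every derived statistic
#' (median, credibility bounds, probability of decline) is a true posterior
#' summary.
#'
#' @param fit a `murre_fit`.
#' @param site site label.
#' @return numeric vector, one rate per retained draw (chains combined).
#' @export
rate_of_change <- function(fit, site) {
  if (!site %in% fit$cfg$sites) stop("unknown site: ", site)
  d <- fit_draws(fit, c(sprintf("b0[%s]", site), sprintf("b1[%s]", site)))
  unname(d[, 2] / d[, 1])
}

#' Per-draw mean rate of change for a region or the whole coast
#'
#' The unit-level rate is the unweighted arithmetic mean of the member
#' sites' rates, taken within each draw (aggregation before summarization,
#' so the posterior of the mean is propagated exactly).
#'
#' @param fit a `murre_fit`.
#' @param unit a region code, or `"coast"` for all sites.
#' @return numeric vector, one mean rate per retained draw.
#' @export
aggregate_rate <- function(fit, unit) {
  sites <- if (identical(unit, "coast")) fit$cfg$sites
           else fit$cfg$sites[fit$cfg$site_region == unit]
  if (length(sites) == 0) stop("no sites in unit: ", unit)
  b0 <- fit_draws(fit, sprintf("b0[%s]", sites))
  b1 <- fit_draws(fit, sprintf("b1[%s]", sites))
  unname(rowMeans(b1 / b0))
}

#' Posterior probability of decline
#'
#' Fraction of retained draws in which the rate is strictly negative;
#' draws exactly at zero count as non-declines.
#'
#' @param rates numeric vector of per-draw rates.
#' @return probability in \[0, 1\].
#' @export
prob_decline <- function(rates) {
  if (length(rates) == 0) stop("empty rate series")
  mean(rates < 0)
}

#' Posterior median and credibility bounds of a rate series
#'
#' Empirical quantiles at the 2.5, 5, 50, 95 and 97.5 percentiles, using
#' linear interpolation between order statistics (R's default type-7 rule).
#'
#' @param rates numeric vector of per-draw values.
#' @param unit label for the output row.
#' @return one-row data.frame: `unit`, `median`, `l95`, `u95`, `l90`,
#'   `u90`, `p_decline`.
#' @export
credibility_intervals <- function(rates, unit = "") {
  if (length(rates) == 0) stop("empty rate series")
  q <- unname(quantile(rates, c(0.025, 0.05, 0.5, 0.95, 0.975), type = 7))
  data.frame(unit = unit, median = q[3], l95 = q[1], u95 = q[5],
             l90 = q[2], u90 = q[4], p_decline = prob_decline(rates))
}

#' Posterior day-of-year detection curve for a region
#'
#' The seasonal detection factor \eqn{1 + a_R (D - c_R)^2} over the survey
#' season, with the extremum at day \eqn{182 + c_R}: a maximum when
#' \eqn{a_R < 0}, a minimum when \eqn{a_R > 0}. (Reading the offset as
#' \eqn{182 - c_R} instead would mirror the extremum about mid-year; the
#' model follows the mean-structure algebra, and the alternative day is
#' reported in `extremum_day_mirrored` for reference.)
#'
#' @param fit a `murre_fit`.
#' @param region region code.
#' @param days days of year to evaluate (default 127:227, the survey season).
#' @return list: `extremum_day` (per-draw), `kind` (`"maximum"`/`"minimum"`
#'   by the posterior median sign of `a`), `prop_maximum` (share of draws
#'   with a < 0), `curve` (data.frame day, median, l95, u95 of the factor),
#'   `extremum_day_mirrored` (posterior median of 182 - c).
#' @export
doy_curve <- function(fit, region, days = 127:227) {
  if (!region %in% fit$cfg$regions) stop("unknown region: ", region)
  d <- fit_draws(fit, c(sprintf("a[%s]", region), sprintf("c[%s]", region)))
  a <- d[, 1]; cc <- d[, 2]
  ctr <- fit$cfg$doy_center
  fac <- vapply(days, function(day) {
    f <- 1 + a * (day - ctr - cc)^2
    quantile(f, c(0.5, 0.025, 0.975), type = 7)
  }, numeric(3))
  list(extremum_day = ctr + cc,
       kind = if (median(a) < 0) "maximum" else "minimum",
       prop_maximum = mean(a < 0),
       curve = data.frame(day = days, median = fac[1, ],
                          l95 = fac[2, ], u95 = fac[3, ]),
       extremum_day_mirrored = ctr - median(cc))
}

#' Deterministic tilt detection factor
#'
#' The multiplicative detection effect of tilting the radar antenna upward
#' by `tilt_deg` degrees given a tilt coefficient `t`: `1 + t * tilt_deg`.
#'
#' @param t tilt coefficient (per degree).
#' @param tilt_deg radar tilt in degrees.
#' @return numeric.
#' @export
tilt_factor <- function(t, tilt_deg) 1 + t * tilt_deg

#' Posterior tilt detection multiplier
#'
#' Per-draw multiplicative factor `1 + t * tilt_deg`; exactly 1 at zero
#' tilt. Both the posterior median and mean are reported in attributes,
#' since either may be quoted as "the" effect.
#'
#' @param fit a `murre_fit`.
#' @param tilt_deg radar tilt in degrees (>= 0).
#' @return numeric vector of per-draw factors, with attributes `median` and
#'   `mean`.
#' @export
tilt_multiplier <- function(fit, tilt_deg) {
  stopifnot(tilt_deg >= 0)
  f <- tilt_factor(fit_draws(fit, "t")[, 1], tilt_deg)
  attr(f, "median") <- median(f)
  attr(f, "mean") <- mean(f)
  f
}

post_summary_row <- function(x) {
  q <- unname(quantile(x, c(0.5, 0.025, 0.975), type = 7))
  data.frame(median = q[1], mean = mean(x), l95 = q[2], u95 = q[3],
             signif95 = q[2] > 0 | q[3] < 0)
}

#' Report tables for a converged fit
#'
#' Emits the three standard posterior tables: (1) hyperparameters, tilt,
#' and per-region day-of-year and residual-SD parameters; (2) trends
#' (proportional rate of change with 95% and 90% bounds and probability of
#' decline) at coast, region and site scale; (3) estimated year effects
#' with 95% bounds. A significance flag marks intervals excluding zero.
#' Refuses to run unless the convergence gate passed (override with
#' `force = TRUE` for diagnostics).
#'
#' @param fit a `murre_fit`.
#' @param gate result of [convergence_gate()]; computed if missing.
#' @param force emit tables even if the gate failed.
#' @return list of data.frames `parameters`, `trends`, `year_effects`,
#'   plus the `gate` verdict.
#' @export
report_tables <- function(fit, gate = NULL, force = FALSE) {
  if (is.null(gate)) gate <- convergence_gate(fit)
  if (!gate$pass && !force) {
    stop(sprintf(paste0("convergence gate failed (max Rhat %.3f, max MC ratio %.3f; ",
                        "%d parameters flagged); not emitting trend tables"),
                 gate$rhat_max, gate$mc_ratio_max,
                 length(gate$failed_rhat) + length(gate$failed_mc)))
  }
  cfg <- fit$cfg
  hyper <- c("t", "sigma_Y", "mu_b1", "sigma_b1", "mu_b0", "sigma_b0")
  hyper <- intersect(hyper, fit$param_names)
  region_pars <- c(sprintf("a[%s]", cfg$regions), sprintf("c[%s]", cfg$regions),
                   sprintf("sigma_R[%s]", cfg$regions))
  region_pars <- intersect(region_pars, fit$param_names)
  pars <- c(hyper, region_pars)
  ptab <- do.call(rbind, lapply(pars, function(p) {
    cbind(data.frame(param = p), post_summary_row(fit_draws(fit, p)[, 1]))
  }))

  units <- c(list(c("coast", "coast")),
             lapply(cfg$regions, function(r) c("region", r)),
             lapply(cfg$sites, function(s) c("site", s)))
  ttab <- do.call(rbind, lapply(units, function(u) {
    rates <- if (u[1] == "site") rate_of_change(fit, u[2])
             else aggregate_rate(fit, if (u[1] == "coast") "coast" else u[2])
    row <- credibility_intervals(rates, unit = u[2])
    cbind(data.frame(level = u[1]), row)
  }))
  ttab$signif95 <- ttab$l95 > 0 | ttab$u95 < 0
  ttab$signif90 <- ttab$l90 > 0 | ttab$u90 < 0

  ye <- cfg$year_estimated
  ytab <- NULL
  if (nrow(ye) > 0) {
    ytab <- do.call(rbind, lapply(seq_len(nrow(ye)), function(i) {
      p <- sprintf("Y[%s:%d]", ye$region[i], ye$year[i])
      cbind(data.frame(region = ye$region[i], year = ye$year[i]),
            post_summary_row(fit_draws(fit, p)[, 1]))
    }))
  }
  rownames(ptab) <- rownames(ttab) <- NULL
  list(parameters = ptab, trends = ttab, year_effects = ytab, gate = gate)
}
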