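#' Year effects fixed at zero in the British Columbia study design
#'
#' Per region, the calendar years whose region-wide year effect is fixed at
#' zero: the reference year chosen near the centre of each region's time
#' series (to minimize confounding with the site slopes) together with years
#' that had too few sites sampled to estimate a shared effect. The Central
#' Mainland Coast (CC) is handled separately: all its year effects are fixed
#' because its sites have four or fewer surveyed years each (see
#' `all_fixed_regions` in [build_config()]).
#'
#' @return Named list of integer year vectors.
#' @export
murrelet_fixed_years <- function() {
  list(HG = c(2003, 2004, 2005, 2007),
       EV = 2006,
       WC = 2007,
       NC = c(1998, 2001, 2009),
       SC = c(2000, 2008))
}

#' Build a model configuration from a filtered dataset
#'
#' Determines the free parameter set implied by the survey design: which
#' (region, year) cells receive an estimated year effect, each site's mean
#' survey year (the reference point of its trend line), and the prior
#' specification. Every (region, year) cell present in the data ends up in
#' exactly one of the estimated or fixed-at-zero sets.
#'
#' @param data a filtered [murre_data] object.
#' @param fixed_zero named list (region -> years) of year effects fixed at
#'   zero; defaults to [murrelet_fixed_years()] for the six study regions.
#' @param reference_years named vector (region -> year) of additional
#'   reference years fixed at zero. Any region left without a fixed year
#'   gets its central observed year fixed automatically, which the model
#'   requires for identifiability of year effects against the trend.
#' @param all_fixed_regions regions whose year effects are all fixed at zero
#'   (default `"CC"`, where sites have too few surveyed years).
#' @param min_sites_per_year region-years observed at fewer sites than this
#'   are fixed at zero (default 2): a shared effect cannot be separated from
#'   site-level noise with a single site.
#' @param priors a `murre_priors` list, default [default_priors()].
#' @param b0_prior `"lognormal"` (default) or `"normal"` family for site
#'   intercepts; the lognormal reading keeps intercepts positive and
#'   reproduces order-of-magnitude spread among sites.
#' @param resid_prior_on `"precision"` (default) or `"variance"`: where the
#'   Gamma(0.01, 0.01) residual prior is placed.
#' @param doy_center day-of-year centering constant (default 182, mid-year).
#' @return A `murre_config` object.
#' @export
build_config <- function(data,
                         fixed_zero = murrelet_fixed_years(),
                         reference_years = NULL,
                         all_fixed_regions = "CC",
                         min_sites_per_year = 2,
                         priors = default_priors(),
                         b0_prior = c("lognormal", "normal"),
                         resid_prior_on = c("precision", "variance"),
                         doy_center = 182) {
  stopifnot(inherits(data, "murre_data"))
  b0_prior <- match.arg(b0_prior)
  resid_prior_on <- match.arg(resid_prior_on)
  rec <- data$records

  regions <- sort(unique(rec$region))
  sites <- sort(unique(rec$site))
  site_region <- data$site_index[sites]

  # observation-weighted mean year per site: the trend intercept's reference
  site_mean_year <- c(tapply(rec$year, rec$site, mean))[sites]

  cells <- unique(rec[, c("region", "year")])
  cells <- cells[order(cells$region, cells$year), ]
  rownames(cells) <- NULL

  n_sites_cell <- aggregate(site ~ region + year,
                            data = unique(rec[, c("region", "year", "site")]),
                            FUN = length)
  names(n_sites_cell) <- c("region", "year", "n_sites")
  cells <- merge(cells, n_sites_cell, by = c("region", "year"), sort = FALSE)

  fixed <- logical(nrow(cells))
  for (r in names(fixed_zero)) {
    if (!r %in% regions) next
    yrs <- fixed_zero[[r]]
    absent <- setdiff(yrs, cells$year[cells$region == r])
    if (length(absent) > 0) {
      warning(sprintf("fixed-zero year(s) %s not observed in region %s; ignored",
                      paste(absent, collapse = ","), r))
    }
    fixed[cells$region == r & cells$year %in% yrs] <- TRUE
  }
  if (!is.null(reference_years)) {
    for (r in names(reference_years)) {
      if (!r %in% regions) next
      yr <- reference_years[[r]]
      hit <- cells$region == r & cells$year == yr
      if (!any(hit)) {
        stop(sprintf("config error: reference year %d absent from region %s data", yr, r))
      }
      fixed[hit] <- TRUE
    }
  }
  fixed[cells$region %in% all_fixed_regions] <- TRUE
  fixed[cells$n_sites < min_sites_per_year] <- TRUE

  # identifiability: a region with estimated year effects needs >= 1 fixed
  # year anchoring the trend; fix the central observed year if none listed
  for (r in regions) {
    in_r <- cells$region == r
    if (any(in_r) && !any(fixed[in_r])) {
      yrs <- cells$year[in_r]
      central <- yrs[which.min(abs(yrs - median(yrs)))]
      fixed[in_r & cells$year == central] <- TRUE
    }
  }

  cfg <- structure(list(
    regions = regions,
    sites = sites,
    site_region = site_region,
    site_mean_year = site_mean_year,
    doy_center = doy_center,
    year_estimated = cells[!fixed, c("region", "year")],
    year_fixed_zero = cells[fixed, c("region", "year")],
    priors = priors,
    b0_prior = b0_prior,
    resid_prior_on = resid_prior_on
  ), class = "murre_config")
  rownames(cfg$year_estimated) <- NULL
  rownames(cfg$year_fixed_zero) <- NULL
  cfg$param_index <- build_param_index(cfg)
  cfg
}

# Registry of free parameters, in the fixed order the sampler relies on:
# site intercepts, site slopes, estimated year effects, then per-region DOY
# pairs, residual SDs, the tilt coefficient, and the five hyperparameters.
build_param_index <- function(cfg) {
  ye <- cfg$year_estimated
  idx <- rbind(
    data.frame(type = "b0", unit = cfg$sites, year = NA_integer_),
    data.frame(type = "b1", unit = cfg$sites, year = NA_integer_),
    if (nrow(ye) > 0) data.frame(type = "Y", unit = ye$region, year = ye$year),
    data.frame(type = "a", unit = cfg$regions, year = NA_integer_),
    data.frame(type = "c", unit = cfg$regions, year = NA_integer_),
    data.frame(type = "sigma_R", unit = cfg$regions, year = NA_integer_),
    data.frame(type = c("t", "mu_b0", "sigma_b0", "mu_b1", "sigma_b1", "sigma_Y"),
               unit = NA_character_, year = NA_integer_)
  )
  idx$name <- ifelse(idx$type == "Y",
                     sprintf("Y[%s:%d]", idx$unit, idx$year),
                     ifelse(is.na(idx$unit), idx$type,
                            sprintf("%s[%s]", idx$type, idx$unit)))
  rownames(idx) <- NULL
  idx
}

#' @export
print.murre_config <- function(x, ...) {
  cat(sprintf("<murre_config> %d sites, %d regions; %d estimated + %d fixed year-effect cells; %d free parameters\n",
              length(x$sites), length(x$regions), nrow(x$year_estimated),
              nrow(x$year_fixed_zero), count_parameters(x)))
  cat(sprintf("  site intercept prior: %s; residual Gamma prior on: %s\n",
              x$b0_prior, x$resid_prior_on))
  invisible(x)
}

#' Count free parameters implied by a model configuration
#'
#' Two day-of-year coefficients and one residual SD per region, one tilt
#' coefficient, one year effect per estimated (region, year) cell, a slope
#' and an intercept per site, and five hyperparameters.
#'
#' @param cfg a `murre_config`.
#' @return integer.
#' @export
count_parameters <- function(cfg) {
  stopifnot(inherits(cfg, "murre_config"))
  2L * length(cfg$regions) + length(cfg$regions) + 1L +
    nrow(cfg$year_estimated) + 2L * length(cfg$sites) + 5L
}

#' Template parameter vector for a configuration
#'
#' Returns a named numeric vector with one entry per free parameter, in the
#' canonical order of `cfg$param_index`, filled with neutral values (unit
#' intercepts at the prior intercept median, all modifiers at identity,
#' SDs at 1).
#'
#' @param cfg a `murre_config`.
#' @return named numeric vector.
#' @export
theta_template <- function(cfg) {
  idx <- cfg$param_index
  theta <- setNames(numeric(nrow(idx)), idx$name)
  theta[idx$type %in% c("sigma_R", "sigma_b0", "sigma_b1", "sigma_Y")] <- 1
  theta["mu_b0"] <- 64
  theta[idx$type == "b0"] <- 64
  theta
}

# lookup of the year-effect value for (region, year) under theta:
# estimated cells -> parameter value, fixed cells -> exactly 0
year_effect_value <- function(theta, region, year, cfg) {
  nm <- sprintf("Y[%s:%d]", region, year)
  est <- nm %in% names(theta)
  out <- numeric(length(nm))
  out[est] <- theta[nm[est]]
  is_fixed <- paste(region, year) %in%
    paste(cfg$year_fixed_zero$region, cfg$year_fixed_zero$year)
  if (any(!est & !is_fixed)) {
    bad <- which(!est & !is_fixed)[1]
    stop(sprintf("key error: (region %s, year %d) not in the model configuration",
                 region[bad], year[bad]))
  }
  out
}
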