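#' MCMC settings
#'
#' The production protocol is two chains from distinct overdispersed starts,
#' a 40,000-iteration burn-in and 80,000 retained iterations per chain, with
#' no thinning (retained draws are used only for summary statistics, so
#' autocorrelated draws cost nothing but storage). The `"test"` preset
#' (2,000 burn-in, 8,000 retained) is for desk-scale work such as
#' simulation studies.
#'
#' @param n_chains number of chains (>= 2 for convergence diagnostics).
#' @param n_burnin burn-in iterations discarded per chain.
#' @param n_keep retained iterations per chain.
#' @param seed integer RNG seed; fits are reproducible given the seed.
#' @param init_dispersion scale of the random jitter applied to initial
#'   values, giving each chain a distinct overdispersed start.
#' @param preset `"production"` or `"test"`; explicit arguments override.
#' @return list of class `murre_mcmc_settings`.
#' @export
mcmc_settings <- function(n_chains = 2, n_burnin = NULL, n_keep = NULL,
                          seed = 1, init_dispersion = 0.3,
                          preset = c("production", "test")) {
  preset <- match.arg(preset)
  defaults <- if (preset == "production") c(40000L, 80000L) else c(2000L, 8000L)
  if (is.null(n_burnin)) n_burnin <- defaults[1]
  if (is.null(n_keep)) n_keep <- defaults[2]
  stopifnot(n_chains >= 1, n_keep > 0, n_burnin >= 0)
  structure(list(n_chains = as.integer(n_chains),
                 n_burnin = as.integer(n_burnin),
                 n_keep = as.integer(n_keep),
                 seed = as.integer(seed),
                 init_dispersion = init_dispersion,
                 preset = preset),
            class = "murre_mcmc_settings")
}

# Flatten data + config into the index arrays the compiled sampler uses.
prepare_model_arrays <- function(data, cfg) {
  rec <- data$records
  site_i <- match(rec$site, cfg$sites)
  region_i <- match(rec$region, cfg$regions)
  ye <- cfg$year_estimated
  cell_key <- paste(ye$region, ye$year)
  ycell <- match(paste(rec$region, rec$year), cell_key)
  fixed_key <- paste(cfg$year_fixed_zero$region, cfg$year_fixed_zero$year)
  orphan <- is.na(ycell) & !(paste(rec$region, rec$year) %in% fixed_key)
  if (any(orphan)) {
    stop("key error: observation in (region, year) cell absent from the configuration")
  }
  ycell[is.na(ycell)] <- 0L
  pr <- cfg$priors
  list(
    site = site_i - 1L,
    region = region_i - 1L,
    ycell = as.integer(ycell - 1L),
    dy = rec$year - unname(cfg$site_mean_year[rec$site]),
    D = rec$doy - cfg$doy_center,
    tilt = rec$tilt_deg,
    C = as.numeric(rec$count_in),
    logC = log(as.numeric(rec$count_in)),
    S = length(cfg$sites), R = length(cfg$regions), K = nrow(ye),
    prior_const = c(
      a_sd = prec_sd(pr$a$precision), c_sd = prec_sd(pr$c$precision),
      t_sd = prec_sd(pr$t$precision),
      resid_shape = pr$resid$shape, resid_rate = pr$resid$rate,
      mu_b0_lo = pr$mu_b0$lower, mu_b0_hi = pr$mu_b0$upper,
      sig_b0_logmed = pr$sigma_b0$logmedian,
      sig_b0_logsd = prec_sd(pr$sigma_b0$logprecision),
      mu_b1_sd = prec_sd(pr$mu_b1$precision),
      sig_b1_logmed = pr$sigma_b1$logmedian,
      sig_b1_logsd = prec_sd(pr$sigma_b1$logprecision),
      sig_Y_logmed = pr$sigma_Y$logmedian,
      sig_Y_logsd = prec_sd(pr$sigma_Y$logprecision)),
    b0_lognormal = cfg$b0_prior == "lognormal",
    resid_on_precision = cfg$resid_prior_on == "precision")
}

# observation index list per parameter (0-based, for the compiled core)
obs_index_list <- function(model, cfg) {
  idx <- cfg$param_index
  n <- nrow(idx)
  all_obs <- seq_along(model$site) - 1L
  by_site <- split(all_obs, model$site)
  by_region <- split(all_obs, model$region)
  by_cell <- split(all_obs, model$ycell)
  empty <- integer(0)
  out <- vector("list", n)
  for (k in seq_len(n)) {
    out[[k]] <- switch(idx$type[k],
      b0 = ,
      b1 = by_site[[as.character(match(idx$unit[k], cfg$sites) - 1L)]],
      Y = by_cell[[as.character(k - 2L * length(cfg$sites) - 1L)]],
      a = ,
      c = ,
      sigma_R = by_region[[as.character(match(idx$unit[k], cfg$regions) - 1L)]],
      t = all_obs,
      empty)
    if (is.null(out[[k]])) out[[k]] <- empty
  }
  out
}

# Overdispersed but posterior-feasible initial values: intercepts near the
# site mean counts, slopes and modifiers near zero, SDs at 0.5, jittered by
# init_dispersion so chains start apart.
initial_theta <- function(data, cfg, dispersion) {
  idx <- cfg$param_index
  rec <- data$records
  site_mean <- tapply(rec$count_in, rec$site, mean)[cfg$sites]
  theta <- setNames(numeric(nrow(idx)), idx$name)
  jit <- function(n, s = 1) exp(s * dispersion * rnorm(n))
  nS <- length(cfg$sites)
  theta[idx$type == "b0"] <- pmax(site_mean * jit(nS), 0.5)
  theta[idx$type == "b1"] <- 0.2 * dispersion * rnorm(nS)
  theta[idx$type == "sigma_R"] <- 0.5 * jit(length(cfg$regions))
  theta["mu_b0"] <- min(max(mean(site_mean) * jit(1), 1.5), 1999)
  theta["sigma_b0"] <- 0.8 * jit(1)
  theta["mu_b1"] <- 0.2 * dispersion * rnorm(1)
  theta["sigma_b1"] <- 1.0 * jit(1)
  theta["sigma_Y"] <- 0.5 * jit(1)
  theta
}

# Positive-support parameters with right-skewed posteriors are proposed on
# the log scale (multiplicative random walk with Jacobian); their scales
# are log-scale step sizes. mu_b0 stays additive because of its bounds,
# and site intercepts stay additive under the normal-family switch.
proposal_types <- function(cfg) {
  idx <- cfg$param_index
  mult <- idx$type %in% c("sigma_R", "sigma_b0", "sigma_b1", "sigma_Y") |
    (idx$type == "b0" & cfg$b0_prior == "lognormal")
  as.integer(mult)
}

default_scales <- function(theta, cfg, types = proposal_types(cfg)) {
  idx <- cfg$param_index
  sc <- setNames(numeric(nrow(idx)), idx$name)
  sc[idx$type == "b0"] <- pmax(0.1 * abs(theta[idx$type == "b0"]), 0.5)
  sc[idx$type == "b1"] <- 0.5
  sc[idx$type == "Y"] <- 0.15
  sc[idx$type == "a"] <- 1e-4
  sc[idx$type == "c"] <- 3
  sc["t"] <- 0.03
  sc["mu_b0"] <- 5
  sc["mu_b1"] <- 0.5
  sc[types == 1L] <- 0.15
  sc
}

#' Fit the trend model by MCMC
#'
#' Runs adaptive random-walk Metropolis-within-Gibbs chains on the model's
#' log posterior. Each chain starts from a distinct overdispersed initial
#' state with a finite posterior (bounded retries otherwise), adapts its
#' per-parameter proposal scales during burn-in only, and retains `n_keep`
#' post-burn-in draws of every free parameter. Fits are deterministic given
#' `settings$seed`.
#'
#' @param data a filtered [murre_data] (all counts >= 1).
#' @param cfg a `murre_config` built from `data`.
#' @param settings a [mcmc_settings()] object.
#' @param fixed optional named numeric vector of parameters to hold fixed at
#'   given values (excluded from sampling and from the draw matrix); used
#'   for reduced toy models and sensitivity runs.
#' @param verbose print per-chain progress.
#' @return A `murre_fit`: per-chain draw matrices (iterations x free
#'   parameters), log-posterior traces, acceptance rates, frozen proposal
#'   scales, the configuration and settings used.
#' @export
run_mcmc <- function(data, cfg, settings = mcmc_settings(), fixed = NULL,
                     verbose = FALSE) {
  stopifnot(inherits(data, "murre_data"), inherits(cfg, "murre_config"))
  if (any(data$records$count_in < 1)) {
    stop("counts < 1 present; apply filter_surveys() before fitting")
  }
  model <- prepare_model_arrays(data, cfg)
  obs_of <- obs_index_list(model, cfg)
  idx <- cfg$param_index
  free <- rep(TRUE, nrow(idx))
  if (!is.null(fixed)) {
    bad <- setdiff(names(fixed), idx$name)
    if (length(bad) > 0) stop("unknown parameter(s) in 'fixed': ", paste(bad, collapse = ", "))
    free[match(names(fixed), idx$name)] <- FALSE
  }

  chains <- vector("list", settings$n_chains)
  logpost <- vector("list", settings$n_chains)
  acc <- vector("list", settings$n_chains)
  inits <- vector("list", settings$n_chains)
  for (ch in seq_len(settings$n_chains)) {
    set.seed(settings$seed + 7919L * (ch - 1L))
    disp <- settings$init_dispersion * ch  # chains increasingly dispersed
    theta0 <- NULL
    for (try in 1:20) {
      cand <- initial_theta(data, cfg, disp / try)
      if (!is.null(fixed)) cand[names(fixed)] <- fixed
      if (is.finite(mwg_logpost(cand, model))) { theta0 <- cand; break }
    }
    if (is.null(theta0)) {
      stop("initialization error: no finite-posterior start found after 20 tries")
    }
    inits[[ch]] <- theta0
    types <- proposal_types(cfg)
    # site trend pairs get a second update per sweep: near-boundary sites
    # (steep proportional declines) mix slowly under single updates
    extra <- as.integer(idx$type %in% c("b0", "b1"))
    res <- mwg_run(theta0, model, obs_of, free,
                   default_scales(theta0, cfg, types), types, extra,
                   settings$n_burnin, settings$n_keep)
    colnames(res$draws) <- idx$name[free]
    chains[[ch]] <- res$draws
    logpost[[ch]] <- res$logpost
    acc[[ch]] <- setNames(res$acc_rate, idx$name[free])
    if (verbose) {
      message(sprintf("chain %d: %d draws, mean acceptance %.2f",
                      ch, nrow(res$draws), mean(res$acc_rate)))
    }
  }
  structure(list(chains = chains, logpost = logpost, acceptance = acc,
                 param_names = idx$name[free],
                 fixed = fixed, cfg = cfg, settings = settings,
                 inits = inits, n_obs = nrow(data$records)),
            class = "murre_fit")
}

#' @export
print.murre_fit <- function(x, ...) {
  cat(sprintf("<murre_fit> %d chains x %d retained draws, %d free parameters, %d observations\n",
              length(x$chains), nrow(x$chains[[1]]),
              length(x$param_names), x$n_obs))
  invisible(x)
}

#' Extract retained draws from a fit
#'
#' @param fit a `murre_fit`.
#' @param pars optional character vector of parameter names.
#' @param combine if `TRUE` (default) rbind chains into one matrix.
#' @return matrix (combined) or list of per-chain matrices.
#' @export
fit_draws <- function(fit, pars = NULL, combine = TRUE) {
  stopifnot(inherits(fit, "murre_fit"))
  get <- function(m) {
    if (is.null(pars)) m else {
      missing <- setdiff(pars, colnames(m))
      if (length(missing) > 0) stop("unknown parameter(s): ", paste(missing, collapse = ", "))
      m[, pars, drop = FALSE]
    }
  }
  out <- lapply(fit$chains, get)
  if (combine) do.call(rbind, out) else out
}
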