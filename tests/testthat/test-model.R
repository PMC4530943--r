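test_that("predicted count reduces to the intercept when all modifiers are off", {
  cfg <- tiny_config()
  theta <- feasible_theta(cfg, seed = 1)
  theta[cfg$param_index$type %in% c("b1", "Y", "a", "c")] <- 0
  theta["t"] <- 0
  rec <- tiny_records()
  expect_equal(predicted_count(theta, rec, cfg),
               unname(theta[sprintf("b0[%s]", rec$site)]))
})

test_that("the tilt term multiplies counts as a linear detection factor", {
  cfg <- tiny_config()
  theta <- feasible_theta(cfg, seed = 2)
  theta[cfg$param_index$type %in% c("b1", "Y", "a", "c")] <- 0
  theta[cfg$param_index$type == "b0"] <- 1
  theta["t"] <- 0.096
  rec <- tiny_records()[1, ]
  rec$tilt_deg <- 12.3
  expect_equal(predicted_count(theta, rec, cfg), 1 + 0.096 * 12.3)
  expect_equal(round(predicted_count(theta, rec, cfg), 1), 2.2)
})

test_that("the full mean structure composes multiplicatively", {
  # one site surveyed in 1999 and 2005 (mean year 2002), so the 2005 row
  # sits 3 years past the site's reference point
  rec <- data.frame(region = "HG", site = "A", year = c(1999, 2005),
                    doy = c(150, 202), tilt_deg = 0, count_in = 10)
  d <- murre_data(rec)
  cfg <- build_config(d, fixed_zero = list(HG = 1999),
                      all_fixed_regions = character(0), min_sites_per_year = 1)
  theta <- theta_template(cfg)
  theta["b0[A]"] <- 100
  theta["b1[A]"] <- 2
  theta["Y[HG:2005]"] <- 0.1
  theta["a[HG]"] <- -3e-4
  theta["c[HG]"] <- 0
  theta["t"] <- 0
  # (100 + 2*3) * 1.1 * (1 - 3e-4 * 20^2) * 1 = 106 * 1.1 * 0.88
  expect_equal(predicted_count(theta, rec[2, ], cfg), 106 * 1.1 * 0.88)
  expect_equal(predicted_count(theta, rec[2, ], cfg), 102.608)
})

test_that("unknown sites and unconfigured cells raise key errors", {
  cfg <- tiny_config()
  theta <- feasible_theta(cfg, seed = 3)
  rec <- tiny_records()[1, ]
  rec$site <- "Nowhere"
  expect_error(predicted_count(theta, rec, cfg), "key error")
  rec2 <- tiny_records()[1, ]
  rec2$year <- 1950
  expect_error(predicted_count(theta, rec2, cfg), "key error")
})

test_that("lognormal log-likelihood matches closed forms and rejects Chat <= 0", {
  rec <- data.frame(region = "HG", site = "A", year = 2000, doy = 182,
                    tilt_deg = 0, count_in = 1)
  d <- murre_data(rec)
  cfg <- build_config(d, fixed_zero = list(HG = 2000),
                      all_fixed_regions = character(0), min_sites_per_year = 1)
  theta <- theta_template(cfg)
  theta["b0[A]"] <- 1
  theta["b1[A]"] <- 0
  theta["sigma_R[HG]"] <- 1
  # C = Chat = 1, sigma = 1: only the normalizing constant survives
  expect_equal(log_likelihood(theta, d, cfg), -0.5 * log(2 * pi))

  theta["b0[A]"] <- -2
  expect_identical(log_likelihood(theta, d, cfg), -Inf)
})

test_that("log-likelihood sums per-observation lognormal densities", {
  cfg <- tiny_config()
  theta <- feasible_theta(cfg, seed = 4)
  d <- tiny_dataset()
  chat <- predicted_count(theta, d$records, cfg)
  sig <- theta[sprintf("sigma_R[%s]", d$records$region)]
  manual <- sum(dlnorm(d$records$count_in, meanlog = log(chat),
                       sdlog = sig, log = TRUE))
  expect_equal(log_likelihood(theta, d, cfg), manual, tolerance = 1e-12)
})

test_that("prior support boundaries give -Inf", {
  cfg <- tiny_config()
  theta <- feasible_theta(cfg, seed = 5)
  for (bad in list(c("mu_b0", 0.5), c("mu_b0", 2001), c("sigma_Y", -1),
                   c("sigma_b0", 0), c("sigma_R[HG]", -0.1))) {
    th <- theta
    th[bad[1]] <- as.numeric(bad[2])
    expect_identical(log_prior(th, cfg), -Inf)
    expect_identical(log_posterior(th, tiny_dataset(), cfg), -Inf)
  }
})

test_that("the year-effect SD hyperprior has its stated lognormal density", {
  # config with every year effect fixed: changing sigma_Y then only moves
  # its own hyperprior term, which at the prior median e^2.303 equals
  # -log(x) - log(0.8) - log(sqrt(2*pi)) (log-SD = 1/sqrt(1.5625) = 0.8)
  d <- tiny_dataset()
  cfg <- build_config(d, fixed_zero = list(HG = c(2004, 2006), NC = c(2005, 2007)),
                      all_fixed_regions = character(0), min_sites_per_year = 1)
  expect_equal(sum(cfg$param_index$type == "Y"), 0)
  theta <- feasible_theta(cfg, seed = 6)
  f <- function(s) { th <- theta; th["sigma_Y"] <- s; log_prior(th, cfg) }
  x <- exp(2.303)
  expected_at_median <- -log(x) - log(0.8) - 0.5 * log(2 * pi)
  expect_equal(f(x) - f(1),
               expected_at_median - dlnorm(1, 2.303, 0.8, log = TRUE),
               tolerance = 1e-12)
})

test_that("fixed year effects are constants, absent from the parameter space", {
  cfg <- tiny_config()
  expect_false(any(grepl("Y\\[HG:2004\\]|Y\\[NC:2005\\]", cfg$param_index$name)))
  expect_true(all(c("Y[HG:2006]", "Y[NC:2007]") %in% cfg$param_index$name))
})

test_that("log posterior is the sum of likelihood and prior, and is pure", {
  cfg <- tiny_config()
  d <- tiny_dataset()
  theta <- feasible_theta(cfg, seed = 7)
  lp <- log_posterior(theta, d, cfg)
  expect_equal(lp, log_likelihood(theta, d, cfg) + log_prior(theta, cfg))
  expect_identical(lp, log_posterior(theta, d, cfg))
})

test_that("modular, monolithic-oracle, and compiled evaluations agree", {
  for (seed in 1:5) {
    sim <- small_sim(seed = seed, sites = 2, years = 2005:2010)
    dat <- filter_surveys(sim$data)
    cfg <- sim$cfg
    model <- murretrend:::prepare_model_arrays(dat, cfg)
    for (draw in 1:3) {
      theta <- feasible_theta(cfg, seed = 100 * seed + draw)
      ours <- log_posterior(theta, dat, cfg)
      oracle <- oracle_logpost(theta, dat, cfg)
      expect_equal(ours, oracle, tolerance = 1e-10)
      expect_equal(murretrend:::mwg_logpost(theta, model), ours, tolerance = 1e-10)
    }
    # impossible states agree too
    theta["b0[HG01]"] <- -5
    expect_identical(log_posterior(theta, dat, cfg), -Inf)
    expect_identical(oracle_logpost(theta, dat, cfg), -Inf)
    expect_identical(murretrend:::mwg_logpost(theta, model), -Inf)
  }
})

test_that("parameter counting matches the design formula", {
  # 1 region, 1 site, no estimated year effects: 2 + 1 + 1 + 0 + 2 + 5
  rec <- data.frame(region = "HG", site = "A", year = c(2000, 2002),
                    doy = 180, tilt_deg = 0, count_in = 10)
  cfg1 <- build_config(murre_data(rec), fixed_zero = list(HG = c(2000, 2002)),
                       all_fixed_regions = character(0), min_sites_per_year = 1)
  expect_equal(count_parameters(cfg1), 11)
  expect_equal(count_parameters(cfg1), nrow(cfg1$param_index))

  cfg2 <- tiny_config()
  expect_equal(count_parameters(cfg2), nrow(cfg2$param_index))
})

test_that("config partitions observed cells into estimated and fixed sets", {
  rec <- data.frame(region = "EV", site = rep(c("S1", "S2"), each = 3),
                    year = rep(c(2005, 2006, 2007), 2), doy = 180,
                    tilt_deg = 0, count_in = 20)
  cfg <- build_config(murre_data(rec), fixed_zero = list(EV = 2006),
                      all_fixed_regions = character(0), min_sites_per_year = 1)
  expect_equal(cfg$year_estimated$year, c(2005, 2007))
  expect_equal(cfg$year_fixed_zero$year, 2006)

  # all cells observed land in exactly one set
  cells <- unique(rec[, c("region", "year")])
  got <- rbind(cfg$year_estimated, cfg$year_fixed_zero)
  expect_equal(nrow(got), nrow(cells))

  # a region fixed wholesale contributes no year-effect parameters
  cfg_cc <- build_config(murre_data(transform(rec, region = "CC")),
                         fixed_zero = NULL, all_fixed_regions = "CC",
                         min_sites_per_year = 1)
  expect_equal(sum(cfg_cc$param_index$type == "Y"), 0)
})

test_that("reference years absent from a region's data are an error", {
  expect_error(
    build_config(tiny_dataset(), fixed_zero = NULL,
                 reference_years = c(HG = 1990),
                 all_fixed_regions = character(0), min_sites_per_year = 1),
    "reference year")
})

test_that("fixing year effects breaks the scaling non-identifiability", {
  # rescaling (1+Y) by k and site parameters by 1/k leaves terms in
  # estimated years unchanged, but observations in fixed years pin the
  # scale: the likelihood must differ
  cfg <- tiny_config()
  d <- tiny_dataset()
  theta <- feasible_theta(cfg, seed = 8)
  k <- 1.3
  theta2 <- theta
  for (nm in cfg$param_index$name[cfg$param_index$type == "Y"]) {
    theta2[nm] <- (1 + theta[nm]) * k - 1
  }
  for (s in cfg$sites) {
    theta2[sprintf("b0[%s]", s)] <- theta[sprintf("b0[%s]", s)] / k
    theta2[sprintf("b1[%s]", s)] <- theta[sprintf("b1[%s]", s)] / k
  }
  ll1 <- log_likelihood(theta, d, cfg)
  ll2 <- log_likelihood(theta2, d, cfg)
  expect_gt(abs(ll1 - ll2), 1e-6)

  # while rows in estimated years are individually invariant
  est_rows <- d$records$year %in% cfg$year_estimated$year
  expect_equal(predicted_count(theta, d$records[est_rows, ], cfg),
               predicted_count(theta2, d$records[est_rows, ], cfg),
               tolerance = 1e-12)
})

test_that("counts drawn at the study-shaped design span orders of magnitude", {
  sim <- simulate_study_standin(seed = 99)
  counts <- filter_surveys(sim$data)$records$count_in
  expect_true(all(counts >= 1))
  expect_gte(max(counts) / min(counts), 100)
})
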