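test_that("the noiseless generator reproduces expected counts exactly", {
  spec <- truth_spec(regions = c("HG", "SC"), sites_per_region = 3,
                     years = 2004:2010, site_span = 5,
                     sigma_R = c(HG = 1e-9, SC = 1e-9), round_counts = FALSE)
  sim <- simulate_dataset(spec, seed = 5)
  chat <- predicted_count(sim$truth, sim$data$records, sim$cfg)
  expect_equal(sim$data$records$count_in, chat, tolerance = 1e-6)
})

test_that("generation is byte-identical under a fixed seed", {
  spec <- truth_spec(regions = c("HG", "NC"), sites_per_region = 3,
                     years = 2004:2010, site_span = 5)
  s1 <- simulate_dataset(spec, seed = 12)
  s2 <- simulate_dataset(spec, seed = 12)
  expect_identical(s1$data$records, s2$data$records)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_dataset(spec, seed = 13)
  expect_false(identical(s1$data$records, s3$data$records))
})

test_that("generated data matches the spec's moments at scale", {
  # isolate the residual layer: flat season, no tilt effect, quiet years
  spec <- truth_spec(regions = c("WC", "EV"), sites_per_region = 20,
                     years = 2004:2009, site_span = 6, visit_every = 1,
                     surveys_per_visit = 8,
                     doy_a = c(WC = 0, EV = 0), doy_c = c(WC = 0, EV = 0),
                     t = 0, sigma_Y = 1e-6,
                     sigma_R = c(WC = 0.45, EV = 0.93),
                     round_counts = FALSE)
  sim <- simulate_dataset(spec, seed = 31)
  rec <- sim$data$records
  # residual SD of log counts within site-years, by region
  for (r in c("WC", "EV")) {
    rr <- rec[rec$region == r, ]
    dev <- unlist(lapply(split(log(rr$count_in), paste(rr$site, rr$year)),
                         function(x) x - mean(x)))
    n_cells <- length(unique(paste(rr$site, rr$year)))
    est <- sqrt(sum(dev^2) / (length(dev) - n_cells))
    expect_lt(abs(est - spec$sigma_R[[r]]), 0.15 * spec$sigma_R[[r]])
  }
  # between-site spread of log mean counts tracks the intercept log-SD
  site_logmean <- tapply(log(rec$count_in), rec$site, mean)
  expect_lt(abs(sd(site_logmean) - 0.78), 0.2)
})

test_that("moment calibration pins the sample hyperparameters exactly", {
  spec <- truth_spec(regions = c("HG", "NC"), sites_per_region = 6,
                     years = 2004:2010, site_span = 5)
  sim <- simulate_dataset(spec, seed = 41,
                          calibrate = list(hyper_moments = TRUE,
                                           region_rates = c(HG = -0.03, NC = 0.01)))
  b0 <- sim$truth[grep("^b0\\[", names(sim$truth))]
  b1 <- sim$truth[grep("^b1\\[", names(sim$truth))]
  expect_equal(mean(log(b0)), log(64), tolerance = 1e-10)
  expect_equal(sd(log(b0)), 0.78, tolerance = 1e-10)
  expect_equal(sd(b1), 2.78, tolerance = 1e-6)
  reg <- sim$cfg$site_region[sub("b0\\[(.*)\\]", "\\1", names(b0))]
  expect_equal(mean((b1 / b0)[reg == "HG"]), -0.03, tolerance = 1e-10)
  expect_equal(mean((b1 / b0)[reg == "NC"]), 0.01, tolerance = 1e-10)
})

test_that("the generator and the likelihood are inverses in expectation", {
  spec <- truth_spec(regions = c("HG", "SC"), sites_per_region = 5,
                     years = 2004:2011, site_span = 6)
  sim <- simulate_dataset(spec, seed = 51)
  dat <- filter_surveys(sim$data)
  ll_truth <- log_likelihood(sim$truth, dat, sim$cfg)
  for (perturb in list(c("t", 0.4), c("sigma_R[HG]", 1.8))) {
    th <- sim$truth
    th[perturb[1]] <- as.numeric(perturb[2])
    expect_gt(ll_truth, log_likelihood(th, dat, sim$cfg))
  }
  th <- sim$truth
  b1n <- grep("^b1\\[", names(th))
  th[b1n] <- th[b1n] + 1.5
  expect_gt(ll_truth, log_likelihood(th, dat, sim$cfg))
})

test_that("rounding plus the zero rule barely perturbs the residual SD", {
  spec_r <- truth_spec(regions = c("WC", "EV"), sites_per_region = 10,
                       years = 2004:2011, site_span = 6, surveys_per_visit = 3)
  spec_c <- spec_r
  spec_c$round_counts <- FALSE
  sim_r <- simulate_dataset(spec_r, seed = 61)
  sim_c <- simulate_dataset(spec_c, seed = 61)
  sigma_hat <- function(sim) {
    dat <- filter_surveys(sim$data)
    chat <- predicted_count(sim$truth, dat$records, sim$cfg)
    z <- log(dat$records$count_in / chat)
    vapply(split(z, dat$records$region), function(x) sqrt(mean(x^2)), numeric(1))
  }
  sr <- sigma_hat(sim_r); sc <- sigma_hat(sim_c)
  expect_true(all(abs(sr - sc) / sc < 0.05))
})

test_that("pathological truth specs abort with a redraw error", {
  spec <- truth_spec(regions = "HG", sites_per_region = 10,
                     years = 1996:2013, site_span = 18,
                     mu_b0 = 3, sigma_b1 = 6)
  expect_error(simulate_dataset(spec, seed = 71), "redraws|redraw loop")
})

test_that("the study stand-in reproduces the published design structure", {
  sim <- simulate_study_standin(seed = 2)
  expect_equal(sim$data$n_sites, 58)
  expect_equal(sim$data$n_regions, 6)
  expect_equal(nrow(sim$cfg$year_estimated), 30)
  expect_equal(count_parameters(sim$cfg), 170)
  # CC contributes no year effects; every CC cell is fixed
  expect_false("CC" %in% sim$cfg$year_estimated$region)
  # year-effect cells match the published region-year table
  expect_equal(sum(sim$cfg$year_estimated$region == "WC"), 16)
  expect_equal(sum(sim$cfg$year_estimated$region == "EV"), 9)
  expect_equal(sum(sim$cfg$year_estimated$region == "SC"), 3)
  expect_equal(sim$cfg$year_estimated$year[sim$cfg$year_estimated$region == "HG"], 2010)
  expect_equal(sim$cfg$year_estimated$year[sim$cfg$year_estimated$region == "NC"], 2005)
  # observation count near the historical record's size
  expect_gt(nrow(sim$data$records), 850)
  expect_lt(nrow(sim$data$records), 1000)
  # generative region rates match the calibration targets exactly
  b0 <- sim$truth[sprintf("b0[%s]", sim$cfg$sites)]
  b1 <- sim$truth[sprintf("b1[%s]", sim$cfg$sites)]
  rates <- b1 / b0
  for (r in sim$cfg$regions) {
    expect_equal(mean(rates[sim$cfg$site_region == r]),
                 unname(sim$region_rates[r]), tolerance = 1e-10)
  }
})

test_that("a short recovery study returns calibrated bookkeeping", {
  spec <- truth_spec(regions = c("HG", "SC"), sites_per_region = 3,
                     years = 2005:2010, site_span = 6, visit_every = 2)
  rs <- recovery_study(spec, mcmc_settings(n_burnin = 300, n_keep = 1200),
                       n_replicates = 2, seed = 5)
  expect_setequal(rs$summary$class, c("b1", "site_rate", "region_rate", "sigma_Y"))
  expect_true(all(rs$summary$coverage95 >= 0 & rs$summary$coverage95 <= 1))
  expect_equal(sum(rs$per_param$class == "sigma_Y"), 2)
  expect_true(all(rs$per_param$l95 <= rs$per_param$u95))
})
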