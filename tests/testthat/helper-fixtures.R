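# Shared fixtures, all generated in code.

# a minimal hand-written survey table: 2 regions, 3 sites
tiny_records <- function() {
  data.frame(
    region = c("HG", "HG", "HG", "HG", "NC", "NC", "NC", "NC"),
    site = c("Alder", "Alder", "Birch", "Birch", "Cedar", "Cedar", "Cedar", "Cedar"),
    year = c(2004, 2006, 2004, 2006, 2005, 2005, 2007, 2007),
    doy = c(160, 175, 182, 190, 170, 171, 180, 181),
    tilt_deg = c(0, 5.2, 10, 0, 25, 0, 11.3, 12.8),
    count_in = c(40, 55, 12, 9, 150, 130, 170, 160),
    complete = TRUE,
    rain_gt10min = FALSE)
}

tiny_dataset <- function() murre_data(tiny_records())

# config for the tiny dataset: one fixed year per region
tiny_config <- function(...) {
  build_config(tiny_dataset(),
               fixed_zero = list(HG = 2004, NC = 2005),
               all_fixed_regions = character(0),
               min_sites_per_year = 1, ...)
}

# a complete, valid parameter vector for an arbitrary config, with gentle
# values well inside every prior's support
feasible_theta <- function(cfg, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  idx <- cfg$param_index
  theta <- setNames(numeric(nrow(idx)), idx$name)
  n_s <- sum(idx$type == "b0")
  theta[idx$type == "b0"] <- exp(rnorm(n_s, log(50), 0.4))
  theta[idx$type == "b1"] <- rnorm(n_s, 0, 1)
  theta[idx$type == "Y"] <- rnorm(sum(idx$type == "Y"), 0, 0.3)
  theta[idx$type == "a"] <- rnorm(sum(idx$type == "a"), 0, 2e-4)
  theta[idx$type == "c"] <- rnorm(sum(idx$type == "c"), 0, 5)
  theta[idx$type == "sigma_R"] <- exp(rnorm(sum(idx$type == "sigma_R"), log(0.6), 0.2))
  theta["t"] <- rnorm(1, 0.1, 0.03)
  theta["mu_b0"] <- runif(1, 40, 80)
  theta["sigma_b0"] <- exp(rnorm(1, log(0.8), 0.2))
  theta["mu_b1"] <- rnorm(1, 0, 0.5)
  theta["sigma_b1"] <- exp(rnorm(1, log(2), 0.2))
  theta["sigma_Y"] <- exp(rnorm(1, log(0.5), 0.2))
  theta
}

# a fake murre_fit with prescribed per-parameter draws (list name -> vector),
# for unit-testing summaries and diagnostics without running MCMC
fake_fit <- function(draws_by_param, cfg = NULL, n_chains = 2) {
  m <- do.call(cbind, draws_by_param)
  colnames(m) <- names(draws_by_param)
  n <- nrow(m)
  half <- floor(n / n_chains)
  chains <- lapply(seq_len(n_chains), function(ch) {
    m[((ch - 1) * half + 1):(ch * half), , drop = FALSE]
  })
  structure(list(chains = chains, param_names = colnames(m), cfg = cfg,
                 settings = NULL, n_obs = 0),
            class = "murre_fit")
}

# small simulated instance used by several sampler tests
small_sim <- function(seed = 7, sites = 4, years = 2004:2011) {
  spec <- truth_spec(regions = c("HG", "SC"), sites_per_region = sites,
                     years = years, site_span = 6, visit_every = 2,
                     surveys_per_visit = 2)
  simulate_dataset(spec, seed = seed)
}
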