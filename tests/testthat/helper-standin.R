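# The end-to-end checks at the published study's scale share one fit of
# the synthetic study stand-in at the production MCMC protocol (2 chains,
# 40k burn-in, 80k retained). It is computed on first use and cached for
# the rest of the test run.
.standin_cache <- new.env(parent = emptyenv())

standin_fit <- function() {
  if (is.null(.standin_cache$fit)) {
    sim <- simulate_study_standin(seed = 20150810)
    dat <- filter_surveys(sim$data)
    fit <- run_mcmc(dat, sim$cfg, mcmc_settings(seed = 11))
    .standin_cache$sim <- sim
    .standin_cache$fit <- fit
    .standin_cache$gate <- convergence_gate(fit)
  }
  list(sim = .standin_cache$sim, fit = .standin_cache$fit,
       gate = .standin_cache$gate)
}
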