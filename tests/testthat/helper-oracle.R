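# Independent monolithic evaluation of the model's unnormalized log
# posterior: one flat loop over survey rows for the mean structure and
# lognormal density, plus longhand prior densities. Deliberately coded
# without reusing any package internals, so it can act as an oracle for
# the modular implementation.
oracle_logpost <- function(theta, data, cfg) {
  rec <- data$records
  ll <- 0
  for (i in seq_len(nrow(rec))) {
    s <- rec$site[i]; r <- rec$region[i]; y <- rec$year[i]
    b0 <- theta[[paste0("b0[", s, "]")]]
    b1 <- theta[[paste0("b1[", s, "]")]]
    ynm <- paste0("Y[", r, ":", y, "]")
    Y <- if (ynm %in% names(theta)) theta[[ynm]] else 0
    a <- theta[[paste0("a[", r, "]")]]
    cc <- theta[[paste0("c[", r, "]")]]
    sig <- theta[[paste0("sigma_R[", r, "]")]]
    D <- rec$doy[i] - 182
    chat <- (b0 + b1 * (y - cfg$site_mean_year[[s]])) * (1 + Y) *
      (1 + a * (D - cc)^2) * (1 + theta[["t"]] * rec$tilt_deg[i])
    if (chat <= 0 || sig <= 0) return(-Inf)
    C <- rec$count_in[i]
    ll <- ll + log(1 / (C * sqrt(2 * pi) * sig) *
                     exp(-(log(C / chat))^2 / (2 * sig^2)))
  }

  ln_norm <- function(x, mu, sd) -0.5 * log(2 * pi) - log(sd) - (x - mu)^2 / (2 * sd^2)
  ln_lnorm <- function(x, logmed, logsd) {
    if (x <= 0) return(-Inf)
    -log(x) - 0.5 * log(2 * pi) - log(logsd) - (log(x) - logmed)^2 / (2 * logsd^2)
  }
  mu_b0 <- theta[["mu_b0"]]; sigma_b0 <- theta[["sigma_b0"]]
  mu_b1 <- theta[["mu_b1"]]; sigma_b1 <- theta[["sigma_b1"]]
  sigma_Y <- theta[["sigma_Y"]]
  if (sigma_b0 <= 0 || sigma_b1 <= 0 || sigma_Y <= 0) return(-Inf)
  if (mu_b0 < 1 || mu_b0 > 2000) return(-Inf)

  lp <- 0
  for (s in cfg$sites) {
    b0 <- theta[[paste0("b0[", s, "]")]]
    if (cfg$b0_prior == "lognormal") {
      if (b0 <= 0) return(-Inf)
      lp <- lp + ln_lnorm(b0, log(mu_b0), sigma_b0)
    } else {
      lp <- lp + ln_norm(b0, mu_b0, sigma_b0)
    }
    lp <- lp + ln_norm(theta[[paste0("b1[", s, "]")]], mu_b1, sigma_b1)
  }
  for (nm in names(theta)[startsWith(names(theta), "Y[")]) {
    lp <- lp + ln_norm(theta[[nm]], 0, sigma_Y)
  }
  for (r in cfg$regions) {
    lp <- lp + ln_norm(theta[[paste0("a[", r, "]")]], 0, 1 / sqrt(10000))
    lp <- lp + ln_norm(theta[[paste0("c[", r, "]")]], 0, 1 / sqrt(0.01))
    sig <- theta[[paste0("sigma_R[", r, "]")]]
    if (sig <= 0) return(-Inf)
    if (cfg$resid_prior_on == "precision") {
      tau <- 1 / sig^2
      lp <- lp + log(0.01^0.01 / gamma(0.01) * tau^(0.01 - 1) * exp(-0.01 * tau)) +
        log(2 / sig^3)
    } else {
      v <- sig^2
      lp <- lp + log(0.01^0.01 / gamma(0.01) * v^(0.01 - 1) * exp(-0.01 * v)) +
        log(2 * sig)
    }
  }
  lp <- lp + ln_norm(theta[["t"]], 0, 1)
  lp <- lp + log(1 / (2000 - 1))
  lp <- lp + ln_lnorm(sigma_b0, 3.91, 1 / sqrt(1.5625))
  lp <- lp + ln_norm(mu_b1, 0, 1 / sqrt(0.0001))
  lp <- lp + ln_lnorm(sigma_b1, 2.30, 1 / sqrt(1.5625))
  lp <- lp + ln_lnorm(sigma_Y, 2.303, 1 / sqrt(1.5625))
  ll + lp
}
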