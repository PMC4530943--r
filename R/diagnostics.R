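#' Gelman-Rubin potential scale reduction factor
#'
#' Computes the PSRF per parameter across chains. By default each chain is
#' split in half first (the split-chain variant, which also detects
#' within-chain drift); `split = FALSE` gives the classic two-chain
#' statistic, for which two identical stationary chains yield exactly
#' \eqn{\sqrt{(n-1)/n}}. Parameters with zero within-chain variance are
#' flagged degenerate (`NA` with a `degenerate` attribute) rather than
#' silently reported.
#'
#' @param fit a `murre_fit`, or a list of per-chain draw matrices.
#' @param pars optional parameter subset.
#' @param split split each chain in half before computing (default `TRUE`).
#' @return named numeric vector of PSRF values; attribute `degenerate`
#'   names any zero-variance parameters.
#' @export
gelman_rubin <- function(fit, pars = NULL, split = TRUE) {
  chains <- if (inherits(fit, "murre_fit")) fit_draws(fit, pars, combine = FALSE)
            else fit
  if (length(chains) < 2 && !split) stop("need >= 2 chains for the unsplit PSRF")
  if (split) {
    chains <- unlist(lapply(chains, function(m) {
      n <- nrow(m)
      h <- floor(n / 2)
      list(m[seq_len(h), , drop = FALSE],
           m[(n - h + 1):n, , drop = FALSE])
    }), recursive = FALSE)
  }
  p <- ncol(chains[[1]])
  nms <- colnames(chains[[1]])
  out <- setNames(rep(NA_real_, p), nms)
  degen <- character(0)
  n <- nrow(chains[[1]])
  for (j in seq_len(p)) {
    draws <- vapply(chains, function(m) m[, j], numeric(n))
    W <- mean(apply(draws, 2, stats::var))
    if (!is.finite(W) || W == 0) {
      degen <- c(degen, nms[j])
      next
    }
    B_over_n <- stats::var(colMeans(draws))
    out[j] <- sqrt((n - 1) / n + B_over_n / W)
  }
  attr(out, "degenerate") <- degen
  out
}

# batch-means Monte Carlo standard error of the mean of one chain
batch_mcse <- function(x) {
  n <- length(x)
  b <- max(2L, floor(sqrt(n)))       # batch length
  nb <- floor(n / b)
  if (nb < 2) return(NA_real_)
  means <- colMeans(matrix(x[seq_len(nb * b)], nrow = b))
  sd(means) / sqrt(nb)
}

#' Monte Carlo error check
#'
#' Estimates the Monte Carlo standard error of each posterior mean by batch
#' means per chain (which accounts for autocorrelation), pools across
#' chains, and compares it to the posterior SD. The fit protocol requires
#' the ratio to stay below about 3% for all reported statistics.
#'
#' @param fit a `murre_fit`.
#' @param pars optional parameter subset.
#' @param threshold_frac maximum acceptable mcse/sd ratio (default 0.03).
#' @return data.frame with `param`, `mcse`, `post_sd`, `ratio`, `pass`,
#'   `degenerate` (TRUE for constant chains).
#' @export
mc_error_check <- function(fit, pars = NULL, threshold_frac = 0.03) {
  chains <- fit_draws(fit, pars, combine = FALSE)
  all_draws <- do.call(rbind, chains)
  nms <- colnames(all_draws)
  C <- length(chains)
  res <- lapply(seq_along(nms), function(j) {
    per_chain <- vapply(chains, function(m) batch_mcse(m[, j]), numeric(1))
    mcse <- sqrt(sum(per_chain^2)) / C   # se of the across-chain mean
    post_sd <- sd(all_draws[, j])
    degenerate <- !is.finite(post_sd) || post_sd == 0
    ratio <- if (degenerate) NA_real_ else mcse / post_sd
    data.frame(param = nms[j], mcse = mcse, post_sd = post_sd,
               ratio = ratio, pass = !degenerate && ratio < threshold_frac,
               degenerate = degenerate)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Autocorrelation report for retained draws
#'
#' Sample autocorrelation per lag, averaged across chains, with a summary
#' of the slowest-mixing parameters (largest lag-1 autocorrelation).
#' Constant chains are flagged rather than reported as numbers.
#'
#' @param fit a `murre_fit`.
#' @param max_lag largest lag (default 50).
#' @param pars optional parameter subset.
#' @return list with `acf` (matrix lag x parameter), `slowest` (data.frame
#'   of parameters ordered by lag-1 autocorrelation), `degenerate`.
#' @export
autocorrelation_report <- function(fit, max_lag = 50, pars = NULL) {
  chains <- fit_draws(fit, pars, combine = FALSE)
  nms <- colnames(chains[[1]])
  degen <- character(0)
  ac <- matrix(NA_real_, nrow = max_lag, ncol = length(nms),
               dimnames = list(paste0("lag", seq_len(max_lag)), nms))
  for (j in seq_along(nms)) {
    per_chain <- lapply(chains, function(m) {
      x <- m[, j]
      if (sd(x) == 0) return(NULL)
      drop(acf(x, lag.max = max_lag, plot = FALSE)$acf)[-1]
    })
    per_chain <- per_chain[!vapply(per_chain, is.null, logical(1))]
    if (length(per_chain) == 0) {
      degen <- c(degen, nms[j])
      next
    }
    ac[, j] <- rowMeans(do.call(cbind, per_chain))
  }
  ok <- setdiff(nms, degen)
  slowest <- data.frame(param = ok, lag1 = ac[1, ok])
  slowest <- slowest[order(-slowest$lag1), ]
  rownames(slowest) <- NULL
  list(acf = ac, slowest = slowest, degenerate = degen)
}

#' Convergence gate for a fit
#'
#' The fit protocol requires, before any trend table is emitted: the
#' Gelman-Rubin statistic near 1 for every site slope and intercept, and a
#' Monte Carlo error below `mc_threshold` of the posterior SD for the same
#' parameters. Returns the verdict with the offending parameters listed.
#'
#' @param fit a `murre_fit`.
#' @param rhat_threshold maximum acceptable PSRF (default 1.1).
#' @param mc_threshold maximum mcse/sd ratio (default 0.03).
#' @return list with `pass`, `rhat_max`, `mc_ratio_max`, `failed_rhat`,
#'   `failed_mc`.
#' @export
convergence_gate <- function(fit, rhat_threshold = 1.1, mc_threshold = 0.03) {
  pars <- grep("^b[01]\\[", fit$param_names, value = TRUE)
  rh <- gelman_rubin(fit, pars)
  mc <- mc_error_check(fit, pars, threshold_frac = mc_threshold)
  failed_rhat <- names(rh)[!is.na(rh) & rh > rhat_threshold]
  failed_rhat <- c(failed_rhat, attr(rh, "degenerate"))
  failed_mc <- mc$param[!mc$pass]
  list(pass = length(failed_rhat) == 0 && length(failed_mc) == 0,
       rhat_max = max(rh, na.rm = TRUE),
       mc_ratio_max = max(mc$ratio, na.rm = TRUE),
       failed_rhat = failed_rhat,
       failed_mc = failed_mc)
}
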