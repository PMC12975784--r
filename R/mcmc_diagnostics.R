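## Convergence diagnostics for single Gibbs chains: Geweke's z,
## Heidelberger-Welch stationarity/halfwidth, effective sample size, and
## burn-in/thinning bookkeeping. The spectral density at frequency zero is
## estimated by batch means with ceiling(sqrt(n)) batches.

spectral0_batch <- function(x) {
  n <- length(x)
  nb <- ceiling(sqrt(n))
  bs <- n %/% nb
  if (bs < 1L) stop("chain too short for the batch-means estimator")
  m <- colMeans(matrix(x[seq_len(nb * bs)], nrow = bs))
  bs * var(m)
}

#' Discard burn-in and thin a raw chain
#'
#' Keeps cycles `burn_in + thin, burn_in + 2*thin, ...`; the stored count is
#' `floor((L - burn_in) / thin)`.
#'
#' @param x numeric vector (or matrix with cycles in rows) of raw samples.
#' @param config a [gibbs_config()] (its `chain_length` is ignored; the
#'   actual length of `x` is used).
#' @return The stored samples, same shape as `x`.
#' @export
apply_burnin_thin <- function(x, config) {
  n <- if (is.matrix(x)) nrow(x) else length(x)
  if (config$burn_in >= n) stop("burn_in is not smaller than the chain length")
  keep <- seq.int(config$burn_in + config$thin, n, by = config$thin)
  if (is.matrix(x)) x[keep, , drop = FALSE] else x[keep]
}

#' Geweke's convergence diagnostic
#'
#' Compares the means of an early and a late chain window:
#' `z = (mean_A - mean_B) / sqrt(s_A/n_A + s_B/n_B)` with `s` the
#' batch-means estimate of the spectral density at frequency zero in each
#' window. Approximately standard normal for a stationary chain.
#'
#' @param x numeric chain (>= 100 samples).
#' @param frac_first fraction of the chain in the early window (default 0.1).
#' @param frac_last fraction in the late window (default 0.5).
#' @return The z-score.
#' @export
geweke_z <- function(x, frac_first = 0.1, frac_last = 0.5) {
  n <- length(x)
  if (n < 100) stop("need at least 100 samples")
  a <- x[seq_len(floor(frac_first * n))]
  b <- x[seq.int(n - floor(frac_last * n) + 1L, n)]
  if (var(a) == 0 || var(b) == 0) stop("degenerate chain: zero-variance window")
  (mean(a) - mean(b)) /
    sqrt(spectral0_batch(a) / length(a) + spectral0_batch(b) / length(b))
}

#' Heidelberger-Welch stationarity and halfwidth tests
#'
#' Stationarity: Cramer-von Mises statistic of the standardized cumulative
#' sum process against the Brownian-bridge null; on failure the initial 10%
#' of the chain is discarded and the test repeated, down to 50% retention.
#' Halfwidth: the retained segment passes when
#' `z_(1-alpha/2) * sqrt(s/n) / |mean|` is below `eps`; a mean of zero makes
#' the relative precision undefined and fails the test.
#'
#' @param x numeric chain (>= 100 samples).
#' @param alpha test level (default 0.05).
#' @param eps relative halfwidth target (default 0.1).
#' @return List: `stationary` flag, `retained` fraction (1.0, 0.9, ... 0.5),
#'   `halfwidth_passed`, `halfwidth`, `mean` of the retained segment.
#' @export
heidelberger_welch <- function(x, alpha = 0.05, eps = 0.1) {
  n0 <- length(x)
  if (n0 < 100) stop("need at least 100 samples")
  if (var(x) == 0) stop("degenerate chain: zero variance")
  crit <- cvm_critical(alpha)
  stationary <- FALSE
  retained <- 0.5
  seg <- x
  for (dropfrac in seq(0, 0.5, by = 0.1)) {
    seg <- x[seq.int(floor(dropfrac * n0) + 1L, n0)]
    s0 <- spectral0_batch(seg)
    if (s0 <= 0) next
    m <- length(seg)
    cs <- cumsum(seg) - seq_len(m) * mean(seg)
    stat <- sum((cs / sqrt(m * s0))^2) / m
    if (stat < crit) {
      stationary <- TRUE
      retained <- round(1 - dropfrac, 1)
      break
    }
  }
  mu <- mean(seg)
  hw <- qnorm(1 - alpha / 2) * sqrt(spectral0_batch(seg) / length(seg))
  hw_pass <- is.finite(hw) && mu != 0 && (hw / abs(mu)) <= eps
  list(stationary = stationary, retained = retained,
       halfwidth_passed = hw_pass, halfwidth = hw, mean = mu)
}

## Asymptotic critical values of the one-sample Cramer-von Mises statistic
## (integral of a squared Brownian bridge), as used for the stationarity test.
cvm_critical <- function(alpha) {
  tab <- c("0.1" = 0.3473, "0.05" = 0.46136, "0.025" = 0.58061,
           "0.01" = 0.74346)
  key <- as.character(alpha)
  if (!key %in% names(tab)) stop("alpha must be one of 0.1, 0.05, 0.025, 0.01")
  tab[[key]]
}

#' Effective sample size
#'
#' `n * gamma_0 / s` with `s` the initial-positive-sequence estimate of the
#' spectral density at zero (Geyer's monotone sum of autocovariance pairs),
#' clipped to `[1, n]`.
#'
#' @param x numeric chain (>= 100 samples).
#' @return Effective number of independent samples.
#' @export
effective_sample_size <- function(x) {
  n <- length(x)
  if (n < 100) stop("need at least 100 samples")
  g0 <- var(x)
  if (g0 == 0) stop("degenerate chain: zero variance")
  xc <- x - mean(x)
  maxlag <- min(n - 1L, 10L * ceiling(sqrt(n)))
  ac <- vapply(0:maxlag, function(k)
    sum(xc[seq_len(n - k)] * xc[seq.int(k + 1L, n)]) / n, numeric(1))
  s <- -ac[1]
  for (m in seq_len(floor((maxlag - 1) / 2))) {
    gam <- ac[2 * m - 1] + ac[2 * m]   # lags 2m-2 and 2m-1
    if (gam <= 0) break
    s <- s + 2 * gam
  }
  s <- max(s, ac[1] / n)
  min(max(n * ac[1] / s, 1), n)
}

#' Convergence report for a fitted chain
#'
#' Per stored parameter: Geweke z, Heidelberger-Welch flags and retained
#' fraction, and effective sample size, with the conventional |z| < 1.96 and
#' stationarity-pass convergence call.
#'
#' @param fit a `gibbs_fit` or `gibbs_bifit` (or a data frame of samples).
#' @param alpha,eps passed to [heidelberger_welch()].
#' @return Data frame with one row per parameter.
#' @export
diagnostic_report <- function(fit, alpha = 0.05, eps = 0.1) {
  sam <- if (is.data.frame(fit)) fit else fit$samples
  sam <- sam[, setdiff(names(sam), "cycle"), drop = FALSE]
  rows <- lapply(names(sam), function(p) {
    x <- sam[[p]]
    gz <- tryCatch(geweke_z(x), error = function(e) NA_real_)
    hw <- tryCatch(heidelberger_welch(x, alpha, eps),
                   error = function(e) NULL)
    es <- tryCatch(effective_sample_size(x), error = function(e) NA_real_)
    data.frame(parameter = p, geweke_z = gz,
               hw_stationary = if (is.null(hw)) NA else hw$stationary,
               hw_retained = if (is.null(hw)) NA_real_ else hw$retained,
               hw_halfwidth = if (is.null(hw)) NA else hw$halfwidth_passed,
               ess = es,
               converged = !is.na(gz) && abs(gz) < 1.96 &&
                 !is.null(hw) && isTRUE(hw$stationary))
  })
  do.call(rbind, rows)
}
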