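## Two-trait linear-threshold Gibbs sampler: a binary trait on the liability
## scale (residual variance fixed at 1) jointly with a continuous trait,
## estimating the 2x2 genetic covariance matrix and the genetic correlation.

#' Run the bivariate linear-threshold chain on prepared inputs
#'
#' Trait 1 is binary (threshold, residual variance fixed at 1), trait 2
#' continuous. Rows are animal records; a missing channel (`NA`) is handled
#' by data augmentation. The residual covariance is sampled in the
#' conditional-regression parameterization (regression of the linear-trait
#' residual on the threshold residual plus the conditional variance), which
#' keeps `R[1,1] = 1` exactly in every stored sample.
#'
#' @param score binary scores (0/1, `NA` if unrecorded) per row.
#' @param y continuous phenotypes (`NA` if unrecorded) per row.
#' @param X1,X2 sparse fixed-effect designs for the two traits (rows
#'   aligned; all-zero rows are allowed for a missing channel).
#' @param animal integer pedigree code per row.
#' @param ainv an `a_inverse` object or sparse A-inverse.
#' @param config a [gibbs_config()].
#' @param prior_G inverse-Wishart prior as `list(df, scale)` with a 2x2
#'   scale matrix; default `df = 4` and a small multiple of the starting
#'   variances.
#' @param prior_residual [variance_prior()] for the linear trait's
#'   conditional residual variance.
#' @param start optional list with `G` (2x2) and `r22` starting values.
#' @param zero_cov force all genetic and residual cross-covariances to zero
#'   (the independence special case used for cross-checks).
#' @return A `gibbs_bifit` with per-sample `g11, g12, g22, r11, r12, r22,
#'   r_g, h2_1, h2_2` and EBV posterior means for both traits.
#' @export
gibbs_bivariate_model <- function(score, y, X1, X2, animal, ainv,
                                  config = gibbs_config(burn_in = 300000),
                                  prior_G = NULL,
                                  prior_residual = variance_prior(),
                                  start = list(), zero_cov = FALSE) {
  Ai <- as_ainv_matrix(ainv)
  q <- nrow(Ai)
  X1 <- methods::as(X1, "CsparseMatrix")
  X2 <- methods::as(X2, "CsparseMatrix")
  n <- length(score)
  stopifnot(length(y) == n, nrow(X1) == n, nrow(X2) == n,
            length(animal) == n)
  miss1 <- as.integer(is.na(score))
  miss2 <- as.integer(is.na(y))
  if (any(miss1 & miss2))
    stop("rows with both channels missing carry no information; drop them")
  vy <- var(y, na.rm = TRUE)
  G0 <- start$G %||% diag(c(0.2, 0.4 * vy))
  r220 <- start$r22 %||% (0.6 * vy)
  ## inverse-Wishart df 5 with a diagonal scale whose threshold-channel
  ## marginal matches the univariate weakly informative default
  ## (inverse-chi-square df 4, scale 0.2)
  if (is.null(prior_G))
    prior_G <- list(df = 5, scale = diag(4 * c(0.2, diag(G0)[2])))
  sc <- score; sc[is.na(sc)] <- 0
  yy <- y; yy[is.na(yy)] <- 0
  set.seed(config$seed)
  res <- gibbs_biv_cpp(as.numeric(sc), miss1, as.numeric(yy), miss2,
                       X1, X2, as.integer(animal), q,
                       methods::as(Ai, "dMatrix"),
                       G0, prior_G$df, prior_G$scale,
                       r220, prior_residual$df, prior_residual$scale,
                       config$chain_length, config$burn_in, config$thin,
                       zero_cov)
  samples <- as.data.frame(res$samples)
  names(samples) <- c("g11", "g12", "g22", "r11", "r12", "r22", "r_g",
                      "h2_1", "h2_2")
  samples <- cbind(cycle = config$burn_in + config$thin * seq_len(nrow(samples)),
                   samples)
  structure(list(samples = samples,
                 ebv = list(trait1 = res$ebv1_mean, trait2 = res$ebv2_mean),
                 config = config, n_records = n, n_animals = q,
                 final_state = list(liability = res$final_liability),
                 score = score, call = match.call()),
            class = "gibbs_bifit")
}

#' Fit the bivariate linear-threshold model from phenotype records
#'
#' Prepares both traits (contemporary groups, filters, designs) on a shared
#' pedigree, merges them by animal and runs [gibbs_bivariate_model()]. By
#' default the yearling-weight covariate is dropped from the binary trait's
#' model (fitting the weight it is being correlated with would be
#' circular); `yw_covariate = TRUE` restores it.
#'
#' @param records long-format phenotype data frame holding both traits.
#' @param pedigree a [ped_table].
#' @param trait_binary,trait_linear trait codes (default FL and YW).
#' @param config a [gibbs_config()].
#' @param yw_covariate keep the yearling-weight covariate in the binary
#'   trait's fixed effects (default FALSE).
#' @param ... passed to [gibbs_bivariate_model()].
#' @return A `gibbs_bifit`.
#' @export
fit_bivariate_model <- function(records, pedigree, trait_binary = "FL",
                                trait_linear = "YW",
                                config = gibbs_config(burn_in = 300000),
                                yw_covariate = FALSE, ...) {
  f1 <- filter_records(records, trait_binary)
  f2 <- filter_records(records, trait_linear)
  d1 <- build_design(f1$records, pedigree, yw_covariate = yw_covariate)
  d2 <- build_design(f2$records, pedigree)
  a1 <- d1$animal; a2 <- d2$animal
  if (!length(intersect(a1, a2)))
    warning("traits measured on disjoint animal sets; ",
            "genetic correlation only weakly identified through the pedigree")
  rows <- sort(unique(c(a1, a2)))
  n <- length(rows)
  place <- function(X, an) {
    i <- match(an, rows)
    s <- Matrix::summary(methods::as(X, "TsparseMatrix"))
    Matrix::sparseMatrix(i = i[s$i], j = s$j, x = s$x,
                         dims = c(n, ncol(X)))
  }
  score <- rep(NA_real_, n)
  score[match(a1, rows)] <- f1$records$score
  yv <- rep(NA_real_, n)
  yv[match(a2, rows)] <- f2$records$score
  fit <- gibbs_bivariate_model(score, yv, place(d1$X, a1), place(d2$X, a2),
                               rows, build_a_inverse(pedigree),
                               config = config, ...)
  names(fit$ebv$trait1) <- names(fit$ebv$trait2) <- pedigree$id
  fit$traits <- c(trait_binary, trait_linear)
  fit$prep <- list(binary = f1, linear = f2)
  fit$call <- match.call()
  fit
}

#' Posterior summary of the genetic correlation
#'
#' Summarizes the per-sample genetic correlation
#' `r_g = g12 / sqrt(g11 g22)`. Cycles with a non-positive-definite genetic
#' covariance sample are rejected and counted; more than 1% rejections
#' raises a warning.
#'
#' @param fit a `gibbs_bifit`.
#' @param level credibility level.
#' @return One-row data frame: mean, PSD, equal-tail credibility interval,
#'   and the number of rejected cycles.
#' @export
genetic_correlation_summary <- function(fit, level = 0.95) {
  s <- fit$samples
  ok <- s$g11 > 0 & s$g22 > 0 & (s$g11 * s$g22 - s$g12^2) > 0
  n_rej <- sum(!ok)
  if (n_rej > 0.01 * nrow(s))
    warning(sprintf("%d of %d genetic covariance samples not positive definite",
                    n_rej, nrow(s)))
  rg <- s$r_g[ok]
  if (length(rg) < 1) stop("no valid genetic correlation samples")
  ci <- ci_equal_tail(rg, level)
  data.frame(parameter = "r_g", mean = mean(rg), psd = sd(rg),
             ci_low = ci[1], ci_high = ci[2], n_rejected = n_rej)
}

#' @export
print.gibbs_bifit <- function(x, ...) {
  cat("Bayesian bivariate linear-threshold animal model",
      if (!is.null(x$traits)) paste0("(", paste(x$traits, collapse = " + "), ")"),
      "\n")
  cat(sprintf("rows: %d   animals in pedigree: %d\n", x$n_records, x$n_animals))
  cat(sprintf("chain: %d cycles, burn-in %d, thin %d, %d stored (seed %d)\n",
              x$config$chain_length, x$config$burn_in, x$config$thin,
              nrow(x$samples), x$config$seed))
  g <- genetic_correlation_summary(x)
  cat(sprintf("posterior r_g = %.3f +/- %.3f (95%% CI %.3f to %.3f)\n",
              g$mean, g$psd, g$ci_low, g$ci_high))
  invisible(x)
}

#' @export
summary.gibbs_bifit <- function(object, ...) summarize_posterior(object, ...)

#' @export
ebv.gibbs_bifit <- function(fit) fit$ebv

#' @export
plot.gibbs_bifit <- function(x, parameter = "r_g", ...) {
  graphics::plot(x$samples$cycle, x$samples[[parameter]], type = "l",
                 xlab = "cycle", ylab = parameter,
                 main = "Gibbs chain trace", ...)
  graphics::abline(h = mean(x$samples[[parameter]]), col = 2, lty = 2)
  invisible(x)
}
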