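## Univariate threshold / linear animal-model Gibbs sampler: configuration,
## component full-conditional samplers, the chain driver, and the fitted-model
## class.

#' Prior for a variance component
#'
#' Scaled inverse chi-square prior with `df` degrees of freedom and scale
#' `scale`. The default `df = -2, scale = 0` is the improper flat prior on
#' the variance (the full conditional then has `q - 2` degrees of freedom);
#' a weakly informative choice is `variance_prior(4, prior_guess)`.
#'
#' @param df prior degrees of freedom.
#' @param scale prior scale (a variance-sized prior guess).
#' @export
variance_prior <- function(df = -2, scale = 0) {
  stopifnot(is.numeric(df), is.numeric(scale), scale >= 0)
  structure(list(df = df, scale = scale), class = "variance_prior")
}

#' Model specification for the univariate animal model
#'
#' For threshold (binary) traits the liability threshold is fixed at 0 and
#' the residual variance at 1 — the standard identification, under which
#' `h2 = sigma2_a / (sigma2_a + 1)`. For linear traits the residual variance
#' is sampled.
#'
#' @param trait_kind `"threshold"` or `"linear"`.
#' @param prior_genetic,prior_residual [variance_prior()]s; the residual
#'   prior is ignored for threshold traits. The genetic-variance default is
#'   the flat prior for linear traits but a proper weakly informative
#'   `variance_prior(4, 0.2)` for threshold traits: with binary records the
#'   likelihood flattens towards the heritability-one limit, and improper
#'   variance priors then leave the chain free to drift into that region.
#' @export
model_spec <- function(trait_kind = c("threshold", "linear"),
                       prior_genetic = NULL,
                       prior_residual = variance_prior()) {
  trait_kind <- match.arg(trait_kind)
  if (is.null(prior_genetic))
    prior_genetic <- if (trait_kind == "threshold") variance_prior(4, 0.2)
      else variance_prior()
  structure(list(trait_kind = trait_kind, threshold = 0,
                 prior_genetic = prior_genetic,
                 prior_residual = prior_residual),
            class = "model_spec")
}

#' Gibbs chain configuration
#'
#' Defaults mirror a full production run: 1,000,000 cycles, 250,000 burn-in,
#' storage interval (thin) 25, giving 30,000 stored samples. `scale_factor`
#' shrinks chain length and burn-in proportionally for desk-scale runs while
#' keeping the thin interval (e.g. `scale_factor = 0.02` gives 20,000 cycles
#' with 5,000 burn-in).
#'
#' @param chain_length total Gibbs cycles.
#' @param burn_in initial cycles discarded.
#' @param thin storage interval; cycles `burn_in + thin, burn_in + 2*thin,
#'   ...` are kept.
#' @param seed integer seed governing all randomness of the run.
#' @param scale_factor multiplier applied to `chain_length` and `burn_in`.
#' @export
gibbs_config <- function(chain_length = 1e6, burn_in = 250000, thin = 25,
                         seed = 1, scale_factor = 1) {
  chain_length <- as.integer(round(chain_length * scale_factor))
  burn_in <- as.integer(round(burn_in * scale_factor))
  thin <- as.integer(thin)
  if (thin < 1L) stop("thin must be >= 1")
  if (burn_in < 0L || burn_in >= chain_length)
    stop("burn_in must be in [0, chain_length)")
  structure(list(chain_length = chain_length, burn_in = burn_in, thin = thin,
                 seed = as.integer(seed),
                 n_stored = (chain_length - burn_in) %/% thin),
            class = "gibbs_config")
}

#' Sample latent liabilities for a threshold trait
#'
#' Draws each liability from a normal with the record's current mean,
#' truncated to `(-Inf, t]` for score 0 and `(t, Inf)` for score 1, by
#' inverse CDF in log space (robust for extreme means).
#'
#' @param mu vector of liability means (current `X beta + Z a`).
#' @param score binary scores (0/1).
#' @param threshold liability threshold t (default 0).
#' @param sd residual standard deviation (default 1).
#' @return Vector of liability draws, sign-consistent with the scores.
#' @export
sample_liabilities <- function(mu, score, threshold = 0, sd = 1) {
  if (!all(score %in% c(0, 1))) stop("scores must be 0 or 1")
  out <- numeric(length(mu))
  for (i in seq_along(mu))
    out[i] <- rtnorm_cpp(1L, mu[i], sd, threshold, score[i] == 1)
  out
}

#' One Gibbs pass over location effects
#'
#' Single-site (Gauss-Seidel-with-noise) updates of the fixed effects and
#' breeding values from their full conditionals under the mixed-model
#' equations, with `lambda = sigma2_e / sigma2_a` weighting the sparse
#' A-inverse. Reference R implementation of the pass used inside the
#' compiled chain driver; intended for small problems and cross-checks.
#'
#' @param y current data vector (liabilities for threshold traits).
#' @param X fixed-effect design (coercible to sparse).
#' @param animal integer pedigree code per record.
#' @param ainv an `a_inverse` object or sparse A-inverse matrix.
#' @param beta,a current fixed-effect and breeding-value states.
#' @param sigma2_a,sigma2_e current variance components.
#' @return List with updated `beta` and `a`.
#' @export
sample_location <- function(y, X, animal, ainv, beta, a, sigma2_a, sigma2_e) {
  if (sigma2_a <= 0) stop("sigma2_a must be positive")
  Ai <- as_ainv_matrix(ainv)
  X <- methods::as(X, "CsparseMatrix")
  lambda <- sigma2_e / sigma2_a
  e <- as.numeric(y - X %*% beta)
  e <- e - a[animal]
  for (j in seq_len(ncol(X))) {
    x <- X[, j]
    xtx <- sum(x^2)
    if (xtx == 0) next
    mean_j <- beta[j] + sum(x * e) / xtx
    bnew <- rnorm(1, mean_j, sqrt(sigma2_e / xtx))
    e <- e - x * (bnew - beta[j])
    beta[j] <- bnew
  }
  nrec <- tabulate(animal, nbins = nrow(Ai))
  for (k in seq_len(nrow(Ai))) {
    arow <- sum(Ai[, k] * a) - Ai[k, k] * a[k]
    recs <- which(animal == k)
    d <- nrec[k] + lambda * Ai[k, k]
    mean_k <- (sum(e[recs]) + nrec[k] * a[k] - lambda * arow) / d
    anew <- rnorm(1, mean_k, sqrt(sigma2_e / d))
    if (length(recs)) e[recs] <- e[recs] - (anew - a[k])
    a[k] <- anew
  }
  list(beta = beta, a = a)
}

#' Draw the additive genetic variance from its full conditional
#'
#' Scaled inverse chi-square with `q + df` degrees of freedom and sum of
#' squares `a' A^-1 a + df * scale`, where q is the number of animals.
#'
#' @param a breeding-value vector.
#' @param ainv an `a_inverse` object or sparse A-inverse matrix.
#' @param prior a [variance_prior()].
#' @param n number of draws (default 1).
#' @export
sample_genetic_variance <- function(a, ainv, prior = variance_prior(),
                                    n = 1) {
  Ai <- as_ainv_matrix(ainv)
  ss <- as.numeric(t(a) %*% (Ai %*% a))
  if (ss < 0) stop("a' A^-1 a negative: A-inverse is not positive definite")
  q <- length(a)
  df <- q + prior$df
  if (df <= 0) stop("full conditional has non-positive degrees of freedom")
  (ss + prior$df * prior$scale) / rchisq(n, df)
}

as_ainv_matrix <- function(ainv) {
  if (inherits(ainv, "a_inverse")) ainv$a_inverse
  else methods::as(ainv, "CsparseMatrix")
}

#' Run the univariate Gibbs chain on prepared inputs
#'
#' Low-level driver: cycles liabilities (threshold traits), location effects
#' and the variance components, storing post-burn-in thinned samples of
#' `sigma2_a`, `sigma2_e` and `h2 = sigma2_a / (sigma2_a + sigma2_e)` plus
#' running posterior means of the breeding values. Identical seed and
#' configuration give a bit-identical chain.
#'
#' @param y data vector: 0/1 scores (threshold) or phenotypes (linear).
#' @param X sparse fixed-effect design matrix.
#' @param animal integer pedigree code per record.
#' @param ainv an `a_inverse` object (or sparse A-inverse).
#' @param model a [model_spec()].
#' @param config a [gibbs_config()].
#' @param start optional list with `sigma2_a`, `sigma2_e` starting values.
#' @param update optional list to freeze components, e.g.
#'   `list(sigma2_a = FALSE)` keeps `sigma2_a` at its starting value.
#' @return A `gibbs_fit` object; its `summary()` method returns the
#'   posterior summary.
#' @export
gibbs_animal_model <- function(y, X, animal, ainv, model = model_spec(),
                               config = gibbs_config(), start = list(),
                               update = list()) {
  Ai <- as_ainv_matrix(ainv)
  q <- nrow(Ai)
  X <- methods::as(X, "CsparseMatrix")
  threshold <- model$trait_kind == "threshold"
  vy <- var(y)
  s2a0 <- start$sigma2_a %||% if (threshold) 0.2 else 0.4 * vy
  s2e0 <- start$sigma2_e %||% if (threshold) 1 else 0.6 * vy
  up_a <- update$sigma2_a %||% TRUE
  up_e <- update$sigma2_e %||% TRUE
  set.seed(config$seed)
  res <- gibbs_uni_cpp(
    as.numeric(y), threshold, X, as.integer(animal), q,
    methods::as(Ai, "dMatrix"),
    model$prior_genetic$df, model$prior_genetic$scale,
    model$prior_residual$df, model$prior_residual$scale,
    s2a0, s2e0, config$chain_length, config$burn_in, config$thin,
    up_a, !threshold && up_e)
  samples <- as.data.frame(res$samples)
  names(samples) <- c("sigma2_a", "sigma2_e", "h2")
  samples <- cbind(cycle = config$burn_in + config$thin * seq_len(nrow(samples)),
                   samples)
  structure(list(samples = samples, ebv = res$ebv_mean,
                 beta = setNames(res$beta_mean, colnames(X)),
                 final_state = list(liability = res$final_liability,
                                    a = res$final_a, beta = res$final_beta),
                 model = model, config = config, y = as.numeric(y),
                 X = X, animal = as.integer(animal), n_records = length(y),
                 n_animals = q, call = match.call()),
            class = "gibbs_fit")
}

#' Fit the animal model to phenotype records end to end
#'
#' High-level interface: assembles contemporary groups, applies the record
#' filters, builds the design and the sparse A-inverse, and runs the Gibbs
#' chain. Threshold model for binary traits, linear model for yearling
#' weight.
#'
#' @param records long-format phenotype data frame.
#' @param pedigree a [ped_table] covering all phenotyped animals.
#' @param trait trait code (see [TRAIT_CODES]).
#' @param model a [model_spec()]; default chosen from the trait.
#' @param config a [gibbs_config()].
#' @param yw_covariate fit centered yearling weight + square as covariates
#'   (default: TRUE for FL when the column is available).
#' @param lineage optional lineage column name fitted as fixed.
#' @param use_inbreeding account for inbreeding in A-inverse.
#' @param ... passed to [filter_records()].
#' @return A `gibbs_fit` with the prep products in `$prep`; breeding values
#'   in `$ebv` are named by animal id.
#' @export
fit_animal_model <- function(records, pedigree, trait, model = NULL,
                             config = gibbs_config(), yw_covariate = NULL,
                             lineage = NULL, use_inbreeding = TRUE, ...) {
  stopifnot(trait %in% TRAIT_CODES)
  if (is.null(model))
    model <- model_spec(if (is_binary_trait(trait)) "threshold" else "linear")
  if (is.null(yw_covariate))
    yw_covariate <- trait == "FL" && "yearling_weight" %in% names(records) &&
      !anyNA(records$yearling_weight[records$trait == trait])
  flt <- filter_records(records, trait, ...)
  des <- build_design(flt$records, pedigree, yw_covariate = yw_covariate,
                      lineage = lineage)
  ainv <- build_a_inverse(pedigree, use_inbreeding = use_inbreeding)
  fit <- gibbs_animal_model(flt$records$score, des$X, des$animal, ainv,
                            model = model, config = config)
  names(fit$ebv) <- pedigree$id
  fit$trait <- trait
  fit$prep <- list(filter = flt, design = des, pedigree = pedigree)
  fit$call <- match.call()
  fit
}

#' Posterior summary of a fitted chain
#'
#' Posterior mean, posterior standard deviation (PSD), equal-tail 95%
#' credibility interval, effective sample size and convergence flags
#' (Geweke z, Heidelberger-Welch) for each stored parameter.
#'
#' @param fit a `gibbs_fit` (or `gibbs_bifit`) object.
#' @param level credibility level (default 0.95).
#' @return Object of class `posterior_summary`: data frame with one row per
#'   parameter.
#' @export
summarize_posterior <- function(fit, level = 0.95) {
  sam <- fit$samples[, setdiff(names(fit$samples), "cycle"), drop = FALSE]
  if (!nrow(sam)) stop("empty chain: nothing to summarize")
  rows <- lapply(names(sam), function(p) {
    x <- sam[[p]]
    ci <- ci_equal_tail(x, level)
    gz <- tryCatch(geweke_z(x), error = function(e) NA_real_)
    hw <- tryCatch(heidelberger_welch(x), error = function(e) NULL)
    es <- tryCatch(effective_sample_size(x), error = function(e) NA_real_)
    conv <- if (sd(x) == 0) NA else
      !is.na(gz) && abs(gz) < 1.96 && !is.null(hw) && isTRUE(hw$stationary)
    data.frame(parameter = p, mean = mean(x), psd = sd(x),
               ci_low = ci[1], ci_high = ci[2], ess = es, geweke_z = gz,
               converged = conv)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("posterior_summary", "data.frame")
  out
}

#' @export
print.gibbs_fit <- function(x, ...) {
  cat("Bayesian", x$model$trait_kind, "animal model",
      if (!is.null(x$trait)) paste0("(trait ", x$trait, ")"), "\n")
  cat(sprintf("records: %d   animals in pedigree: %d\n",
              x$n_records, x$n_animals))
  cat(sprintf("chain: %d cycles, burn-in %d, thin %d, %d stored (seed %d)\n",
              x$config$chain_length, x$config$burn_in, x$config$thin,
              nrow(x$samples), x$config$seed))
  cat(sprintf("posterior h2 = %.3f +/- %.3f\n",
              mean(x$samples$h2), sd(x$samples$h2)))
  invisible(x)
}

#' @export
summary.gibbs_fit <- function(object, ...) summarize_posterior(object, ...)

#' @export
print.posterior_summary <- function(x, ...) {
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) signif(v, 4))
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
coef.gibbs_fit <- function(object, ...) object$beta

#' Posterior-mean breeding values of a fit
#'
#' @param fit a `gibbs_fit` or `gibbs_bifit`.
#' @return Named numeric vector of EBVs (posterior means), in pedigree code
#'   order.
#' @export
ebv <- function(fit) UseMethod("ebv")

#' @export
ebv.gibbs_fit <- function(fit) fit$ebv

#' @export
fitted.gibbs_fit <- function(object, ...) {
  mu <- if (length(object$beta))
    as.numeric(object$X %*% object$beta) else rep(0, object$n_records)
  mu + unname(object$ebv[object$animal])
}

#' @export
residuals.gibbs_fit <- function(object, ...) {
  if (object$model$trait_kind == "threshold")
    object$final_state$liability - fitted(object)
  else object$y - fitted(object)
}

#' @export
predict.gibbs_fit <- function(object, newanimals = NULL, ...) {
  if (is.null(newanimals)) return(fitted(object))
  object$ebv[as.character(newanimals)]
}

#' @export
plot.gibbs_fit <- function(x, parameter = "h2", ...) {
  graphics::plot(x$samples$cycle, x$samples[[parameter]], type = "l",
                 xlab = "cycle", ylab = parameter,
                 main = "Gibbs chain trace", ...)
  graphics::abline(h = mean(x$samples[[parameter]]), col = 2, lty = 2)
  invisible(x)
}

#' @export
simulate.gibbs_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- fitted(object)
  out <- replicate(nsim, {
    if (object$model$trait_kind == "threshold")
      as.numeric(rnorm(length(mu), mu, 1) > object$model$threshold)
    else rnorm(length(mu), mu, sqrt(mean(object$samples$sigma2_e)))
  })
  as.data.frame(out)
}
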