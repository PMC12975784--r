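# Unit behavior of the univariate sampler's building blocks and contracts.
# Parameter-recovery suites at study scale live in test-acceptance.R.

test_that("liability draws respect truncation and closed-form moments", {
  set.seed(1)
  n <- 20000
  up <- sample_liabilities(rep(0, n), rep(1, n))
  dn <- sample_liabilities(rep(0, n), rep(0, n))
  expect_true(all(up > 0) && all(dn <= 0))
  expect_equal(mean(up), sqrt(2 / pi), tolerance = 0.02)
  expect_equal(mean(dn), -sqrt(2 / pi), tolerance = 0.02)
  # mean far above the threshold: truncation mass negligible
  far <- sample_liabilities(rep(10, n / 4), rep(1, n / 4))
  expect_equal(mean(far), 10, tolerance = 0.02)
  expect_equal(sd(far), 1, tolerance = 0.05)
  # mean far on the wrong side: tail sampler stays finite and consistent
  hard <- sample_liabilities(rep(-8, 500), rep(1, 500))
  expect_true(all(is.finite(hard)) && all(hard > 0))
  hard2 <- sample_liabilities(rep(12, 500), rep(0, 500))
  expect_true(all(is.finite(hard2)) && all(hard2 <= 0))
  expect_error(sample_liabilities(0, 2), "0 or 1")
})

test_that("genetic variance draws follow the scaled inverse chi-square", {
  q <- 40
  ped <- ped_table(1:q, rep(0, q), rep(0, q))  # A = I
  ai <- build_a_inverse(ped)
  a <- rnorm(q)
  S <- sum(a^2)
  set.seed(2)
  draws <- sample_genetic_variance(a, ai, variance_prior(0, 0), n = 5000)
  expect_equal(mean(draws), S / (q - 2), tolerance = 0.05)
  # exact distribution check: S / chisq_q
  u <- 1 - pchisq(S / draws, df = q)
  expect_gt(ks.test(u, "punif")$p.value, 0.001)
  # informative prior pools the prior sum of squares
  set.seed(3)
  d2 <- sample_genetic_variance(a, ai, variance_prior(4, 0.2), n = 5000)
  expect_equal(mean(d2), (S + 0.8) / (q + 4 - 2), tolerance = 0.05)
  expect_error(sample_genetic_variance(a, ai, variance_prior(-60, 0)),
               "degrees of freedom")
})

test_that("location pass matches the mixed-model-equation solution", {
  set.seed(4)
  n <- 60; q <- 30
  ped <- ped_table(1:q, rep(0, q), rep(0, q))
  ai <- build_a_inverse(ped)
  X <- cbind(1, rep(c(0, 1), each = n / 2))
  animal <- sample(1:q, n, replace = TRUE)
  y <- rnorm(n, 2 + X[, 2], 1)
  s2a <- 0.5; s2e <- 1
  fit <- gibbs_animal_model(y, X, animal, ai, model = model_spec("linear"),
    config = gibbs_config(chain_length = 15000, burn_in = 2000, thin = 5,
                          seed = 5),
    start = list(sigma2_a = s2a, sigma2_e = s2e),
    update = list(sigma2_a = FALSE, sigma2_e = FALSE))
  Z <- Matrix::sparseMatrix(i = 1:n, j = animal, dims = c(n, q))
  W <- cbind(X, as.matrix(Z))
  C <- crossprod(W) / s2e +
    Matrix::bdiag(Matrix::Diagonal(2, 0), ai$a_inverse / s2a)
  sol <- as.numeric(Matrix::solve(C + Matrix::Diagonal(q + 2, 1e-10),
                                  crossprod(W, y) / s2e))
  expect_equal(unname(coef(fit)), sol[1:2], tolerance = 0.05)
  expect_equal(fit$ebv, sol[3:(q + 2)], tolerance = 0.1)
  expect_gt(cor(fit$ebv, sol[3:(q + 2)]), 0.99)

  # the exported single pass agrees in expectation on the same system
  set.seed(6)
  passes <- replicate(400, {
    st <- sample_location(y, X, animal, ai, beta = sol[1:2],
                          a = sol[3:(q + 2)], sigma2_a = s2a, sigma2_e = s2e)
    c(st$beta, st$a)
  })
  expect_equal(rowMeans(passes)[1:2], sol[1:2], tolerance = 0.08)
  expect_error(sample_location(y, X, animal, ai, rep(0, 2), rep(0, q),
                               sigma2_a = 0, sigma2_e = 1), "positive")
})

test_that("infinite shrinkage drives breeding values to zero", {
  set.seed(8)
  n <- 40; q <- 20
  ped <- ped_table(1:q, rep(0, q), rep(0, q))
  ai <- build_a_inverse(ped)
  animal <- rep(1:q, each = 2)
  y <- rnorm(n)
  fit <- gibbs_animal_model(y, matrix(1, n, 1), animal, ai,
    model = model_spec("linear"),
    config = gibbs_config(chain_length = 3000, burn_in = 500, thin = 5,
                          seed = 8),
    start = list(sigma2_a = 1e-8, sigma2_e = 1),
    update = list(sigma2_a = FALSE, sigma2_e = FALSE))
  expect_lt(max(abs(fit$ebv)), 1e-3)
  # and the single fixed effect then recovers the data mean
  expect_equal(unname(coef(fit)), mean(y), tolerance = 0.05)
})

test_that("threshold chains keep the identification constraints", {
  set.seed(10)
  df <- random_pedigree_frame(80, seed = 10)
  ped <- ped_table(df$animal, df$sire, df$dam)
  animal <- 17:80
  score <- rbinom(64, 1, 0.3)
  fit <- gibbs_animal_model(score, matrix(1, 64, 1), animal,
                            build_a_inverse(ped),
                            model = model_spec("threshold",
                              prior_genetic = variance_prior(4, 0.2)),
                            config = gibbs_config(chain_length = 2000,
                                                  burn_in = 500, thin = 5,
                                                  seed = 10))
  expect_true(all(fit$samples$sigma2_e == 1))
  expect_equal(fit$samples$h2,
               fit$samples$sigma2_a / (fit$samples$sigma2_a + 1))
  # threshold consistency at the final stored state
  l <- fit$final_state$liability
  expect_true(all(l[score == 1] > 0))
  expect_true(all(l[score == 0] <= 0))
  # identical seed and config give a bit-identical chain
  fit2 <- gibbs_animal_model(score, matrix(1, 64, 1), animal,
                             build_a_inverse(ped),
                             model = model_spec("threshold",
                               prior_genetic = variance_prior(4, 0.2)),
                             config = gibbs_config(chain_length = 2000,
                                                   burn_in = 500, thin = 5,
                                                   seed = 10))
  expect_identical(fit$samples, fit2$samples)
  expect_identical(fit$ebv, fit2$ebv)
})

test_that("intercept-only linear model approaches conjugate behavior", {
  set.seed(12)
  n <- 200
  ped <- ped_table(1:n, rep(0, n), rep(0, n))
  y <- rnorm(n, 5, 2)
  fit <- gibbs_animal_model(y, matrix(1, n, 1), 1:n, build_a_inverse(ped),
    model = model_spec("linear"),
    config = gibbs_config(chain_length = 20000, burn_in = 4000, thin = 8,
                          seed = 12))
  expect_equal(unname(coef(fit)), mean(y), tolerance = 0.1)
  # total variance is identified even though the split is weak at A = I
  tot <- fit$samples$sigma2_a + fit$samples$sigma2_e
  expect_equal(mean(tot), var(y), tolerance = 0.2)
})

test_that("posterior summaries expose mean, PSD and credibility bounds", {
  fake <- structure(list(samples = data.frame(cycle = 1:200,
                                              h2 = rep(0.3, 200))),
                    class = "gibbs_fit")
  s <- summarize_posterior(fake)
  expect_equal(s$mean, 0.3)
  expect_equal(s$psd, 0)
  expect_equal(c(s$ci_low, s$ci_high), c(0.3, 0.3))
  expect_error(summarize_posterior(
    structure(list(samples = data.frame(h2 = numeric())),
              class = "gibbs_fit")), "empty chain")
})

test_that("threshold posterior matches an exact quadrature oracle", {
  # paternal half-sib design: the marginal likelihood factorizes into 1-D
  # integrals per sire family, giving the exact posterior without MCMC
  set.seed(21)
  ns <- 10; m <- 40
  q <- ns + ns * m
  sire <- c(rep(0, ns), rep(1:ns, each = m))
  ped <- ped_table(1:q, sire, rep(0, q))
  u <- simulate_breeding_values(ped, 0.5)
  off <- (ns + 1):q
  thr <- qnorm(0.8) * sqrt(1.5)
  y <- as.numeric(u[off] + rnorm(ns * m) > thr)

  margll <- function(s2, mu) {
    sc <- sqrt(1 + 0.75 * s2)
    tot <- 0
    for (f in 1:ns) {
      k <- sum(y[sire[off] == f])
      g <- function(s) {
        p <- pnorm((mu + s / 2) / sc)
        p^k * (1 - p)^(m - k) * dnorm(s, 0, sqrt(s2))
      }
      tot <- tot + log(integrate(Vectorize(g), -12 * sqrt(s2),
                                 12 * sqrt(s2))$value)
    }
    tot
  }
  s2g <- exp(seq(log(0.02), log(30), length.out = 50))
  ds2 <- diff(c(0, s2g))
  mug <- seq(-3, 0.5, by = 0.175)
  lp <- outer(s2g, mug, Vectorize(margll))
  # prior matching the threshold default, variance_prior(4, 0.2)
  lp <- sweep(lp, 1, log(dchisq(0.8 / s2g, 4) * 0.8 / s2g^2), "+")
  w <- exp(lp - max(lp))
  w <- sweep(w, 1, ds2, "*")
  w <- w / sum(w)
  h2g <- s2g / (1 + s2g)
  exact_mean_h2 <- sum(h2g * rowSums(w))

  fit <- gibbs_animal_model(y, matrix(1, ns * m, 1), off,
                            build_a_inverse(ped),
                            model = model_spec("threshold"),
                            config = gibbs_config(30000, 5000, 25, seed = 21))
  expect_equal(mean(fit$samples$h2), exact_mean_h2, tolerance = 0.12)
})
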