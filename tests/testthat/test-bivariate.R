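# Unit contracts of the bivariate linear-threshold sampler. Recovery of the
# genetic correlation at study scale lives in test-acceptance.R.

biv_toy <- function(seed = 1, n_founders = 120, gens = 2, rg = 0) {
  g12 <- rg * sqrt(0.3 * 100)
  cfg <- sim_config(n_founders = n_founders, n_generations = gens,
                    offspring_per_mating = 3, sires_per_generation = 6,
                    traits = "both",
                    true_G = matrix(c(0.3, g12, g12, 100), 2),
                    true_R = matrix(c(1, 0, 0, 150), 2),
                    incidence_target = 0.2, n_cg = 6, seed = seed)
  simulate_herd(cfg)
}

fit_biv_toy <- function(herd, seed = 1, n_iter = 3000, burn = 500,
                        zero_cov = FALSE) {
  fit_bivariate_model(herd$records, herd$pedigree,
                      config = gibbs_config(n_iter, burn, thin = 5,
                                            seed = seed),
                      zero_cov = zero_cov)
}

test_that("the residual constraint and PD hold in every stored sample", {
  herd <- biv_toy(seed = 2)
  fit <- fit_biv_toy(herd, seed = 2)
  s <- fit$samples
  expect_true(all(s$r11 == 1))
  expect_true(all(s$r22 - s$r12^2 > 0))       # residual PD
  expect_true(all(s$g11 > 0 & s$g22 > 0 & s$g11 * s$g22 - s$g12^2 > 0))
  expect_true(all(abs(s$r_g) < 1))
  expect_equal(s$r_g, s$g12 / sqrt(s$g11 * s$g22))
  # liability consistency for observed binary records at the final state
  sc <- fit$score
  l <- fit$final_state$liability
  obs <- !is.na(sc)
  expect_true(all(l[obs][sc[obs] == 1] > 0))
  expect_true(all(l[obs][sc[obs] == 0] <= 0))
})

test_that("bivariate chains are seed-deterministic", {
  herd <- biv_toy(seed = 3)
  f1 <- fit_biv_toy(herd, seed = 5, n_iter = 1000, burn = 200)
  f2 <- fit_biv_toy(herd, seed = 5, n_iter = 1000, burn = 200)
  expect_identical(f1$samples, f2$samples)
})

test_that("forcing zero covariances reproduces univariate estimates", {
  herd <- biv_toy(seed = 4, n_founders = 160)
  fitb <- fit_bivariate_model(herd$records, herd$pedigree,
    config = gibbs_config(6000, 1000, thin = 5, seed = 4),
    prior_G = list(df = 4, scale = diag(c(0.2, 50))), zero_cov = TRUE)
  expect_true(all(fitb$samples$g12 == 0) && all(fitb$samples$r12 == 0))
  # univariate runs with the channel-matched priors
  fitu1 <- fit_animal_model(herd$records, herd$pedigree, "FL",
    model = model_spec("threshold", prior_genetic = variance_prior(4, 0.2)),
    config = gibbs_config(6000, 1000, thin = 5, seed = 14))
  expect_equal(mean(fitb$samples$g11), mean(fitu1$samples$sigma2_a),
               tolerance = 0.35)
  fitu2 <- fit_animal_model(herd$records, herd$pedigree, "YW",
    model = model_spec("linear", prior_genetic = variance_prior(4, 50)),
    config = gibbs_config(6000, 1000, thin = 5, seed = 15))
  expect_equal(mean(fitb$samples$g22), mean(fitu2$samples$sigma2_a),
               tolerance = 0.3)
  expect_equal(mean(fitb$samples$h2_2), mean(fitu2$samples$h2),
               tolerance = 0.15)
})

test_that("negating the continuous trait flips the genetic correlation", {
  herd <- biv_toy(seed = 6, rg = -0.5)
  fit <- fit_biv_toy(herd, seed = 6, n_iter = 4000, burn = 1000)
  rec_neg <- herd$records
  yw <- rec_neg$trait == "YW"
  rec_neg$score[yw] <- 600 - rec_neg$score[yw]
  fit_neg <- fit_bivariate_model(rec_neg, herd$pedigree,
                                 config = gibbs_config(4000, 1000, thin = 5,
                                                       seed = 6))
  r1 <- genetic_correlation_summary(fit)
  r2 <- genetic_correlation_summary(fit_neg)
  expect_lt(r1$mean, 0)
  expect_gt(r2$mean, 0)
  expect_equal(r1$mean, -r2$mean, tolerance = 0.25)
})

test_that("genetic correlation summary arithmetic on constructed chains", {
  mk <- function(g11, g12, g22) {
    structure(list(samples = data.frame(
      cycle = seq_along(g11), g11 = g11, g12 = g12, g22 = g22,
      r11 = 1, r12 = 0, r22 = 1, r_g = g12 / sqrt(g11 * g22),
      h2_1 = 0.2, h2_2 = 0.4)), class = "gibbs_bifit")
  }
  # constant G
  cs <- genetic_correlation_summary(mk(rep(1, 200), rep(0.5, 200),
                                       rep(1, 200)))
  expect_equal(cs$mean, 0.5)
  expect_equal(cs$psd, 0)
  # zero covariance
  expect_equal(genetic_correlation_summary(mk(rep(1, 200), rep(0, 200),
                                              rep(1, 200)))$mean, 0)
  # mixture of two values averages the per-sample correlations
  mix <- mk(rep(1, 200), rep(c(0.2, 0.6), each = 100), rep(1, 200))
  expect_equal(genetic_correlation_summary(mix)$mean, 0.4)
  # non-PD samples are rejected with a warning
  bad <- mk(c(rep(1, 150), rep(0.01, 50)), rep(0.5, 200), rep(1, 200))
  expect_warning(out <- genetic_correlation_summary(bad), "positive definite")
  expect_equal(out$n_rejected, 50)
})

test_that("disjoint trait sets raise the weak-identification warning", {
  herd <- biv_toy(seed = 8)
  rec <- herd$records
  fl <- rec[rec$trait == "FL", ]
  yw <- rec[rec$trait == "YW", ]
  half <- nrow(fl) %/% 2
  rec2 <- rbind(fl[seq_len(half), ], yw[-seq_len(half), ])
  expect_warning(
    fit_bivariate_model(rec2, herd$pedigree,
                        config = gibbs_config(400, 100, thin = 5, seed = 8)),
    "disjoint")
})
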