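# Zero-inflated Poisson occurrence model: pmf, likelihood, MLE oracle,
# MCMC sampler and convergence diagnostics.

test_that("the ZIP pmf matches hand evaluation and normalizes", {
  expect_equal(zip_logpmf(0, 0.4, 2), log(0.6 + 0.4 * exp(-2)))
  # q = 1 degenerates to the plain Poisson
  expect_equal(zip_logpmf(0:10, 1, 3.5), dpois(0:10, 3.5, log = TRUE))
  # brute-force normalization over the support
  expect_equal(sum(exp(zip_logpmf(0:200, 0.7, 5))), 1, tolerance = 1e-12)
  expect_error(zip_logpmf(-1, 0.5, 1), "non-negative")
  expect_error(zip_logpmf(1.5, 0.5, 1), "non-negative integers")
  expect_error(zip_logpmf(1, 1.2, 1), "q must")
})

test_that("the model log-likelihood assembles per-site pmf terms with the offset", {
  # all beta = 0, T = 1: lambda = 1 everywhere, closed-form assembly
  y <- c(0, 0, 1, 2, 5)
  Tt <- rep(1, 5); Z <- matrix(rnorm(10), 5, 2)
  q <- 0.6
  expected <- 2 * log((1 - q) + q * exp(-1)) +
    sum(log(q) - 1 + y[3:5] * log(1) - lfactorial(y[3:5]))
  expect_equal(zip_loglik(y, Tt, Z, q, c(0, 0, 0)), expected)

  # doubling the effort doubles lambda (offset behaviour)
  beta <- c(-0.5, 0.3, -0.2); Tt2 <- runif(5, 10, 20)
  lam <- exp(beta[1] + Z %*% beta[-1] + log(Tt2))
  expect_equal(zip_loglik(y, 2 * Tt2, Z, q, beta),
               sum(zip_logpmf(y, q, 2 * lam)))
  expect_true(is.finite(zip_loglik(y, Tt2, Z, 0.999, c(50, -20, 30))))
  expect_error(zip_loglik(y, Tt2, Z[1:3, ], q, beta), "matching")
  expect_error(zip_loglik(y, Tt2, Z, q, c(0, 0)), "length")
})

test_that("the MLE recovers simulation truth and detects degenerate inputs", {
  set.seed(41)
  n <- 2000
  Z <- matrix(rnorm(n), n, 1, dimnames = list(NULL, "z1"))
  Tt <- runif(n, 13, 17)
  lam <- exp(-1 + 0.5 * Z[, 1] + log(Tt))
  y <- rbinom(n, 1, 0.7) * rpois(n, lam)
  fit <- fit_zip_mle(y, Tt, Z, seed = 1)
  expect_true(abs(fit$q - 0.7) < 3 * fit$se[["q"]])
  expect_true(abs(fit$beta[["(Intercept)"]] - (-1)) < 3 * fit$se[["(Intercept)"]])
  expect_true(abs(fit$beta[["z1"]] - 0.5) < 3 * fit$se[["z1"]])

  expect_error(fit_zip_mle(rep(0L, 20), rep(15, 20), matrix(rnorm(20))),
               "not identifiable")

  # plain Poisson data with no extra zeros: zero inflation vanishes
  y2 <- rpois(n, exp(0.5 + log(Tt)))
  fit2 <- fit_zip_mle(y2, Tt, Z, seed = 1)
  expect_gt(fit2$q, 0.95)
})

test_that("the MLE is a local optimum and reduces to the Poisson GLM at q = 1", {
  set.seed(42)
  n <- 300
  Z <- matrix(rnorm(2 * n), n, 2, dimnames = list(NULL, c("z1", "z2")))
  Tt <- runif(n, 10, 20)
  y <- rbinom(n, 1, 0.6) * rpois(n, exp(-0.5 + 0.4 * Z[, 1] + log(Tt)))
  fit <- fit_zip_mle(y, Tt, Z, seed = 2)
  ll_hat <- fit$loglik
  for (i in 1:100) {
    pert <- c(qlogis(fit$q), fit$beta) + rnorm(4, 0, 0.05)
    expect_lte(zip_loglik(y, Tt, Z, plogis(pert[1]), pert[-1]), ll_hat + 1e-8)
  }

  glm_fit <- glm(y ~ Z, family = poisson, offset = log(Tt))
  fixed <- fit_zip_mle(y, Tt, Z, seed = 2, fix_q = 1)
  expect_equal(unname(fixed$beta), unname(coef(glm_fit)), tolerance = 1e-6)
})

test_that("split R-hat separates mixed from unmixed chains", {
  set.seed(43)
  good <- matrix(rnorm(4000), 1000, 4)
  expect_lt(rhat(good), 1.01)
  offset_chains <- cbind(rnorm(500), rnorm(500) + 10)
  expect_gt(rhat(offset_chains), 1.5)
  expect_equal(rhat(matrix(2, 100, 4)), 1)   # 0/0 guarded by convention
  expect_error(rhat(matrix(rnorm(100), 100, 1)), "two chains")
})

test_that("the MCMC sampler is seed-deterministic and agrees with the MLE oracle", {
  set.seed(44)
  n <- 600
  Z <- matrix(rnorm(2 * n), n, 2, dimnames = list(NULL, c("z1", "z2")))
  Tt <- runif(n, 13, 17)
  y <- rbinom(n, 1, 0.7) * rpois(n, exp(-1 + 0.5 * Z[, 1] + log(Tt)))

  p1 <- fit_zip_mcmc(y, Tt, Z, chains = 2, iterations = 300, warmup = 150,
                     seed = 9)
  p2 <- fit_zip_mcmc(y, Tt, Z, chains = 2, iterations = 300, warmup = 150,
                     seed = 9)
  expect_identical(p1$draws, p2$draws)

  post <- fit_zip_mcmc(y, Tt, Z, seed = 3)
  expect_true(post$converged)
  mle <- fit_zip_mle(y, Tt, Z, seed = 3)
  pm <- apply(post$draws, 3, mean)
  psd <- apply(post$draws, 3, sd)
  expect_true(all(abs(pm - c(mle$q, mle$beta)) < 2 * psd))
})

test_that("effect summaries use equal-tailed intervals with nested CIs", {
  set.seed(45)
  draws <- array(NA_real_, dim = c(1000, 4, 2),
                 dimnames = list(NULL, NULL, c("q", "(Intercept)")))
  draws[, , "q"] <- runif(4000, 0.4, 0.6)
  draws[, , "(Intercept)"] <- rnorm(4000, 1, 0.1)
  post <- structure(list(draws = draws,
                         rhat = c(q = 1, "(Intercept)" = 1),
                         ess = c(q = 4000, "(Intercept)" = 4000),
                         converged = TRUE, settings = list()),
                    class = "zip_posterior")
  eff <- summarize_effects(post)
  b <- eff[eff$parameter == "(Intercept)", ]
  expect_equal(b$lo95, 0.804, tolerance = 0.01)
  expect_equal(b$hi95, 1.196, tolerance = 0.01)
  expect_true(b$significant)
  expect_true(b$lo95 <= b$lo80 && b$hi80 <= b$hi95)   # nesting

  draws[, , "(Intercept)"] <- rnorm(4000, 0, 1)
  post$draws <- draws
  eff0 <- summarize_effects(post)
  expect_false(eff0$significant[eff0$parameter == "(Intercept)"])
})
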