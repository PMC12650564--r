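# Short chains are used throughout; they are ample for the moments being
# checked and keep the suite fast.

fast_cfg <- function(method, ..., n_iterations = 3000, burn_in = 500,
                     seed = 4) {
  bayes_config(method, n_iterations = n_iterations, burn_in = burn_in,
               seed = seed, ...)
}

test_that("BayesA matches the conjugate closed form with pinned variances", {
  set.seed(8)
  n <- 150
  x <- rnorm(n)
  y <- 0.8 * x + rnorm(n, sd = 0.5)
  sigma_e2 <- 0.25
  sigma_b2 <- 10
  # near-degenerate priors pin both variances at known values, making the
  # beta conditional exactly conjugate normal
  cfg <- fast_cfg("A", n_iterations = 6000, burn_in = 1000,
                  nu = 1e8, scale = sigma_b2, nu_e = 1e8,
                  scale_e = sigma_e2)
  fit <- bayes_a(matrix(x), y, cfg)
  xc <- x - mean(x)
  c_xx <- sum(xc^2)
  # conjugate posterior for beta given variances (intercept = mean(y))
  post_mean <- sum(xc * (y - mean(y))) / (c_xx + sigma_e2 / sigma_b2)
  post_sd <- sqrt(sigma_e2 / (c_xx + sigma_e2 / sigma_b2))
  mc_se <- post_sd / sqrt(fit$n_saved)
  expect_lt(abs(fit$effects - post_mean), 3 * mc_se + 1e-8)
  expect_equal(fit$sigma_e2, sigma_e2, tolerance = 1e-2)
})

test_that("two-marker joint update matches the exact ridge posterior", {
  # with both variances pinned, the joint posterior of beta is exactly
  # N((X'X + (se2/sb2) I)^-1 X'y, .) - an analytic oracle for the sampler
  set.seed(12)
  n <- 100
  X <- matrix(rnorm(2 * n), n)
  y <- 0.6 * X[, 1] - 0.3 * X[, 2] + rnorm(n, sd = 0.4)
  sigma_e2 <- 0.16; sigma_b2 <- 5
  cfg <- fast_cfg("A", n_iterations = 8000, burn_in = 1000,
                  nu = 1e8, scale = sigma_b2, nu_e = 1e8,
                  scale_e = sigma_e2)
  fit <- bayes_a(X, y, cfg)
  Xc <- scale(X, scale = FALSE)
  A <- crossprod(Xc) + diag(sigma_e2 / sigma_b2, 2)
  post_mean <- solve(A, crossprod(Xc, y - mean(y)))
  post_sd <- sqrt(diag(sigma_e2 * solve(A)))
  mc_se <- 3 * post_sd / sqrt(fit$n_saved / 5)  # allow autocorrelation
  expect_lt(abs(fit$effects[1] - post_mean[1]), mc_se[1])
  expect_lt(abs(fit$effects[2] - post_mean[2]), mc_se[2])
})

test_that("shuffling y against features shrinks BayesA effects", {
  sim <- toy_panel(n = 200, m = 60, n_qtl = 10, h2 = 0.7, seed = 21)
  X <- gsae:::feature_values(sim$genotype)
  y <- sim$phenotypes$trait
  fit <- bayes_a(X, y, fast_cfg("A"))
  set.seed(1)
  fit_null <- bayes_a(X, sample(y), fast_cfg("A"))
  expect_lt(mean(abs(fit_null$effects)), mean(abs(fit$effects)))
})

test_that("BayesB with pi = 1 forces all effects to exactly zero", {
  set.seed(2)
  X <- matrix(rnorm(100 * 20), 100)
  y <- rnorm(100)
  fit <- bayes_b(X, y, fast_cfg("B", pi = 1, n_iterations = 1000,
                                burn_in = 200))
  expect_true(all(fit$effects == 0))
  gebv <- gebv_from_posterior(fit, X)
  expect_equal(unname(gebv), rep(fit$intercept, 100))
})

test_that("BayesB with pi = 0 collapses to the BayesA model", {
  sim <- toy_panel(n = 150, m = 40, n_qtl = 8, h2 = 0.6, seed = 22)
  X <- gsae:::feature_values(sim$genotype)
  y <- sim$phenotypes$trait
  fa <- bayes_a(X, y, fast_cfg("A", n_iterations = 4000, burn_in = 1000))
  fb <- bayes_b(X, y, fast_cfg("B", pi = 0, n_iterations = 4000,
                               burn_in = 1000))
  # same model => GEBVs agree within Monte-Carlo noise
  expect_gt(cor(gebv_from_posterior(fa, X), gebv_from_posterior(fb, X)),
            0.98)
})

test_that("BayesB ranks true QTL above null markers by inclusion", {
  sc <- sim_config(400, 200, n_qtl = 5, h2 = 0.6, ld_rho = 0, seed = 23)
  sim <- simulate_phenotypes(simulate_genotypes(sc), sc)
  X <- gsae:::feature_values(sim$genotype)
  fit <- bayes_b(X, sim$phenotypes$trait,
                 fast_cfg("B", n_iterations = 4000, burn_in = 1000))
  inc_qtl <- mean(fit$inclusion_prob[sim$qtl_idx])
  inc_null <- mean(fit$inclusion_prob[-sim$qtl_idx])
  expect_gt(inc_qtl, inc_null)
})

test_that("BayesCpi recovers the non-null fraction and bounds k", {
  sc <- sim_config(500, 300, n_qtl = 30, h2 = 0.6, ld_rho = 0, seed = 24)
  sim <- simulate_phenotypes(simulate_genotypes(sc), sc)
  X <- gsae:::feature_values(sim$genotype)
  fit <- bayes_cpi(X, sim$phenotypes$trait,
                   fast_cfg("Cpi", n_iterations = 4000, burn_in = 1000))
  expect_lt(abs((1 - fit$pi) - 0.10), 0.1)
  k <- fit$trace[, "k_included"]
  expect_true(all(k >= 0 & k <= ncol(X)))
  # all-null data: pi and sigma_b2 are only jointly identified (the
  # posterior has a ridge where (1-pi)*sigma_b2 ~ 0), so pi alone does not
  # concentrate near 1; the identified quantity is that markers explain
  # ~no phenotypic variance, with pi still clearly above the signal case
  set.seed(3)
  y0 <- rnorm(500)
  fit0 <- bayes_cpi(X, y0,
                    fast_cfg("Cpi", n_iterations = 2000, burn_in = 500))
  expect_gt(fit0$pi, 0.5)
  # markers absorb a small variance fraction on null data (~8% at
  # stationarity) versus ~60% in the signal fit above
  expect_lt(mean(fit0$trace[, "var_g"]) / var(y0), 0.15)
})

test_that("Bayesian Lasso shrinks and responds to fixed large lambda", {
  set.seed(5)
  n <- 120
  x <- rnorm(n)
  y <- x + rnorm(n, sd = 0.5)
  ols <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  fit <- bayes_lasso(matrix(x), y, fast_cfg("Lasso"))
  expect_lt(abs(fit$effects), abs(ols))      # shrinkage toward zero
  expect_gt(fit$effects * ols, 0)            # same sign
  big <- bayes_lasso(matrix(x), y,
                     fast_cfg("Lasso", lambda2 = 1e8,
                              n_iterations = 1500, burn_in = 300))
  expect_lt(abs(big$effects), 0.05 * abs(ols))
})

test_that("gebv_from_posterior is the centered linear predictor", {
  sim <- toy_panel(n = 80, m = 30, seed = 25)
  X <- gsae:::feature_values(sim$genotype)
  fit <- bayes_a(X[1:60, ], sim$phenotypes$trait[1:60],
                 fast_cfg("A", n_iterations = 1500, burn_in = 300))
  gebv <- gebv_from_posterior(fit, X)
  manual <- fit$intercept +
    drop(sweep(X, 2, fit$centers) %*% fit$effects)
  expect_equal(unname(gebv), unname(manual))
  # a validation row identical to a training row gets the same GEBV
  expect_equal(gebv[1], gebv_from_posterior(fit, X[1, , drop = FALSE]))
  # shifting a feature column identically in train and prediction leaves
  # GEBV differences unchanged
  X2 <- X; X2[, 3] <- X2[, 3] + 7
  fit2 <- bayes_a(X2[1:60, ], sim$phenotypes$trait[1:60],
                  fast_cfg("A", n_iterations = 1500, burn_in = 300))
  g2 <- gebv_from_posterior(fit2, X2)
  expect_equal(diff(gebv), diff(g2), tolerance = 1e-6)
  expect_error(gebv_from_posterior(fit, X[, 1:10]), "columns")
})

test_that("chains are seed-reproducible with correct draw accounting", {
  set.seed(9)
  X <- matrix(rnorm(60 * 10), 60)
  y <- rnorm(60)
  cfg <- fast_cfg("Cpi", n_iterations = 1100, burn_in = 250, thinning = 3)
  f1 <- bayes_cpi(X, y, cfg)
  f2 <- bayes_cpi(X, y, cfg)
  expect_identical(f1$effects, f2$effects)
  expect_identical(f1$trace, f2$trace)
  expect_identical(f1$n_saved, as.integer(floor((1100 - 250) / 3)))
  # residual-variance draws are strictly positive
  expect_true(all(f1$trace[, "sigma_e2"] > 0))
})

test_that("posterior ESS diagnostics are reported for monitored scalars", {
  skip_if_not_installed("coda")
  set.seed(10)
  X <- matrix(rnorm(50 * 5), 50)
  fit <- bayes_a(X, rnorm(50), fast_cfg("A", n_iterations = 1200,
                                        burn_in = 200))
  ess <- posterior_ess(fit)
  expect_true(ess[["sigma_e2"]] > 10)
})
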