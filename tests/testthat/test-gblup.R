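# rrblup_oracle() lives in helper-oracles.R (shared with the acceptance
# suite).

test_that("GBLUP equals RR-BLUP predictions (equivalence oracle)", {
  sim <- toy_panel(n = 80, m = 300, n_qtl = 30, h2 = 0.5, seed = 11)
  y <- sim$phenotypes$trait
  obs <- 1:60
  G <- vanraden_g(sim$genotype)
  vc <- list(sigma_a2 = 1.3, sigma_e2 = 0.9)   # arbitrary fixed VCs
  fit <- solve_mme(y, G = G, vc = vc,
                   observed_mask = seq_along(y) %in% obs)
  oracle <- rrblup_oracle(sim$genotype, y, obs, vc)
  expect_equal(unname(fit$gebv), oracle$gebv, tolerance = 1e-6)
  expect_equal(unname(fit$b), oracle$b, tolerance = 1e-6)
})

test_that("solve_mme has the closed-form shrinkage solution when G = I", {
  y <- c(1.0, 3.0)
  G <- diag(2)
  vc <- list(sigma_a2 = 2, sigma_e2 = 1)
  fit <- solve_mme(y, G = G, vc = vc, observed_mask = c(TRUE, TRUE))
  # direct Henderson solve: [X'X X'Z; Z'X Z'Z + I*lambda] [b; a] = [X'y; y]
  lambda <- vc$sigma_e2 / vc$sigma_a2
  C <- rbind(c(2, 1, 1), c(1, 1 + lambda, 0), c(1, 0, 1 + lambda))
  sol <- solve(C, c(sum(y), y))
  expect_equal(unname(fit$b), sol[1], tolerance = 1e-10)
  expect_equal(unname(fit$gebv), sol[2:3], tolerance = 1e-10)
  # shrinkage form: a_i = (y_i - b) * sigma_a2 / (sigma_a2 + sigma_e2)
  expect_equal(unname(fit$gebv),
               (y - sol[1]) * vc$sigma_a2 / (vc$sigma_a2 + vc$sigma_e2),
               tolerance = 1e-10)
})

test_that("lambda -> infinity drives GEBVs to zero; translation shifts b", {
  sim <- toy_panel(n = 40, m = 100, seed = 12)
  y <- sim$phenotypes$trait
  G <- vanraden_g(sim$genotype)
  fit <- solve_mme(y, G = G, vc = list(sigma_a2 = 1e-10, sigma_e2 = 1))
  expect_lt(max(abs(fit$gebv)), 1e-6)
  vc <- list(sigma_a2 = 1, sigma_e2 = 1)
  f1 <- solve_mme(y, G = G, vc = vc)
  f2 <- solve_mme(y + 5, G = G, vc = vc)
  expect_equal(unname(f2$b - f1$b), 5, tolerance = 1e-8)
  expect_equal(f2$gebv, f1$gebv, tolerance = 1e-8)
})

test_that("solve_mme respects the MME stationarity conditions", {
  sim <- toy_panel(n = 50, m = 150, seed = 14)
  y <- sim$phenotypes$trait
  G <- vanraden_g(sim$genotype)$values
  vc <- list(sigma_a2 = 1.5, sigma_e2 = 0.8)
  fit <- solve_mme(y, G = G, vc = vc)
  lambda <- vc$sigma_e2 / vc$sigma_a2
  a <- fit$gebv
  b <- fit$b
  # stationarity: X'X b + X'Z a = X'y ; Z'X b + (Z'Z + G^-1 lambda) a = Z'y
  Gi <- solve(G + diag(1e-10, nrow(G)))
  r1 <- length(y) * b + sum(a) - sum(y)
  r2 <- b + a + lambda * drop(Gi %*% a) - y
  expect_lt(abs(r1), 1e-6)
  expect_lt(max(abs(r2)), 1e-5)   # G^-1 uses a tiny jitter
})

test_that("REML recovers variance components and warns when flat", {
  sim <- toy_panel(n = 300, m = 1000, n_qtl = 100, h2 = 0.5, seed = 15)
  G <- vanraden_g(sim$genotype)
  vc <- reml_variance_components(sim$phenotypes$trait, G = G)
  expect_gt(vc$h2, 0.3)
  expect_lt(vc$h2, 0.7)
  # scaling y by c scales variances by c^2 and leaves h2 unchanged
  vc2 <- reml_variance_components(sim$phenotypes$trait * 3, G = G)
  expect_equal(vc2$h2, vc$h2, tolerance = 1e-4)
  expect_equal(vc2$sigma_a2, 9 * vc$sigma_a2, tolerance = 1e-3)
  # G = I: flat restricted likelihood is detected
  set.seed(1)
  expect_warning(reml_variance_components(rnorm(50), G = diag(50)),
                 "flat")
  expect_error(reml_variance_components(rnorm(5), G = diag(5)),
               "at least 10")
})

test_that("gblup_predict masks validation phenotypes and is consistent", {
  sim <- toy_panel(n = 120, m = 400, n_qtl = 40, h2 = 0.6, seed = 16)
  y <- sim$phenotypes$trait
  val <- 101:120
  res <- gblup_predict(sim$genotype, y, validation = val)
  expect_length(res$gebv, 120)
  # identical genotype rows receive identical GEBVs
  v <- sim$genotype$values
  v[2, ] <- v[1, ]
  g2 <- genotype_matrix(v)
  res2 <- gblup_predict(g2, y, validation = c(1L, 2L))
  expect_equal(unname(res2$gebv[1]), unname(res2$gebv[2]),
               tolerance = 1e-8)
  # validation accuracy against TBV is positive and meaningful
  expect_gt(cor(res$gebv[val], sim$tbv[val]), 0.3)
})

test_that("higher heritability gives higher GBLUP validation accuracy", {
  accs <- vapply(c(0.1, 0.9), function(h2) {
    mean(vapply(1:3, function(s) {
      sim <- toy_panel(n = 150, m = 300, n_qtl = 50, h2 = h2,
                       seed = 100 + s)
      val <- 121:150
      res <- gblup_predict(sim$genotype, sim$phenotypes$trait,
                           validation = val)
      cor(res$gebv[val], sim$phenotypes$trait[val])
    }, numeric(1)))
  }, numeric(1))
  expect_gt(accs[2], accs[1])
})
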