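toy_M <- function(n, m, p = 0.3, seed = 1) {
  set.seed(seed)
  matrix(rbinom(n * m, 2, p), n, m,
         dimnames = list(as.character(seq_len(n)), paste0("m", seq_len(m))))
}

test_that("VanRaden K has the expected arithmetic and scaling", {
  # identical genotype rows are genomically identical
  M <- rbind(a = c(0, 1, 2, 1), b = c(0, 1, 2, 1), c = c(2, 1, 0, 1))
  colnames(M) <- paste0("m", 1:4)
  K <- genomic_relationship_matrix(M)
  expect_equal(K["a", "a"], K["b", "b"])
  expect_equal(K["a", "b"], K["a", "a"])
  # 2 individuals x 2 markers hand computation: dosages [[0,2],[2,0]]
  M2 <- matrix(c(0, 2, 2, 0), 2, 2, dimnames = list(c("i1", "i2"),
                                                    c("m1", "m2")))
  # p = (0.5, 0.5); W = [[-1,1],[1,-1]]; denom = 2*(0.25+0.25) = 1
  expect_equal(unname(genomic_relationship_matrix(M2)),
               matrix(c(2, -2, -2, 2), 2))
  # large unrelated HWE panel: mean diagonal near 1
  Mbig <- toy_M(200, 10000, p = 0.3, seed = 2)
  expect_equal(mean(diag(genomic_relationship_matrix(Mbig))), 1,
               tolerance = 0.02)
  expect_error(genomic_relationship_matrix(matrix(0, 3, 2)), "monomorphic")
})

test_that("GBLUP Gibbs matches the closed-form ridge oracle", {
  M <- toy_M(20, 10, seed = 11)
  set.seed(12)
  y <- drop(scale(M, scale = FALSE) %*% rnorm(10, 0, 0.6)) + rnorm(20)
  fit <- fit_gblup(y, M, variance_ratio = 2 / 3,
                   mcmc_settings(12000, 2000, 10, seed = 1),
                   fixed_sigma_e2 = 1)
  orc <- ridge_oracle(y, M, fit$lambda)
  z <- abs(fit$a_post_mean - orc) / (fit$a_post_sd / sqrt(fit$n_kept))
  expect_true(all(z < 3))
  expect_equal(fit$n_kept, 1000L)
  # no-signal limit: constant response
  fit0 <- fit_gblup(rep(5, 20), M, mcmc = mcmc_settings(2000, 500, 5, seed = 2))
  expect_lt(max(abs(fit0$a_post_mean)), 1e-6)
  expect_equal(unname(predict(fit0, M)), rep(fit0$mu, 20), tolerance = 1e-6)
})

test_that("marker-effect GBLUP equals kinship-parameterized GBLUP", {
  M <- toy_M(15, 8, seed = 21)
  set.seed(22)
  y <- rnorm(15, 0, 2)
  a <- gblup_direct(y, M, 2 / 3, "marker")
  k <- gblup_direct(y, M, 2 / 3, "kinship")
  expect_equal(a$fitted, k$fitted, tolerance = 1e-10)
})

test_that("BayesC-pi limits: pure spike and slab-only ridge", {
  M <- toy_M(20, 10, seed = 31)
  set.seed(32)
  y <- drop(scale(M, scale = FALSE) %*% rnorm(10, 0, 0.6)) + rnorm(20)
  # pi = 1: every effect exactly zero, predictions collapse to mu
  f1 <- fit_bayescpi(y, M, mcmc_settings(2000, 500, 5, seed = 3), pi_fixed = 1)
  expect_true(all(f1$a_post_mean == 0))
  expect_true(all(f1$inclusion_prob == 0))
  expect_equal(unname(predict(f1, M)), rep(f1$mu, 20))
  # pi = 0 with fixed variances: common-variance model = ridge oracle
  p <- colMeans(M) / 2
  cscale <- 2 * sum(p * (1 - p))
  sig_a <- (2 / 3) / cscale  # sigma_e2 = 1, lambda = cscale / (2/3)
  f0 <- fit_bayescpi(y, M, mcmc_settings(12000, 2000, 10, seed = 4),
                     pi_fixed = 0, fixed_sigma_a2 = sig_a, fixed_sigma_e2 = 1)
  orc <- ridge_oracle(y, M, cscale / (2 / 3))
  z <- abs(f0$a_post_mean - orc) / (f0$a_post_sd / sqrt(f0$n_kept))
  expect_true(all(z < 3))
  expect_true(all(f0$inclusion_prob == 1))
})

test_that("BayesC-pi concentrates inclusion on causal markers", {
  hits <- numeric(5)
  for (s in 1:5) {
    M <- toy_M(150, 500, p = 0.3, seed = 50 + s)
    set.seed(60 + s)
    causal <- sample(500, 5)
    y <- drop(scale(M[, causal], scale = FALSE) %*% rep(1.2, 5)) +
      rnorm(150, 0, 1)
    fit <- fit_bayescpi(y, M, mcmc_settings(3000, 1000, 5, seed = 70 + s))
    top_decile <- names(sort(fit$inclusion_prob, decreasing = TRUE))[1:50]
    hits[s] <- mean(paste0("m", causal) %in% top_decile)
  }
  expect_true(all(hits == 1))
})

test_that("predict applies training centers and validates columns", {
  M <- toy_M(20, 6, seed = 41)
  set.seed(42)
  y <- rnorm(20)
  fit <- fit_gblup(y, M, mcmc = mcmc_settings(1500, 500, 5, seed = 5))
  # in-sample fitted values
  expect_equal(predict(fit, M),
               fit$mu + drop(sweep(M, 2, fit$centers) %*% fit$a_post_mean),
               ignore_attr = TRUE)
  # all-zero genotype row: prediction = mu minus centered contribution
  M0 <- matrix(0, 1, 6, dimnames = list("z", colnames(M)))
  expect_equal(unname(predict(fit, M0)),
               fit$mu - sum(fit$centers * fit$a_post_mean))
  # single marker arithmetic: mu = 0, a = 1.5, dosage 2, centering at 0
  f <- list(model = "gblup", mu = 0, a_post_mean = c(m1 = 1.5),
            centers = c(m1 = 0))
  class(f) <- "gp_fit"
  expect_equal(unname(predict(f, matrix(2, 1, 1,
                                        dimnames = list("x", "m1")))), 3)
  # column mismatch errors name the offender
  Mbad <- M[, c(2:6, 1)]
  expect_error(predict(fit, Mbad), "m")
  expect_error(predict(fit, M[, 1:5]), "m6")
})

test_that("posterior predictions are insensitive to marker column order", {
  M <- toy_M(25, 12, seed = 81)
  set.seed(82)
  y <- drop(scale(M, scale = FALSE) %*% rnorm(12, 0, 0.5)) + rnorm(25, 0, 0.5)
  perm <- sample(12)
  f1 <- fit_gblup(y, M, mcmc = mcmc_settings(8000, 2000, 5, seed = 6))
  f2 <- fit_gblup(y, M[, perm], mcmc = mcmc_settings(8000, 2000, 5, seed = 7))
  p1 <- predict(f1, M); p2 <- predict(f2, M[, perm])
  # Monte-Carlo noise only: compare predictions within a tight envelope
  expect_gt(cor(p1, p2), 0.999)
  expect_lt(max(abs(p1 - p2)), 0.05 * sd(y))
  # the direct solver is exactly invariant
  expect_equal(gblup_direct(y, M)$fitted, gblup_direct(y, M[, perm])$fitted,
               tolerance = 1e-10)
})

test_that("mcmc settings are validated", {
  expect_error(mcmc_settings(1000, 1000), "burn_in")
  expect_error(mcmc_settings(1000, 100, 0), "thin")
  M <- toy_M(10, 4)
  expect_error(fit_gblup(rnorm(5), M), "length")
  expect_error(fit_gblup(rnorm(10), M, mcmc = list(n_iter = 10)), "mcmc")
})
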