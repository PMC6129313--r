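# Phenotype components: genetic variants, infinitesimal effects,
# trait-covariance construction, correlated and observational noise.

test_that("genetic variant component is the causal-dosage/effect-size product", {
  g <- simulate_genotypes(20, 6, seed = 71)
  snps <- sample_causal_snps(g, 6, theta = 0.5, seed = 72)

  # null effects give the zero matrix
  b0 <- effect_sizes(matrix(0, 3, 2), "normal", c(0, 1), "shared")
  bi <- make_independent_effect_sizes(3, 2, 2, "normal", seed = 1)
  gv <- genetic_variant_component(snps$shared, snps$independent, b0, bi)
  expect_true(all(gv$shared$values == 0))
  expect_equal(gv$independent$values,
               snps$independent$dosages %*% bi$values, ignore_attr = TRUE)

  # 1 SNP, 2 traits, b_s = 2, b_p = (1, -1): trait 2 is the negative of trait 1
  one <- subset_snps(g, 1)
  b <- effect_sizes(outer(2, c(1, -1)), "normal", c(0, 1), "shared")
  gv1 <- genetic_variant_component(one, NULL, b, NULL, P = 2)
  expect_equal(gv1$shared$values[, 2], -gv1$shared$values[, 1])
  expect_equal(gv1$shared$values[, 1], 2 * as.vector(one$dosages),
               ignore_attr = TRUE)
  # empty independent set becomes an explicit zero matrix
  expect_true(all(gv1$independent$values == 0))

  # independent effect on P_ind = 1 of 3 traits supports exactly one column
  b3 <- make_independent_effect_sizes(3, 3, 1, "normal", seed = 3)
  gv3 <- genetic_variant_component(NULL, snps$independent, NULL, b3, P = 3)
  expect_equal(sum(colSums(gv3$independent$values != 0) > 0), 1)

  expect_error(genetic_variant_component(snps$shared, NULL,
                                         effect_sizes(matrix(1, 5, 2), "normal",
                                                      c(0, 1), "shared"),
                                         NULL, P = 2),
               "effect-size rows")
})

test_that("covariate component multiplies the gamma-partitioned covariates", {
  specs <- rep(list(list(dist = "normal")), 3)
  cv <- simulate_covariates(50, specs, gamma = 1, seed = 81)
  a <- make_shared_effect_sizes(3, 2, "normal", seed = 82)
  comp <- covariate_component(cv, a, NULL)
  expect_equal(comp$shared$values, cv$values %*% a$values, ignore_attr = TRUE)
  # gamma = 1: independent part is an N x P zero matrix
  expect_equal(comp$independent$values, matrix(0, 50, 2), ignore_attr = TRUE)

  # a single shared covariate with rank-one effects gives perfectly
  # correlated component columns
  cv1 <- simulate_covariates(100, list(list(dist = "normal")), gamma = 1,
                             seed = 83)
  a1 <- make_shared_effect_sizes(1, 2, "normal", seed = 84)
  c1 <- covariate_component(cv1, a1, NULL)
  expect_lt(max_corr_dev(c1$shared$values), 1e-12)
})

test_that("kinship factorization reconstructs K, including rank-deficient cases", {
  # K = I: any orthogonal factor is valid, so test B B^T
  k_i <- kinship(diag(4))
  b <- kinship_factor(k_i)
  expect_equal(tcrossprod(b), diag(4), tolerance = 1e-12, ignore_attr = TRUE)

  # rank-one K = J/2 for N = 2: single-column factor
  k_j <- kinship(matrix(0.5, 2, 2))
  bj <- kinship_factor(k_j)
  expect_equal(ncol(bj), 1)
  expect_equal(tcrossprod(bj), matrix(0.5, 2, 2), tolerance = 1e-12,
               ignore_attr = TRUE)

  # random PSD K, N = 50: relative Frobenius reconstruction error < 1e-8
  set.seed(91)
  m <- random_psd(50)
  m <- m / mean(diag(m))
  k <- kinship(m)
  bf <- kinship_factor(k)
  expect_lt(norm(tcrossprod(bf) - m, "F") / norm(m, "F"), 1e-8)

  # an eigenvalue below -tolerance is an error naming the eigenvalue
  neg <- diag(c(1, 1, -0.5))
  expect_error(kinship_factor(kinship(neg)), "-5.0*e-0*1|eigenvalue")
})

test_that("infinitesimal effects have the designed trait structure", {
  n <- 500
  b_i <- kinship_factor(kinship(diag(n)))

  u_sh <- infinitesimal_component(b_i, 3, "shared", seed = 101)
  expect_lt(max_corr_dev(u_sh$values), 1e-3)

  b_big <- kinship_factor(kinship(diag(10000)))
  u_ind <- infinitesimal_component(b_big, 2, "independent", seed = 102)
  expect_lt(abs(cor(u_ind$values)[1, 2]), 4 / sqrt(10000))
})

test_that("vec(U) covariance matches the Kronecker product C x K (MC oracle)", {
  set.seed(111)
  n <- 3; p <- 2; reps <- 20000
  g <- simulate_genotypes(n, 40, freq_range = c(0.2, 0.8))
  k <- suppressWarnings(estimate_kinship(g))  # N = 3 leaves some SNPs constant
  bf <- kinship_factor(k)
  a <- matrix(rnorm(p * p), p, p)  # fixed trait factor, C = A A^T
  cmat <- tcrossprod(a)
  draws <- matrix(0, reps, n * p)
  for (r in seq_len(reps)) {
    u <- infinitesimal_component(bf, p, "independent", trait_factor = a)
    draws[r, ] <- as.vector(u$values)
  }
  emp <- crossprod(draws) / reps       # mean is exactly 0 in the model
  expected <- kronecker(cmat, k$matrix)
  big <- abs(expected) > 0.05
  expect_true(any(big))
  expect_lt(max(abs(emp[big] - expected[big]) / abs(expected[big])), 0.05)
})

test_that("exponential-decay trait covariance has entries r^|i-j|", {
  tc <- build_trait_covariance(3, 0.5)
  expect_equal(unname(tc$matrix),
               matrix(c(1, 0.5, 0.25, 0.5, 1, 0.5, 0.25, 0.5, 1), 3, 3))
  expect_equal(unname(build_trait_covariance(4, 0)$matrix), diag(4))
  # log of the d-th off-diagonal is exactly d * log r
  tc7 <- build_trait_covariance(5, 0.7)
  for (d in 1:4)
    expect_equal(log(tc7$matrix[1, 1 + d]), d * log(0.7))
  # positive definite for |r| < 1
  ev <- eigen(build_trait_covariance(6, 0.8)$matrix, only.values = TRUE)$values
  expect_gt(min(ev), 0)
  expect_error(build_trait_covariance(3, 1), "below 1")
  expect_error(trait_covariance(matrix(c(1, 2, 3, 4), 2, 2)), "symmetric")
})

test_that("correlated noise reproduces the target trait covariance", {
  # C = I: off-diagonal correlations vanish at the null rate
  t_i <- correlated_noise_component(10000, trait_covariance(diag(3)),
                                    seed = 121)
  cc <- cor(t_i$values)
  expect_lt(max(abs(cc[upper.tri(cc)])), 4 / sqrt(10000))

  # exponential decay r = 0.7: adjacent-trait correlation within 0.02
  t_r <- correlated_noise_component(50000, build_trait_covariance(4, 0.7),
                                    seed = 122)
  cr <- cor(t_r$values)
  expect_lt(max(abs(cr[cbind(1:3, 2:4)] - 0.7)), 0.02)

  # univariate reduction: column variance within 3 SE of C[1,1]
  t_1 <- correlated_noise_component(10000, trait_covariance(matrix(2)),
                                    seed = 123)
  se_var <- sqrt(2 * 4 / 10000)  # var of sample variance of N(0, 2)
  expect_lt(abs(var(t_1$values[, 1]) - 2), 3 * se_var)
})

test_that("correlated noise sampler agrees with an independent MVN sampler", {
  skip_if_not_installed("MASS")
  cmat <- build_trait_covariance(3, 0.6)$matrix
  ours <- correlated_noise_component(20000, trait_covariance(cmat), seed = 124)
  set.seed(124)
  ref <- MASS::mvrnorm(20000, mu = rep(0, 3), Sigma = cmat)
  expect_lt(max(abs(cov(ours$values) - cov(ref))), 0.05)
})

test_that("observational noise designs control the trait correlation", {
  psi_sh <- observational_noise_component(500, 3, "shared", seed = 131)
  expect_lt(max_corr_dev(psi_sh$values), 1e-3)

  psi_ind <- observational_noise_component(10000, 3, "independent", seed = 132)
  ci <- abs(cor(psi_ind$values))
  expect_lt(max(ci[upper.tri(ci)]), 4 / sqrt(10000))

  # P = 1: both designs reduce to a scaled iid normal column
  for (design in c("shared", "independent")) {
    psi <- observational_noise_component(5000, 1, design, seed = 133)
    expect_gt(var(psi$values[, 1]), 0)
    expect_lt(abs(mean(psi$values[, 1])) / sd(psi$values[, 1]),
              4 / sqrt(5000))
  }
})

test_that("component generators are bitwise-deterministic under a fixed seed", {
  bf <- kinship_factor(kinship(diag(20)))
  expect_identical(infinitesimal_component(bf, 3, "shared", seed = 9)$values,
                   infinitesimal_component(bf, 3, "shared", seed = 9)$values)
  expect_identical(
    correlated_noise_component(20, build_trait_covariance(3, 0.5), seed = 9)$values,
    correlated_noise_component(20, build_trait_covariance(3, 0.5), seed = 9)$values)
  expect_identical(observational_noise_component(20, 3, "shared", seed = 9)$values,
                   observational_noise_component(20, 3, "shared", seed = 9)$values)
})
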