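# Biallelic genotype simulation, kinship estimation, causal-SNP sampling.

test_that("simulated dosages follow the binomial(2, f) model", {
  # degenerate frequencies force constant dosages
  g0 <- simulate_genotypes(4, 2, allele_freqs = c(0, 0), seed = 1)
  expect_true(all(g0$dosages == 0))
  g2 <- simulate_genotypes(4, 2, allele_freqs = c(1, 1), seed = 1)
  expect_true(all(g2$dosages == 2))

  # mean 2f: n = 10000, f = 0.2, SE = sqrt(2 * 0.2 * 0.8 / 10000)
  g <- simulate_genotypes(10000, 1, allele_freqs = 0.2, seed = 42)
  se_mean <- sqrt(2 * 0.2 * 0.8 / 10000)
  expect_lt(abs(mean(g$dosages) - 0.4), 3 * se_mean)

  # variance 2f(1-f) at f = 0.5; SE of the sample variance from the fourth
  # central moment of Binomial(2, 0.5): (mu4 - sigma^4)/n = (0.5 - 0.25)/n
  g5 <- simulate_genotypes(10000, 1, allele_freqs = 0.5, seed = 43)
  se_var <- sqrt((0.5 - 0.25) / 10000)
  expect_lt(abs(var(as.vector(g5$dosages)) - 0.5), 3 * se_var)

  expect_true(all(g$dosages %in% c(0, 1, 2)))
  expect_error(simulate_genotypes(0, 5), "positive")
  expect_error(simulate_genotypes(5, 2, allele_freqs = c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("empirical allele frequencies converge to the requested ones", {
  set.seed(11)
  freqs <- c(0.05, 0.2, 0.35, 0.5)
  g <- simulate_genotypes(10000, length(freqs), allele_freqs = freqs)
  emp <- colMeans(g$dosages) / 2
  bound <- 4 * sqrt(freqs * (1 - freqs) / (2 * 10000))
  expect_true(all(abs(emp - freqs) < bound))
  # stored frequency is the requested one
  expect_identical(g$allele_freqs, freqs)
})

test_that("kinship is XX^T normalized to mean diagonal one", {
  # orthonormal rows: XX^T = I, m = 1, K = I
  g <- genotype_data(diag(2))
  k <- estimate_kinship(g, standardize = FALSE)
  expect_equal(unname(k$matrix), diag(2), tolerance = 1e-12)
  expect_equal(k$normalizer_m, 1)

  # identical sample rows give off-diagonal entries equal to the diagonals
  x <- rbind(c(0, 1, 2, 1), c(0, 1, 2, 1), c(2, 0, 1, 0))
  kd <- estimate_kinship(genotype_data(x), standardize = FALSE)
  expect_equal(kd$matrix[1, 2], kd$matrix[1, 1])
  expect_equal(kd$matrix[1, 2], kd$matrix[2, 2])
})

test_that("kinship invariants hold for random panels in both modes", {
  set.seed(21)
  for (i in 1:20) {
    n <- sample(5:30, 1)
    s <- sample(20:60, 1)
    g <- simulate_genotypes(n, s, freq_range = c(0.1, 0.9))
    for (std in c(TRUE, FALSE)) {
      k <- suppressWarnings(estimate_kinship(g, standardize = std))
      expect_lt(max(abs(k$matrix - t(k$matrix))), 1e-10)
      expect_lt(abs(mean(diag(k$matrix)) - 1), 1e-10)
      ev <- eigen(k$matrix, symmetric = TRUE, only.values = TRUE)$values
      expect_gt(min(ev), -1e-8)
    }
  }
})

test_that("degenerate genotype matrices are rejected or repaired", {
  # zero-variance SNPs are dropped with a warning in standardized mode
  x <- cbind(c(1, 1, 1, 1), c(0, 1, 2, 1), c(2, 0, 1, 2))
  expect_warning(k <- estimate_kinship(genotype_data(x)), "zero-variance")
  expect_lt(abs(mean(diag(k$matrix)) - 1), 1e-10)
  # all-constant matrix cannot be normalized
  expect_error(estimate_kinship(genotype_data(matrix(0, 3, 2)),
                                standardize = FALSE), "constant")
  expect_error(suppressWarnings(
    estimate_kinship(genotype_data(matrix(1, 3, 2)), standardize = TRUE)),
    "nonzero variance")
})

test_that("causal SNP sampling splits by theta with half-up rounding", {
  g <- simulate_genotypes(20, 10, seed = 5)
  all_shared <- sample_causal_snps(g, 10, theta = 1, seed = 9)
  expect_equal(ncol(all_shared$shared$dosages), 10)
  expect_null(all_shared$independent)

  split <- sample_causal_snps(g, 10, theta = 0.6, seed = 9)
  expect_equal(ncol(split$shared$dosages), 6)
  expect_equal(ncol(split$independent$dosages), 4)
  expect_length(intersect(split$shared$snp_ids, split$independent$snp_ids), 0)

  # half-away-from-zero rounding: 0.25 * 10 = 2.5 -> 3 shared
  q <- sample_causal_snps(g, 10, theta = 0.25, seed = 2)
  expect_equal(ncol(q$shared$dosages), 3)

  # determinism under a fixed seed
  a <- sample_causal_snps(g, 5, theta = 0.6, seed = 123)
  b <- sample_causal_snps(g, 5, theta = 0.6, seed = 123)
  expect_identical(a$shared$snp_ids, b$shared$snp_ids)
  expect_identical(a$independent$snp_ids, b$independent$snp_ids)

  expect_error(sample_causal_snps(g, 11, theta = 0.5), "available")
})
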