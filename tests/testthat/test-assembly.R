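# Variance-budget scaling and phenotype assembly.

test_that("the variance scale factor is a = x / Vbar_col and scaling is exact", {
  # component with mean column variance exactly 2.0
  vals <- cbind(c(-1, 1, -1, 1) * sqrt(2) / sqrt(4 / 3),
                c(-1, 1, 1, -1) * sqrt(2) / sqrt(4 / 3))
  comp <- pheno_component(vals, "observational_noise", "whole")
  expect_equal(mean(apply(vals, 2, var)), 2.0)
  sc <- scale_component(comp, 0.4)
  expect_equal(sc$scale_factor, 0.2)
  expect_equal(mean(apply(sc$component$values, 2, var)), 0.4, tolerance = 1e-12)

  # fixed point: Vbar_col already equals x
  set.seed(141)
  m <- matrix(rnorm(300), 100, 3)
  v <- mean(apply(m, 2, var))
  fix <- pheno_component(m, "correlated_noise", "whole")
  sc_fix <- scale_component(fix, v)
  expect_equal(sc_fix$scale_factor, 1)
  expect_identical(sc_fix$component$values, m)

  # independent recomputation at x = 0.25
  sc25 <- scale_component(fix, 0.25)
  expect_lt(abs(mean(apply(sc25$component$values, 2, var)) - 0.25), 1e-12)

  # x = 0 returns the zero matrix; constant components cannot be scaled up
  expect_true(all(scale_component(fix, 0)$component$values == 0))
  const <- pheno_component(matrix(5, 10, 2), "covariates", "shared")
  expect_error(scale_component(const, 0.1), "zero average column variance")
  expect_identical(scale_component(const, 0)$scale_factor, 0)
})

test_that("scaling is exact for arbitrary components and targets (property)", {
  set.seed(142)
  for (i in 1:25) {
    n <- sample(10:80, 1); p <- sample(1:6, 1)
    m <- matrix(rnorm(n * p, sd = runif(1, 0.1, 10)), n, p) + runif(1, -5, 5)
    x <- runif(1, 0.01, 1)
    sc <- scale_component(pheno_component(m, "correlated_noise", "whole"), x)
    expect_lt(abs(mean(apply(sc$component$values, 2, var)) - x), 1e-10)
  }
})

test_that("variance budgets are validated without silent renormalization", {
  expect_error(variance_budget(observational_noise = 0.9),
               "sum to 1.*0.9")
  expect_error(variance_budget(observational_noise = -0.2,
                               correlated_noise = 1.2), "non-negative")
  expect_error(variance_budget(junk = 1), "unknown component role")
  expect_error(variance_budget(), "at least one")
  b <- variance_budget(genetic_variant = c(shared = 0.3, independent = 0.1),
                       observational_noise = 0.6)
  expect_equal(sum(b$x), 1)
  expect_setequal(b$part, c("shared", "independent", "whole"))
})

test_that("assembly sums the scaled components exactly", {
  set.seed(143)
  comps <- list(
    pheno_component(matrix(rnorm(300), 100, 3), "correlated_noise", "whole"),
    pheno_component(matrix(rnorm(300, sd = 3), 100, 3),
                    "observational_noise", "shared"),
    pheno_component(matrix(rnorm(300, sd = 0.2), 100, 3),
                    "observational_noise", "independent"))
  budget <- variance_budget(correlated_noise = 0.3,
                            observational_noise = c(shared = 0.5,
                                                    independent = 0.2))
  res <- assemble_phenotype(comps, budget)
  # additivity is exact at double precision
  recomposed <- Reduce(`+`, lapply(res$components, `[[`, "values"))
  expect_identical(unname(res$Y), unname(recomposed))
  # per-component realized shares equal the budget exactly
  rep <- variance_report(res)
  shares <- rep$table$mean_variance[match(names(res$components),
                                          rep$table$component)]
  expect_equal(shares, c(0.3, 0.5, 0.2), tolerance = 1e-10)
  # budget conservation: shares sum to 1 by construction
  expect_lt(abs(sum(shares) - 1), 1e-10)
})

test_that("a single full-budget component passes through with unit variance", {
  set.seed(144)
  comp <- pheno_component(matrix(rnorm(200), 100, 2), "observational_noise",
                          "whole")
  res <- assemble_phenotype(list(comp), variance_budget(observational_noise = 1))
  expect_lt(abs(mean(apply(res$Y, 2, var)) - 1), 1e-10)
})

test_that("independent noise components add their variances in Y", {
  set.seed(145)
  comps <- list(
    pheno_component(matrix(rnorm(20000), 10000, 2), "correlated_noise", "whole"),
    pheno_component(matrix(rnorm(20000), 10000, 2), "observational_noise",
                    "whole"))
  res <- assemble_phenotype(comps, variance_budget(correlated_noise = 0.5,
                                                   observational_noise = 0.5))
  # cross-covariance is O(1/sqrt(N)), so total variance is 1 within 3%
  expect_lt(abs(mean(apply(res$Y, 2, var)) - 1), 0.03)
})

test_that("budget/component mismatches are rejected", {
  comp <- pheno_component(matrix(rnorm(20), 10, 2), "correlated_noise", "whole")
  expect_error(assemble_phenotype(list(comp),
                                  variance_budget(observational_noise = 1)),
               "mismatch")
  expect_error(assemble_phenotype(list(comp, comp),
                                  variance_budget(correlated_noise = 1)),
               "duplicate")
})

test_that("the variance report is a pure recomputation and guards degeneracy", {
  res <- run_simulation(case_config(seed = 3), quiet = TRUE)
  r1 <- variance_report(res)
  r2 <- variance_report(res)
  expect_identical(r1, r2)

  # shared-only genetic variant component: |correlation| matrix is all 1
  gcor <- r1$correlations$components[["genetic_variant:shared"]]
  expect_lt(max(abs(abs(gcor) - 1)), 1e-10)

  # the empty independent genetic part is flagged, not NaN-propagated
  tab <- r1$table
  expect_true(tab$degenerate[tab$component == "genetic_variant:independent"])
  zcor <- r1$correlations$components[["genetic_variant:independent"]]
  expect_true(all(is.na(zcor)))
  expect_false(any(is.nan(unlist(r1$table$mean_variance))))
})
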