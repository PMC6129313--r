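# Shared fixtures, built in code.

# A reduced-scale multi-trait simulation configuration: 3 traits, 10 shared
# causal SNPs, 4 covariates (two binary, two normal), infinitesimal,
# correlated and observational noise; total genetic variance 40%, noise
# 60%; split components 80% shared.
case_config <- function(seed = 1, n_samples = 200, n_snps = 100) {
  list(
    n_samples = n_samples, n_traits = 3, seed = seed,
    genotypes = list(source = "simulate", n_snps = n_snps),
    n_causal = 10, theta = 1, gamma = 0.5,
    covariates = list(list(dist = "binomial", prob = 0.5),
                      list(dist = "binomial", prob = 0.3),
                      list(dist = "normal", mean = 0, sd = 1),
                      list(dist = "normal", mean = 50, sd = 5)),
    trait_correlation = list(r = 0.8),
    budget = list(genetic_variant = 0.2, infinitesimal = 0.2,
                  covariates = 0.1, correlated_noise = 0.1,
                  observational_noise = 0.4),
    shared_fraction = list(genetic_variant = 1, infinitesimal = 0.8,
                           covariates = 0.8, observational_noise = 0.8)
  )
}

# random symmetric PSD matrix of size n with given rank
random_psd <- function(n, rank = n) {
  f <- matrix(rnorm(n * rank), n, rank)
  tcrossprod(f) / rank
}

# max |pairwise column Pearson correlation| deviation from 1
max_corr_dev <- function(m) {
  cc <- abs(cor(m))
  max(abs(cc - 1))
}
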