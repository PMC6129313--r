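Package: phenosim
Title: Simulation of Multi-Trait, Multi-Locus Phenotypes for Genetic Association Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates quantitative phenotypes for multiple traits as an
    additive combination of five variance components: genetic variant
    effects, infinitesimal (polygenic) genetic effects, non-genetic
    covariate effects, correlated non-genetic effects and observational
    noise. Each component can be split into a part shared across all
    traits and a part acting independently on a trait subset, and is
    rescaled so that its average column variance matches a user-specified
    share of the total phenotypic variance. Includes a simple biallelic
    genotype simulator, genetic relationship matrix estimation, import of
    genotypes from PLINK text, Oxford gen/sample, BIMBAM mean-genotype and
    generic delimited formats, and export of phenotypes, genotypes,
    covariates and kinship in formats consumed by standard association
    tools (PLINK, GEMMA, SNPTEST, BIMBAM).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
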