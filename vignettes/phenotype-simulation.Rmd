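---
title: "Simulating multi-trait, multi-locus phenotypes with phenosim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating multi-trait, multi-locus phenotypes with phenosim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenosim)
```

## The model

phenosim generates an $N \times P$ phenotype matrix $Y$ ($N$ samples, $P$
traits) as an additive combination of five variance components:

$$
Y = X^{s}B^{s} + X^{i}B^{i}
  + W^{s}A^{s} + W^{i}A^{i}
  + U^{s} + U^{i}
  + T
  + \Psi^{s} + \Psi^{i},
$$

where the superscripts mark the *shared* ($s$) and *independent* ($i$)
parts of each component:

* **Genetic variant effects** $XB$ — fixed effects of causal SNPs drawn
  from the genotype panel. Of the causal SNPs, a fraction $\theta$ acts on
  all traits with proportionally identical (pleiotropic) effects; the rest
  act on a random subset of $P_{\mathrm{ind}}$ traits with unrelated
  effect sizes.
* **Infinitesimal genetic effects** $U$ — the polygenic background. Its
  vectorization follows a matrix-variate normal with separable covariance
  $C \otimes K$: $K$ is the genetic relationship matrix over samples, $C$
  the trait covariance.
* **Non-genetic covariate effects** $WA$ — fixed effects of $K_{\mathrm{cov}}$
  covariates with user-chosen marginal distributions (normal, uniform,
  binomial, categorical), a fraction $\gamma$ of which is shared across
  traits.
* **Correlated non-genetic effects** $T$ — rows iid $N(0, C)$ for a trait
  covariance $C$ that is either user-supplied or the exponential-decay
  structure $C_{ij} = r^{|i-j|}$ (a simple model for spatially ordered
  traits such as image-derived phenotypes).
* **Observational noise** $\Psi$ — measurement error, again split into a
  shared (perfectly trait-correlated) and an independent part.

Every (sub)component is rescaled before summation so that its *average
column variance* $\bar V_{\mathrm{col}} = \tfrac1P\sum_p V_p$ equals a
user-specified share $x$ of the total phenotypic variance. The scale
factor is

$$ a = x \, \bar V_{\mathrm{col}}^{-1}, $$

and matrix entries are multiplied by $\sqrt a$. We interpret $a$ as a
*variance* scale factor deliberately: multiplying entries by $a$ itself
would give variance $a^2\bar V$, which contradicts the goal that the
component "explains a share $x$" of the variance. With the $\sqrt a$
convention the realized mean column variance of every scaled component
equals its budget entry to within $10^{-10}$, and the per-component shares
sum to 1 exactly. Note that the *total* empirical variance of $Y$ equals 1
only in expectation: components are scaled individually and their
finite-sample cross-covariances are $O(1/\sqrt N)$.

## Genotypes and kinship

The built-in genotype simulator draws each SNP independently as
$\mathrm{Binomial}(2, f_j)$ hard-call dosages under Hardy–Weinberg
equilibrium, with per-SNP allele frequencies either given or drawn
uniformly from a range (default $[0.05, 0.5]$, a typical GWAS minor
allele frequency spectrum). This model has **no linkage disequilibrium**;
realistic LD requires importing genotypes from a coalescent, forward-time
or resampling simulator, which is why `read_genotypes()` supports PLINK
text, Oxford gen/sample, BIMBAM mean-genotype and generic delimited
dosage tables.

The genetic relationship matrix is estimated as
$K = \tfrac1m XX^{\mathsf T}$ with $m$ the mean diagonal of
$XX^{\mathsf T}$, so that $K$ always has mean diagonal exactly 1. By
default SNP columns are centred and scaled first — standard GRM practice
that removes allele-frequency weighting — and a raw-dosage mode is
available (`standardize = FALSE`) because the normalization alone already
guarantees the mean-diagonal invariant. Zero-variance SNPs cannot be
scaled and are dropped with a warning in standardized mode.

## Sampling $U$ with Kronecker covariance

Rather than factor the full $NP \times NP$ covariance $C \otimes K$, the
infinitesimal component is drawn as

$$ U = B Z A^{\mathsf T}, \qquad K = BB^{\mathsf T},\; C = AA^{\mathsf T}, $$

with $Z$ an $M \times L$ iid standard normal matrix. Then
$\mathrm{vec}(U) = (A \otimes B)\,\mathrm{vec}(Z)$ has covariance
$(AA^{\mathsf T}) \otimes (BB^{\mathsf T}) = C \otimes K$, at
$O(N M L)$ cost. The factor $B$ comes from a symmetric eigendecomposition
with eigenvalues clipped at $\lambda_{\max}\cdot 10^{-12}$ and small
negative eigenvalues (above $-10^{-8}$) zeroed; we avoid Cholesky so
rank-deficient kinship matrices (e.g. duplicated samples, $M < N$) are
supported. The test suite verifies the Kronecker identity by brute force:
20 000 Monte-Carlo draws at $N = 3$, $P = 2$ reproduce every entry of
$C \otimes K$ larger than 0.05 within 5% relative error.

The trait factor $A$ encodes the design: a column-rank-one $A$ (one
latent column drives all traits) gives the shared design with pairwise
trait correlations of $\pm 1$; a diagonal $A$ gives the independent
design with traits conditionally independent given $K$. The defaults are
$M = \mathrm{rank}(K)$ and $L = P$.

## Effect-size laws

Shared effect sizes are the rank-one outer product $B = b_s b_p^{\mathsf T}$,
which makes any two columns perfectly correlated — a SNP's effect is
proportionally the same on every trait. Under the **normal** law (the
default), $b_s \sim N(\mu, \sigma^2)$ with user parameters (default
$\mu = 0, \sigma = 1$) and $b_p \sim N(0, 1)$.

Under the **uniform** law, $b_s$ and $b_p$ are drawn from exponential
distributions and the entries of $-\log(b_s b_p^{\mathsf T})$ are min–max
normalized onto the requested range. Because
$-\log(s_i p_j) = -\log s_i - \log p_j$, the columns of this matrix differ
only by additive constants, so the exact $\pm 1$ column-correlation
property is preserved under the affine normalization. The price is that
the entries are only loosely "uniform": the construction guarantees exact
coverage of $[\mathrm{min}, \mathrm{max}]$ but the mass is bell-shaped
(a normalized sum of two Gumbel-type variables), and no affine map can
make it flat, while any distribution-flattening transform would destroy
the exact correlation structure. We therefore treat range coverage and
the correlation property as the contract of the shared uniform law.
*Independent* effect sizes have no cross-column constraint, so there the
uniform law uses exact iid $\mathrm{Uniform}(\mathrm{min}, \mathrm{max})$
draws (verified by a Kolmogorov–Smirnov test at $n = 10^4$), and the
normal law iid $N(\mu, \sigma^2)$. For the independent design,
$P - P_{\mathrm{ind}}$ traits are selected once (a single draw applied to
all predictor rows, so the affected-trait set is a property of the
component) and zeroed; a per-row masking variant is available behind
`per_row = TRUE`.

Categorical covariates enter the effect product as integer level codes
$0, \dots, L-1$, keeping one column per covariate; one-hot encoding is a
reasonable alternative we did not make the default because it changes the
covariate count that $\gamma$ partitions.

## Parameters that matter

| Parameter | Meaning | Default |
|---|---|---|
| `n_samples`, `n_traits` | $N$, $P$ | required |
| `genotypes$n_snps` | SNPs in the simulated panel | required (simulate) |
| `n_causal` | causal SNPs drawn without replacement | required if variant effects budgeted |
| `theta` | fraction of causal SNPs with shared effects | 1 |
| `P_ind` | traits hit by each independent effect | `n_traits` |
| `gamma` | fraction of covariates shared across traits | 1 |
| `trait_correlation$r` | adjacent-trait correlation of $C$, $|r|<1$ | — |
| `budget` | per-component variance shares, must sum to 1 | required |
| `shared_fraction` | per-component shared sub-budget $s$ | `theta` / `gamma` / 0.5 |
| `seed` | RNG seed for the whole pipeline | none |

Counts derived from fractions (`round(theta * n_causal)`,
`round(gamma * K)`) round half away from zero so they are reproducible
across platforms (base R's `round()` rounds half to even). The shared
covariate set is the *first* $\mathrm{round}(\gamma K)$ columns — a
deterministic, documented choice; reorder the specs to change it. A split
component's budget entry $x$ is divided into $x\,s$ (shared) and
$x(1-s)$ (independent); empty subparts (e.g. $\theta = 1$ leaves no
independent causal SNPs) are carried as explicit zero matrices with a
zero sub-budget so that assembly is uniform. The budget must sum to 1
within $10^{-6}$; there is no silent renormalization because a wrong sum
almost always indicates a configuration bug. Components are not
re-centred before scaling — the variance, not the second moment, is
scaled, so covariates keep their means.

## A worked configuration

The example used throughout the tests and in `scripts/acceptance.R` is a
reduced-scale multi-trait study: $N = 200$ samples, a 100-SNP simulated
panel, $P = 3$ traits, 10 causal SNPs with shared effects only
($\theta = 1$), four covariates (two binary, two normal), infinitesimal,
correlated-noise ($r = 0.8$) and observational-noise components. The
total genetic variance is 40% — split evenly between variant and
infinitesimal effects, a choice we fixed once since only their sum is
constrained by the design — and the non-genetic 60% is split 10/10/40
between covariates, correlated noise and observational noise. All split
components carry 80% of their variance in the shared part. These problem
sizes keep a full run below ten seconds while leaving every realized
share identifiable in the variance report.

```{r example, eval = FALSE}
cfg <- list(
  n_samples = 200, n_traits = 3, seed = 1,
  genotypes = list(source = "simulate", n_snps = 100),
  n_causal = 10, theta = 1, gamma = 0.5,
  covariates = list(list(dist = "binomial", prob = 0.5),
                    list(dist = "binomial", prob = 0.3),
                    list(dist = "normal", mean = 0, sd = 1),
                    list(dist = "normal", mean = 50, sd = 5)),
  trait_correlation = list(r = 0.8),
  budget = list(genetic_variant = 0.2, infinitesimal = 0.2, covariates = 0.1,
                correlated_noise = 0.1, observational_noise = 0.4),
  shared_fraction = list(genetic_variant = 1, infinitesimal = 0.8,
                         covariates = 0.8, observational_noise = 0.8))
res <- run_simulation(cfg, out_dir = "sim_out")
summary(res)
```

## What the generator does and does not emulate

The built-in genotypes reproduce marginal allele-frequency spectra and
Hardy–Weinberg genotype proportions but **no LD, no population
structure beyond what the kinship estimate captures from random
genotypes, and no selection or demography**. Consequently, a passing test
suite demonstrates that the variance decomposition, the covariance
structures and the format plumbing behave as specified — it does not
demonstrate that downstream association methods will behave on real
cohorts, where LD between causal and tagging variants and confounding
structure dominate. For those questions, import genotypes from a
dedicated simulator (HAPGEN2, msprime, simuPOP, ...) and let phenosim
supply the phenotype layer on top.

Other known limitations, shared with the additive model itself: no
epistatic (SNP-by-SNP) or gene–environment interaction effects, no
dominance coding (additive dosage only), and phenotypes that are by
construction well described by a linear mixed model — benchmarks built on
this simulator will flatter LMM-family methods.

## Numerical and degenerate-input choices

* Sample variances use the $n-1$ denominator everywhere, including the
  scaling step and all checks.
* A component with zero average column variance cannot be scaled to a
  positive target and raises an error; a zero target returns the zero
  matrix with scale factor 0.
* User-supplied trait covariances are validated for symmetry
  ($10^{-8}$) and positive semi-definiteness; eigenvalues in
  $(-10^{-8}\lambda_{\max}, 0)$ are clipped to zero with a warning.
* The variance report flags traits with zero variance as degenerate and
  reports their correlations as `NA` instead of propagating `NaN`.
* All floating-point output uses fixed-notation formatting with a
  configurable number of decimals (default 6) and a locale-independent
  decimal separator, so identical configurations and seeds produce
  byte-identical output bundles.
* PLINK text holds hard calls only; the writer refuses fractional
  dosages (use BIMBAM/Oxford/delimited for imputed data). On import the
  reader counts the lexicographically first observed allele, matching the
  writer's "A"/"B" labels; a SNP observed only as "B" is taken as
  dosage 0 of the unobserved effect allele.
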