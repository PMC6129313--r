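# The five phenotype components.
#
# Each constructor returns an N x P matrix wrapped in a pheno_component
# object tagged with its role (which of the five variance components it is)
# and its part (shared across traits / independent / whole). Components are
# simulated on an arbitrary scale and later rescaled to their variance
# budget during assembly.

COMPONENT_ROLES <- c("genetic_variant", "infinitesimal", "covariates",
                     "correlated_noise", "observational_noise")

#' Construct a phenotype component
#'
#' @param values N x P numeric matrix (one additive term of the phenotype).
#' @param role one of \code{"genetic_variant"}, \code{"infinitesimal"},
#'   \code{"covariates"}, \code{"correlated_noise"},
#'   \code{"observational_noise"}.
#' @param part \code{"shared"}, \code{"independent"} or \code{"whole"}.
#' @return An object of class \code{pheno_component}.
#' @export
pheno_component <- function(values, role, part = "whole") {
  values <- as.matrix(values)
  role <- match.arg(role, COMPONENT_ROLES)
  part <- match.arg(part, c("shared", "independent", "whole"))
  if (any(!is.finite(values))) stop("phenotype component has non-finite entries")
  structure(list(values = values, role = role, part = part),
            class = "pheno_component")
}

#' @export
print.pheno_component <- function(x, ...) {
  cat(sprintf("phenotype component %s (%s): %d x %d, mean column variance %.4g\n",
              x$role, x$part, nrow(x$values), ncol(x$values),
              mean_column_variance(x$values)))
  invisible(x)
}

component_key <- function(component) paste(component$role, component$part, sep = ":")

# mean over traits of the per-trait sample variance (n - 1 denominator)
mean_column_variance <- function(values) {
  mean(apply(values, 2L, stats::var))
}

zero_component <- function(n, p, role, part) {
  pheno_component(matrix(0, n, p), role = role, part = part)
}

#' Genetic variant effect component
#'
#' Computes the shared part as X_shared B_shared and the independent part as
#' X_ind B_ind, where the X are causal-SNP dosage matrices (see
#' \code{\link{sample_causal_snps}}) and the B are effect-size matrices.
#' Either SNP set may be \code{NULL} (e.g. theta = 1 leaves no independent
#' causal SNPs), in which case the corresponding part is an explicit zero
#' matrix so that phenotype assembly stays uniform.
#'
#' @param shared_snps \code{genotype_data} of shared causal SNPs, or NULL.
#' @param ind_snps \code{genotype_data} of independent causal SNPs, or NULL.
#' @param B_shared shared \code{effect_sizes} (rows = shared SNPs), or NULL.
#' @param B_ind independent \code{effect_sizes} (rows = independent SNPs),
#'   or NULL.
#' @param P number of traits; required only when one of the parts is empty.
#' @return List with \code{pheno_component} elements \code{shared} and
#'   \code{independent}; each carries a \code{predictors} attribute with the
#'   causal SNP identifiers and their effect-size matrix (ground truth for
#'   downstream method evaluation).
#' @export
genetic_variant_component <- function(shared_snps, ind_snps, B_shared, B_ind,
                                      P = NULL) {
  one_part <- function(snps, beta, part) {
    if (is.null(snps)) return(NULL)
    stopifnot(inherits(snps, "genotype_data"), inherits(beta, "effect_sizes"))
    x <- snps$dosages
    if (ncol(x) != nrow(beta$values))
      stop(sprintf("%s part: %d causal SNPs but %d effect-size rows",
                   part, ncol(x), nrow(beta$values)))
    comp <- pheno_component(x %*% beta$values, role = "genetic_variant",
                            part = part)
    attr(comp, "predictors") <- list(ids = snps$snp_ids,
                                     effects = beta$values)
    comp
  }
  shared <- one_part(shared_snps, B_shared, "shared")
  independent <- one_part(ind_snps, B_ind, "independent")
  if (is.null(shared) && is.null(independent))
    stop("at least one causal SNP set is required")
  if (is.null(P))
    P <- ncol(if (is.null(shared)) independent$values else shared$values)
  n <- nrow(if (is.null(shared)) independent$values else shared$values)
  if (is.null(shared)) shared <- zero_component(n, P, "genetic_variant", "shared")
  if (is.null(independent))
    independent <- zero_component(n, P, "genetic_variant", "independent")
  list(shared = shared, independent = independent)
}

#' Non-genetic covariate effect component
#'
#' Computes W_shared A_shared and W_ind A_ind from a simulated covariate set
#' and effect-size matrices built as for the genetic effects. Empty column
#' partitions (gamma at 0 or 1) yield explicit zero matrices.
#'
#' @param covariates a \code{covariate_set}.
#' @param A_shared shared \code{effect_sizes} (rows = shared covariates), or
#'   NULL when there are none.
#' @param A_ind independent \code{effect_sizes}, or NULL.
#' @param P number of traits; required when a part is empty.
#' @return List with \code{pheno_component} elements \code{shared} and
#'   \code{independent}.
#' @export
covariate_component <- function(covariates, A_shared, A_ind, P = NULL) {
  stopifnot(inherits(covariates, "covariate_set"))
  n <- nrow(covariates$values)
  one_part <- function(cols, alpha, part) {
    if (length(cols) == 0L) return(NULL)
    if (is.null(alpha)) stop(sprintf("%s covariates present but no effect sizes given", part))
    stopifnot(inherits(alpha, "effect_sizes"))
    w <- covariates$values[, cols, drop = FALSE]
    if (ncol(w) != nrow(alpha$values))
      stop(sprintf("%s part: %d covariates but %d effect-size rows",
                   part, ncol(w), nrow(alpha$values)))
    pheno_component(w %*% alpha$values, role = "covariates", part = part)
  }
  shared <- one_part(covariates$shared_cols, A_shared, "shared")
  independent <- one_part(covariates$independent_cols, A_ind, "independent")
  if (is.null(P)) {
    P <- ncol(if (is.null(shared)) independent$values else shared$values)
  }
  if (is.null(shared)) shared <- zero_component(n, P, "covariates", "shared")
  if (is.null(independent))
    independent <- zero_component(n, P, "covariates", "independent")
  list(shared = shared, independent = independent)
}

# Factor a symmetric PSD matrix as F F^T via symmetric eigendecomposition.
# Eigenvalues below max(lambda) * 1e-12 are dropped (rank truncation), small
# negatives within tolerance are zeroed, larger negatives are an error.
factor_psd <- function(mat, tolerance = 1e-8, label = "matrix") {
  eig <- eigen((mat + t(mat)) / 2, symmetric = TRUE)
  lam <- eig$values
  lam_max <- max(lam, 0)
  if (any(lam < -tolerance))
    stop(sprintf("%s is not positive semi-definite: eigenvalue %.3e below -%g",
                 label, min(lam), tolerance))
  lam[lam < 0] <- 0
  keep <- lam > lam_max * 1e-12
  if (!any(keep)) stop(sprintf("%s has numerical rank 0", label))
  eig$vectors[, keep, drop = FALSE] %*%
    diag(sqrt(lam[keep]), nrow = sum(keep))
}

#' Factor a kinship matrix as K = B B^T
#'
#' Symmetric eigendecomposition with rank truncation: eigenvalues below
#' max(lambda) * 1e-12 are dropped and small negative eigenvalues within the
#' tolerance are zeroed, so rank-deficient kinship matrices are supported
#' (a Cholesky factor would not be). An eigenvalue below \code{-tolerance}
#' raises an error reporting its value.
#'
#' @param kin a \code{kinship} object.
#' @param tolerance largest admissible magnitude for negative eigenvalues.
#' @return An N x M matrix B with B B^T = K (M = numerical rank of K).
#' @export
kinship_factor <- function(kin, tolerance = 1e-8) {
  stopifnot(inherits(kin, "kinship"))
  factor_psd(kin$matrix, tolerance = tolerance, label = "kinship matrix")
}

#' Infinitesimal genetic effect component
#'
#' Simulates the polygenic background U whose vectorization follows a
#' matrix-variate normal with sample covariance K (relatedness) and trait
#' covariance C = A A^T, realized as U = B Z A^T with K = B B^T and Z an
#' iid standard normal M x L matrix (L = P). The shared design uses a
#' column-rank-one A (one latent trait column drives all traits, giving
#' pairwise trait correlation of magnitude 1); the independent design uses
#' a diagonal A with standard normal entries (traits conditionally
#' independent given the relatedness structure).
#'
#' @param kin_factor N x M factor of the kinship matrix from
#'   \code{\link{kinship_factor}}.
#' @param P number of traits.
#' @param design \code{"shared"} or \code{"independent"}.
#' @param trait_factor optional fixed P x L trait-covariance factor A; when
#'   given, only Z is redrawn, so repeated calls sample from the
#'   matrix-variate normal with fixed C = A A^T (useful for checking the
#'   realized covariance against C \%x\% K).
#' @param seed optional integer seed.
#' @return A \code{pheno_component} with role \code{"infinitesimal"}; the
#'   realized trait-covariance factor A is attached as attribute
#'   \code{"trait_factor"}.
#' @export
infinitesimal_component <- function(kin_factor, P, design = c("shared", "independent"),
                                    trait_factor = NULL, seed = NULL) {
  design <- match.arg(design)
  if (!is.null(seed)) set.seed(seed)
  stopifnot(is.matrix(kin_factor), P >= 1)
  m <- ncol(kin_factor)
  l <- if (is.null(trait_factor)) P else ncol(trait_factor)
  z <- matrix(stats::rnorm(m * l), m, l)
  if (!is.null(trait_factor)) {
    stopifnot(nrow(trait_factor) == P)
    a <- trait_factor
  } else {
    a <- matrix(0, P, l)
    if (design == "shared") {
      a[, 1L] <- stats::rnorm(P)
    } else {
      diag(a) <- stats::rnorm(P)
    }
  }
  u <- kin_factor %*% z %*% t(a)
  comp <- pheno_component(u, role = "infinitesimal", part = design)
  attr(comp, "trait_factor") <- a
  comp
}

#' Construct a trait-correlation matrix object
#'
#' @param matrix P x P symmetric PSD matrix.
#' @param origin provenance label.
#' @return An object of class \code{trait_covariance}.
#' @export
trait_covariance <- function(matrix, origin = "user_supplied") {
  matrix <- as.matrix(matrix)
  if (nrow(matrix) != ncol(matrix)) stop("trait covariance must be square")
  if (max(abs(matrix - t(matrix))) > 1e-8)
    stop("trait covariance must be symmetric (tolerance 1e-8)")
  eig <- eigen((matrix + t(matrix)) / 2, symmetric = TRUE, only.values = TRUE)$values
  lam_max <- max(abs(eig))
  if (min(eig) < -1e-8 * max(lam_max, 1))
    stop(sprintf("trait covariance is not positive semi-definite (eigenvalue %.3e)",
                 min(eig)))
  if (min(eig) < 0) {
    warning("clipping small negative eigenvalues of the trait covariance to zero")
    e <- eigen((matrix + t(matrix)) / 2, symmetric = TRUE)
    lam <- pmax(e$values, 0)
    matrix <- e$vectors %*% diag(lam, nrow = length(lam)) %*% t(e$vectors)
    matrix <- (matrix + t(matrix)) / 2
  }
  structure(list(matrix = matrix, origin = origin), class = "trait_covariance")
}

#' @export
print.trait_covariance <- function(x, ...) {
  cat(sprintf("trait covariance: %d x %d (%s)\n",
              nrow(x$matrix), ncol(x$matrix), x$origin))
  invisible(x)
}

#' Exponential-decay trait correlation
#'
#' Builds the P x P matrix with entry (i, j) = r^|i - j|: adjacent traits
#' have correlation r, traits at distance d have correlation r^d, a simple
#' approximation for spatially ordered phenotypes (e.g. image-derived
#' traits). This Kac-Murdock-Szego structure is positive definite for
#' |r| < 1.
#'
#' @param P number of traits.
#' @param r correlation of adjacent traits, |r| < 1.
#' @return A \code{trait_covariance} with origin
#'   \code{"exponential_decay"}.
#' @export
build_trait_covariance <- function(P, r) {
  stopifnot(P >= 1)
  if (abs(r) >= 1) stop("|r| must be below 1 for a positive-definite correlation matrix")
  m <- stats::toeplitz(r ^ (0:(P - 1L)))
  trait_covariance(m, origin = "exponential_decay")
}

#' Read a square matrix (kinship or trait covariance) from delimited text
#'
#' @param path file path.
#' @param sep field separator.
#' @param header does the file carry a header row (and matching ID column)?
#' @return A numeric matrix with any IDs applied as dimnames.
#' @export
read_square_matrix <- function(path, sep = ",", header = FALSE) {
  df <- utils::read.table(path, sep = sep, header = header,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (header && !is.numeric(df[[1L]])) {
    ids <- as.character(df[[1L]])
    df <- df[, -1L, drop = FALSE]
    m <- as.matrix(df)
    dimnames(m) <- list(ids, colnames(df))
  } else {
    m <- as.matrix(df)
    dimnames(m) <- NULL
  }
  if (nrow(m) != ncol(m))
    stop(sprintf("matrix in %s is %d x %d, expected square", path, nrow(m), ncol(m)))
  storage.mode(m) <- "double"
  m
}

#' Correlated non-genetic effect component
#'
#' Simulates T with iid rows from N(0, C), where C is the trait covariance
#' (user-supplied or exponential-decay). Sampling goes through the
#' package's PSD factorization so rank-deficient C is supported.
#'
#' @param n_samples number of samples N.
#' @param cov a \code{trait_covariance}.
#' @param seed optional integer seed.
#' @return A \code{pheno_component} with role \code{"correlated_noise"} and
#'   part \code{"whole"}.
#' @export
correlated_noise_component <- function(n_samples, cov, seed = NULL) {
  stopifnot(inherits(cov, "trait_covariance"), n_samples >= 1)
  if (!is.null(seed)) set.seed(seed)
  f <- factor_psd(cov$matrix, label = "trait covariance")
  # f is P x k with f f^T = C, so z f^T has N(0, C) rows even when C is
  # rank deficient
  z <- matrix(stats::rnorm(n_samples * ncol(f)), n_samples, ncol(f))
  pheno_component(z %*% t(f), role = "correlated_noise", part = "whole")
}

#' Observational noise component
#'
#' Simulates measurement noise as B A with B an N x P iid standard normal
#' matrix. The shared design uses a row-rank-one A (first row standard
#' normal, zeros elsewhere), which makes all traits perfectly correlated
#' within this component; the independent design uses a diagonal A with
#' standard normal entries, giving asymptotically uncorrelated traits.
#'
#' @param n_samples number of samples N.
#' @param P number of traits.
#' @param design \code{"shared"} or \code{"independent"}.
#' @param seed optional integer seed.
#' @return A \code{pheno_component} with role \code{"observational_noise"}.
#' @export
observational_noise_component <- function(n_samples, P,
                                          design = c("shared", "independent"),
                                          seed = NULL) {
  design <- match.arg(design)
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n_samples >= 1, P >= 1)
  b <- matrix(stats::rnorm(n_samples * P), n_samples, P)
  a <- matrix(0, P, P)
  if (design == "shared") {
    a[1L, ] <- stats::rnorm(P)
  } else {
    diag(a) <- stats::rnorm(P)
  }
  pheno_component(b %*% a, role = "observational_noise", part = design)
}
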