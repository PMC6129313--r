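# Genotype simulation, kinship estimation and causal-SNP sampling.

#' Construct a genotype panel object
#'
#' Container for an N x S dosage matrix (samples in rows, SNPs in columns)
#' together with sample/SNP identifiers, map positions and per-SNP effect
#' allele frequencies. Dosages count copies of the effect allele and lie in
#' [0, 2]; self-simulated genotypes are hard calls in {0, 1, 2}, imported
#' imputed genotypes may be fractional.
#'
#' @param dosages numeric matrix, N samples x S SNPs, entries in [0, 2].
#' @param sample_ids character vector of length N.
#' @param snp_ids character vector of length S.
#' @param chromosomes chromosome labels (opaque strings), length S.
#' @param positions 1-based base-pair positions, length S.
#' @param allele_freqs effect allele frequencies in [0, 1], length S. If
#'   missing, computed from the dosages as column mean / 2.
#' @return An object of class \code{genotype_data}.
#' @export
genotype_data <- function(dosages, sample_ids = NULL, snp_ids = NULL,
                          chromosomes = NULL, positions = NULL,
                          allele_freqs = NULL) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  n <- nrow(dosages)
  s <- ncol(dosages)
  if (n < 1L || s < 1L)
    stop("genotype panel must have at least one sample and one SNP")
  if (any(!is.finite(dosages)) || any(dosages < 0) || any(dosages > 2))
    stop("dosages must be finite and within [0, 2]")
  if (is.null(sample_ids)) sample_ids <- paste0("ID_", seq_len(n))
  if (is.null(snp_ids)) snp_ids <- paste0("SNP_", seq_len(s))
  if (is.null(chromosomes)) chromosomes <- rep("1", s)
  if (is.null(positions)) positions <- seq_len(s)
  if (is.null(allele_freqs)) allele_freqs <- colMeans(dosages) / 2
  stopifnot(length(sample_ids) == n, length(snp_ids) == s,
            length(chromosomes) == s, length(positions) == s,
            length(allele_freqs) == s)
  if (any(allele_freqs < 0 | allele_freqs > 1))
    stop("allele frequencies must lie in [0, 1]")
  dimnames(dosages) <- list(as.character(sample_ids), as.character(snp_ids))
  structure(list(dosages = dosages,
                 sample_ids = as.character(sample_ids),
                 snp_ids = as.character(snp_ids),
                 chromosomes = as.character(chromosomes),
                 positions = as.integer(positions),
                 allele_freqs = as.numeric(allele_freqs)),
            class = "genotype_data")
}

#' @export
print.genotype_data <- function(x, ...) {
  cat(sprintf("genotype panel: %d samples x %d SNPs\n",
              nrow(x$dosages), ncol(x$dosages)))
  cat(sprintf("  allele frequency range: [%.3f, %.3f]\n",
              min(x$allele_freqs), max(x$allele_freqs)))
  invisible(x)
}

#' @export
dim.genotype_data <- function(x) dim(x$dosages)

#' Subset a genotype panel by SNP columns
#'
#' @param genotypes a \code{genotype_data} object.
#' @param snps integer or character index of SNP columns to keep.
#' @return A \code{genotype_data} object restricted to the selected SNPs.
#' @export
subset_snps <- function(genotypes, snps) {
  stopifnot(inherits(genotypes, "genotype_data"))
  if (is.character(snps)) snps <- match(snps, genotypes$snp_ids)
  if (anyNA(snps)) stop("unknown SNP identifier in subset")
  out <- genotypes
  out$dosages <- genotypes$dosages[, snps, drop = FALSE]
  out$snp_ids <- genotypes$snp_ids[snps]
  out$chromosomes <- genotypes$chromosomes[snps]
  out$positions <- genotypes$positions[snps]
  out$allele_freqs <- genotypes$allele_freqs[snps]
  out
}

#' Simulate unlinked biallelic genotypes
#'
#' Draws each SNP independently from a binomial distribution with two trials
#' and success probability equal to its allele frequency, i.e. hard-call
#' dosages under Hardy-Weinberg equilibrium. SNPs are mutually independent:
#' this simple model carries no linkage disequilibrium. For LD-structured
#' genotypes, import panels produced by an external simulator via
#' \code{\link{read_genotypes}}.
#'
#' @param n_samples number of samples N.
#' @param n_snps number of SNPs S.
#' @param allele_freqs either a vector of S frequencies in (0, 1) (recycled
#'   if scalar), or \code{NULL} to draw per-SNP frequencies uniformly from
#'   \code{freq_range}. Degenerate frequencies 0 and 1 are accepted and give
#'   constant columns.
#' @param freq_range length-2 range from which per-SNP frequencies are drawn
#'   when \code{allele_freqs} is \code{NULL}.
#' @param seed optional integer seed; \code{NULL} uses the current RNG state.
#' @return A \code{genotype_data} object with dosages in \{0, 1, 2\}; the
#'   stored \code{allele_freqs} are the requested (not empirical) ones.
#' @export
simulate_genotypes <- function(n_samples, n_snps, allele_freqs = NULL,
                               freq_range = c(0.05, 0.5), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (length(n_samples) != 1L || n_samples < 1 ||
      length(n_snps) != 1L || n_snps < 1)
    stop("n_samples and n_snps must be positive integers")
  n_samples <- as.integer(n_samples)
  n_snps <- as.integer(n_snps)
  if (is.null(allele_freqs)) {
    stopifnot(length(freq_range) == 2L, freq_range[1] <= freq_range[2])
    allele_freqs <- stats::runif(n_snps, freq_range[1], freq_range[2])
  } else {
    if (length(allele_freqs) == 1L) allele_freqs <- rep(allele_freqs, n_snps)
    if (length(allele_freqs) != n_snps)
      stop("allele_freqs must have length 1 or n_snps")
  }
  if (any(allele_freqs < 0 | allele_freqs > 1))
    stop("allele frequencies must lie in [0, 1]")
  dosages <- matrix(stats::rbinom(n_samples * n_snps, size = 2L,
                                  prob = rep(allele_freqs, each = n_samples)),
                    nrow = n_samples, ncol = n_snps)
  genotype_data(dosages, allele_freqs = allele_freqs)
}

#' Construct a kinship object
#'
#' @param matrix N x N symmetric matrix.
#' @param sample_ids sample identifiers, length N.
#' @param normalizer_m the mean diagonal of XX^T used for normalization.
#' @return An object of class \code{kinship}.
#' @export
kinship <- function(matrix, sample_ids = NULL, normalizer_m = NA_real_) {
  matrix <- as.matrix(matrix)
  n <- nrow(matrix)
  if (n != ncol(matrix)) stop("kinship matrix must be square")
  if (max(abs(matrix - t(matrix))) > 1e-10)
    stop("kinship matrix must be symmetric (tolerance 1e-10)")
  if (is.null(sample_ids)) sample_ids <- paste0("ID_", seq_len(n))
  dimnames(matrix) <- list(sample_ids, sample_ids)
  structure(list(matrix = matrix, sample_ids = as.character(sample_ids),
                 normalizer_m = normalizer_m),
            class = "kinship")
}

#' @export
print.kinship <- function(x, ...) {
  cat(sprintf("kinship matrix: %d x %d, mean diagonal %.6f\n",
              nrow(x$matrix), ncol(x$matrix), mean(diag(x$matrix))))
  invisible(x)
}

#' Estimate the genetic relationship matrix from genotypes
#'
#' Computes K = XX^T / m where m is the mean of the diagonal of XX^T, so
#' that the returned matrix has mean diagonal exactly 1. By default the
#' dosage matrix is column-centred and scaled to unit variance first
#' (standard GRM practice); set \code{standardize = FALSE} to use raw
#' dosages. Zero-variance SNPs carry no relatedness information and cannot
#' be scaled; they are dropped with a warning in standardized mode.
#'
#' @param genotypes a \code{genotype_data} object with at least 2 samples.
#' @param standardize centre and unit-scale SNP columns before the
#'   cross-product (default \code{TRUE}).
#' @return A \code{kinship} object (symmetric, PSD, mean diagonal 1).
#' @export
estimate_kinship <- function(genotypes, standardize = TRUE) {
  stopifnot(inherits(genotypes, "genotype_data"))
  x <- genotypes$dosages
  if (nrow(x) < 2L) stop("kinship estimation requires at least 2 samples")
  if (standardize) {
    v <- apply(x, 2L, stats::var)
    zero <- v <= .Machine$double.eps
    if (any(zero)) {
      warning(sprintf("dropping %d zero-variance SNP(s) before standardized kinship estimation",
                      sum(zero)))
      x <- x[, !zero, drop = FALSE]
      if (ncol(x) == 0L) stop("no SNPs with nonzero variance; cannot estimate kinship")
    }
    x <- scale(x)
  }
  xxt <- tcrossprod(x)
  m <- mean(diag(xxt))
  if (m <= .Machine$double.eps)
    stop("mean diagonal of XX^T is zero (constant genotype matrix); cannot normalize kinship")
  k <- xxt / m
  k <- (k + t(k)) / 2  # enforce exact symmetry against rounding
  kinship(k, sample_ids = genotypes$sample_ids, normalizer_m = m)
}

# round half away from zero, so causal/shared counts are reproducible
# across platforms (base round() rounds half to even)
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Sample causal SNPs and split them into shared and independent sets
#'
#' Selects \code{n_causal} SNPs without replacement, then assigns a
#' proportion \code{theta} of them (rounded half away from zero) to act on
#' all traits (shared) and the remainder to act on a trait subset
#' (independent). The two sets are disjoint by construction.
#'
#' @param genotypes a \code{genotype_data} object.
#' @param n_causal total number of causal SNPs to draw.
#' @param theta fraction of causal SNPs with a shared (pleiotropic) effect,
#'   in [0, 1].
#' @param seed optional integer seed.
#' @return A list with \code{genotype_data} elements \code{shared} and
#'   \code{independent} (either may have zero columns at the theta
#'   boundaries, signalled by a \code{NULL} entry replaced with an empty
#'   panel marker: here, zero-column panels are represented by \code{NULL}).
#' @export
sample_causal_snps <- function(genotypes, n_causal, theta, seed = NULL) {
  stopifnot(inherits(genotypes, "genotype_data"))
  if (!is.null(seed)) set.seed(seed)
  s_avail <- ncol(genotypes$dosages)
  if (n_causal > s_avail)
    stop(sprintf("requested %d causal SNPs but only %d are available",
                 n_causal, s_avail))
  if (theta < 0 || theta > 1) stop("theta must lie in [0, 1]")
  chosen <- sample.int(s_avail, n_causal)
  n_shared <- as.integer(round_half_up(theta * n_causal))
  shared_idx <- chosen[seq_len(n_shared)]
  ind_idx <- setdiff(chosen, shared_idx)
  list(shared = if (n_shared > 0L) subset_snps(genotypes, shared_idx) else NULL,
       independent = if (length(ind_idx) > 0L) subset_snps(genotypes, ind_idx) else NULL)
}
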