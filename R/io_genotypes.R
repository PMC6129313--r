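# Readers and writers for standard genotype text formats.
#
# All formats are normalized to the internal samples x SNPs dosage
# orientation on read, regardless of the on-disk orientation. Dosages count
# copies of the effect allele; writers label the effect allele "A" and the
# other allele "B", and the PLINK reader counts the lexicographically first
# allele so that write -> read round-trips.

GENOTYPE_FORMATS <- c("plink_text", "oxford_gen", "bimbam_mean", "delimited")

fmt_num <- function(x, precision = 6L) {
  formatC(x, format = "f", digits = precision)
}

stop_malformed <- function(format, line, msg) {
  stop(sprintf("malformed %s record at line %d: %s", format, line, msg),
       call. = FALSE)
}

#' Read genotypes from a standard text format
#'
#' Supported dialects: PLINK text (\code{.ped}/\code{.map} pair), Oxford
#' gen/sample (as emitted by HAPGEN2/IMPUTE; genotype probability triples
#' are collapsed to expected dosage p1 + 2 p2), BIMBAM mean-genotype, and
#' generic delimited dosage tables (as emitted by simuPOP, ForSim and
#' similar simulators). Orientation is normalized to samples x SNPs.
#'
#' @param path file path; for \code{plink_text} and \code{oxford_gen} the
#'   prefix shared by the companion files (\code{prefix.ped} +
#'   \code{prefix.map}, \code{prefix.gen} + \code{prefix.sample}).
#' @param format one of \code{"plink_text"}, \code{"oxford_gen"},
#'   \code{"bimbam_mean"}, \code{"delimited"}.
#' @param sep field separator for \code{delimited} (default \code{","}).
#' @param snps_in_rows for \code{delimited}: is the on-disk table SNPs x
#'   samples (default \code{FALSE}, i.e. samples in rows)?
#' @param header for \code{delimited}: first row holds column names.
#' @param id_col for \code{delimited}: first column holds row identifiers.
#' @return A \code{genotype_data} object.
#' @export
read_genotypes <- function(path, format = c("plink_text", "oxford_gen",
                                            "bimbam_mean", "delimited"),
                           sep = ",", snps_in_rows = FALSE, header = TRUE,
                           id_col = TRUE) {
  format <- match.arg(format)
  switch(format,
         plink_text = read_plink_text(path),
         oxford_gen = read_oxford_gen(path),
         bimbam_mean = read_bimbam_mean(path),
         delimited = read_delimited_genotypes(path, sep = sep,
                                              snps_in_rows = snps_in_rows,
                                              header = header,
                                              id_col = id_col))
}

#' Write genotypes to a standard text format
#'
#' @param genotypes a \code{genotype_data} object.
#' @param path output path or prefix (see \code{\link{read_genotypes}}).
#' @param format target dialect.
#' @param precision decimal digits for fractional dosages/probabilities.
#' @inheritParams read_genotypes
#' @return Invisibly, the character vector of files written.
#' @export
write_genotypes <- function(genotypes, path,
                            format = c("plink_text", "oxford_gen",
                                       "bimbam_mean", "delimited"),
                            precision = 6L, sep = ",",
                            snps_in_rows = FALSE, header = TRUE,
                            id_col = TRUE) {
  stopifnot(inherits(genotypes, "genotype_data"))
  format <- match.arg(format)
  files <- switch(format,
                  plink_text = write_plink_text(genotypes, path),
                  oxford_gen = write_oxford_gen(genotypes, path, precision),
                  bimbam_mean = write_bimbam_mean(genotypes, path, precision),
                  delimited = write_delimited_genotypes(genotypes, path,
                                                        precision, sep,
                                                        snps_in_rows, header,
                                                        id_col))
  invisible(files)
}

## ---- PLINK text (.ped/.map) -------------------------------------------

write_plink_text <- function(genotypes, prefix) {
  d <- genotypes$dosages
  if (any(d != round(d)))
    stop("PLINK text format holds hard genotype calls; dosages must be integers in {0, 1, 2}")
  map <- paste(genotypes$chromosomes, genotypes$snp_ids, 0L,
               genotypes$positions, sep = "\t")
  map_file <- paste0(prefix, ".map")
  writeLines(map, map_file)
  # allele pair per dosage: effect allele "A", other "B"
  pair <- c("B B", "A B", "A A")
  geno_str <- matrix(pair[d + 1L], nrow = nrow(d))
  ped <- vapply(seq_len(nrow(d)), function(i) {
    paste(c(genotypes$sample_ids[i], genotypes$sample_ids[i], "0", "0", "0",
            "-9", geno_str[i, ]), collapse = "\t")
  }, character(1))
  ped_file <- paste0(prefix, ".ped")
  writeLines(ped, ped_file)
  c(ped_file, map_file)
}

read_plink_text <- function(prefix) {
  ped_file <- paste0(prefix, ".ped")
  map_file <- paste0(prefix, ".map")
  if (!file.exists(ped_file) || !file.exists(map_file))
    stop(sprintf("PLINK text input requires both %s and %s", ped_file, map_file))
  map_lines <- readLines(map_file)
  map <- lapply(seq_along(map_lines), function(i) {
    f <- strsplit(trimws(map_lines[i]), "[ \t]+")[[1]]
    if (length(f) < 4L)
      stop_malformed("plink_text (.map)", i, "expected 4 fields (chrom, id, cM, position)")
    f
  })
  snp_ids <- vapply(map, `[`, character(1), 2L)
  chroms <- vapply(map, `[`, character(1), 1L)
  positions <- as.integer(vapply(map, `[`, character(1), 4L))
  s <- length(snp_ids)
  ped_lines <- readLines(ped_file)
  n <- length(ped_lines)
  alleles <- matrix(NA_character_, nrow = n, ncol = 2L * s)
  sample_ids <- character(n)
  for (i in seq_len(n)) {
    f <- strsplit(trimws(ped_lines[i]), "[ \t]+")[[1]]
    if (length(f) != 6L + 2L * s)
      stop_malformed("plink_text (.ped)", i,
                     sprintf("expected %d fields, found %d", 6L + 2L * s, length(f)))
    sample_ids[i] <- f[2L]
    alleles[i, ] <- f[-(1:6)]
  }
  if (any(alleles == "0"))
    stop("missing genotype code '0' in .ped file is not supported")
  dosages <- matrix(0, nrow = n, ncol = s)
  for (j in seq_len(s)) {
    a <- alleles[, c(2L * j - 1L, 2L * j), drop = FALSE]
    u <- sort(unique(as.vector(a)))
    if (length(u) == 1L && u == "B") {
      # monomorphic for the conventional non-effect allele label: the
      # effect allele "A" is unobserved, dosage 0 for every sample
      dosages[, j] <- 0
    } else {
      eff <- u[1L]  # lexicographically first observed allele
      dosages[, j] <- rowSums(a == eff)
    }
  }
  genotype_data(dosages, sample_ids = sample_ids, snp_ids = snp_ids,
                chromosomes = chroms, positions = positions)
}

## ---- Oxford gen/sample -------------------------------------------------

# probability triple with the given expected dosage and minimal spread,
# so collapsing back to expected dosage is exact
dosage_to_triple <- function(d) {
  if (d <= 1) c(1 - d, d, 0) else c(0, 2 - d, d - 1)
}

write_oxford_gen <- function(genotypes, prefix, precision = 6L) {
  d <- genotypes$dosages
  n <- nrow(d); s <- ncol(d)
  gen_lines <- vapply(seq_len(s), function(j) {
    probs <- unlist(lapply(d[, j], dosage_to_triple))
    paste(c(genotypes$chromosomes[j], genotypes$snp_ids[j],
            genotypes$snp_ids[j], genotypes$positions[j], "A", "B",
            fmt_num(probs, precision)), collapse = " ")
  }, character(1))
  gen_file <- paste0(prefix, ".gen")
  writeLines(gen_lines, gen_file)
  sample_file <- paste0(prefix, ".sample")
  writeLines(c("ID_1 ID_2 missing", "0 0 0",
               paste(genotypes$sample_ids, genotypes$sample_ids, "0")),
             sample_file)
  c(gen_file, sample_file)
}

read_oxford_gen <- function(prefix) {
  gen_file <- paste0(prefix, ".gen")
  sample_file <- paste0(prefix, ".sample")
  if (!file.exists(gen_file) || !file.exists(sample_file))
    stop(sprintf("Oxford input requires both %s and %s", gen_file, sample_file))
  sample_lines <- readLines(sample_file)
  if (length(sample_lines) < 3L)
    stop("Oxford .sample file must have two header lines and at least one sample")
  sample_ids <- vapply(strsplit(trimws(sample_lines[-(1:2)]), "[ \t]+"),
                       `[`, character(1), 2L)
  n <- length(sample_ids)
  gen_lines <- readLines(gen_file)
  s <- length(gen_lines)
  dosages <- matrix(0, nrow = n, ncol = s)
  snp_ids <- character(s); chroms <- character(s); positions <- integer(s)
  for (j in seq_len(s)) {
    f <- strsplit(trimws(gen_lines[j]), "[ \t]+")[[1]]
    # 6 leading fields (chrom, snp id, rs id, position, alleleA, alleleB)
    # then one probability triple per sample, as emitted by HAPGEN2/IMPUTE
    if (length(f) != 6L + 3L * n)
      stop_malformed("oxford_gen", j,
                     sprintf("expected 6 + 3x%d sample fields, found %d (does .sample match .gen?)",
                             n, length(f)))
    chroms[j] <- f[1L]; snp_ids[j] <- f[3L]
    positions[j] <- as.integer(f[4L])
    p <- matrix(as.numeric(f[-(1:6)]), nrow = 3L)
    if (anyNA(p)) stop_malformed("oxford_gen", j, "non-numeric genotype probability")
    dosages[, j] <- p[2L, ] + 2 * p[3L, ]
  }
  genotype_data(dosages, sample_ids = sample_ids, snp_ids = snp_ids,
                chromosomes = chroms, positions = positions)
}

## ---- BIMBAM mean genotype ----------------------------------------------

write_bimbam_mean <- function(genotypes, path, precision = 6L) {
  d <- genotypes$dosages
  lines <- vapply(seq_len(ncol(d)), function(j) {
    paste(c(genotypes$snp_ids[j], "A", "B", fmt_num(d[, j], precision)),
          collapse = ", ")
  }, character(1))
  writeLines(lines, path)
  # companion SNP location file (rs, pos, chrom)
  pos_file <- paste0(path, ".pos")
  writeLines(paste(genotypes$snp_ids, genotypes$positions,
                   genotypes$chromosomes, sep = ", "), pos_file)
  c(path, pos_file)
}

read_bimbam_mean <- function(path) {
  lines <- readLines(path)
  s <- length(lines)
  fields <- strsplit(lines, "[, \t]+")
  nf <- lengths(fields)
  if (length(unique(nf)) != 1L)
    stop_malformed("bimbam_mean", which(nf != nf[1])[1], "inconsistent field count")
  n <- nf[1] - 3L
  if (n < 1L) stop_malformed("bimbam_mean", 1L, "no dosage columns")
  snp_ids <- vapply(fields, `[`, character(1), 1L)
  dosages <- matrix(0, nrow = n, ncol = s)
  for (j in seq_len(s)) {
    v <- suppressWarnings(as.numeric(fields[[j]][-(1:3)]))
    if (anyNA(v)) stop_malformed("bimbam_mean", j, "non-numeric dosage")
    dosages[, j] <- v
  }
  pos_file <- paste0(path, ".pos")
  chroms <- NULL; positions <- NULL
  if (file.exists(pos_file)) {
    pf <- strsplit(readLines(pos_file), "[, \t]+")
    idx <- match(snp_ids, vapply(pf, `[`, character(1), 1L))
    if (!anyNA(idx)) {
      positions <- as.integer(vapply(pf, `[`, character(1), 2L))[idx]
      chroms <- vapply(pf, `[`, character(1), 3L)[idx]
    }
  }
  genotype_data(dosages, snp_ids = snp_ids, chromosomes = chroms,
                positions = positions)
}

## ---- generic delimited dosage table ------------------------------------

write_delimited_genotypes <- function(genotypes, path, precision = 6L,
                                      sep = ",", snps_in_rows = FALSE,
                                      header = TRUE, id_col = TRUE) {
  d <- genotypes$dosages
  if (snps_in_rows) {
    m <- t(d); row_ids <- genotypes$snp_ids; col_ids <- genotypes$sample_ids
  } else {
    m <- d; row_ids <- genotypes$sample_ids; col_ids <- genotypes$snp_ids
  }
  body <- apply(matrix(fmt_num(m, precision), nrow = nrow(m)), 1L,
                paste, collapse = sep)
  if (id_col) body <- paste(row_ids, body, sep = sep)
  lines <- body
  if (header) {
    head <- paste(col_ids, collapse = sep)
    if (id_col) head <- paste("id", head, sep = sep)
    lines <- c(head, body)
  }
  writeLines(lines, path)
  path
}

read_delimited_genotypes <- function(path, sep = ",", snps_in_rows = FALSE,
                                     header = TRUE, id_col = TRUE) {
  df <- utils::read.table(path, sep = sep, header = header,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "")
  row_ids <- NULL
  if (id_col) {
    row_ids <- as.character(df[[1L]])
    df <- df[, -1L, drop = FALSE]
  }
  m <- as.matrix(df)
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(as.numeric(m))))[1]
    stop_malformed("delimited", (bad - 1L) %% nrow(m) + 1L + as.integer(header),
                   "non-numeric dosage value")
  }
  col_ids <- if (header) colnames(df) else NULL
  if (snps_in_rows) {
    genotype_data(t(m), sample_ids = col_ids, snp_ids = row_ids)
  } else {
    genotype_data(m, sample_ids = row_ids, snp_ids = col_ids)
  }
}
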