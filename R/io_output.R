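# Writers for complete simulation output bundles in the input dialects of
# standard association tools (PLINK, GEMMA, SNPTEST, BIMBAM) plus plain
# CSV. All floating output goes through fixed-notation formatting with a
# configurable number of decimals so that repeated runs are byte-identical.

write_lines_file <- function(lines, path) {
  writeLines(lines, path)
  path
}

#' Write a complete simulation output bundle
#'
#' Emits phenotypes, genotypes, covariates and kinship in each requested
#' format, with identical sample ordering across all files, plus a JSON
#' manifest recording formats, dimensions, seed, variance budget and the
#' written files. Simulated data are complete; no missing-data codes are
#' ever emitted.
#'
#' Formats: \code{gemma} (headerless whitespace phenotype N x P, square
#' kinship, BIMBAM mean genotypes, headerless covariates), \code{snptest}
#' (Oxford .gen plus a .sample file carrying phenotypes typed 'P' and
#' covariates typed 'C'/'D'), \code{plink} (.ped/.map with the alternate
#' phenotype file holding all traits), \code{bimbam} (mean genotypes and a
#' multi-column phenotype file), \code{csv} (everything with header row and
#' sample-ID column).
#'
#' @param result a \code{phenosim_result}.
#' @param genotypes a \code{genotype_data} (full panel).
#' @param covariates a \code{covariate_set} or NULL.
#' @param kinship_obj a \code{kinship} or NULL.
#' @param dir destination directory (created if missing).
#' @param formats subset of \code{c("plink", "bimbam", "gemma", "snptest",
#'   "csv")}.
#' @param precision decimal digits for floating output (default 6).
#' @param seed the simulation seed, recorded in the manifest.
#' @return Invisibly, the character vector of written file paths.
#' @export
write_bundle <- function(result, genotypes, covariates = NULL,
                         kinship_obj = NULL, dir,
                         formats = c("csv"), precision = 6L, seed = NULL) {
  stopifnot(inherits(result, "phenosim_result"),
            inherits(genotypes, "genotype_data"))
  formats <- match.arg(formats, c("plink", "bimbam", "gemma", "snptest", "csv"),
                       several.ok = TRUE)
  if (!identical(result$sample_ids, genotypes$sample_ids))
    stop("sample IDs of phenotypes and genotypes do not match")
  if (!is.null(covariates) && nrow(covariates$values) != nrow(result$Y))
    stop("sample count of covariates does not match phenotypes")
  if (!is.null(kinship_obj) && !identical(kinship_obj$sample_ids, result$sample_ids))
    stop("sample IDs of kinship and phenotypes do not match")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  y <- result$Y
  files <- character(0)

  if ("gemma" %in% formats) {
    files <- c(files, write_lines_file(
      apply(matrix(fmt_num(y, precision), nrow(y)), 1L, paste, collapse = " "),
      file.path(dir, "phenotypes_gemma.txt")))
    if (!is.null(kinship_obj))
      files <- c(files, write_lines_file(
        apply(matrix(fmt_num(kinship_obj$matrix, precision),
                     nrow(kinship_obj$matrix)), 1L, paste, collapse = " "),
        file.path(dir, "kinship_gemma.txt")))
    if (!is.null(covariates))
      files <- c(files, write_lines_file(
        apply(cbind("1", matrix(fmt_num(covariates$values, precision),
                                nrow(covariates$values))),
              1L, paste, collapse = " "),
        file.path(dir, "covariates_gemma.txt")))
    files <- c(files, write_genotypes(genotypes,
                                      file.path(dir, "genotypes_gemma.txt"),
                                      "bimbam_mean", precision = precision))
  }

  if ("bimbam" %in% formats) {
    files <- c(files, write_genotypes(genotypes,
                                      file.path(dir, "genotypes.bimbam"),
                                      "bimbam_mean", precision = precision))
    files <- c(files, write_lines_file(
      apply(matrix(fmt_num(y, precision), nrow(y)), 1L, paste, collapse = " "),
      file.path(dir, "phenotypes.bimbam")))
  }

  if ("plink" %in% formats) {
    files <- c(files, write_genotypes(genotypes, file.path(dir, "genotypes_plink"),
                                      "plink_text"))
    # PLINK's .ped holds a single phenotype column; all traits go to the
    # alternate-phenotype file (FID IID trait1..traitP)
    files <- c(files, write_lines_file(
      paste(result$sample_ids, result$sample_ids,
            apply(matrix(fmt_num(y, precision), nrow(y)), 1L, paste,
                  collapse = "\t"), sep = "\t"),
      file.path(dir, "phenotypes_plink.txt")))
  }

  if ("snptest" %in% formats) {
    gen_files <- write_genotypes(genotypes, file.path(dir, "genotypes_snptest"),
                                 "oxford_gen", precision = precision)
    files <- c(files, gen_files[1L])
    # .sample with phenotype columns typed P and covariates typed C
    # (continuous) or D (discrete)
    cov_vals <- if (is.null(covariates)) NULL else covariates$values
    cov_types <- if (is.null(covariates)) character(0) else
      vapply(covariates$specs, function(sp)
        if (sp$dist %in% c("binomial", "categorical")) "D" else "C", character(1))
    head1 <- paste(c("ID_1", "ID_2", "missing",
                     if (length(cov_types)) colnames(cov_vals),
                     result$trait_ids), collapse = " ")
    head2 <- paste(c("0", "0", "0", cov_types, rep("P", ncol(y))),
                   collapse = " ")
    body <- vapply(seq_len(nrow(y)), function(i) {
      paste(c(result$sample_ids[i], result$sample_ids[i], "0",
              if (!is.null(cov_vals)) fmt_num(cov_vals[i, ], precision),
              fmt_num(y[i, ], precision)), collapse = " ")
    }, character(1))
    files <- c(files, write_lines_file(c(head1, head2, body),
                                       file.path(dir, "genotypes_snptest.sample")))
  }

  if ("csv" %in% formats) {
    write_csv_matrix <- function(m, path, col_ids) {
      lines <- c(paste(c("id", col_ids), collapse = ","),
                 paste(result$sample_ids,
                       apply(matrix(fmt_num(m, precision), nrow(m)), 1L,
                             paste, collapse = ","), sep = ","))
      write_lines_file(lines, path)
    }
    files <- c(files, write_csv_matrix(y, file.path(dir, "phenotypes.csv"),
                                       result$trait_ids))
    files <- c(files, write_genotypes(genotypes, file.path(dir, "genotypes.csv"),
                                      "delimited", precision = precision))
    if (!is.null(covariates))
      files <- c(files, write_csv_matrix(covariates$values,
                                         file.path(dir, "covariates.csv"),
                                         colnames(covariates$values)))
    if (!is.null(kinship_obj))
      files <- c(files, write_csv_matrix(kinship_obj$matrix,
                                         file.path(dir, "kinship.csv"),
                                         kinship_obj$sample_ids))
  }

  manifest <- list(formats = formats,
                   n_samples = nrow(y), n_traits = ncol(y),
                   n_snps = ncol(genotypes$dosages),
                   n_covariates = if (is.null(covariates)) 0L else ncol(covariates$values),
                   seed = seed,
                   precision = precision,
                   budget = as.data.frame(result$budget),
                   scale_factors = as.list(result$scale_factors),
                   files = basename(files))
  manifest_file <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  files <- c(files, manifest_file)
  invisible(files)
}

#' Write per-component ground-truth matrices
#'
#' Saves every scaled component matrix, the applied variance scale factors
#' and the causal-SNP list (identifiers and per-trait effect sizes) so that
#' downstream association methods can be evaluated against the simulation's
#' known truth.
#'
#' @param result a \code{phenosim_result}.
#' @param dir destination directory (created if missing).
#' @param precision decimal digits.
#' @return Invisibly, the written file paths.
#' @export
write_component_matrices <- function(result, dir, precision = 6L) {
  stopifnot(inherits(result, "phenosim_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (key in names(result$components)) {
    comp <- result$components[[key]]
    path <- file.path(dir, paste0("component_", gsub(":", "_", key), ".csv"))
    lines <- c(paste(c("id", result$trait_ids), collapse = ","),
               paste(result$sample_ids,
                     apply(matrix(fmt_num(comp$values, precision),
                                  nrow(comp$values)), 1L, paste, collapse = ","),
                     sep = ","))
    files <- c(files, write_lines_file(lines, path))
  }
  sf <- data.frame(component = names(result$scale_factors),
                   scale_factor = unname(result$scale_factors),
                   stringsAsFactors = FALSE)
  sf_path <- file.path(dir, "scale_factors.csv")
  write_lines_file(c("component,scale_factor",
                     paste(sf$component, fmt_num(sf$scale_factor, 12L), sep = ",")),
                   sf_path)
  files <- c(files, sf_path)
  causal <- collect_causal_snps(result)
  if (!is.null(causal)) {
    causal_path <- file.path(dir, "causal_snps.csv")
    lines <- c(paste(c("snp_id", "part", result$trait_ids), collapse = ","),
               paste(causal$snp_id, causal$part,
                     apply(matrix(fmt_num(as.matrix(causal[, -(1:2), drop = FALSE]),
                                          precision), nrow(causal)),
                           1L, paste, collapse = ","), sep = ","))
    files <- c(files, write_lines_file(lines, causal_path))
  }
  invisible(files)
}

# gather causal SNP ids and (scaled) effect sizes from the genetic variant
# components' predictor attributes
collect_causal_snps <- function(result) {
  rows <- list()
  for (key in names(result$components)) {
    comp <- result$components[[key]]
    pred <- attr(comp, "predictors")
    if (comp$role == "genetic_variant" && !is.null(pred)) {
      eff <- pred$effects * sqrt(result$scale_factors[[key]])
      df <- data.frame(snp_id = pred$ids, part = comp$part,
                       stringsAsFactors = FALSE)
      rows[[key]] <- cbind(df, as.data.frame(eff))
    }
  }
  if (length(rows) == 0L) return(NULL)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
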