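# Config-driven end-to-end simulation: genotypes -> components -> scaling
# -> phenotypes -> output.

#' Validate and normalize a simulation configuration
#'
#' Accepts a named list, or a path to a YAML/JSON file holding one, and
#' checks every invariant, reporting ALL violations at once (not just the
#' first). Missing optional fields are filled with documented defaults and
#' the normalized configuration is returned; re-validating a returned
#' configuration is a no-op (validation is idempotent).
#'
#' Required fields: \code{n_samples}, \code{n_traits}, \code{budget}
#' (named list of variance shares per component role, summing to 1), and
#' \code{genotypes$n_snps} when genotypes are simulated. See the package
#' vignette for the full field list.
#'
#' @param config named list or path to a YAML/JSON config file.
#' @return An object of class \code{sim_config} (a named list with all
#'   defaults resolved).
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop(sprintf("config file not found: %s", config))
    config <- if (grepl("\\.json$", config, ignore.case = TRUE))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a named list or a path to a config file")
  errs <- character(0)
  err <- function(key, msg) errs[[length(errs) + 1L]] <<- sprintf("%s: %s", key, msg)
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

  cfg <- config
  # dimensions
  if (!num1(cfg$n_samples) || cfg$n_samples < 1) err("n_samples", "must be a positive integer")
  if (!num1(cfg$n_traits) || cfg$n_traits < 1) err("n_traits", "must be a positive integer")
  p <- if (num1(cfg$n_traits)) as.integer(cfg$n_traits) else 1L

  # genotype source
  if (is.null(cfg$genotypes)) cfg$genotypes <- list(source = "simulate")
  gsrc <- cfg$genotypes$source
  if (is.null(gsrc)) gsrc <- cfg$genotypes$source <- "simulate"
  if (!gsrc %in% c("simulate", "import"))
    err("genotypes$source", "must be 'simulate' or 'import'")
  if (identical(gsrc, "import")) {
    if (is.null(cfg$genotypes$path)) err("genotypes$path", "required for imported genotypes")
    if (is.null(cfg$genotypes$format) ||
        !cfg$genotypes$format %in% GENOTYPE_FORMATS)
      err("genotypes$format", sprintf("must be one of %s",
                                      paste(GENOTYPE_FORMATS, collapse = ", ")))
  } else {
    if (!num1(cfg$genotypes$n_snps) || cfg$genotypes$n_snps < 1)
      err("genotypes$n_snps", "must be a positive integer for simulated genotypes")
    if (is.null(cfg$genotypes$freq_range)) cfg$genotypes$freq_range <- c(0.05, 0.5)
  }

  # budget
  if (is.null(cfg$budget) || length(cfg$budget) == 0L) {
    err("budget", "at least one phenotype component is required")
    roles <- character(0)
  } else {
    roles <- names(cfg$budget)
    bad <- setdiff(roles, COMPONENT_ROLES)
    if (length(bad)) err("budget", sprintf("unknown component role(s): %s",
                                           paste(bad, collapse = ", ")))
    bx <- unlist(cfg$budget)
    if (any(bx < 0)) err("budget", "variance shares must be non-negative")
    if (abs(sum(bx) - 1) > 1e-6)
      err("budget", sprintf("variance shares must sum to 1 (found %.8f)", sum(bx)))
  }

  # genetic variant parameters
  if (is.null(cfg$theta)) cfg$theta <- 1
  if (!num1(cfg$theta) || cfg$theta < 0 || cfg$theta > 1)
    err("theta", "must lie in [0, 1]")
  if (is.null(cfg$P_ind)) cfg$P_ind <- p
  if (!num1(cfg$P_ind) || cfg$P_ind < 1 || cfg$P_ind > p)
    err("P_ind", sprintf("must lie in 1..%d", p))
  if ("genetic_variant" %in% roles) {
    if (!num1(cfg$n_causal) || cfg$n_causal < 1)
      err("n_causal", "must be a positive integer when genetic variant effects are simulated")
  }
  if (is.null(cfg$snp_effect)) cfg$snp_effect <- list(law = "normal", params = c(0, 1))
  if (is.null(cfg$covariate_effect))
    cfg$covariate_effect <- list(law = "normal", params = c(0, 1))
  for (fld in c("snp_effect", "covariate_effect")) {
    law <- cfg[[fld]]$law
    if (is.null(law) || !law %in% c("normal", "uniform"))
      err(fld, "law must be 'normal' or 'uniform'")
  }

  # covariates
  if (is.null(cfg$gamma)) cfg$gamma <- 1
  if (!num1(cfg$gamma) || cfg$gamma < 0 || cfg$gamma > 1)
    err("gamma", "must lie in [0, 1]")
  if ("covariates" %in% roles) {
    if (is.null(cfg$covariates) || length(cfg$covariates) == 0L) {
      err("covariates", "covariate specs required when covariate effects are budgeted")
    } else {
      for (k in seq_along(cfg$covariates)) {
        sp <- cfg$covariates[[k]]
        if (is.null(sp$dist) ||
            !sp$dist %in% c("normal", "uniform", "binomial", "categorical"))
          err(sprintf("covariates[[%d]]", k),
              "dist must be normal, uniform, binomial or categorical")
        else if (sp$dist == "categorical" &&
                 (is.null(sp$probs) || abs(sum(sp$probs) - 1) > 1e-8))
          err(sprintf("covariates[[%d]]", k), "categorical probs must sum to 1")
        else if (sp$dist == "binomial" &&
                 (is.null(sp$prob) || sp$prob < 0 || sp$prob > 1))
          err(sprintf("covariates[[%d]]", k), "binomial prob must lie in [0, 1]")
      }
    }
  }

  # kinship source
  if (is.null(cfg$kinship)) cfg$kinship <- list(source = "estimate", standardize = TRUE)
  if (is.null(cfg$kinship$source)) cfg$kinship$source <- "estimate"
  if (!cfg$kinship$source %in% c("estimate", "import"))
    err("kinship$source", "must be 'estimate' or 'import'")
  if (identical(cfg$kinship$source, "import") && is.null(cfg$kinship$path))
    err("kinship$path", "required for imported kinship")
  if (is.null(cfg$kinship$standardize)) cfg$kinship$standardize <- TRUE

  # trait correlation for the correlated noise component
  if ("correlated_noise" %in% roles) {
    tc <- cfg$trait_correlation
    if (is.null(tc) || (is.null(tc$r) && is.null(tc$path)))
      err("trait_correlation", "needs 'r' (exponential decay) or 'path' (matrix file)")
    else if (!is.null(tc$r) && (!num1(tc$r) || abs(tc$r) >= 1))
      err("trait_correlation$r", "must satisfy |r| < 1")
  }

  # shared fractions of split components
  split_roles <- intersect(roles, c("genetic_variant", "infinitesimal",
                                    "covariates", "observational_noise"))
  if (is.null(cfg$shared_fraction)) cfg$shared_fraction <- list()
  defaults <- list(genetic_variant = if (num1(cfg$theta)) cfg$theta else 1,
                   infinitesimal = 0.5,
                   covariates = if (num1(cfg$gamma)) cfg$gamma else 1,
                   observational_noise = 0.5)
  for (role in split_roles) {
    if (is.null(cfg$shared_fraction[[role]]))
      cfg$shared_fraction[[role]] <- defaults[[role]]
    s <- cfg$shared_fraction[[role]]
    if (!num1(s) || s < 0 || s > 1)
      err(sprintf("shared_fraction$%s", role), "must lie in [0, 1]")
  }
  # a positive sub-budget needs a nonempty subcomponent to scale
  if ("genetic_variant" %in% roles && num1(cfg$theta) && num1(cfg$n_causal)) {
    s <- cfg$shared_fraction$genetic_variant
    n_shared <- round_half_up(cfg$theta * cfg$n_causal)
    if (num1(s) && s > 0 && n_shared == 0)
      err("shared_fraction$genetic_variant",
          "positive shared budget but theta leaves no shared causal SNPs")
    if (num1(s) && s < 1 && n_shared == cfg$n_causal)
      err("shared_fraction$genetic_variant",
          "positive independent budget but theta leaves no independent causal SNPs")
  }
  if ("covariates" %in% roles && num1(cfg$gamma) && !is.null(cfg$covariates)) {
    s <- cfg$shared_fraction$covariates
    k_total <- length(cfg$covariates)
    n_shared <- round_half_up(cfg$gamma * k_total)
    if (num1(s) && s > 0 && n_shared == 0)
      err("shared_fraction$covariates",
          "positive shared budget but gamma leaves no shared covariates")
    if (num1(s) && s < 1 && n_shared == k_total)
      err("shared_fraction$covariates",
          "positive independent budget but gamma leaves no independent covariates")
  }

  # output
  if (is.null(cfg$output)) cfg$output <- list()
  if (is.null(cfg$output$formats)) cfg$output$formats <- "csv"
  bad_fmt <- setdiff(cfg$output$formats, c("plink", "bimbam", "gemma", "snptest", "csv"))
  if (length(bad_fmt)) err("output$formats", sprintf("unknown format(s): %s",
                                                     paste(bad_fmt, collapse = ", ")))
  if (is.null(cfg$output$precision)) cfg$output$precision <- 6L
  if (is.null(cfg$seed)) cfg$seed <- NULL else if (!num1(cfg$seed))
    err("seed", "must be a single integer")

  if (length(errs))
    stop(paste(c("invalid simulation config:", paste(" -", errs)), collapse = "\n"),
         call. = FALSE)
  class(cfg) <- c("sim_config", "list")
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("simulation config: N=%d, P=%d, components: %s\n",
              x$n_samples, x$n_traits, paste(names(x$budget), collapse = ", ")))
  invisible(x)
}

# expand per-role totals + shared fractions into a variance_budget
expand_budget <- function(cfg) {
  entries <- list()
  for (role in names(cfg$budget)) {
    x <- cfg$budget[[role]]
    s <- cfg$shared_fraction[[role]]
    if (role == "correlated_noise" || is.null(s)) {
      entries[[role]] <- x
    } else {
      entries[[role]] <- c(shared = x * s, independent = x * (1 - s))
    }
  }
  variance_budget(entries)
}

#' Run the full phenotype simulation pipeline
#'
#' Executes the five stages in order — genotype simulation/import, kinship,
#' phenotype components, variance scaling and assembly, and (optionally)
#' output — logging each stage's realized dimensions. Fully reproducible
#' under a fixed \code{seed}: the seed is set once and a single RNG stream
#' is consumed by all stages in a fixed order.
#'
#' @param config a \code{sim_config}, a named list, or a config file path
#'   (passed through \code{\link{validate_config}}).
#' @param out_dir optional output directory; when given, the output bundle,
#'   per-component ground-truth matrices and the variance report are
#'   written there.
#' @param quiet suppress stage log messages.
#' @return A \code{phenosim_result} with additional elements
#'   \code{genotypes}, \code{covariates}, \code{kinship}, \code{config} and
#'   \code{files} (written paths, when \code{out_dir} is given).
#' @export
run_simulation <- function(config, out_dir = NULL, quiet = FALSE) {
  cfg <- validate_config(config)
  log <- function(...) if (!quiet) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s': %s", name, conditionMessage(e)), call. = FALSE))
  }
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n <- as.integer(cfg$n_samples)
  p <- as.integer(cfg$n_traits)
  roles <- names(cfg$budget)

  ## stage 1: genotypes
  geno <- stage("genotypes", {
    if (identical(cfg$genotypes$source, "import")) {
      g <- do.call(read_genotypes,
                   c(list(path = cfg$genotypes$path, format = cfg$genotypes$format),
                     cfg$genotypes$options))
      if (nrow(g$dosages) != n)
        stop(sprintf("imported panel has %d samples, config says %d",
                     nrow(g$dosages), n))
      g
    } else {
      simulate_genotypes(n, as.integer(cfg$genotypes$n_snps),
                         allele_freqs = cfg$genotypes$allele_freqs,
                         freq_range = cfg$genotypes$freq_range)
    }
  })
  log("stage genotypes: %d samples x %d SNPs", nrow(geno$dosages), ncol(geno$dosages))

  ## stage 2: kinship (only needed for the infinitesimal component)
  kin <- NULL
  if ("infinitesimal" %in% roles) {
    kin <- stage("kinship", {
      if (identical(cfg$kinship$source, "import")) {
        m <- read_square_matrix(cfg$kinship$path,
                                sep = if (is.null(cfg$kinship$sep)) "," else cfg$kinship$sep,
                                header = isTRUE(cfg$kinship$header))
        kinship(m, sample_ids = geno$sample_ids,
                normalizer_m = mean(diag(m)))
      } else {
        estimate_kinship(geno, standardize = isTRUE(cfg$kinship$standardize))
      }
    })
    log("stage kinship: %d x %d (mean diagonal %.4f)",
        nrow(kin$matrix), ncol(kin$matrix), mean(diag(kin$matrix)))
  }

  ## stage 3: components
  components <- list()
  covset <- NULL
  if ("genetic_variant" %in% roles) {
    gv <- stage("genetic variant effects", {
      snps <- sample_causal_snps(geno, as.integer(cfg$n_causal), cfg$theta)
      b_shared <- if (!is.null(snps$shared))
        make_shared_effect_sizes(ncol(snps$shared$dosages), p,
                                 law = cfg$snp_effect$law,
                                 law_params = cfg$snp_effect$params) else NULL
      b_ind <- if (!is.null(snps$independent))
        make_independent_effect_sizes(ncol(snps$independent$dosages), p,
                                      P_ind = as.integer(cfg$P_ind),
                                      law = cfg$snp_effect$law,
                                      law_params = cfg$snp_effect$params) else NULL
      genetic_variant_component(snps$shared, snps$independent, b_shared, b_ind,
                                P = p)
    })
    components <- c(components, list(gv$shared, gv$independent))
    log("stage components: genetic variant effects (%d causal SNPs)",
        as.integer(cfg$n_causal))
  }
  if ("infinitesimal" %in% roles) {
    comp <- stage("infinitesimal genetic effects", {
      bfac <- kinship_factor(kin)
      list(shared = infinitesimal_component(bfac, p, "shared"),
           independent = infinitesimal_component(bfac, p, "independent"))
    })
    components <- c(components, list(comp$shared, comp$independent))
    log("stage components: infinitesimal genetic effects")
  }
  if ("covariates" %in% roles) {
    cv <- stage("covariate effects", {
      covset <- simulate_covariates(n, cfg$covariates, gamma = cfg$gamma)
      a_shared <- if (length(covset$shared_cols))
        make_shared_effect_sizes(length(covset$shared_cols), p,
                                 law = cfg$covariate_effect$law,
                                 law_params = cfg$covariate_effect$params) else NULL
      a_ind <- if (length(covset$independent_cols))
        make_independent_effect_sizes(length(covset$independent_cols), p,
                                      P_ind = as.integer(cfg$P_ind),
                                      law = cfg$covariate_effect$law,
                                      law_params = cfg$covariate_effect$params) else NULL
      list(covset = covset, comp = covariate_component(covset, a_shared, a_ind, P = p))
    })
    covset <- cv$covset
    components <- c(components, list(cv$comp$shared, cv$comp$independent))
    log("stage components: covariate effects (%d covariates)", length(cfg$covariates))
  }
  if ("correlated_noise" %in% roles) {
    comp <- stage("correlated non-genetic effects", {
      tc <- if (!is.null(cfg$trait_correlation$r))
        build_trait_covariance(p, cfg$trait_correlation$r)
      else trait_covariance(read_square_matrix(
        cfg$trait_correlation$path,
        sep = if (is.null(cfg$trait_correlation$sep)) "," else cfg$trait_correlation$sep,
        header = isTRUE(cfg$trait_correlation$header)))
      correlated_noise_component(n, tc)
    })
    components <- c(components, list(comp))
    log("stage components: correlated non-genetic effects")
  }
  if ("observational_noise" %in% roles) {
    comp <- stage("observational noise", {
      list(shared = observational_noise_component(n, p, "shared"),
           independent = observational_noise_component(n, p, "independent"))
    })
    components <- c(components, list(comp$shared, comp$independent))
    log("stage components: observational noise")
  }

  ## stage 4: scaling and assembly
  result <- stage("assembly", {
    assemble_phenotype(components, expand_budget(cfg),
                       sample_ids = geno$sample_ids)
  })
  rep <- variance_report(result)
  log("stage assembly: %d components, realized shares sum %.6f",
      length(result$components), sum(rep$table$mean_variance[-1L]))

  result$genotypes <- geno
  result$covariates <- covset
  result$kinship <- kin
  result$config <- cfg

  ## stage 5: output
  if (!is.null(out_dir)) {
    files <- stage("output", {
      f1 <- write_bundle(result, geno, covset, kin, dir = out_dir,
                         formats = cfg$output$formats,
                         precision = cfg$output$precision, seed = cfg$seed)
      f2 <- write_component_matrices(result, file.path(out_dir, "components"),
                                     precision = cfg$output$precision)
      f3 <- write_variance_report(rep, out_dir,
                                  precision = cfg$output$precision)
      c(f1, f2, f3)
    })
    result$files <- files
    log("stage output: %d files written to %s", length(files), out_dir)
  }
  result
}
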