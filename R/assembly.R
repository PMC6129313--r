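# Variance-budget scaling and phenotype assembly.
#
# Each simulated component is rescaled so that its average column variance
# (mean over traits of the per-trait sample variance, n - 1 denominator)
# equals its share x of the total phenotypic variance: the variance scale
# factor is a = x / Vbar_col and entries are multiplied by sqrt(a), so the
# variance condition holds exactly. Components are not re-centred: the
# variance, not the second moment, is scaled, so covariates with nonzero
# mean keep their mean.

#' Construct a variance budget
#'
#' Named arguments map component roles to their target share of total
#' phenotypic variance. Each entry is either a single fraction (the
#' component is not split) or a named vector
#' \code{c(shared = ..., independent = ...)} giving the sub-budgets of the
#' shared and independent parts. All fractions must be non-negative and sum
#' to 1 within 1e-6; there is no silent renormalization, a wrong sum is an
#' error (it usually indicates a configuration bug).
#'
#' @param ... named budget entries, names from
#'   \code{c("genetic_variant", "infinitesimal", "covariates",
#'   "correlated_noise", "observational_noise")}.
#' @return An object of class \code{variance_budget}: a data.frame with
#'   columns \code{role}, \code{part}, \code{x}.
#' @export
variance_budget <- function(...) {
  entries <- list(...)
  if (length(entries) == 1L && is.null(names(entries)) && is.list(entries[[1L]]))
    entries <- entries[[1L]]
  if (length(entries) == 0L)
    stop("variance budget requires at least one phenotype component")
  if (is.null(names(entries)) || any(names(entries) == ""))
    stop("all variance budget entries must be named by component role")
  bad_roles <- setdiff(names(entries), COMPONENT_ROLES)
  if (length(bad_roles))
    stop(sprintf("unknown component role(s) in variance budget: %s",
                 paste(bad_roles, collapse = ", ")))
  rows <- lapply(names(entries), function(role) {
    x <- unlist(entries[[role]])
    if (length(x) == 1L && is.null(names(entries[[role]]))) {
      data.frame(role = role, part = "whole", x = as.numeric(x),
                 stringsAsFactors = FALSE)
    } else {
      if (is.null(names(x)) || !all(names(x) %in% c("shared", "independent")))
        stop(sprintf("budget entry '%s': split entries must be named shared/independent", role))
      data.frame(role = role, part = names(x), x = as.numeric(x),
                 stringsAsFactors = FALSE)
    }
  })
  budget <- do.call(rbind, rows)
  if (any(budget$x < 0)) stop("variance budget fractions must be non-negative")
  total <- sum(budget$x)
  if (abs(total - 1) > 1e-6)
    stop(sprintf("variance budget must sum to 1 (found %.8f)", total))
  structure(budget, class = c("variance_budget", "data.frame"))
}

#' @export
print.variance_budget <- function(x, ...) {
  cat("variance budget:\n")
  print.data.frame(x)
  invisible(x)
}

#' Scale a phenotype component to a target variance share
#'
#' Applies the variance scale factor a = x / Vbar_col, multiplying entries
#' by sqrt(a) so that the rescaled component's mean column variance equals
#' x exactly. A target of zero returns the zero matrix; a constant
#' component (zero variance) cannot be scaled to a positive target and is
#' an error.
#'
#' @param component a \code{pheno_component}.
#' @param x target fraction of total phenotypic variance (>= 0).
#' @return List with elements \code{component} (the scaled
#'   \code{pheno_component}) and \code{scale_factor} (a).
#' @export
scale_component <- function(component, x) {
  stopifnot(inherits(component, "pheno_component"))
  if (x < 0) stop("target variance fraction must be non-negative")
  if (x == 0) {
    out <- component
    out$values[] <- 0
    return(list(component = out, scale_factor = 0))
  }
  vbar <- mean_column_variance(component$values)
  if (vbar <= 0)
    stop(sprintf("component %s has zero average column variance; cannot scale it to %g",
                 component_key(component), x))
  a <- x / vbar
  out <- component
  out$values <- component$values * sqrt(a)
  list(component = out, scale_factor = a)
}

#' Assemble the final phenotype from scaled components
#'
#' Scales every component to its variance-budget entry and sums them into
#' the final N x P phenotype Y. Split components are matched to their
#' shared/independent sub-budget entries; unsplit components match a
#' \code{"whole"} entry. Budget keys and provided components must agree
#' exactly in both directions.
#'
#' @param components list of \code{pheno_component} objects.
#' @param budget a \code{variance_budget} (or arguments accepted by
#'   \code{\link{variance_budget}} as a list).
#' @param sample_ids optional sample identifiers (length N).
#' @param trait_ids optional trait identifiers (length P).
#' @return An object of class \code{phenosim_result} with elements
#'   \code{Y}, \code{components} (scaled), \code{scale_factors} (named by
#'   \code{role:part}), \code{sample_ids}, \code{trait_ids}.
#' @export
assemble_phenotype <- function(components, budget, sample_ids = NULL,
                               trait_ids = NULL) {
  if (!inherits(budget, "variance_budget")) budget <- variance_budget(budget)
  stopifnot(length(components) >= 1)
  lapply(components, function(cc) stopifnot(inherits(cc, "pheno_component")))
  keys <- vapply(components, component_key, character(1))
  if (anyDuplicated(keys))
    stop(sprintf("duplicate component: %s", keys[duplicated(keys)][1]))
  budget_keys <- paste(budget$role, budget$part, sep = ":")
  missing_comp <- setdiff(budget_keys, keys)
  extra_comp <- setdiff(keys, budget_keys)
  if (length(missing_comp) || length(extra_comp))
    stop(sprintf("budget/component mismatch:%s%s",
                 if (length(missing_comp))
                   paste0(" budget entries without component: ",
                          paste(missing_comp, collapse = ", ")) else "",
                 if (length(extra_comp))
                   paste0(" components without budget entry: ",
                          paste(extra_comp, collapse = ", ")) else ""))
  dims <- vapply(components, function(cc) dim(cc$values), integer(2))
  if (length(unique(dims[1, ])) != 1L || length(unique(dims[2, ])) != 1L)
    stop("all components must share the same N x P dimensions")
  n <- dims[1, 1]; p <- dims[2, 1]
  scaled <- vector("list", length(components))
  factors <- numeric(length(components))
  for (i in seq_along(components)) {
    x <- budget$x[match(keys[i], budget_keys)]
    sc <- scale_component(components[[i]], x)
    scaled[[i]] <- sc$component
    factors[i] <- sc$scale_factor
  }
  names(scaled) <- keys
  names(factors) <- keys
  y <- Reduce(`+`, lapply(scaled, `[[`, "values"))
  if (is.null(sample_ids)) sample_ids <- paste0("ID_", seq_len(n))
  if (is.null(trait_ids)) trait_ids <- paste0("Trait_", seq_len(p))
  dimnames(y) <- list(sample_ids, trait_ids)
  structure(list(Y = y, components = scaled, scale_factors = factors,
                 budget = budget, sample_ids = sample_ids,
                 trait_ids = trait_ids),
            class = "phenosim_result")
}

#' @export
print.phenosim_result <- function(x, ...) {
  cat(sprintf("simulated phenotypes: %d samples x %d traits\n",
              nrow(x$Y), ncol(x$Y)))
  cat(sprintf("components (%d):\n", length(x$components)))
  rep <- variance_report(x)
  print.data.frame(rep$table[, c("component", "mean_variance", "degenerate")],
                   row.names = FALSE)
  invisible(x)
}

#' @export
summary.phenosim_result <- function(object, ...) variance_report(object)

#' @export
plot.phenosim_result <- function(x, ...) {
  rep <- variance_report(x)
  mats <- c(list(Y = rep$correlations$Y), rep$correlations$components)
  mats <- Filter(function(m) !all(is.na(m)), mats)
  nplots <- length(mats)
  old <- graphics::par(mfrow = c(1, nplots), mar = c(2, 2, 3, 1))
  on.exit(graphics::par(old))
  for (nm in names(mats)) {
    m <- mats[[nm]]
    graphics::image(seq_len(nrow(m)), seq_len(ncol(m)), t(m[rev(seq_len(nrow(m))), ]),
                    zlim = c(-1, 1), col = grDevices::hcl.colors(51, "Blue-Red 3"),
                    main = nm, xlab = "", ylab = "", axes = FALSE)
    graphics::box()
  }
  invisible(x)
}

#' Realized variance and correlation report
#'
#' Recomputes, for the final phenotype and each scaled component, the
#' per-trait sample variances, the mean column variance (the realized
#' variance share) and the P x P Pearson trait-by-trait correlation.
#' Components with zero variance in some trait are flagged as degenerate
#' and their correlation entries reported as NA rather than propagating
#' NaN.
#'
#' @param result a \code{phenosim_result}.
#' @return An object of class \code{variance_report}: list with a summary
#'   \code{table} (data.frame), \code{trait_variances} (matrix, rows =
#'   components), and \code{correlations} (list: \code{Y} plus one entry
#'   per component).
#' @export
variance_report <- function(result) {
  stopifnot(inherits(result, "phenosim_result"))
  p <- ncol(result$Y)
  safe_cor <- function(m) {
    v <- apply(m, 2L, stats::var)
    if (any(v <= 0)) {
      cc <- matrix(NA_real_, p, p)
      ok <- v > 0
      if (sum(ok) > 1L)
        cc[ok, ok] <- stats::cor(m[, ok, drop = FALSE])
      diag(cc)[ok] <- 1
      cc
    } else {
      stats::cor(m)
    }
  }
  entries <- c(list(Y = result$Y),
               lapply(result$components, `[[`, "values"))
  tv <- t(vapply(entries, function(m) apply(m, 2L, stats::var), numeric(p)))
  colnames(tv) <- result$trait_ids
  tab <- data.frame(component = names(entries),
                    mean_variance = rowMeans(tv),
                    degenerate = apply(tv, 1L, function(v) any(v <= 0)),
                    stringsAsFactors = FALSE)
  cors <- lapply(entries, safe_cor)
  structure(list(table = tab, trait_variances = tv,
                 correlations = list(Y = cors$Y, components = cors[-1L])),
            class = "variance_report")
}

#' @export
print.variance_report <- function(x, ...) {
  cat("realized variance shares (mean column variance):\n")
  print.data.frame(x$table, row.names = FALSE)
  invisible(x)
}

#' Write a variance report to delimited text and JSON
#'
#' @param report a \code{variance_report}.
#' @param dir destination directory (created if missing).
#' @param precision decimal digits.
#' @return Invisibly, the written file paths.
#' @export
write_variance_report <- function(report, dir, precision = 6L) {
  stopifnot(inherits(report, "variance_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- file.path(dir, "variance_report.tsv")
  tab <- report$table
  tab$mean_variance <- fmt_num(tab$mean_variance, precision)
  utils::write.table(tab, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  js <- file.path(dir, "variance_report.json")
  jsonlite::write_json(list(table = report$table,
                            trait_variances = as.data.frame(report$trait_variances),
                            correlations = c(list(Y = report$correlations$Y),
                                             report$correlations$components)),
                       js, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(c(tsv, js))
}
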