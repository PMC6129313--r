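# Effect-size matrices and non-genetic covariates.
#
# Shared effects act identically (up to scale) on all traits: the effect
# size matrix is built so that any two columns are perfectly correlated,
# which models e.g. pleiotropic variants whose effect is proportionally the
# same on every affected trait. Independent effects act on a random subset
# of traits with unrelated effect sizes.

#' Construct an effect-size matrix object
#'
#' @param values (n_predictors x P) numeric matrix.
#' @param law \code{"normal"} or \code{"uniform"}.
#' @param law_params numeric parameter vector (normal: mean, sd; uniform:
#'   range_min, range_max).
#' @param design \code{"shared"} or \code{"independent"}.
#' @param affected_traits for the independent design, the trait (column)
#'   indices with nonzero entries.
#' @return An object of class \code{effect_sizes}.
#' @export
effect_sizes <- function(values, law, law_params, design,
                         affected_traits = NULL) {
  values <- as.matrix(values)
  structure(list(values = values, law = law, law_params = law_params,
                 design = design, affected_traits = affected_traits),
            class = "effect_sizes")
}

#' @export
print.effect_sizes <- function(x, ...) {
  cat(sprintf("%s %s effect sizes: %d predictors x %d traits\n",
              x$design, x$law, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Simulate a shared (rank-one) effect-size matrix
#'
#' Builds B = b_s b_p^T so that every predictor's effect is proportionally
#' identical across traits (any two nonzero columns have Pearson
#' correlation of absolute value 1). Under the normal law, b_s ~
#' N(mean, sd^2) and b_p ~ N(0, 1). Under the uniform law, b_s and b_p are
#' drawn from two exponential distributions and the entries of
#' -log(b_s b_p^T) are min-max normalized onto [range_min, range_max]; the
#' result covers the requested range with approximately (not exactly)
#' uniform mass and retains exact pairwise column correlation +1 because
#' -log turns the outer product into a column-shifted common vector.
#'
#' @param n_predictors number of predictors (rows).
#' @param P number of traits (columns).
#' @param law \code{"normal"} or \code{"uniform"}.
#' @param law_params normal: \code{c(mean, sd)} for b_s (default
#'   \code{c(0, 1)}); uniform: \code{c(range_min, range_max)}.
#' @param seed optional integer seed.
#' @return An \code{effect_sizes} object with design \code{"shared"}.
#' @export
make_shared_effect_sizes <- function(n_predictors, P,
                                     law = c("normal", "uniform"),
                                     law_params = NULL, seed = NULL) {
  law <- match.arg(law)
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n_predictors >= 1, P >= 1)
  if (law == "normal") {
    if (is.null(law_params)) law_params <- c(0, 1)
    if (length(law_params) != 2L || law_params[2] <= 0)
      stop("normal law requires c(mean, sd) with sd > 0")
    b_s <- stats::rnorm(n_predictors, mean = law_params[1], sd = law_params[2])
    b_p <- stats::rnorm(P, mean = 0, sd = 1)
    values <- outer(b_s, b_p)
  } else {
    if (is.null(law_params) || length(law_params) != 2L ||
        law_params[1] >= law_params[2])
      stop("uniform law requires c(range_min, range_max) with range_min < range_max")
    e_s <- stats::rexp(n_predictors)
    e_p <- stats::rexp(P)
    u <- -log(outer(e_s, e_p))
    rng <- range(u)
    if (rng[2] > rng[1]) {
      u <- (u - rng[1]) / (rng[2] - rng[1])
    } else {
      u[] <- 0.5  # single entry: midpoint of the target range
    }
    values <- law_params[1] + u * (law_params[2] - law_params[1])
  }
  effect_sizes(values, law = law, law_params = law_params, design = "shared")
}

#' Simulate an independent effect-size matrix
#'
#' Entries are iid from the chosen law (normal with user mean/sd, or exact
#' uniform over [range_min, range_max]); then P - P_ind traits are randomly
#' selected once and their columns set to zero, so only \code{P_ind} traits
#' carry the effect. With \code{per_row = TRUE} the zeroed trait set is
#' redrawn independently for every predictor row instead.
#'
#' @param n_predictors number of predictors (rows).
#' @param P number of traits (columns).
#' @param P_ind number of traits affected (1 <= P_ind <= P).
#' @param law \code{"normal"} or \code{"uniform"}.
#' @param law_params normal: \code{c(mean, sd)}; uniform:
#'   \code{c(range_min, range_max)}.
#' @param per_row redraw the affected-trait set per predictor row.
#' @param seed optional integer seed.
#' @return An \code{effect_sizes} object with design \code{"independent"}
#'   and the affected trait indices recorded.
#' @export
make_independent_effect_sizes <- function(n_predictors, P, P_ind,
                                          law = c("normal", "uniform"),
                                          law_params = NULL,
                                          per_row = FALSE, seed = NULL) {
  law <- match.arg(law)
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n_predictors >= 1, P >= 1)
  if (P_ind < 1 || P_ind > P)
    stop("P_ind must satisfy 1 <= P_ind <= P")
  draw <- function(n) {
    if (law == "normal") {
      lp <- if (is.null(law_params)) c(0, 1) else law_params
      if (length(lp) != 2L || lp[2] <= 0)
        stop("normal law requires c(mean, sd) with sd > 0")
      stats::rnorm(n, lp[1], lp[2])
    } else {
      lp <- law_params
      if (is.null(lp) || length(lp) != 2L || lp[1] >= lp[2])
        stop("uniform law requires c(range_min, range_max) with range_min < range_max")
      stats::runif(n, lp[1], lp[2])
    }
  }
  values <- matrix(draw(n_predictors * P), nrow = n_predictors, ncol = P)
  if (per_row) {
    affected <- seq_len(P)
    for (i in seq_len(n_predictors)) {
      zeroed <- sample.int(P, P - P_ind)
      values[i, zeroed] <- 0
    }
  } else {
    zeroed <- sample.int(P, P - P_ind)
    values[, zeroed] <- 0
    affected <- setdiff(seq_len(P), zeroed)
  }
  effect_sizes(values, law = law,
               law_params = if (is.null(law_params)) c(0, 1) else law_params,
               design = "independent", affected_traits = affected)
}

#' Simulate non-genetic covariates
#'
#' Draws N samples for each covariate independently from its specified
#' distribution (normal, uniform, binomial or categorical, mimicking e.g.
#' age, sex or cohort), and partitions the covariates into a set shared
#' across all traits (the first \code{round(gamma * K)} columns, rounding
#' half away from zero) and an independent set.
#'
#' @param n_samples number of samples N.
#' @param specs list of per-covariate descriptors, each a list with element
#'   \code{dist} in \code{c("normal", "uniform", "binomial", "categorical")}
#'   and parameters: normal \code{mean}/\code{sd}, uniform
#'   \code{min}/\code{max}, binomial \code{prob}, categorical \code{probs}
#'   (must sum to 1 within 1e-8; levels are coded 0..L-1).
#' @param gamma fraction of covariates shared across traits, in [0, 1].
#' @param seed optional integer seed.
#' @return An object of class \code{covariate_set} with the N x K value
#'   matrix, the specs, and the shared/independent column partition.
#' @export
simulate_covariates <- function(n_samples, specs, gamma = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (gamma < 0 || gamma > 1) stop("gamma must lie in [0, 1]")
  stopifnot(n_samples >= 1, length(specs) >= 1)
  cols <- lapply(seq_along(specs), function(k) {
    sp <- specs[[k]]
    if (is.null(sp$dist))
      stop(sprintf("covariate spec %d: missing 'dist'", k))
    switch(sp$dist,
           normal = {
             m <- if (is.null(sp$mean)) 0 else sp$mean
             s <- if (is.null(sp$sd)) 1 else sp$sd
             stats::rnorm(n_samples, m, s)
           },
           uniform = {
             a <- if (is.null(sp$min)) 0 else sp$min
             b <- if (is.null(sp$max)) 1 else sp$max
             stats::runif(n_samples, a, b)
           },
           binomial = {
             if (is.null(sp$prob)) stop(sprintf("covariate spec %d: binomial needs 'prob'", k))
             stats::rbinom(n_samples, 1L, sp$prob)
           },
           categorical = {
             if (is.null(sp$probs)) stop(sprintf("covariate spec %d: categorical needs 'probs'", k))
             if (abs(sum(sp$probs) - 1) > 1e-8)
               stop(sprintf("covariate spec %d: categorical probs must sum to 1", k))
             sample(seq_along(sp$probs) - 1L, n_samples, replace = TRUE,
                    prob = sp$probs)
           },
           stop(sprintf("covariate spec %d: unknown distribution '%s'", k, sp$dist)))
  })
  values <- do.call(cbind, cols)
  colnames(values) <- paste0("Covariate_", seq_along(specs))
  k_total <- length(specs)
  n_shared <- as.integer(round_half_up(gamma * k_total))
  structure(list(values = values, specs = specs, gamma = gamma,
                 shared_cols = seq_len(n_shared),
                 independent_cols = setdiff(seq_len(k_total), seq_len(n_shared))),
            class = "covariate_set")
}

#' @export
print.covariate_set <- function(x, ...) {
  cat(sprintf("covariate set: %d samples x %d covariates (%d shared, %d independent)\n",
              nrow(x$values), ncol(x$values), length(x$shared_cols),
              length(x$independent_cols)))
  invisible(x)
}
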