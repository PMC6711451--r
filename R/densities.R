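#' Multivariate normal density over a named parameter vector
#'
#' The lingua franca of every level of the hierarchy: subject-level posteriors
#' and priors, the group-level prior and posterior, and hyperparameter
#' posteriors are all `gaussian_density` objects. A parameter that a reduced
#' model "switches off" is represented by shrinking its prior variance to a
#' small floor at the prior mean, never by deleting the dimension, so that all
#' models stay aligned over one labelled parameter vector.
#'
#' @param mean Numeric vector of expected values (model-specific units; for
#'   connectivity parameters typically unitless log-scaling values or Hz).
#' @param cov Symmetric positive-semidefinite covariance matrix, same ordering.
#' @param labels Character vector of parameter names; defaults to
#'   `names(mean)` or `p1..pP`.
#' @param tol Tolerance for symmetry/PSD validation.
#' @return An object of class `gaussian_density` with elements `labels`,
#'   `mean`, `cov`.
#' @export
gaussian_density <- function(mean, cov, labels = NULL, tol = 1e-6) {
  mean <- as.numeric(mean)
  cov <- as.matrix(cov)
  p <- length(mean)
  if (is.null(labels)) {
    labels <- if (!is.null(names(mean))) names(mean) else paste0("p", seq_len(p))
  }
  if (length(labels) != p || nrow(cov) != p || ncol(cov) != p) {
    stop("gaussian_density: mean (", p, "), labels (", length(labels),
         ") and cov (", nrow(cov), "x", ncol(cov), ") dimensions disagree")
  }
  scale <- max(abs(cov), 1e-300)
  if (max(abs(cov - t(cov))) > tol * scale) {
    stop("gaussian_density: covariance is not symmetric to tolerance")
  }
  cov <- symm(cov)
  ev_min <- min(eigen(cov, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < -tol * scale) {
    stop("gaussian_density: covariance has eigenvalue ", format(ev_min),
         " below -tol; not positive semidefinite")
  }
  structure(list(labels = as.character(labels), mean = mean, cov = cov),
            class = "gaussian_density")
}

#' @export
print.gaussian_density <- function(x, ...) {
  cat("<gaussian_density> over", length(x$mean), "parameters\n")
  sd <- sqrt(pmax(diag(x$cov), 0))
  df <- data.frame(label = x$labels, mean = x$mean, sd = sd)
  print(utils::head(df, 12), row.names = FALSE)
  if (length(x$mean) > 12) cat("  ... (", length(x$mean) - 12, " more)\n", sep = "")
  invisible(x)
}

#' @export
length.gaussian_density <- function(x) length(x$mean)

# Precision matrix of a density (ridge-guarded).
dens_precision <- function(d, eps = 1e-8) ridge_inv(d$cov, eps = eps)

#' One subject's first-level summary: posterior, prior and log evidence
#'
#' Bundles what group-level estimation needs from a subject: the posterior
#' density over the selected parameters, the prior density they were estimated
#' under, and (optionally) the negative variational free energy of the fit.
#' The subject's raw data never enter the group level; its influence flows
#' entirely through these two densities, so precisely estimated subjects carry
#' more weight than noisy ones.
#'
#' @param subject_id Character scalar identifying the subject.
#' @param posterior,prior `gaussian_density` objects with identical labels and
#'   ordering. The posterior need not dominate the prior in precision (data
#'   may be uninformative along some directions).
#' @param free_energy Optional scalar log evidence (nats); `NA` when unknown,
#'   in which case it is treated as a constant offset in all comparisons.
#' @return An object of class `first_level_unit`.
#' @export
first_level_unit <- function(subject_id, posterior, prior, free_energy = NA_real_) {
  stopifnot(inherits(posterior, "gaussian_density"),
            inherits(prior, "gaussian_density"))
  if (!identical(posterior$labels, prior$labels)) {
    stop("first_level_unit('", subject_id, "'): posterior and prior labels differ: ",
         paste(setdiff(union(posterior$labels, prior$labels),
                       intersect(posterior$labels, prior$labels)), collapse = ", "))
  }
  structure(list(subject_id = as.character(subject_id), posterior = posterior,
                 prior = prior, free_energy = as.numeric(free_energy)),
            class = "first_level_unit")
}

#' @export
print.first_level_unit <- function(x, ...) {
  cat("<first_level_unit>", x$subject_id, "-", length(x$posterior$mean),
      "parameters, F =", format(x$free_energy), "\n")
  invisible(x)
}

#' Combine a Gaussian density with an additive precision update
#'
#' Conjugate Gaussian product: given a density with precision `P` and
#' precision-weighted mean `P m`, returns the density with precision
#' `P + delta_precision` and precision-mean `P m + delta_precision_mean`.
#' This is the primitive underlying Bayesian model reduction and the
#' construction of empirical priors.
#'
#' @param a A `gaussian_density`.
#' @param delta_precision Symmetric matrix added to the precision of `a`.
#' @param delta_precision_mean Vector added to the precision-weighted mean.
#' @param eps Ridge used for the inversions.
#' @return The combined `gaussian_density` (same labels).
#' @export
combine_precisions <- function(a, delta_precision, delta_precision_mean, eps = 1e-8) {
  stopifnot(inherits(a, "gaussian_density"))
  p <- length(a$mean)
  delta_precision <- as.matrix(delta_precision)
  if (!all(dim(delta_precision) == p) || length(delta_precision_mean) != p) {
    stop("combine_precisions: update dimensions (", nrow(delta_precision), "x",
         ncol(delta_precision), ", mean ", length(delta_precision_mean),
         ") do not match density over [", paste(a$labels, collapse = ", "), "]")
  }
  pa <- dens_precision(a, eps = eps)
  pm <- drop(pa %*% a$mean) + as.numeric(delta_precision_mean)
  pn <- symm(pa + delta_precision)
  ev <- eigen(pn, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) {
    stop("combine_precisions: combined precision is singular ",
         "(min eigenvalue ", format(min(ev)), ", condition ",
         format(max(ev) / max(min(ev), .Machine$double.xmin)), ")")
  }
  cov <- ridge_inv(pn, eps = eps)
  gaussian_density(drop(cov %*% pm), cov, labels = a$labels)
}
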