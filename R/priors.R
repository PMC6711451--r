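#' Default second-level priors for a PEB model
#'
#' Constructs the group-level prior expectation eta, prior covariance Sigma3
#' over the C*P covariate-by-parameter effects, and the random-effects (RFX)
#' precision components Q_j with a Gaussian hyperprior on their log-scaling
#' parameters gamma_j.
#'
#' Defaults mirror common practice for hierarchical models over connectivity
#' parameters: the prior variances used at the first level are reused as the
#' prior variance around the group mean (ratio `alpha`, default 1), and the
#' baseline between-subject (RFX) variance is set to 1/16 of the first-level
#' prior variance (ratio `beta`, default 16) - i.e. random effects are assumed
#' a priori to have a quarter of the standard deviation of the plausible
#' parameter range. The group-mean block of eta equals the first-level prior
#' mean (so a null group is a priori centred on the first-level prior);
#' other covariate blocks are centred on zero.
#'
#' The RFX precision is \eqn{\Pi^{(2)}(\gamma) = \sum_j e^{\gamma_j} Q_j}
#' with baseline components \eqn{Q_j} scaled so that \eqn{\gamma = 0} yields
#' variance = first-level prior variance / beta. Each gamma_j carries a
#' Normal(0, `gamma_prior_var`) hyperprior (default variance 1/16, a weakly
#' informative log-scaling prior).
#'
#' @param first_level_prior `gaussian_density` over the P selected parameters.
#' @param n_covariates Number of columns C of the between-subjects design.
#' @param alpha Ratio of group-level to first-level prior variance (default 1).
#' @param beta Ratio of first-level prior variance to baseline RFX variance
#'   (default 16).
#' @param rfx One of `"single"` (one shared precision component, default) or
#'   `"all"` (one component per parameter, allowing parameter-wise RFX
#'   resolution).
#' @param gamma_prior_var Variance of the Normal hyperprior on each gamma_j.
#' @param covariate_scale Optional length-C multiplier on the prior variance of
#'   each covariate block (first entry is the group-mean block); default all 1.
#'   Exposed so covariate-norm rescaling can be applied if desired; not
#'   applied by default.
#' @return Object of class `peb_priors` with elements `eta`, `sigma3`,
#'   `rfx_components` (list of P x P precision components at baseline scale),
#'   `gamma_prior` (`gaussian_density`), `alpha`, `beta`, `parameter_labels`.
#' @export
default_priors <- function(first_level_prior, n_covariates,
                           alpha = 1, beta = 16, rfx = c("single", "all"),
                           gamma_prior_var = 1 / 16, covariate_scale = NULL) {
  stopifnot(inherits(first_level_prior, "gaussian_density"))
  rfx <- match.arg(rfx)
  if (n_covariates < 1) stop("default_priors: n_covariates must be >= 1")
  v <- diag(as.matrix(first_level_prior$cov))
  p <- length(v)
  if (any(v <= 0)) {
    # switched-off first-level parameters keep a variance floor, never zero
    v <- pmax(v, 1e-8)
  }
  if (is.null(covariate_scale)) covariate_scale <- rep(1, n_covariates)
  if (length(covariate_scale) != n_covariates) {
    stop("default_priors: covariate_scale must have length ", n_covariates)
  }
  sigma3 <- kronecker(diag(covariate_scale * alpha, n_covariates), diag(v, p))
  eta <- c(first_level_prior$mean, rep(0, (n_covariates - 1) * p))
  # baseline precision beta/v per parameter: gamma = 0 gives variance v/beta
  if (rfx == "single") {
    q <- list(diag(beta / v, p))
  } else {
    q <- lapply(seq_len(p), function(j) {
      m <- matrix(0, p, p)
      m[j, j] <- beta / v[j]
      m
    })
  }
  gp <- gaussian_density(rep(0, length(q)),
                         diag(gamma_prior_var, length(q)),
                         labels = paste0("gamma", seq_along(q)))
  structure(list(eta = eta, sigma3 = sigma3, rfx_components = q,
                 gamma_prior = gp, alpha = alpha, beta = beta,
                 parameter_labels = first_level_prior$labels),
            class = "peb_priors")
}

#' @export
print.peb_priors <- function(x, ...) {
  p <- length(x$parameter_labels)
  cat("<peb_priors>", length(x$eta), "group effects (",
      length(x$eta) / p, "covariates x", p, "parameters ),",
      length(x$rfx_components), "RFX component(s); alpha =", x$alpha,
      ", beta =", x$beta, "\n")
  invisible(x)
}

# RFX precision at hyperparameters gamma: sum_j exp(gamma_j) Q_j.
rfx_precision <- function(priors, gamma) {
  stopifnot(length(gamma) == length(priors$rfx_components))
  Reduce(`+`, Map(function(g, q) exp(g) * q, gamma, priors$rfx_components))
}

#' Assemble a PEB model
#'
#' Binds the second-level design, priors and subject-level units into the
#' hierarchical model: subject parameters are a linear combination of
#' group effects (design-weighted) plus zero-mean Gaussian random effects,
#' and the group effects carry a Gaussian prior N(eta, Sigma3).
#'
#' @param units List of `first_level_unit`s (one per subject, order matching
#'   the rows of the between-subjects design).
#' @param design A `full_design`.
#' @param priors A `peb_priors`; defaults to [default_priors()] built from the
#'   first unit's prior.
#' @return Object of class `peb_model`.
#' @export
peb_model <- function(units, design, priors = NULL) {
  stopifnot(inherits(design, "full_design"), length(units) >= 1)
  lapply(units, function(u) stopifnot(inherits(u, "first_level_unit")))
  plabs <- design$within$parameter_labels
  for (u in units) {
    if (!identical(u$posterior$labels, plabs)) {
      stop("peb_model: unit '", u$subject_id,
           "' labels do not match the within-subject design: [",
           paste(u$posterior$labels, collapse = ", "), "] vs [",
           paste(plabs, collapse = ", "), "]")
    }
  }
  n <- nrow(design$between$XB)
  if (length(units) != n) {
    stop("peb_model: ", length(units), " units but design has ", n, " subjects")
  }
  if (is.null(priors)) {
    priors <- default_priors(units[[1]]$prior, ncol(design$between$XB))
  }
  if (length(priors$eta) != ncol(design$X)) {
    stop("peb_model: priors cover ", length(priors$eta),
         " effects but the design has ", ncol(design$X), " columns")
  }
  structure(list(units = units, design = design, priors = priors),
            class = "peb_model")
}

#' @export
print.peb_model <- function(x, ...) {
  cat("<peb_model>", length(x$units), "subjects,",
      ncol(x$design$X), "group effects\n")
  invisible(x)
}
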