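# Hierarchical synthetic data with known truth. Subjects are sampled from the
# group GLM with additive random effects; their "measurements" come from a
# small linear forward model inverted exactly by conjugate Bayes, so every
# first-level posterior and log evidence is exact rather than approximate.
# The group level only ever sees Gaussian posterior/prior pairs, so this
# linear toy exercises every group-level code path exactly.

#' Simulation configuration
#'
#' Defaults mirror the shape of a typical group connectivity study: 60
#' subjects, 8 connectivity parameters, a group-mean column plus one
#' covariate of interest. True group effects default to zero (a null group);
#' the between-subject (RFX) standard deviation defaults to 1/4 of the
#' first-level prior standard deviation, matching the modelling assumption
#' that random effects have a quarter of the a-priori plausible spread.
#'
#' @param n_subjects Number of subjects N.
#' @param n_params Number of subject-level parameters P.
#' @param covariates Data frame of between-subject covariates (N rows,
#'   without the constant column), or `NULL` to draw standard-normal,
#'   mean-centred covariates named by `covariate_names[-1]`.
#' @param covariate_names Names of the design columns including the leading
#'   `"mean"`; length C.
#' @param effects True group effects: C x P matrix (rows in covariate order,
#'   first row = group mean), or `NULL` for all zero.
#' @param rfx_sd Between-subject standard deviation per parameter (scalar or
#'   length P).
#' @param n_obs Observations T per subject for the linear forward model.
#' @param obs_noise_sd Observation noise standard deviation.
#' @param prior_mean,prior_var First-level prior mean and variance per
#'   parameter.
#' @param seed Integer seed; all randomness flows from it.
#' @return A list of class `sim_config`.
#' @export
simulation_config <- function(n_subjects = 60, n_params = 8,
                              covariates = NULL,
                              covariate_names = c("mean", "LI"),
                              effects = NULL, rfx_sd = 0.125,
                              n_obs = 32, obs_noise_sd = 0.25,
                              prior_mean = 0, prior_var = 0.25,
                              seed = 1L) {
  n_cov <- length(covariate_names)
  if (is.null(effects)) effects <- matrix(0, n_cov, n_params)
  effects <- as.matrix(effects)
  if (nrow(effects) != n_cov || ncol(effects) != n_params) {
    stop("simulation_config: effects must be ", n_cov, " x ", n_params)
  }
  rfx_sd <- rep_len(rfx_sd, n_params)
  if (any(rfx_sd <= 0) || obs_noise_sd <= 0) {
    stop("simulation_config: all standard deviations must be positive")
  }
  if (n_obs < n_params) {
    warning("simulation_config: n_obs < n_params; the toy first level is under-determined")
  }
  structure(list(n_subjects = n_subjects, n_params = n_params,
                 covariates = covariates, covariate_names = covariate_names,
                 effects = effects, rfx_sd = rfx_sd, n_obs = n_obs,
                 obs_noise_sd = obs_noise_sd,
                 prior_mean = rep_len(prior_mean, n_params),
                 prior_var = rep_len(prior_var, n_params),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Sample true subject-level parameters from the group model
#'
#' Draws each subject's true parameter vector as its design-predicted value
#' plus an independent Gaussian random effect:
#' theta_i = (X theta_true)_i + N(0, diag(rfx_sd^2)).
#'
#' @param config A `sim_config`.
#' @return List with `theta_true` (N x P matrix), `covariates` (data frame,
#'   the generated or supplied non-constant columns), `xb` (the N x C design
#'   including the constant column).
#' @export
simulate_group <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_subjects
  p <- config$n_params
  cn <- config$covariate_names
  if (is.null(config$covariates)) {
    cov_df <- as.data.frame(stats::setNames(lapply(cn[-1], function(nm) {
      x <- stats::rnorm(n)
      x - mean(x)
    }), cn[-1]))
  } else {
    cov_df <- as.data.frame(config$covariates)
    if (nrow(cov_df) != n) stop("simulate_group: covariates must have ", n, " rows")
  }
  xb <- matrix(1, n, 1, dimnames = list(NULL, "mean"))
  if (ncol(cov_df) > 0) xb <- cbind(xb, as.matrix(cov_df))
  pred <- xb %*% config$effects # N x P
  rfx <- matrix(stats::rnorm(n * p, sd = rep(config$rfx_sd, each = n)), n, p)
  theta <- pred + rfx
  colnames(theta) <- paste0("theta", seq_len(p))
  list(theta_true = theta, covariates = cov_df, xb = xb)
}

# Exact conjugate inversion of one linear problem y = G theta + noise under a
# Gaussian prior; returns a first_level_unit with the exact log evidence.
#' Invert a linear forward problem exactly
#'
#' Conjugate Bayesian inversion of `y = G theta + e`, `e ~ N(0, s^2 I)`,
#' under a Gaussian prior: posterior precision `P0 + G'G/s^2`, and the exact
#' log evidence in closed form.
#'
#' @param problem List with `y` (length T), `G` (T x P), `noise_sd`.
#' @param prior `gaussian_density` over the P parameters.
#' @param subject_id Subject identifier for the returned unit.
#' @return A `first_level_unit` with exact posterior and `free_energy`.
#' @export
invert_linear_problem <- function(problem, prior, subject_id = "sub") {
  g <- as.matrix(problem$G)
  y <- as.numeric(problem$y)
  s2 <- problem$noise_sd^2
  tt <- length(y)
  p0 <- dens_precision(prior)
  pn <- symm(p0 + crossprod(g) / s2)
  ch <- chol(pn)
  u <- drop(p0 %*% prior$mean) + drop(crossprod(g, y)) / s2
  mu_n <- backsolve(ch, forwardsolve(t(ch), u))
  cov_n <- symm(chol2inv(ch))
  # ln p(y) = -T/2 ln(2 pi s^2) - (ln|Sigma0| - ln|Sigma_n|)/2
  #           - (y'y/s^2 + mu0' P0 mu0 - mu_n' Pn mu_n)/2
  log_ev <- -0.5 * tt * log(2 * pi * s2) -
    0.5 * (-log_det_stable(p0) + 2 * sum(log(diag(ch)))) -
    0.5 * (sum(y^2) / s2 + quad_form(prior$mean, p0) - sum(u * mu_n))
  first_level_unit(subject_id,
                   posterior = gaussian_density(drop(mu_n), cov_n, labels = prior$labels),
                   prior = prior,
                   free_energy = log_ev)
}

#' Generate first-level units from true parameters
#'
#' One shared T x P forward design G (orthonormal columns drawn from the
#' seed) maps each subject's true parameters to T noisy observations, which
#' are inverted exactly under the configured first-level prior. Posteriors are
#' exact Gaussians and log evidences exact scalars.
#'
#' @param theta_true N x P matrix of true subject parameters.
#' @param config A `sim_config`.
#' @param G Optional T x P forward matrix overriding the generated one.
#' @return List with `units` (list of `first_level_unit`) and `problems`
#'   (list of `y`/`G`/`noise_sd` per subject, for re-inversion).
#' @export
simulate_first_level <- function(theta_true, config, G = NULL) {
  stopifnot(inherits(config, "sim_config"))
  # separate stream from the group-level draws: consecutive study seeds must
  # not share substreams between levels
  set.seed((as.numeric(config$seed) * 7919 + 1237) %% 2147483647)
  n <- nrow(theta_true)
  p <- ncol(theta_true)
  if (is.null(G)) {
    G <- qr.Q(qr(matrix(stats::rnorm(config$n_obs * p), config$n_obs, p)))
  }
  if (qr(G)$rank < p) {
    warning("simulate_first_level: forward design is rank deficient; some ",
            "parameters are data-uninformative")
  }
  prior <- gaussian_density(config$prior_mean, diag(config$prior_var, p),
                            labels = paste0("theta", seq_len(p)))
  problems <- vector("list", n)
  units <- vector("list", n)
  for (i in seq_len(n)) {
    y <- drop(G %*% theta_true[i, ]) +
      stats::rnorm(nrow(G), sd = config$obs_noise_sd)
    problems[[i]] <- list(y = y, G = G, noise_sd = config$obs_noise_sd)
    units[[i]] <- invert_linear_problem(problems[[i]], prior,
                                        subject_id = sprintf("sub-%03d", i))
  }
  list(units = units, problems = problems, prior = prior)
}

#' Simulate a full hierarchical study
#'
#' Group sampling plus exact first-level inversion, bundled with the ground
#' truth for recovery and calibration studies.
#'
#' @param config A `sim_config` (see [simulation_config()]).
#' @return Object of class `peb_study`: `units`, `problems`, `covariates`,
#'   `theta_true`, `effects_true` (C x P), `parameter_labels`,
#'   `first_level_prior`, `config`.
#' @export
simulate_study <- function(config = simulation_config()) {
  grp <- simulate_group(config)
  fl <- simulate_first_level(grp$theta_true, config)
  structure(list(units = fl$units, problems = fl$problems,
                 covariates = grp$covariates, theta_true = grp$theta_true,
                 effects_true = config$effects,
                 parameter_labels = fl$prior$labels,
                 first_level_prior = fl$prior,
                 config = config),
            class = "peb_study")
}

#' @export
print.peb_study <- function(x, ...) {
  cat("<peb_study>", length(x$units), "subjects x",
      length(x$parameter_labels), "parameters;",
      ncol(x$effects_true) * nrow(x$effects_true), "true group effects\n")
  invisible(x)
}

#' Fit the group model to a simulated (or loaded) study
#'
#' Convenience wrapper: builds the mean-centred between-subjects design from
#' the study covariates, an all-on within-subject design, default priors, and
#' fits.
#'
#' @param study A `peb_study` (or list with `units` and `covariates`).
#' @param priors Optional `peb_priors`.
#' @param ... Passed to [fit_peb()].
#' @return A `peb_result`.
#' @export
fit_study <- function(study, priors = NULL, ...) {
  xb <- build_between_design(study$covariates, n = length(study$units))
  xw <- within_design(study$units[[1]]$posterior$labels)
  fit_peb(peb_model(study$units, build_full_design(xb, xw), priors), ...)
}
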