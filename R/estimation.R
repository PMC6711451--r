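# Second-level estimation: exact linear-Gaussian conditional over the group
# effects at fixed RFX hyperparameters, with damped Newton ascent on the
# log-precision hyperparameters gamma and a Laplace account of their
# uncertainty.
#
# Each subject's data enter only through its posterior/prior pair. Writing
# the subject's likelihood over its parameters as the exact ratio
#   p(Y_i | theta_i) = exp(F_i) N(theta_i; mu_i, Sigma_i) / N(theta_i; mu0, Sigma0)
# gives an (unnormalised) Gaussian kernel exp(-theta' Pd theta / 2 + theta' u)
# with Pd = P_i - P0 and u = P_i mu_i - P0 mu0. Pd need not be positive
# definite (data may be uninformative along some directions); the algebra
# below never inverts it, only M = Pd + Pi2 which is guarded by the RFX
# precision.

# Sufficient statistics per subject, computed once per model.
peb_suffstats <- function(model, eps = 1e-8) {
  xw <- model$design$within$XW
  xb <- model$design$between$XB
  stats <- lapply(seq_along(model$units), function(i) {
    u <- model$units[[i]]
    Pi <- dens_precision(u$posterior, eps = eps)
    P0 <- dens_precision(u$prior, eps = eps)
    mu_i <- u$posterior$mean
    mu_0 <- u$prior$mean
    fe <- if (is.finite(u$free_energy)) u$free_energy else 0
    list(
      Pd = symm(Pi - P0),
      u = drop(Pi %*% mu_i) - drop(P0 %*% mu_0),
      c0 = fe + 0.5 * (log_det_stable(Pi) - log_det_stable(P0) -
                         quad_form(mu_i, Pi) + quad_form(mu_0, P0)),
      xb = xb[i, ]
    )
  })
  list(stats = stats, XW = xw, n = length(stats),
       p = ncol(xw), c = ncol(xb))
}

# Effective group-level prior: clamp effects whose design column is all zero
# (e.g. parameters excluded by the within-subject design) at their prior mean
# with a near-delta variance, instead of removing them.
effective_group_prior <- function(model, off_floor = 1e-8) {
  eta <- model$priors$eta
  sigma3 <- as.matrix(model$priors$sigma3)
  zero_cols <- which(colSums(abs(model$design$X)) == 0)
  if (length(zero_cols)) {
    sigma3[zero_cols, ] <- 0
    sigma3[, zero_cols] <- 0
    diag(sigma3)[zero_cols] <- off_floor
  }
  gaussian_density(eta, sigma3, labels = colnames(model$design$X))
}

# Log marginal likelihood ln p(D | gamma) of the collapsed linear-Gaussian
# model, together with the conditional posterior N(m, S) over group effects.
# `prior` is the group-level prior density (possibly reduced/clamped).
peb_log_marginal <- function(ss, pi2, prior, eps = 1e-8) {
  p <- ss$p
  xw <- ss$XW
  ld_pi2 <- log_det_stable(pi2)
  pi3 <- ridge_inv(prior$cov, eps = eps)
  eta <- prior$mean
  cp <- length(eta)
  A <- matrix(0, cp, cp)
  r <- drop(pi3 %*% eta)
  s_sum <- 0
  c0 <- 0
  for (st in ss$stats) {
    M <- st$Pd + pi2
    ch <- tryCatch(chol(symm(M)), error = function(e) NULL)
    if (is.null(ch)) {
      stop("peb_log_marginal: subject-level precision Pd + Pi2 is not positive ",
           "definite; a subject's posterior is much broader than its prior ",
           "relative to the current RFX precision")
    }
    Minv_u <- backsolve(ch, forwardsolve(t(ch), st$u))
    Minv_pi2 <- backsolve(ch, forwardsolve(t(ch), pi2))
    W <- symm(pi2 - pi2 %*% Minv_pi2)         # = (Sigma2 + Pd^-1)^-1 when defined
    s_sum <- s_sum + 0.5 * ld_pi2 - sum(log(diag(ch))) +
      0.5 * sum(st$u * Minv_u)
    B <- crossprod(xw, W %*% xw)
    A <- A + kronecker(tcrossprod(st$xb), B)
    w <- drop(crossprod(xw, pi2 %*% Minv_u))
    r <- r + kronecker(st$xb, w)
    c0 <- c0 + st$c0
  }
  s_inv <- symm(pi3 + A)
  ch_s <- tryCatch(chol(s_inv), error = function(e) NULL)
  if (is.null(ch_s)) {
    ev <- eigen(s_inv, symmetric = TRUE, only.values = TRUE)$values
    stop("peb_log_marginal: combined group precision singular (eigenvalues in [",
         format(min(ev)), ", ", format(max(ev)), "])")
  }
  m <- backsolve(ch_s, forwardsolve(t(ch_s), r))
  S <- symm(chol2inv(ch_s))
  lml <- c0 + s_sum + 0.5 * log_det_stable(pi3) - sum(log(diag(ch_s))) +
    0.5 * sum(r * m) - 0.5 * quad_form(eta, pi3)
  list(mean = drop(m), cov = S, lml = lml)
}

#' Conditional group posterior at fixed RFX hyperparameters
#'
#' Exact linear-Gaussian conditional posterior over the group effects, and the
#' corresponding log marginal likelihood, with the RFX precision fixed at
#' \eqn{\Pi^{(2)} = \sum_j e^{\gamma_j} Q_j}. Each subject contributes
#' precision \eqn{X_i' (\Sigma^{(2)} + \tilde\Sigma_i)^{-1} X_i}, where
#' \eqn{\tilde\Sigma_i} is the subject's data uncertainty implied by its
#' posterior/prior pair, combined with the group prior N(eta, Sigma3).
#'
#' @param model A `peb_model`.
#' @param gamma Numeric vector of log-scaling hyperparameters, one per RFX
#'   precision component.
#' @param prior Optional `gaussian_density` overriding the model's group-level
#'   prior (used e.g. to re-invert under a reduced prior).
#' @param off_floor Variance floor for effects clamped by zeroed design columns.
#' @param eps Ridge for inversions.
#' @return List with `posterior` (`gaussian_density` over group effects) and
#'   `lml` (log marginal likelihood at this gamma, in nats).
#' @export
conditional_group_posterior <- function(model, gamma, prior = NULL,
                                        off_floor = 1e-8, eps = 1e-8) {
  stopifnot(inherits(model, "peb_model"))
  ss <- peb_suffstats(model, eps = eps)
  if (is.null(prior)) prior <- effective_group_prior(model, off_floor)
  pi2 <- rfx_precision(model$priors, gamma)
  fit <- peb_log_marginal(ss, pi2, prior, eps = eps)
  list(posterior = gaussian_density(fit$mean, fit$cov, labels = prior$labels),
       lml = fit$lml)
}

#' Fit a PEB model
#'
#' Maximises the second-level free energy by alternating the exact conditional
#' posterior over group effects with damped Newton ascent on the RFX
#' log-precision hyperparameters gamma (finite-difference gradient and
#' Hessian; the Newton step is halved until the objective does not decrease).
#' The returned free energy includes the Gaussian hyperprior on gamma and a
#' Laplace correction for its posterior uncertainty, so it approximates the
#' log evidence of the whole hierarchical model up to the subjects' stored
#' first-level accuracy terms.
#'
#' @param model A `peb_model`.
#' @param max_iter Maximum Newton iterations (default 64).
#' @param tol Convergence tolerance on the objective increase, nats
#'   (default 1e-4).
#' @param off_floor Variance floor for zero-design-column effects.
#' @param eps Ridge for matrix inversions.
#' @param fd_step Finite-difference step for gamma derivatives.
#' @param verbose Print per-iteration objective values.
#' @return Object of class `peb_result`: `group_posterior` (N(m, S) over the
#'   C*P effects), `gamma_posterior`, `rfx_estimate` (estimated between-subject
#'   variance per parameter), `free_energy` (nats), `empirical_priors` (the
#'   level-2-implied prior density for each subject), `iterations` (objective
#'   trace), `converged`, plus the model, the effective group prior
#'   (`prior_used`) and the gamma mode for downstream model reduction.
#' @export
fit_peb <- function(model, max_iter = 64, tol = 1e-4, off_floor = 1e-8,
                    eps = 1e-8, fd_step = 1e-3, verbose = FALSE) {
  stopifnot(inherits(model, "peb_model"))
  ss <- peb_suffstats(model, eps = eps)
  prior <- effective_group_prior(model, off_floor)
  gp <- model$priors$gamma_prior
  gp_prec <- ridge_inv(gp$cov, eps = eps)
  nj <- length(gp$mean)

  objective <- function(gamma) {
    pi2 <- rfx_precision(model$priors, gamma)
    fit <- peb_log_marginal(ss, pi2, prior, eps = eps)
    d <- gamma - gp$mean
    fit$lml - 0.5 * quad_form(d, gp_prec) - 0.5 * log_det_stable(gp$cov) -
      0.5 * nj * log(2 * pi)
  }

  gamma <- gp$mean
  h <- objective(gamma)
  if (!is.finite(h)) stop("fit_peb: objective is not finite at the hyperprior mean")
  trace <- h
  converged <- FALSE
  H <- diag(-1, nj)
  for (iter in seq_len(max_iter)) {
    gr <- numeric(nj)
    H <- matrix(0, nj, nj)
    # central finite differences for gradient and Hessian
    fp <- numeric(nj); fm <- numeric(nj)
    for (j in seq_len(nj)) {
      ej <- replace(numeric(nj), j, fd_step)
      fp[j] <- objective(gamma + ej)
      fm[j] <- objective(gamma - ej)
      gr[j] <- (fp[j] - fm[j]) / (2 * fd_step)
      H[j, j] <- (fp[j] - 2 * h + fm[j]) / fd_step^2
    }
    if (nj > 1) {
      for (j in seq_len(nj - 1)) for (k in (j + 1):nj) {
        ej <- replace(numeric(nj), j, fd_step)
        ek <- replace(numeric(nj), k, fd_step)
        H[j, k] <- H[k, j] <-
          (objective(gamma + ej + ek) - objective(gamma + ej - ek) -
             objective(gamma - ej + ek) + objective(gamma - ej - ek)) /
          (4 * fd_step^2)
      }
    }
    if (any(!is.finite(gr)) || any(!is.finite(H))) {
      stop("fit_peb: NaN in hyperparameter updates at iteration ", iter)
    }
    nH <- -symm(H)
    # guard: Newton needs a positive-definite curvature; ridge it if not
    ev_min <- min(eigen(nH, symmetric = TRUE, only.values = TRUE)$values)
    if (ev_min <= 1e-8) nH <- nH + diag(abs(ev_min) + 1e-6, nj)
    step <- drop(solve(nH, gr))
    # damp: halve until the objective does not decrease
    h_new <- -Inf
    for (k in 0:16) {
      cand <- gamma + step / 2^k
      h_new <- objective(cand)
      if (is.finite(h_new) && h_new >= h - 1e-12) break
    }
    if (!is.finite(h_new) || h_new < h - 1e-12) {
      break # no ascent direction improves: treat as converged at current gamma
    }
    gamma <- gamma + step / 2^k
    dh <- h_new - h
    h <- h_new
    trace <- c(trace, h)
    if (verbose) message(sprintf("  iter %2d: F = %.6f (dF = %.2e)", iter, h, dh))
    if (dh < tol) { converged <- TRUE; break }
  }

  pi2 <- rfx_precision(model$priors, gamma)
  fit <- peb_log_marginal(ss, pi2, prior, eps = eps)
  group_posterior <- gaussian_density(fit$mean, fit$cov, labels = prior$labels)
  nH <- -symm(H)
  ev_min <- min(eigen(nH, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min <= 1e-8) nH <- nH + diag(abs(ev_min) + 1e-6, nj)
  gamma_cov <- ridge_inv(nH, eps = eps)
  free_energy <- h + 0.5 * nj * log(2 * pi) - 0.5 * log_det_stable(nH)
  sigma2 <- ridge_inv(pi2, eps = eps)
  # level-2-implied (empirical) prior per subject: N(X_i m, Sigma2 + X_i S X_i')
  xw <- model$design$within$XW
  plabs <- model$design$within$parameter_labels
  emp <- lapply(seq_along(model$units), function(i) {
    xi <- kronecker(matrix(ss$stats[[i]]$xb, 1), xw) # P x CP
    gaussian_density(drop(xi %*% fit$mean),
                     symm(sigma2 + xi %*% fit$cov %*% t(xi)),
                     labels = plabs)
  })
  names(emp) <- vapply(model$units, `[[`, "", "subject_id")
  structure(list(
    group_posterior = group_posterior,
    gamma_posterior = gaussian_density(gamma, gamma_cov, labels = gp$labels),
    rfx_estimate = stats::setNames(diag(sigma2), plabs),
    free_energy = free_energy,
    empirical_priors = emp,
    iterations = trace,
    converged = converged,
    gamma = gamma,
    lml_at_mode = fit$lml,
    prior_used = prior,
    model = model,
    settings = list(max_iter = max_iter, tol = tol, off_floor = off_floor,
                    eps = eps, fd_step = fd_step)
  ), class = "peb_result")
}

#' @export
print.peb_result <- function(x, ...) {
  cat("<peb_result> F =", format(x$free_energy),
      if (x$converged) "(converged," else "(NOT converged,",
      length(x$iterations) - 1, "iterations)\n")
  cat("  group effects:", length(x$group_posterior$mean),
      "; RFX variance range [", format(min(x$rfx_estimate), digits = 3), ", ",
      format(max(x$rfx_estimate), digits = 3), "]\n")
  invisible(x)
}

#' Iteratively re-estimate first-level units under empirical priors
#'
#' For simulation studies with an exact conjugate linear first level: each
#' round re-inverts every subject's linear problem under the empirical prior
#' implied by the current group fit, then re-fits the group model. On these
#' linear problems the total free energy is expected to be non-decreasing
#' across rounds; if it decreases the procedure stops and returns the best
#' round.
#'
#' @param study A study from [simulate_study()] (carries the linear first-level
#'   problems alongside the units).
#' @param xb,xw Between- and within-subject designs; default built from the
#'   study's covariates with mean-centring, and all parameters on.
#' @param priors Optional `peb_priors`.
#' @param n_rounds Number of re-estimation rounds (>= 1).
#' @param ... Passed to [fit_peb()].
#' @return List with `units` (re-estimated), `fit` (final `peb_result`),
#'   `f_trace` (free energy per round, round 0 = original units) and
#'   `rounds_run`.
#' @export
refit_with_empirical_priors <- function(study, xb = NULL, xw = NULL,
                                        priors = NULL, n_rounds = 1, ...) {
  stopifnot(n_rounds >= 1, !is.null(study$problems))
  if (is.null(xb)) xb <- build_between_design(study$covariates)
  if (is.null(xw)) xw <- within_design(study$parameter_labels)
  design <- build_full_design(xb, xw)
  units <- study$units
  # group-level priors are fixed at round 0: re-estimating units under
  # empirical priors must not narrow the group prior itself
  if (is.null(priors)) priors <- default_priors(units[[1]]$prior, ncol(xb$XB))
  best <- NULL
  f_trace <- numeric(0)
  for (round in 0:n_rounds) {
    fit <- fit_peb(peb_model(units, design, priors), ...)
    f_trace <- c(f_trace, fit$free_energy)
    if (is.null(best) || fit$free_energy >= best$fit$free_energy - 1e-9) {
      best <- list(units = units, fit = fit, round = round)
    } else {
      break # divergence: keep the best round seen
    }
    if (round == n_rounds) break
    units <- lapply(seq_along(units), function(i) {
      invert_linear_problem(study$problems[[i]],
                            prior = fit$empirical_priors[[i]],
                            subject_id = units[[i]]$subject_id)
    })
  }
  list(units = best$units, fit = best$fit, f_trace = f_trace,
       rounds_run = length(f_trace) - 1)
}

#' Tabular report of group effects
#'
#' One row per (covariate, parameter) cell: posterior mean, sd, and the
#' posterior probability that the effect is non-zero in the direction of its
#' mean (Phi(|mean|/sd)).
#'
#' @param result A `peb_result` or `bma_result`.
#' @return A data.frame with columns covariate, parameter, mean, sd,
#'   probability.
#' @export
peb_report <- function(result) {
  dens <- if (inherits(result, "bma_result")) result$density else result$group_posterior
  parts <- strsplit(dens$labels, ":", fixed = TRUE)
  sd <- sqrt(pmax(diag(dens$cov), 0))
  data.frame(
    covariate = vapply(parts, `[`, "", 1),
    parameter = vapply(parts, function(x) paste(x[-1], collapse = ":"), ""),
    mean = dens$mean,
    sd = sd,
    probability = ifelse(sd > 0, stats::pnorm(abs(dens$mean) / sd), 1)
  )
}
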