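# Leave-one-out cross-validation: predict a held-out subject's covariate from
# their first-level posterior under the group model fitted to the remaining
# subjects. The unknown covariate value is given a Gaussian prior matched to
# the training distribution and inferred on a dense grid from the evidence of
# the held-out subject's posterior under the empirical prior each candidate
# value implies.

#' Leave-one-out cross-validation of a between-subject covariate
#'
#' For each fold, the group model is fitted to N-1 subjects with the target
#' covariate mean-centred over the training set. The left-out subject's
#' target value x* is treated as unknown with prior N(0, sd_train^2); for
#' each of `grid_points` candidate values spanning +/- `grid_span` training
#' standard deviations, the subject's design row is rebuilt, the implied
#' empirical prior N(X_i(x*) m, Sigma2 + X_i S X_i') formed, and the log
#' evidence of the subject's first-level posterior under that prior computed.
#' Softmax over the grid yields a posterior over x*, reported as its mean and
#' central credible interval. Out-of-sample performance is summarised by the
#' Pearson correlation of predicted versus actual (mean-centred) covariate
#' values across folds, with a two-sided p-value.
#'
#' @param units List of `first_level_unit`s (one per subject).
#' @param covariates Data frame of between-subject covariates (one row per
#'   subject; not yet centred), containing `target_covariate`.
#' @param target_covariate Name of the covariate to predict.
#' @param cells Optional character vector of parameter labels used for
#'   prediction (the within-subject design diagonal); default all.
#' @param priors Optional `peb_priors` for each fold's fit.
#' @param grid_points Number of grid points for the x* posterior (default 64).
#' @param grid_span Half-width of the grid in training standard deviations
#'   (default 4).
#' @param level Credible-interval level (default 0.90).
#' @param ... Passed to [fit_peb()].
#' @return Object of class `loo_result`: `predictions` (data.frame with
#'   subject, actual, predicted, lower, upper, covered), `correlation`,
#'   `p_value`, `coverage` (fraction of subjects whose actual value fell in
#'   the interval), `level`.
#' @export
loo_cv <- function(units, covariates, target_covariate, cells = NULL,
                   priors = NULL, grid_points = 64, grid_span = 4,
                   level = 0.90, ...) {
  n <- length(units)
  if (n < 3) stop("loo_cv: need at least 3 subjects")
  covariates <- as.data.frame(covariates)
  if (!target_covariate %in% names(covariates)) {
    stop("loo_cv: covariate '", target_covariate, "' not found")
  }
  if (nrow(covariates) != n) stop("loo_cv: covariate rows must match units")
  target <- as.numeric(covariates[[target_covariate]])
  other_names <- setdiff(names(covariates), c(target_covariate, "subject_id"))
  plabs <- units[[1]]$posterior$labels
  on <- if (is.null(cells)) rep(1, length(plabs)) else as.numeric(plabs %in% cells)
  xw <- within_design(plabs, on = on)
  alpha <- (1 - level) / 2

  preds <- vector("list", n)
  for (i in seq_len(n)) {
    train <- setdiff(seq_len(n), i)
    t_mean <- mean(target[train])
    t_sd <- stats::sd(target[train])
    if (!is.finite(t_sd) || t_sd < 1e-12) {
      stop("loo_cv: target covariate is (near-)constant over the training set")
    }
    train_cov <- covariates[train, c(target_covariate, other_names), drop = FALSE]
    other_means <- vapply(other_names,
                          function(nm) mean(as.numeric(train_cov[[nm]])), numeric(1))
    xb <- build_between_design(train_cov, mean_centre = TRUE)
    fit <- fit_peb(peb_model(units[train], build_full_design(xb, xw), priors), ...)
    sigma2 <- ridge_inv(rfx_precision(fit$model$priors, fit$gamma))
    m <- fit$group_posterior$mean
    S <- fit$group_posterior$cov

    # held-out subject's sufficient statistics
    u_i <- units[[i]]
    p_post <- dens_precision(u_i$posterior)
    p_prior <- dens_precision(u_i$prior)
    pd <- symm(p_post - p_prior)
    uu <- drop(p_post %*% u_i$posterior$mean) - drop(p_prior %*% u_i$prior$mean)

    grid <- seq(-grid_span * t_sd, grid_span * t_sd, length.out = grid_points)
    other_centred <- vapply(other_names, function(nm) {
      as.numeric(covariates[[nm]][i]) - other_means[[nm]]
    }, numeric(1))
    logp <- vapply(grid, function(x_star) {
      xb_row <- c(1, x_star, other_centred)
      xi <- kronecker(matrix(xb_row, 1), xw$XW) # P x CP
      a <- drop(xi %*% m)
      v <- symm(sigma2 + xi %*% S %*% t(xi))
      v_inv <- ridge_inv(v)
      mm <- symm(pd + v_inv)
      ch <- chol(mm)
      b <- uu + drop(v_inv %*% a)
      mb <- backsolve(ch, forwardsolve(t(ch), b))
      0.5 * (log_det_stable(v_inv) - 2 * sum(log(diag(ch)))) +
        0.5 * (sum(b * mb) - quad_form(a, v_inv)) +
        stats::dnorm(x_star, 0, t_sd, log = TRUE)
    }, numeric(1))
    w <- softmax_logp(logp)
    pred_mean <- sum(w * grid)
    cw <- cumsum(w)
    q_of <- function(p) stats::approx(cw, grid, xout = p, rule = 2, ties = "ordered")$y
    lo <- q_of(alpha); hi <- q_of(1 - alpha)
    actual <- target[i] - t_mean
    preds[[i]] <- data.frame(
      subject = if (!is.null(covariates$subject_id)) as.character(covariates$subject_id[i])
                else sprintf("sub-%03d", i),
      actual = actual, predicted = pred_mean, lower = lo, upper = hi,
      covered = actual >= lo & actual <= hi)
  }
  predictions <- do.call(rbind, preds)
  ct <- stats::cor.test(predictions$predicted, predictions$actual)
  structure(list(predictions = predictions,
                 correlation = unname(ct$estimate),
                 p_value = ct$p.value,
                 coverage = mean(predictions$covered),
                 level = level),
            class = "loo_result")
}

#' @export
print.loo_result <- function(x, ...) {
  cat("<loo_result>", nrow(x$predictions), "folds: r =",
      format(x$correlation, digits = 3), ", p =",
      format(x$p_value, digits = 3), ";",
      sum(x$predictions$covered), "/", nrow(x$predictions),
      "subjects inside the", paste0(100 * x$level, "%"),
      "credible interval\n")
  invisible(x)
}

#' Write LOO predictions to CSV
#' @param loo A `loo_result`.
#' @param path Output CSV path.
#' @export
write_loo_csv <- function(loo, path) {
  utils::write.csv(loo$predictions, path, row.names = FALSE)
  invisible(path)
}
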