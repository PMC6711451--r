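# Internal numerical helpers shared by all modules.

# Symmetrise a matrix that should be symmetric up to floating-point error.
symm <- function(m) (m + t(m)) / 2

#' Stable log-determinant of a symmetric positive-(semi)definite matrix
#'
#' Computes `log(det(m))` via a Cholesky factorisation, falling back to an
#' eigendecomposition when the matrix is semi-definite to working tolerance.
#' Fails loudly when the matrix is indefinite beyond tolerance, rather than
#' returning a complex or silently wrong value.
#'
#' @param m Symmetric positive-(semi)definite numeric matrix.
#' @param tol Relative tolerance on negative eigenvalues; eigenvalues below
#'   `-tol * max(abs(eigenvalues))` raise an error.
#' @return The natural-log determinant (a scalar, in nats when the matrix is a
#'   precision or covariance entering an evidence computation).
#' @export
log_det_stable <- function(m, tol = 1e-8) {
  m <- as.matrix(m)
  stopifnot(nrow(m) == ncol(m))
  if (nrow(m) == 0L) return(0)
  ch <- tryCatch(chol(symm(m)), error = function(e) NULL)
  if (!is.null(ch)) return(2 * sum(log(diag(ch))))
  ev <- eigen(symm(m), symmetric = TRUE, only.values = TRUE)$values
  scale <- max(abs(ev), .Machine$double.xmin)
  if (min(ev) < -tol * scale) {
    stop("log_det_stable: matrix is indefinite (min eigenvalue ",
         format(min(ev)), ", max ", format(max(ev)), ")")
  }
  sum(log(pmax(ev, tol * scale)))
}

# Ridge-regularised inverse of a symmetric matrix. A plain Cholesky is tried
# first (exact for positive-definite input, whatever the scale spread); only
# when that fails is eps * mean(diag) * I added before factorising again.
# Variational first-level covariances are frequently near-singular; the ridge
# keeps every inversion finite without perturbing well-conditioned inputs.
ridge_chol <- function(m, eps = 1e-8, what = "ridge_inv") {
  m <- symm(as.matrix(m))
  ch <- tryCatch(chol(m), error = function(e) NULL)
  if (!is.null(ch)) return(ch)
  d <- mean(diag(m))
  if (!is.finite(d) || d <= 0) d <- 1
  ch <- tryCatch(chol(m + diag(eps * d, nrow(m))), error = function(e) NULL)
  if (is.null(ch)) {
    stop(what, ": matrix not positive definite after ridge ",
         "(eps = ", format(eps), ", mean diag = ", format(d), ")")
  }
  ch
}

ridge_inv <- function(m, eps = 1e-8) {
  symm(chol2inv(ridge_chol(m, eps, "ridge_inv")))
}

# Solve m %*% x = b with the same ridge guard.
ridge_solve <- function(m, b, eps = 1e-8) {
  ch <- ridge_chol(m, eps, "ridge_solve")
  backsolve(ch, forwardsolve(t(ch), b))
}

# Softmax over log-evidences, guarded against overflow: returns normalised
# posterior probabilities under uniform (or supplied log) priors.
softmax_logp <- function(logf, log_prior = NULL) {
  if (!is.null(log_prior)) logf <- logf + log_prior
  z <- exp(logf - max(logf))
  z / sum(z)
}

quad_form <- function(x, m) drop(crossprod(x, m %*% x))
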