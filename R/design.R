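#' Between-subjects design matrix
#'
#' Builds the N x C between-subjects design matrix XB from a covariate table.
#' The first column is always a constant column of ones modelling the
#' commonalities across subjects; remaining columns are the supplied
#' covariates in order. Non-constant columns are mean-centred by default, in
#' which case the constant column is interpretable as the group mean and the
#' covariate effects add to or subtract from it; without centring it is the
#' baseline/intercept.
#'
#' Categorical covariates must be encoded numerically by the caller (e.g.
#' -1/+1); the constructor does not dummy-code, keeping column order and
#' interpretation explicit.
#'
#' @param covariates Data frame (or named list) of numeric covariates, one row
#'   per subject; an optional `subject_id` column is carried through as row
#'   labels. May be `NULL` for a mean-only design (requires `n`).
#' @param mean_centre Logical scalar or vector (one per covariate): centre the
#'   covariate columns that follow the constant term. Default `TRUE` for all.
#' @param n Number of subjects when `covariates` is `NULL`.
#' @return An object of class `between_design` with elements `XB`,
#'   `covariate_names`, `mean_centred`, `column_norms` (Euclidean norm of each
#'   column, recorded for optional prior rescaling), `subject_ids`.
#' @export
build_between_design <- function(covariates = NULL, mean_centre = TRUE, n = NULL) {
  if (!is.null(covariates) && ncol(as.data.frame(covariates)) == 0) covariates <- NULL
  if (is.null(covariates)) {
    if (is.null(n) || n < 2) stop("build_between_design: need covariates or n >= 2")
    xb <- matrix(1, n, 1, dimnames = list(NULL, "mean"))
    return(structure(list(XB = xb, covariate_names = "mean",
                          mean_centred = FALSE, column_norms = sqrt(n),
                          subject_ids = paste0("sub-", seq_len(n))),
                     class = "between_design"))
  }
  covariates <- as.data.frame(covariates)
  ids <- if ("subject_id" %in% names(covariates)) {
    as.character(covariates$subject_id)
  } else paste0("sub-", seq_len(nrow(covariates)))
  covariates <- covariates[, setdiff(names(covariates), "subject_id"), drop = FALSE]
  n <- nrow(covariates)
  if (n < 2) stop("build_between_design: need at least 2 subjects")
  if (anyNA(covariates)) {
    bad <- names(covariates)[vapply(covariates, anyNA, logical(1))]
    stop("build_between_design: missing values in covariate(s): ",
         paste(bad, collapse = ", "))
  }
  cn <- names(covariates)
  centre <- rep_len(as.logical(mean_centre), length(cn))
  xc <- as.matrix(covariates)
  storage.mode(xc) <- "double"
  for (j in seq_along(cn)) if (centre[j]) xc[, j] <- xc[, j] - mean(xc[, j])
  xb <- cbind(mean = 1, xc)
  const <- apply(xb[, -1, drop = FALSE], 2, function(v) max(v) - min(v) < 1e-12)
  if (any(const)) {
    warning("build_between_design: covariate(s) constant after centring ",
            "(collinear with the mean column): ",
            paste(cn[const], collapse = ", "))
  }
  # rank check over the non-degenerate columns (constant ones already warned)
  keep <- c(TRUE, !const)
  qrx <- qr(xb[, keep, drop = FALSE])
  if (qrx$rank < sum(keep)) {
    dep <- colnames(xb[, keep, drop = FALSE])[qrx$pivot[(qrx$rank + 1):sum(keep)]]
    stop("build_between_design: design is rank deficient; dependent column(s): ",
         paste(dep, collapse = ", "))
  }
  structure(list(XB = xb, covariate_names = colnames(xb),
                 mean_centred = c(FALSE, centre),
                 column_norms = sqrt(colSums(xb^2)),
                 subject_ids = ids),
            class = "between_design")
}

#' @export
print.between_design <- function(x, ...) {
  cat("<between_design>", nrow(x$XB), "subjects x", ncol(x$XB), "covariates:",
      paste(x$covariate_names, collapse = ", "), "\n")
  invisible(x)
}

#' Within-subject design: which parameters receive group-level effects
#'
#' A binary (typically diagonal) P x P matrix whose diagonal selects the
#' subject-level parameters that are modelled at the group level. The identity
#' matrix (default) lets every between-subject effect act on every parameter.
#'
#' @param parameter_labels Character vector of the P selected parameter names.
#' @param on Binary vector over parameters (diagonal of XW); default all 1.
#' @param XW Optional explicit binary matrix overriding `on`.
#' @return Object of class `within_design` with `XW` and `parameter_labels`.
#' @export
within_design <- function(parameter_labels, on = NULL, XW = NULL) {
  p <- length(parameter_labels)
  if (is.null(XW)) {
    if (is.null(on)) on <- rep(1, p)
    if (length(on) != p || !all(on %in% c(0, 1))) {
      stop("within_design: `on` must be a binary vector of length ", p)
    }
    XW <- diag(as.numeric(on), p)
  } else {
    XW <- as.matrix(XW)
    if (!all(XW %in% c(0, 1)) || nrow(XW) != p) {
      stop("within_design: XW must be binary with ", p, " rows")
    }
  }
  dimnames(XW) <- list(parameter_labels, parameter_labels)
  structure(list(XW = XW, parameter_labels = parameter_labels),
            class = "within_design")
}

#' Full second-level design matrix X = XB (x) XW
#'
#' Kronecker product of the between- and within-subject designs: XW is
#' replicated for every element of XB, giving an (N*P) x (C*P) matrix. Rows
#' are ordered subject-major (all parameters of subject 1, then subject 2,
#' ...), columns covariate-major (all parameters of covariate 1, then
#' covariate 2, ...). Each column is one group-level effect of one covariate
#' on one parameter.
#'
#' @param xb A `between_design`.
#' @param xw A `within_design`.
#' @return Object of class `full_design` with `X`, `row_labels`
#'   (subject:parameter), `col_labels` (covariate:parameter), and the parts.
#' @export
build_full_design <- function(xb, xw) {
  stopifnot(inherits(xb, "between_design"), inherits(xw, "within_design"))
  X <- kronecker(xb$XB, xw$XW)
  row_labels <- as.vector(t(outer(xb$subject_ids, xw$parameter_labels, paste, sep = ":")))
  col_labels <- as.vector(t(outer(xb$covariate_names, xw$parameter_labels, paste, sep = ":")))
  dimnames(X) <- list(row_labels, col_labels)
  structure(list(X = X, between = xb, within = xw,
                 row_labels = row_labels, col_labels = col_labels),
            class = "full_design")
}

#' @export
print.full_design <- function(x, ...) {
  cat("<full_design>", nrow(x$X), "x", ncol(x$X), " (",
      nrow(x$between$XB), " subjects x ", length(x$within$parameter_labels),
      " parameters; ", ncol(x$between$XB), " covariates)\n", sep = "")
  invisible(x)
}

#' Write a design matrix to CSV for audit
#'
#' @param design A `between_design` or `full_design`.
#' @param path Output CSV path.
#' @export
write_design_csv <- function(design, path) {
  m <- if (inherits(design, "full_design")) design$X else design$XB
  utils::write.csv(as.data.frame(m), path, row.names = TRUE)
  invisible(path)
}
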