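# Persistent study container: subjects' posterior/prior densities, the
# covariate table, parameter labels and provenance, serialised as JSON with
# full-precision doubles so a write/read round trip reproduces every array
# exactly at the on-disk precision. Covariates travel as a plain table and
# can also be read from CSV.

CONTAINER_VERSION <- "1.0"

#' Bundle units, covariates and provenance into a study container
#'
#' @param units List of `first_level_unit`s.
#' @param covariates Optional data frame of between-subject covariates (one
#'   row per subject).
#' @param provenance Named list recorded verbatim (seed, settings, versions).
#' @return Object of class `study_container`.
#' @export
study_container <- function(units, covariates = NULL, provenance = list()) {
  stopifnot(length(units) >= 1)
  lapply(units, function(u) stopifnot(inherits(u, "first_level_unit")))
  labs <- units[[1]]$posterior$labels
  for (u in units) {
    if (!identical(u$posterior$labels, labs)) {
      stop("study_container: unit '", u$subject_id, "' has mismatched labels")
    }
  }
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != length(units)) {
      stop("study_container: ", nrow(covariates), " covariate rows for ",
           length(units), " subjects")
    }
  }
  provenance$tool <- "peblm"
  provenance$tool_version <- as.character(utils::packageVersion("peblm"))
  structure(list(version = CONTAINER_VERSION, units = units,
                 covariates = covariates, parameter_labels = labs,
                 provenance = provenance),
            class = "study_container")
}

#' @export
print.study_container <- function(x, ...) {
  cat("<study_container> v", x$version, ": ", length(x$units), " subjects x ",
      length(x$parameter_labels), " parameters\n", sep = "")
  invisible(x)
}

#' Write a study container to JSON
#'
#' @param container A `study_container` (or a `peb_study`, whose units and
#'   covariates are bundled automatically).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_container <- function(container, path) {
  if (inherits(container, "peb_study")) {
    container <- study_container(container$units, container$covariates,
                                 provenance = list(seed = container$config$seed))
  }
  stopifnot(inherits(container, "study_container"))
  subjects <- lapply(container$units, function(u) {
    list(subject_id = u$subject_id,
         posterior_mean = u$posterior$mean,
         posterior_cov = u$posterior$cov,
         prior_mean = u$prior$mean,
         prior_cov = u$prior$cov,
         free_energy = u$free_energy)
  })
  obj <- list(version = container$version,
              parameter_labels = container$parameter_labels,
              subjects = subjects,
              covariates = container$covariates,
              provenance = container$provenance)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       na = "null", matrix = "rowmajor")
  invisible(path)
}

#' Read a study container from JSON
#'
#' Validates the format version and per-subject array shapes; truncated or
#' malformed files raise a parse error rather than returning partial data.
#'
#' @param path Path to a container written by [write_container()].
#' @return A `study_container`.
#' @export
read_container <- function(path) {
  if (!file.exists(path)) stop("read_container: no such file: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyMatrix = TRUE)
  if (is.null(obj$version)) stop("read_container: missing format version field")
  if (!identical(as.character(obj$version), CONTAINER_VERSION)) {
    stop("read_container: container version ", obj$version,
         " needs upgrading; this build reads version ", CONTAINER_VERSION)
  }
  labs <- as.character(obj$parameter_labels)
  p <- length(labs)
  subjects <- obj$subjects
  if (is.data.frame(subjects)) {
    subjects <- lapply(seq_len(nrow(subjects)), function(i) {
      lapply(subjects, function(col) if (is.list(col)) col[[i]] else col[i])
    })
  }
  units <- lapply(subjects, function(s) {
    for (fld in c("posterior_mean", "prior_mean")) {
      if (length(s[[fld]]) != p) {
        stop("read_container: subject '", s$subject_id, "' field ", fld,
             " has length ", length(s[[fld]]), ", expected ", p)
      }
    }
    for (fld in c("posterior_cov", "prior_cov")) {
      m <- as.matrix(s[[fld]])
      if (!all(dim(m) == p)) {
        stop("read_container: subject '", s$subject_id, "' field ", fld,
             " is ", nrow(m), "x", ncol(m), ", expected ", p, "x", p)
      }
    }
    first_level_unit(
      s$subject_id,
      posterior = gaussian_density(as.numeric(s$posterior_mean),
                                   as.matrix(s$posterior_cov), labels = labs),
      prior = gaussian_density(as.numeric(s$prior_mean),
                               as.matrix(s$prior_cov), labels = labs),
      free_energy = if (is.null(s$free_energy)) NA_real_ else as.numeric(s$free_energy))
  })
  covariates <- if (!is.null(obj$covariates)) as.data.frame(obj$covariates) else NULL
  sc <- study_container(units, covariates,
                        provenance = as.list(obj$provenance))
  sc$version <- as.character(obj$version)
  sc
}

#' Read a between-subject covariate table from CSV
#'
#' The header row names the covariates; a `subject_id` column is mandatory.
#'
#' @param path CSV path.
#' @return Data frame with `subject_id` first.
#' @export
read_covariates_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"subject_id" %in% names(df)) {
    stop("read_covariates_csv: a subject_id column is mandatory")
  }
  df[, c("subject_id", setdiff(names(df), "subject_id")), drop = FALSE]
}

#' Write a covariate table to CSV
#' @param covariates Data frame (a `subject_id` column is added if absent).
#' @param path CSV path.
#' @export
write_covariates_csv <- function(covariates, path) {
  covariates <- as.data.frame(covariates)
  if (!"subject_id" %in% names(covariates)) {
    covariates <- cbind(subject_id = sprintf("sub-%03d", seq_len(nrow(covariates))),
                        covariates)
  }
  utils::write.csv(covariates, path, row.names = FALSE)
  invisible(path)
}
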