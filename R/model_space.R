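# Factorial model spaces, the commonalities x differences comparison grid,
# family pooling, Bayesian model averaging and the greedy search over
# reduced models.

#' Factorial model space
#'
#' Enumerates every combination of factor levels into on/off masks over a set
#' of parameter cells, optionally appending an all-off null model. A model's
#' on-set is the intersection of the cell sets of its chosen levels, so e.g.
#' three factors with three levels each plus the null give 3*3*3 + 1 = 28
#' models. Ordering is factor-major (the last factor varies fastest), null
#' last.
#'
#' @param factors Named list; each element is a named list of levels, each
#'   level a character vector of cell labels it switches on.
#' @param cells Character vector of all cell labels the masks range over.
#' @param include_null Append the all-off null model (default TRUE).
#' @return Object of class `model_space`: `specs` (list of `model_spec`),
#'   `factors`, `levels` (data.frame of level choices per model), `cells`,
#'   `includes_null`.
#' @export
factorial_space <- function(factors, cells, include_null = TRUE) {
  stopifnot(length(factors) >= 1)
  for (f in names(factors)) {
    if (!length(factors[[f]])) stop("factorial_space: factor '", f, "' has no levels")
    for (lv in names(factors[[f]])) {
      unknown <- setdiff(factors[[f]][[lv]], cells)
      if (length(unknown)) {
        stop("factorial_space: level '", lv, "' of factor '", f,
             "' names unknown cells: ", paste(unknown, collapse = ", "))
      }
    }
  }
  level_names <- lapply(factors, names)
  # factor-major: first factor varies slowest
  grid <- expand.grid(rev(level_names), stringsAsFactors = FALSE)[, rev(seq_along(factors)), drop = FALSE]
  names(grid) <- names(factors)
  specs <- lapply(seq_len(nrow(grid)), function(i) {
    on <- cells
    for (f in names(factors)) on <- intersect(on, factors[[f]][[grid[i, f]]])
    model_spec(paste(unlist(grid[i, ]), collapse = " & "),
               as.integer(cells %in% on))
  })
  if (include_null) {
    specs <- c(specs, list(model_spec("null", rep(0L, length(cells)))))
    grid <- rbind(grid, stats::setNames(as.list(rep("null", ncol(grid))), names(grid)))
  }
  structure(list(specs = specs, factors = factors, levels = grid,
                 cells = cells, includes_null = include_null),
            class = "model_space")
}

#' @export
print.model_space <- function(x, ...) {
  cat("<model_space>", length(x$specs), "models over", length(x$cells),
      "cells (", paste(names(x$factors), collapse = " x "),
      if (x$includes_null) "+ null" else "", ")\n")
  invisible(x)
}

#' @export
length.model_space <- function(x) length(x$specs)

#' Number of models in an exhaustive on/off enumeration
#'
#' The 2^k count of distinct reduced models over k binary cells - the
#' combinatorial bound that makes exhaustive comparison infeasible for large
#' parameter sets (e.g. 2^40 ~ 1.1e12) and motivates the greedy search.
#'
#' @param n_cells Number of binary cells.
#' @return 2^n_cells as a double.
#' @export
exhaustive_model_count <- function(n_cells) 2^as.numeric(n_cells)

#' Commonalities x differences comparison grid
#'
#' Crosses a model space over the common-effect (group mean) block with a
#' model space over a covariate-difference block: entry (i, j) is the reduced
#' GLM whose common-block cells follow model i and whose difference-block
#' cells follow model j; cells in neither block (nuisance covariates) stay on
#' in every model. All models are scored by Bayesian model reduction and the
#' joint posterior probability matrix is obtained by softmax over the evidence
#' under uniform model priors. Marginal posteriors per axis are obtained by
#' summing over the other axis and renormalising.
#'
#' @param peb A fitted `peb_result`.
#' @param common_space,diff_space `model_space`s whose masks are over
#'   `common_cells` and `diff_cells` respectively.
#' @param common_cells,diff_cells Disjoint character vectors of group-effect
#'   labels (elements of `peb$group_posterior$labels`).
#' @return Object of class `comparison_grid`: `prob` (joint posterior matrix),
#'   `delta_f` (evidence matrix, nats relative to the full model),
#'   `common_marginal`, `diff_marginal`, `posteriors` (list-matrix of reduced
#'   posteriors), spaces and cells.
#' @export
compare_grid <- function(peb, common_space, diff_space, common_cells, diff_cells) {
  stopifnot(inherits(peb, "peb_result"),
            inherits(common_space, "model_space"),
            inherits(diff_space, "model_space"))
  labels <- peb$group_posterior$labels
  if (length(overlap <- intersect(common_cells, diff_cells))) {
    stop("compare_grid: cells assigned to both blocks: ",
         paste(overlap, collapse = ", "))
  }
  bad <- setdiff(c(common_cells, diff_cells), labels)
  if (length(bad)) stop("compare_grid: unknown cells: ", paste(bad, collapse = ", "))
  if (length(common_space$cells) != length(common_cells) ||
      length(diff_space$cells) != length(diff_cells)) {
    stop("compare_grid: space mask length must equal its cell block size")
  }
  ic <- match(common_cells, labels)
  id <- match(diff_cells, labels)
  nc <- length(common_space$specs)
  nd <- length(diff_space$specs)
  delta_f <- matrix(NA_real_, nc, nd)
  posts <- vector("list", nc * nd)
  base_mask <- rep(1L, length(labels))
  for (i in seq_len(nc)) {
    for (j in seq_len(nd)) {
      mask <- base_mask
      mask[ic] <- common_space$specs[[i]]$on_mask
      mask[id] <- diff_space$specs[[j]]$on_mask
      red <- bmr_reduce_result(peb, mask)
      delta_f[i, j] <- red$delta_f
      posts[[(j - 1) * nc + i]] <- red$posterior
    }
  }
  prob <- matrix(softmax_logp(as.vector(delta_f)), nc, nd)
  dimnames(prob) <- dimnames(delta_f) <-
    list(vapply(common_space$specs, `[[`, "", "name"),
         vapply(diff_space$specs, `[[`, "", "name"))
  structure(list(prob = prob, delta_f = delta_f,
                 common_marginal = rowSums(prob) / sum(prob),
                 diff_marginal = colSums(prob) / sum(prob),
                 posteriors = posts,
                 common_space = common_space, diff_space = diff_space,
                 common_cells = common_cells, diff_cells = diff_cells),
            class = "comparison_grid")
}

#' @export
print.comparison_grid <- function(x, ...) {
  cat("<comparison_grid>", nrow(x$prob), "x", ncol(x$prob), "models (",
      length(x$prob), "reduced GLMs ); best joint p =",
      format(max(x$prob), digits = 3), "\n")
  invisible(x)
}

#' Write a comparison grid to CSV (joint matrix plus the two marginals)
#' @param grid A `comparison_grid`.
#' @param path Output CSV path.
#' @export
write_grid_csv <- function(grid, path) {
  m <- rbind(cbind(grid$prob, common_marginal = grid$common_marginal),
             c(grid$diff_marginal, NA))
  rownames(m)[nrow(m)] <- "diff_marginal"
  utils::write.csv(as.data.frame(m), path, row.names = TRUE)
  invisible(path)
}

#' Family-wise posterior pooling
#'
#' Groups models into families and compares the pooled evidence of each
#' family under the prior that each family is a priori equally likely: model
#' priors are reweighted to (1/K)/|family|, posteriors computed by softmax of
#' the log evidences plus log priors, and family posteriors are the sums of
#' their members'.
#'
#' @param delta_f Numeric vector of model log evidences (nats; any common
#'   offset cancels).
#' @param family Vector (same length) of family identifiers.
#' @return Named numeric vector of family posterior probabilities (sums to 1).
#' @export
family_pool <- function(delta_f, family) {
  stopifnot(length(delta_f) == length(family))
  family <- as.character(family)
  fams <- unique(family)
  sizes <- table(family)
  if (any(sizes == 0)) stop("family_pool: empty family")
  log_prior <- log(1 / length(fams)) - log(as.numeric(sizes[family]))
  post <- softmax_logp(delta_f, log_prior)
  out <- vapply(fams, function(f) sum(post[family == f]), numeric(1))
  out / sum(out)
}

#' Family pooling of a comparison grid along both axes
#'
#' Assigns each common-axis model and each difference-axis model to a family
#' and pools the joint grid: entry (m, n) is the pooled probability that the
#' common-effect cells follow family m and the difference cells follow family
#' n, with all (m, n) family pairs a priori equally likely.
#'
#' @param grid A `comparison_grid`.
#' @param common_family,diff_family Family id per model of the respective axis.
#' @return Family-by-family posterior probability matrix (sums to 1).
#' @export
family_grid <- function(grid, common_family, diff_family) {
  stopifnot(inherits(grid, "comparison_grid"),
            length(common_family) == nrow(grid$prob),
            length(diff_family) == ncol(grid$prob))
  joint_fam <- outer(as.character(common_family), as.character(diff_family), paste, sep = "\r")
  post <- family_pool(as.vector(grid$delta_f), as.vector(joint_fam))
  fr <- unique(as.character(common_family))
  fc <- unique(as.character(diff_family))
  out <- matrix(0, length(fr), length(fc), dimnames = list(fr, fc))
  for (m in fr) for (n in fc) {
    key <- paste(m, n, sep = "\r")
    if (key %in% names(post)) out[m, n] <- post[[key]]
  }
  out
}

#' Bayesian Model Average over reduced models
#'
#' Mixture of model posteriors weighted by model probabilities: mean
#' `sum_m p_m mu_m`, covariance by the full mixture moments
#' `sum_m p_m (Sigma_m + mu_m mu_m') - mu_bar mu_bar'`. Each cell's posterior
#' probability of being "on" is the summed probability of the models in which
#' it is free; a thresholded view zeroes the mean of cells below threshold.
#'
#' @param posteriors List of `gaussian_density` reduced posteriors.
#' @param prob Numeric vector of model probabilities (normalised).
#' @param masks Optional list/matrix of on-masks (one per model) for the
#'   per-cell on-probabilities.
#' @param threshold Posterior-probability threshold in (0, 1], or `NULL` for
#'   no thresholding (default 0.95).
#' @return Object of class `bma_result`: `density` (averaged
#'   `gaussian_density`), `on_prob` (per-cell probability of being present),
#'   `thresholded` (density with sub-threshold cells zeroed; `NULL` when
#'   `threshold` is `NULL`), `threshold`, `prob`.
#' @export
bma <- function(posteriors, prob, masks = NULL, threshold = 0.95) {
  stopifnot(length(posteriors) == length(prob))
  prob <- prob / sum(prob)
  labels <- posteriors[[1]]$labels
  p <- length(labels)
  mu <- numeric(p)
  m2 <- matrix(0, p, p)
  for (m in seq_along(posteriors)) {
    d <- posteriors[[m]]
    mu <- mu + prob[m] * d$mean
    m2 <- m2 + prob[m] * (d$cov + tcrossprod(d$mean))
  }
  cov <- symm(m2 - tcrossprod(mu))
  # mixture moments can go slightly indefinite in floating point; clip
  ev <- eigen(cov, symmetric = TRUE)
  cov <- symm(ev$vectors %*% (pmax(ev$values, 0) * t(ev$vectors)))
  dens <- gaussian_density(mu, cov, labels = labels)
  on_prob <- NULL
  if (!is.null(masks)) {
    mm <- do.call(rbind, lapply(masks, function(m) {
      if (inherits(m, "model_spec")) m$on_mask else as.integer(as.logical(m))
    }))
    on_prob <- stats::setNames(drop(prob %*% mm), labels)
  }
  thresholded <- NULL
  if (!is.null(threshold) && !is.null(on_prob)) {
    keep <- on_prob >= threshold
    tm <- ifelse(keep, mu, 0)
    tc <- cov
    tc[!keep, ] <- 0
    tc[, !keep] <- 0
    thresholded <- gaussian_density(tm, tc, labels = labels)
  }
  structure(list(density = dens, on_prob = on_prob, thresholded = thresholded,
                 threshold = threshold, prob = prob),
            class = "bma_result")
}

#' @export
print.bma_result <- function(x, ...) {
  cat("<bma_result> over", length(x$density$mean), "cells,",
      length(x$prob), "models")
  if (!is.null(x$threshold) && !is.null(x$on_prob)) {
    cat(";", sum(x$on_prob >= x$threshold), "cells above",
        paste0(100 * x$threshold, "%"), "on-probability")
  }
  cat("\n")
  invisible(x)
}

#' BMA over a comparison grid
#'
#' @param grid A `comparison_grid`.
#' @param threshold Passed to [bma()].
#' @return A `bma_result` over all group-effect cells.
#' @export
bma_grid <- function(grid, threshold = 0.95) {
  nc <- nrow(grid$prob); nd <- ncol(grid$prob)
  labels <- grid$posteriors[[1]]$labels
  ic <- match(grid$common_cells, labels)
  id <- match(grid$diff_cells, labels)
  masks <- vector("list", nc * nd)
  for (i in seq_len(nc)) for (j in seq_len(nd)) {
    mask <- rep(1L, length(labels))
    mask[ic] <- grid$common_space$specs[[i]]$on_mask
    mask[id] <- grid$diff_space$specs[[j]]$on_mask
    masks[[(j - 1) * nc + i]] <- mask
  }
  bma(grid$posteriors, as.vector(grid$prob), masks = masks, threshold = threshold)
}

#' Greedy search over reduced group-level models
#'
#' Exploratory pruning when no model space is pre-specified: starting from the
#' full model, repeatedly evaluates (by Bayesian model reduction) the switch-off
#' of each candidate cell still in play and discards the cell whose removal
#' most increases model evidence, as long as removal does not decrease it
#' (ties broken by the smaller posterior |mean|/sd). When no single removal
#' helps, the K = min(8, remaining) cells whose removal costs the least
#' evidence are treated as undecided: all 2^K on/off combinations (up to 256
#' models) are scored and returned as a Bayesian model average, together with
#' each cell's probability of being present (pooled evidence of models with
#' the cell on versus off).
#'
#' @param peb A fitted `peb_result`.
#' @param candidate_cells Labels of group-effect cells to search over
#'   (default: all). Cells outside the candidate set stay on throughout.
#' @param block_size Terminal enumeration size K cap (default 8, i.e. up to
#'   2^8 = 256 terminal models).
#' @param threshold Threshold for the final BMA (default 0.95).
#' @return Object of class `greedy_result`: `bma` (`bma_result`), `pruned`
#'   (cells switched off), `undecided` (cells enumerated at termination),
#'   `n_terminal_models`, `trace` (data.frame of pruning steps).
#' @export
greedy_search <- function(peb, candidate_cells = NULL, block_size = 8,
                          threshold = 0.95) {
  stopifnot(inherits(peb, "peb_result"))
  labels <- peb$group_posterior$labels
  if (is.null(candidate_cells)) candidate_cells <- labels
  bad <- setdiff(candidate_cells, labels)
  if (length(bad)) stop("greedy_search: unknown cells: ", paste(bad, collapse = ", "))
  if (!length(candidate_cells)) stop("greedy_search: need at least one candidate cell")
  mask <- rep(1L, length(labels))
  names(mask) <- labels
  sd_full <- sqrt(pmax(diag(peb$group_posterior$cov), 1e-300))
  z_full <- abs(peb$group_posterior$mean) / sd_full
  names(z_full) <- labels
  current_f <- 0 # evidence relative to the full model
  trace <- list()
  repeat {
    on_cells <- candidate_cells[mask[candidate_cells] == 1L]
    if (!length(on_cells)) break
    df <- vapply(on_cells, function(cell) {
      m <- mask
      m[cell] <- 0L
      bmr_reduce_result(peb, m)$delta_f - current_f
    }, numeric(1))
    best <- max(df)
    if (best < 0) break
    tied <- on_cells[df >= best - 1e-9]
    drop_cell <- tied[which.min(z_full[tied])]
    mask[drop_cell] <- 0L
    current_f <- current_f + df[[drop_cell]]
    trace[[length(trace) + 1]] <- data.frame(cell = drop_cell,
                                             delta_f = df[[drop_cell]],
                                             f_rel = current_f)
  }
  on_cells <- candidate_cells[mask[candidate_cells] == 1L]
  if (length(on_cells)) {
    df <- vapply(on_cells, function(cell) {
      m <- mask
      m[cell] <- 0L
      bmr_reduce_result(peb, m)$delta_f - current_f
    }, numeric(1))
    k <- min(block_size, length(on_cells))
    undecided <- on_cells[order(-df)][seq_len(k)] # least evidence loss first
  } else {
    undecided <- character(0)
  }
  k <- length(undecided)
  combos <- if (k > 0) {
    as.matrix(expand.grid(rep(list(0:1), k)))[, k:1, drop = FALSE]
  } else {
    matrix(0L, 1, 0)
  }
  masks <- vector("list", nrow(combos))
  posts <- vector("list", nrow(combos))
  dfs <- numeric(nrow(combos))
  for (r in seq_len(nrow(combos))) {
    m <- mask
    if (k > 0) m[undecided] <- as.integer(combos[r, ])
    red <- bmr_reduce_result(peb, m)
    masks[[r]] <- m
    posts[[r]] <- red$posterior
    dfs[r] <- red$delta_f
  }
  prob <- softmax_logp(dfs)
  structure(list(
    bma = bma(posts, prob, masks = masks, threshold = threshold),
    pruned = setdiff(candidate_cells, on_cells),
    undecided = undecided,
    n_terminal_models = nrow(combos),
    delta_f = dfs,
    trace = if (length(trace)) do.call(rbind, trace) else
      data.frame(cell = character(0), delta_f = numeric(0), f_rel = numeric(0))
  ), class = "greedy_result")
}

#' @export
print.greedy_result <- function(x, ...) {
  cat("<greedy_result>", length(x$pruned), "cells pruned,",
      length(x$undecided), "undecided;", x$n_terminal_models,
      "terminal models in the BMA\n")
  invisible(x)
}
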