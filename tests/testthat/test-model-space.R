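make_connectivity_cells <- function() {
  lab <- expand.grid(side = c("l", "r"), band = c("d", "v"), task = c("P", "W"))
  paste0(lab$task, lab$band, lab$side)
}

connectivity_factors <- function(cells) {
  list(
    task = list(both = cells,
                words = cells[grepl("^W", cells)],
                pictures = cells[grepl("^P", cells)]),
    band = list(both = cells,
                dorsal = cells[grepl("d", cells)],
                ventral = cells[grepl("v", cells)]),
    side = list(both = cells,
                left = cells[grepl("l$", cells)],
                right = cells[grepl("r$", cells)]))
}

test_that("factorial spaces have prod(levels) + null models", {
  cells <- make_connectivity_cells()
  sp <- factorial_space(connectivity_factors(cells), cells)
  expect_length(sp, 28) # 3 * 3 * 3 + 1
  expect_true(sp$includes_null)
  expect_equal(sum(sp$specs[[28]]$on_mask), 0)

  sp2 <- factorial_space(list(f = list(a = "x", b = "y")), c("x", "y"),
                         include_null = FALSE)
  expect_length(sp2, 2)
  expect_error(factorial_space(list(f = list()), "x"), "no levels")
  expect_error(factorial_space(list(f = list(a = "nope")), "x"), "unknown cells")
})

test_that("factorial masks equal the set intersection of their level cells", {
  cells <- make_connectivity_cells()
  factors <- connectivity_factors(cells)
  sp <- factorial_space(factors, cells)
  # independent oracle: enumerate with expand.grid + intersect
  combos <- expand.grid(side = names(factors$side), band = names(factors$band),
                        task = names(factors$task), stringsAsFactors = FALSE)
  for (r in seq_len(nrow(combos))) {
    on <- Reduce(intersect, list(factors$task[[combos$task[r]]],
                                 factors$band[[combos$band[r]]],
                                 factors$side[[combos$side[r]]]))
    oracle_mask <- as.integer(cells %in% on)
    found <- Filter(function(s) {
      identical(s$name, paste(combos$task[r], combos$band[r], combos$side[r],
                              sep = " & "))
    }, sp$specs)
    expect_length(found, 1)
    expect_equal(found[[1]]$on_mask, oracle_mask)
  }
  # (words, dorsal, right) switches on exactly the words/dorsal/right cell
  wdr <- Filter(function(s) s$name == "words & dorsal & right", sp$specs)[[1]]
  expect_equal(cells[wdr$on_mask == 1], "Wdr")
})

test_that("the exhaustive enumeration bound for 40 cells is 2^40", {
  expect_equal(exhaustive_model_count(40), 2^40)
  expect_equal(exhaustive_model_count(40) / 1e12, 1.0995, tolerance = 1e-4)
})

test_that("uninformative data give an exactly uniform comparison grid", {
  p <- 4
  prior <- gaussian_density(rep(0, p), diag(0.25, p), labels = paste0("t", 1:p))
  units <- lapply(1:6, function(i) first_level_unit(paste0("s", i), prior, prior))
  xb <- build_between_design(data.frame(x = rnorm(6)))
  mod <- peb_model(units, build_full_design(xb, within_design(paste0("t", 1:p))))
  fit <- fit_peb(mod)
  cells <- fit$group_posterior$labels
  fac <- list(cell = list(all = paste0("t", 1:p),
                          first = "t1", last = "t4"))
  sp <- factorial_space(fac, paste0("t", 1:p))
  g <- compare_grid(fit, sp, sp, cells[1:4], cells[5:8])
  expect_equal(sum(g$prob), 1, tolerance = 1e-12)
  expect_equal(as.vector(g$prob), rep(1 / 16, 16), tolerance = 1e-6)
  # flat case: marginalisation equals the flat single-axis comparison
  expect_equal(g$common_marginal, rep(1 / 4, 4), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("grid posteriors are equivariant under model relabelling", {
  st <- small_study(n = 15, p = 4, seed = 81)
  fit <- fit_small_study(st)
  cells <- fit$group_posterior$labels
  plabs <- st$parameter_labels
  fac <- list(cell = list(all = plabs, a = plabs[1], b = plabs[2]))
  sp <- factorial_space(fac, plabs)
  g <- compare_grid(fit, sp, sp, cells[1:4], cells[5:8])
  # permute the common-axis space
  perm <- c(3, 1, 4, 2)
  sp_perm <- sp
  sp_perm$specs <- sp$specs[perm]
  g_perm <- compare_grid(fit, sp_perm, sp, cells[1:4], cells[5:8])
  expect_equal(unname(g_perm$prob), unname(g$prob[perm, ]), tolerance = 1e-9)
})

test_that("a true covariate effect concentrates the difference-axis marginal", {
  eff <- matrix(0, 2, 4)
  eff[1, ] <- 0.3
  eff[2, 2] <- 3 * 0.125 # effect = 3x RFX sd on cell 2
  st <- simulate_study(simulation_config(
    n_subjects = 100, n_params = 4, effects = eff, rfx_sd = 0.125, seed = 83))
  fit <- fit_study(st)
  cells <- fit$group_posterior$labels
  plabs <- st$parameter_labels
  fac <- list(cell = c(list(all = plabs, none = character(0)),
                       stats::setNames(as.list(plabs), plabs)))
  sp <- factorial_space(fac, plabs, include_null = FALSE)
  g <- compare_grid(fit, sp, sp, cells[1:4], cells[5:8])
  has_k <- vapply(sp$specs, function(s) s$on_mask[2] == 1L, logical(1))
  expect_gt(sum(g$diff_marginal[has_k]), 0.9)
})

test_that("family pooling corrects for family size and matches enumeration", {
  # equal evidence, families of size 1 and 3 -> 0.5 / 0.5
  fp <- family_pool(rep(0, 4), c("A", "B", "B", "B"))
  expect_equal(unname(fp), c(0.5, 0.5))
  # all evidence on one model -> its family wins outright
  fp2 <- family_pool(c(0, 0, 50, 0), c("A", "A", "B", "B"))
  expect_equal(unname(fp2["B"]), 1, tolerance = 1e-12)
  expect_error(family_pool(c(0, 0), c("A", NA)), NA) # NA treated as its own id
  # random evidences vs a brute-force Bayes enumeration
  set.seed(7)
  lf <- rnorm(9, sd = 2)
  fam <- c("A", "A", "B", "B", "B", "C", "C", "C", "C")
  fp3 <- family_pool(lf, fam)
  prior <- (1 / 3) / table(fam)[fam]
  post <- exp(lf) * as.numeric(prior)
  post <- post / sum(post)
  oracle <- tapply(post, fam, sum)
  expect_equal(fp3[names(oracle)], oracle, tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("family grids pool a comparison grid along both axes", {
  st <- small_study(n = 15, p = 4, seed = 85)
  fit <- fit_small_study(st)
  cells <- fit$group_posterior$labels
  plabs <- st$parameter_labels
  fac <- list(cell = list(all = plabs, a = plabs[1], none = character(0)))
  sp <- factorial_space(fac, plabs, include_null = FALSE)
  g <- compare_grid(fit, sp, sp, cells[1:4], cells[5:8])
  fg <- family_grid(g, c("on", "on", "off"), c("on", "on", "off"))
  expect_equal(sum(fg), 1, tolerance = 1e-12)
  expect_equal(dim(fg), c(2, 2))
})

test_that("BMA moments: degenerate and two-component mixtures", {
  d1 <- gaussian_density(0, matrix(1), labels = "x")
  d2 <- gaussian_density(2, matrix(1), labels = "x")
  single <- bma(list(d1), 1, masks = list(1), threshold = NULL)
  expect_equal(single$density$mean, d1$mean)
  expect_equal(single$density$cov, d1$cov)
  mix <- bma(list(d1, d2), c(0.5, 0.5), masks = list(1, 1), threshold = NULL)
  expect_equal(mix$density$mean, 1)
  expect_equal(drop(mix$density$cov), 2)
})

test_that("BMA thresholding keeps only strongly supported cells", {
  eff <- matrix(0, 2, 4)
  eff[2, 1] <- 0.6
  st <- simulate_study(simulation_config(
    n_subjects = 80, n_params = 4, effects = eff, rfx_sd = 0.125, seed = 87))
  fit <- fit_study(st)
  gr <- greedy_search(fit)
  strong <- "LI:theta1"
  expect_gt(gr$bma$on_prob[[strong]], 0.95)
  expect_true(abs(gr$bma$thresholded$mean[match(strong, fit$group_posterior$labels)]) > 0)
  # terminal model probabilities are a normalised softmax of the evidences
  expect_equal(sum(gr$bma$prob), 1, tolerance = 1e-12)
  expect_equal(gr$bma$prob,
               exp(gr$delta_f - max(gr$delta_f)) /
                 sum(exp(gr$delta_f - max(gr$delta_f))),
               tolerance = 1e-12)
})

test_that("BMA shrinks toward zero relative to the full model over nested masks", {
  st <- small_study(n = 20, p = 3, seed = 89)
  fit <- fit_small_study(st)
  full_prior <- fit$prior_used
  labels <- fit$group_posterior$labels
  masks <- list(rep(1L, 6), c(1, 1, 1, 0, 1, 1), c(1, 1, 1, 1, 0, 1),
                c(1, 1, 1, 0, 0, 1))
  posts <- lapply(masks, function(m)
    bmr_evidence(fit$group_posterior, full_prior,
                 reduce_prior(full_prior, m))$posterior)
  avg <- bma(posts, rep(0.25, 4), masks = masks, threshold = NULL)
  off_somewhere <- which(colSums(do.call(rbind, masks)) < 4)
  for (j in off_somewhere) {
    expect_lte(abs(avg$density$mean[j]), abs(fit$group_posterior$mean[j]) + 1e-9)
  }
})

test_that("greedy search keeps strongly supported cells and prunes null ones", {
  eff <- matrix(0, 2, 4)
  eff[1, ] <- 0.6 # strong group means everywhere
  st <- simulate_study(simulation_config(
    n_subjects = 80, n_params = 4, effects = eff, rfx_sd = 0.125, seed = 91))
  fit <- fit_study(st)
  gr <- greedy_search(fit, candidate_cells = fit$group_posterior$labels[1:4])
  expect_equal(nrow(gr$trace), 0) # nothing pruned: all supported
  expect_equal(gr$n_terminal_models, 2^4)
})

test_that("greedy search finds the exhaustive optimum on small problems", {
  # P = 6 mean-only toys: compare against scoring all 2^6 masks
  hits <- 0
  n_rep <- 25
  for (rep in seq_len(n_rep)) {
    eff <- matrix(0, 1, 6)
    eff[1, sample(6, 3)] <- 0.5
    st <- simulate_study(simulation_config(
      n_subjects = 40, n_params = 6, covariate_names = "mean",
      effects = eff, rfx_sd = 0.125, seed = 9000 + rep))
    xb <- build_between_design(n = 40)
    xb$subject_ids <- sprintf("sub-%03d", 1:40)
    mod <- peb_model(st$units, build_full_design(xb, within_design(st$parameter_labels)))
    fit <- fit_peb(mod)
    all_masks <- as.matrix(expand.grid(rep(list(0:1), 6)))
    all_f <- apply(all_masks, 1, function(m)
      peblm:::bmr_reduce_result(fit, m)$delta_f)
    gr <- greedy_search(fit)
    if (max(gr$delta_f) >= max(all_f) - 1e-6) hits <- hits + 1
  }
  expect_gte(hits / n_rep, 0.95)
})
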