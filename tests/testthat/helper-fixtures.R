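# Shared fixtures: everything is generated in code under fixed seeds.

# Random symmetric positive-definite matrix.
rand_spd <- function(p, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  a <- matrix(rnorm(p * p), p)
  crossprod(a) + diag(0.5, p)
}

rand_density <- function(p, seed = NULL, mean_sd = 1) {
  if (!is.null(seed)) set.seed(seed)
  gaussian_density(rnorm(p, sd = mean_sd), rand_spd(p))
}

# A small simulated study with a group-mean effect and one covariate effect.
small_study <- function(n = 20, p = 4, effect = 0.4, mean_effect = 0.3,
                        rfx_sd = 0.125, seed = 101, n_obs = 16,
                        obs_noise_sd = 0.25) {
  eff <- matrix(0, 2, p)
  eff[1, ] <- mean_effect
  eff[2, 1] <- effect
  simulate_study(simulation_config(
    n_subjects = n, n_params = p, covariate_names = c("mean", "LI"),
    effects = eff, rfx_sd = rfx_sd, n_obs = n_obs,
    obs_noise_sd = obs_noise_sd, seed = seed))
}

fit_small_study <- function(study, ...) fit_study(study, ...)

# Log-density of a multivariate normal (independent oracle helper).
ldmvnorm <- function(x, m, C) {
  -0.5 * (length(x) * log(2 * pi) +
            as.numeric(determinant(C, logarithm = TRUE)$modulus) +
            drop(t(x - m) %*% solve(C) %*% (x - m)))
}
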