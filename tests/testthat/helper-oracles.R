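# Independent oracles and small fixtures used across the suite.

# Exact two-sided Mann-Whitney p by brute-force enumeration over all
# rank assignments of the pooled (tie-free) sample.
enumerate_mw_p <- function(a, b) {
  pooled <- c(a, b)
  stopifnot(!anyDuplicated(pooled))
  n <- length(a); m <- length(b)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  sets <- utils::combn(n + m, n)
  all_r <- rank(pooled)
  u_all <- apply(sets, 2, function(ix) sum(sort(all_r)[ix]) - n * (n + 1) / 2)
  min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
}

# quick noise-free acquisition presets with short curves for fast tests
quiet_acq <- function(noise_sd = 0, ...) {
  acquisition_params(noise_sd = noise_sd, retract_distance = 2e-5,
                     sampling_rate = 250, ...)
}

tiny_condition <- function(name = "cond", f_max = 2e-9, tau = 50,
                           f_floor = 0, ...) {
  condition_spec(name, f_max = f_max, tau = tau, f_floor = f_floor, ...)
}

# small additive four-condition config for interaction-test nulls
additive_config <- function(seed, n_cells = 10L, ...) {
  simulation_config(conditions = additive_conditions(...),
                    n_cells = n_cells, seed = seed)
}
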