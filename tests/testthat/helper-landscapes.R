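# Shared ground-truth landscapes and the umbrella-sampling fixture set.
# The double-Gaussian landscape (one barrier, one well) is the recovery
# target; windows are built lazily once and reused across test files.

# oriented lumen (small xi) -> cytosol (large xi): binding well at 4 A,
# selectivity-filter barrier at 7 A
double_gaussian <- function() {
  potential_spec(c(-1.5, 3), c(4, 7), c(1, 1))
}

# mutant analogue: luminal well removed, barrier raised
double_gaussian_mutant <- function() {
  potential_spec(5, 7, 1)
}

confined_double_well <- function() {
  potential_spec(c(1.2, -0.6, -0.6), c(0, -1.5, 1.5), c(0.6, 0.8, 0.8))
}

.cache <- new.env(parent = emptyenv())

# 20 umbrella windows (k = 10, 0.5 A spacing) on a landscape, sampled by
# the Brownian generator; retained 5e4 frames per window after a 1e4
# frame discard, block length 1e4 (the "1 ns" unit).
us_windows <- function(truth = double_gaussian(), seed_base = 1000,
                       n_steps = 6e4, n_discard = 1e4, key = "wt") {
  if (!is.null(.cache[[key]])) return(.cache[[key]])
  centers <- seq(0.5, 10, by = 0.5)
  wins <- lapply(seq_along(centers), function(j) {
    cfg <- langevin_config(n_steps, seed = seed_base + j,
                           initial_position = centers[j])
    xi <- simulate_overdamped(truth, harmonic_bias(centers[j], 10), cfg)
    umbrella_window(centers[j], 10, xi, n_discard = n_discard,
                    block_length = 1e4)
  })
  .cache[[key]] <- wins
  wins
}

us_config <- function() wham_config(n_bins = 300, range = c(0.3, 10.2))

# shifted recovered profile + RMSE against the ground truth (profiles are
# defined up to a constant, so the comparison is mean-aligned)
recovery_rmse <- function(profile, truth) {
  fin <- is.finite(profile$G)
  d <- profile$G[fin] - eval_potential(truth, profile$xi[fin])$energy
  d <- d - mean(d)
  sqrt(mean(d^2))
}
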