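#' Configuration for overdamped Langevin (Brownian) sampling
#'
#' Parameters of the Euler-Maruyama integrator
#' \deqn{\xi' = \xi - (\Delta t/\gamma)\, dU/d\xi +
#'       \sqrt{2 k_B T \Delta t/\gamma}\,\eta,\qquad \eta \sim N(0,1).}
#' The generator is a configurational sampler, not a physical dynamics
#' model: friction and timestep are reduced units chosen so that a
#' "10 ns" umbrella window corresponds to >= 1e5 integration steps.
#'
#' @param n_steps number of integration steps.
#' @param kT thermal energy (kcal/mol); default 300 K.
#' @param friction friction gamma (kcal mol^-1 A^-2 ns).
#' @param timestep integration timestep (ns).
#' @param seed integer seed; identical seeds give identical trajectories.
#'   `NULL` uses the current RNG state.
#' @param initial_position starting coordinate (angstrom).
#' @param bound divergence guard: |xi| beyond this aborts with a
#'   diagnostic naming the step.
#' @return an object of class `langevin_config`.
#' @export
langevin_config <- function(n_steps, kT = thermal_energy(300), friction = 0.5,
                            timestep = 1e-3, seed = NULL,
                            initial_position = 0, bound = 1e4) {
  stopifnot(is.numeric(n_steps), length(n_steps) == 1L, n_steps >= 0,
            kT > 0, friction > 0, timestep > 0, bound > 0,
            is.finite(initial_position))
  structure(list(n_steps = as.integer(n_steps), kT = kT, friction = friction,
                 timestep = timestep, seed = seed,
                 initial_position = initial_position, bound = bound),
            class = "langevin_config")
}

#' Sample a 1D landscape by overdamped Langevin dynamics
#'
#' Generates a reaction-coordinate time series on a [potential_spec()]
#' landscape under optional restraints, with the stationary distribution
#' \eqn{\propto \exp\{-(U + W)/k_B T\}}.  This is the desk-scale stand-in
#' for a biased molecular-dynamics window.
#'
#' @param spec a [potential_spec()].
#' @param biases a `bias_spec` or list of them (see [harmonic_bias()]).
#' @param cfg a [langevin_config()].
#' @return numeric vector of length `n_steps + 1` (the initial position
#'   plus one value per step), with the configuration in attributes.
#' @examples
#' cfg <- langevin_config(1000, seed = 1)
#' xi <- simulate_overdamped(potential_spec(), harmonic_bias(0, 10), cfg)
#' var(xi)  # approaches kT / k for long runs
#' @export
simulate_overdamped <- function(spec, biases = list(), cfg) {
  stopifnot(inherits(spec, "potential_spec"), inherits(cfg, "langevin_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  noise <- rnorm(cfg$n_steps)
  traj <- cpp_overdamped(spec$amplitudes, spec$centers, spec$widths,
                         bias_matrix(biases), cfg$initial_position,
                         cfg$timestep, cfg$friction, cfg$kT, noise, cfg$bound)
  attr(traj, "timestep") <- cfg$timestep
  attr(traj, "seed") <- cfg$seed
  traj
}

#' Linear schedule for a moving restraint center
#'
#' @param from,to start and end centers (angstrom).
#' @param n_steps number of integration steps the pull spans.
#' @return numeric vector of `n_steps + 1` restraint centers.
#' @export
pull_schedule <- function(from, to, n_steps) {
  stopifnot(is.finite(from), is.finite(to), n_steps >= 0)
  seq(from, to, length.out = n_steps + 1)
}

#' Steered pull along the reaction coordinate
#'
#' Drags the particle with a harmonic restraint whose center follows a
#' monotone `schedule`, emulating the steered stage that seeds umbrella
#' window positions.  At steady state on a flat landscape the particle
#' lags the moving center by ~ gamma * v / k_pull.
#'
#' @param spec a [potential_spec()].
#' @param k_pull pulling force constant (kcal mol^-1 A^-2; the study
#'   design uses 1.0 for monovalent and 1.5 for divalent ions).
#' @param schedule restraint-center position per step (length
#'   `n_steps + 1`, e.g. from [pull_schedule()]); must be monotone.
#' @param cfg a [langevin_config()]; `initial_position` should normally
#'   match `schedule[1]`.
#' @param biases optional additional static restraints.
#' @return list with `trajectory` (length `n_steps + 1`) and `centers`
#'   (the schedule, echoed).
#' @export
steered_pull <- function(spec, k_pull, schedule, cfg, biases = list()) {
  stopifnot(inherits(spec, "potential_spec"), inherits(cfg, "langevin_config"),
            is.numeric(k_pull), k_pull > 0)
  schedule <- as.numeric(schedule)
  if (length(schedule) != cfg$n_steps + 1L)
    stop("schedule must supply one center per step plus the start (",
         cfg$n_steps + 1L, " values)")
  dc <- diff(schedule)
  if (length(dc) && !(all(dc >= 0) || all(dc <= 0)))
    stop("pull schedule must be monotone in the pull direction")
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  noise <- rnorm(cfg$n_steps)
  traj <- cpp_pull(spec$amplitudes, spec$centers, spec$widths,
                   bias_matrix(biases), schedule, k_pull,
                   cfg$initial_position, cfg$timestep, cfg$friction, cfg$kT,
                   noise, cfg$bound)
  list(trajectory = traj, centers = schedule)
}
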