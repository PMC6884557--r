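# Langevin dynamics: m r" = F_conservative - xi v + F_random, integrated by
# a BBK-type Langevin velocity Verlet (semi-implicit friction in the second
# half-kick, one Gaussian random force per step with variance 2 xi kT / dt
# per component -- the white-noise discretisation demanded by the
# fluctuation-dissipation theorem). With friction and noise off the scheme
# is exactly deterministic velocity Verlet.

#' Integrator configuration
#'
#' @param timestep Delta t in t_LJ units; must lie in (0, 0.01] (the FENE
#'   spring with k = 30 destabilises larger steps).
#' @param rng_seed base integer seed.
#' @param rng_stream per-event substream index; each translocation event is
#'   seeded from `(rng_seed, rng_stream)` so events are independently
#'   reproducible in any order.
#' @param scheme_id label of the update rule (single documented scheme).
#' @return An `integrator_config` list.
#' @export
integrator_config <- function(timestep = 0.005, rng_seed = 1L,
                              rng_stream = 1L,
                              scheme_id = "langevin-velocity-verlet-bbk") {
  if (!is.numeric(timestep) || timestep <= 0 || timestep > 0.01)
    stop("timestep must lie in (0, 0.01] t_LJ")
  structure(list(timestep = timestep, scheme_id = scheme_id,
                 rng_seed = as.integer(rng_seed),
                 rng_stream = as.integer(rng_stream)),
            class = "integrator_config")
}

#' Derive a 32-bit seed for one (stream, attempt) of a base seed
#'
#' Deterministic mixing of the base seed, the per-event substream and the
#' retry attempt, kept below 2^31 so it is a valid R integer seed.
#'
#' @param seed base seed.
#' @param stream substream index (event number).
#' @param attempt retry counter (fresh stream after a retracted/failed event).
#' @return Integer seed.
#' @export
event_seed <- function(seed, stream, attempt = 1L) {
  m <- 2147483647
  s <- (as.numeric(seed) %% m) * 48271 + as.numeric(stream) * 7919 +
    (as.numeric(attempt) - 1) * 104729
  as.integer(s %% m)
}

#' Draw the per-step random forces
#'
#' Seeds the RNG from `(rng_seed, rng_stream)` of `config` and draws one
#' i.i.d. zero-mean Gaussian force per bead and component with variance
#' `2 * friction * kT / timestep`, the white-noise force discretisation that
#' balances the friction sink at temperature kT.
#'
#' @param config an [integrator_config()].
#' @param params a [simulation_parameters()].
#' @param n_draws number of N x 3 draws to return (stacked rows).
#' @return An `(n_draws * N) x 3` matrix of forces.
#' @export
random_force_draw <- function(config, params, n_draws = 1L) {
  set.seed(event_seed(config$rng_seed, config$rng_stream))
  n <- params$n_monomers * n_draws
  sd <- sqrt(2 * params$friction * params$kT / config$timestep)
  matrix(rnorm(3 * n, sd = sd), n, 3)
}

#' Advance a polymer state by Langevin dynamics
#'
#' Runs `n_steps` of the Langevin velocity-Verlet update. Randomness is
#' drawn from R's global RNG: call `set.seed()` (or use the event-level
#' drivers, which seed from `(rng_seed, rng_stream)`) for reproducible
#' trajectories. `ld_step()` advances a single step.
#'
#' @param state a [polymer_state()].
#' @param geom a [membrane_geometry()].
#' @param params a [simulation_parameters()].
#' @param config an [integrator_config()].
#' @param n_steps number of steps.
#' @param thermostat logical; apply friction and random forces? With
#'   `FALSE` the run is deterministic NVE velocity Verlet.
#' @param use_external logical; apply the pulling force to beads in the pore?
#' @param pinned optional logical vector marking beads held fixed.
#' @param energy_every if > 0, record total (kinetic + potential) energy
#'   every this many steps.
#' @param vel_burnin if >= 0, accumulate per-component mean squared
#'   velocities of free beads after this many steps (for kinetic-temperature
#'   diagnostics).
#' @param xi_override optional friction coefficient replacing the one in
#'   `params` for this run only; `xi_override = 0` with `thermostat = FALSE`
#'   gives strict energy-conserving (NVE) velocity Verlet, while a positive
#'   value with `thermostat = FALSE` gives pure frictional damping without
#'   noise.
#' @return A `polymer_state` with attributes `energies` (two-column matrix
#'   time/energy, if requested) and `v2_mean` (length-3 per-component mean
#'   squared velocity, if requested).
#' @export
ld_run <- function(state, geom, params, config, n_steps,
                   thermostat = TRUE, use_external = FALSE, pinned = NULL,
                   energy_every = 0L, vel_burnin = -1L, xi_override = NULL) {
  stopifnot(inherits(state, "polymer_state"),
            nrow(state$positions) == params$n_monomers)
  if (is.null(pinned)) pinned <- logical(0)
  model <- .model_list(params, geom)
  if (!is.null(xi_override)) {
    stopifnot(is.numeric(xi_override), xi_override >= 0)
    model$xi <- xi_override
  }
  res <- cpp_run_plain(state$positions, state$velocities,
                       model, config$timestep,
                       as.integer(n_steps), thermostat, use_external,
                       pinned, as.integer(energy_every),
                       as.integer(vel_burnin))
  out <- polymer_state(res$positions, res$velocities, state$time + res$time)
  if (energy_every > 0)
    attr(out, "energies") <- cbind(time = res$energy_times + state$time,
                                   energy = res$energies)
  if (vel_burnin >= 0) {
    attr(out, "v2_mean") <- res$v2_mean
    attr(out, "v2_n") <- res$v2_n
  }
  out
}

#' @rdname ld_run
#' @export
ld_step <- function(state, geom, params, config, thermostat = TRUE,
                    use_external = FALSE, pinned = NULL) {
  ld_run(state, geom, params, config, 1L, thermostat, use_external, pinned)
}
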