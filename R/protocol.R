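# Translocation protocol: threaded initial configuration -> pinned-pore
# equilibration of the cis tail -> driven translocation with per-monomer
# first-passage recording.

#' Build the threaded initial configuration
#'
#' Bead 1 sits on the pore axis exactly at the trans exit plane; successive
#' beads are laid back through the pore and out the cis side at the
#' equilibrium FENE+WCA bond length (about 0.96 sigma). Beads inside the
#' pore lie on the axis; cis-side beads get a small deterministic helical
#' offset (0.1 sigma) to break collinearity, which keeps them clear of the
#' membrane surfaces.
#'
#' @param params a [simulation_parameters()].
#' @param geom a [membrane_geometry()]; derived from `params` if omitted.
#' @return A [polymer_state()] at time 0 with zero velocities.
#' @export
build_initial_configuration <- function(params, geom = membrane_geometry(params)) {
  n <- params$n_monomers
  b <- equilibrium_bond_length(params)
  x <- geom$trans_plane_x - (seq_len(n) - 1) * b
  y <- rep(geom$pore_center[2], n)
  z <- rep(geom$pore_center[3], n)
  on_cis <- x < geom$cis_plane_x
  if (any(on_cis)) {
    i <- which(on_cis)
    theta <- 2.399963 * seq_along(i)   # golden-angle helix
    y[i] <- y[i] + 0.1 * params$sigma * cos(theta)
    z[i] <- z[i] + 0.1 * params$sigma * sin(theta)
  }
  st <- polymer_state(cbind(x, y, z))
  d <- sqrt(rowSums(diff(st$positions)^2))
  stopifnot(all(d < params$fene_r0))
  st
}

# beads pinned during equilibration: those initially inside the pore, and
# bead 1 (the anchor at the trans exit) in any case
.pinned_beads <- function(state, geom) {
  pinned <- region_of(state$positions, geom) == "pore"
  pinned[1] <- TRUE
  pinned
}

#' Equilibrate the cis-side tail with the pore beads pinned
#'
#' Beads initially inside the pore (and bead 1) are frozen; the remaining
#' tail evolves under the full thermostatted dynamics without the pulling
#' force. Every `sample_every` steps the radius of gyration of the free
#' beads is recorded; the run terminates once the range of the last
#' `window` samples falls below `rg_tol` (default 2 sigma, the convergence
#' threshold of the protocol). On return all velocities are resampled from
#' the Maxwell distribution at kT and the state is unpinned.
#'
#' @param state state from [build_initial_configuration()].
#' @param geom a [membrane_geometry()].
#' @param params a [simulation_parameters()].
#' @param config an [integrator_config()].
#' @param max_steps abort (with an error) if the criterion is not met by
#'   then.
#' @param sample_every steps between radius-of-gyration samples.
#' @param window number of samples over which the range is monitored.
#' @param rg_tol convergence threshold on the range (sigma units).
#' @return The equilibrated [polymer_state()], with attributes
#'   `equil_steps`, `rg_trace` and `pinned`.
#' @export
equilibrate <- function(state, geom, params, config,
                        max_steps = 400000L, sample_every = 50L,
                        window = 200L, rg_tol = 2 * params$sigma) {
  pinned <- .pinned_beads(state, geom)
  if (all(pinned)) stop("no free beads to equilibrate")
  vel <- state$velocities
  vel[pinned, ] <- 0
  res <- cpp_run_equilibrate(state$positions, vel,
                             .model_list(params, geom), config$timestep,
                             as.integer(max_steps), pinned,
                             as.integer(sample_every), as.integer(window),
                             rg_tol)
  if (!res$converged)
    stop("equilibration did not converge within ", max_steps,
         " steps (radius-of-gyration range still above ", rg_tol, " sigma)")
  out <- polymer_state(res$positions,
                       maxwell_velocities(params$n_monomers, params),
                       state$time + res$steps * config$timestep)
  attr(out, "equil_steps") <- res$steps
  attr(out, "rg_trace") <- res$rg_trace
  attr(out, "pinned") <- pinned
  out
}

#' Run one translocation event
#'
#' Builds the threaded configuration, equilibrates the cis tail, then
#' releases all beads, switches on the pulling force and advances the full
#' Langevin dynamics. For each s = 1..N the first time at which s beads
#' simultaneously lie past the trans exit plane is recorded (a monotone
#' first-passage counter: re-entries never erase a recorded time). The event
#' completes when all N beads are on the trans side; if instead every bead
#' retreats past the cis plane the event is marked retracted, discarded and
#' re-run with a fresh random substream until a completed event is obtained.
#'
#' @param params a [simulation_parameters()].
#' @param config an [integrator_config()]; its `(rng_seed, rng_stream)` pair
#'   fully determines the event.
#' @param geom a [membrane_geometry()]; derived from `params` if omitted.
#' @param record_snapshots logical; store the full bead configuration at
#'   each first-passage instant (needed for the shape observables)?
#' @param max_time cap on the driven phase, in t_LJ units.
#' @param max_attempts give up after this many discarded attempts.
#' @param equil_args list of overrides passed on to [equilibrate()].
#' @return A `translocation_event` list: `exit_times` (length N, t_LJ since
#'   release), `total_time`, `status` (`"completed"`), `snapshots` (list of
#'   N x 3 matrices tagged by s, or NULL), `condition`, `seed_info`,
#'   `n_discarded`, `discarded_statuses`, `equil_steps`.
#' @export
run_event <- function(params, config = integrator_config(timestep = params$timestep,
                                                         rng_seed = params$rng_seed),
                      geom = membrane_geometry(params),
                      record_snapshots = FALSE, max_time = 20000,
                      max_attempts = 20L, equil_args = list()) {
  condition <- c(pore_radius = params$pore_radius,
                 pore_epsilon = params$pore_epsilon,
                 pull_force = params$pull_force)
  discarded <- character(0)
  for (attempt in seq_len(max_attempts)) {
    set.seed(event_seed(config$rng_seed, config$rng_stream, attempt))
    res <- tryCatch(
      .attempt_event(params, geom, config, record_snapshots, max_time,
                     equil_args),
      error = function(e) list(status = "numerics_failed",
                               message = conditionMessage(e)))
    if (identical(res$status, "completed")) {
      res$condition <- condition
      res$seed_info <- c(seed = config$rng_seed, stream = config$rng_stream,
                         attempt = attempt)
      res$n_discarded <- length(discarded)
      res$discarded_statuses <- discarded
      class(res) <- "translocation_event"
      return(res)
    }
    discarded <- c(discarded, res$status)
  }
  stop("no completed translocation event after ", max_attempts,
       " attempts (statuses: ", paste(discarded, collapse = ", "), ")")
}

.attempt_event <- function(params, geom, config, record_snapshots, max_time,
                           equil_args) {
  st <- build_initial_configuration(params, geom)
  st <- do.call(equilibrate,
                c(list(st, geom, params, config), equil_args))
  max_steps <- as.integer(ceiling(max_time / config$timestep))
  res <- cpp_run_translocate(st$positions, st$velocities,
                             .model_list(params, geom), config$timestep,
                             max_steps, record_snapshots)
  status <- c("completed", "retracted", "timed_out")[res$status + 1]
  list(exit_times = as.numeric(res$exit_times),
       total_time = res$exit_times[params$n_monomers],
       status = status,
       snapshots = if (record_snapshots) res$snapshots else NULL,
       equil_steps = attr(st, "equil_steps"))
}

#' @export
print.translocation_event <- function(x, ...) {
  cat(sprintf(
    "<translocation_event> %s in %.1f t_LJ (R_p = %g, eps = %g, f = %g; %d discarded)\n",
    x$status, x$total_time, x$condition[["pore_radius"]],
    x$condition[["pore_epsilon"]], x$condition[["pull_force"]],
    x$n_discarded))
  invisible(x)
}

#' Run an ensemble of independent translocation events
#'
#' Events are seeded from per-event substreams of `base_seed` (stream =
#' event index), so any single event can be reproduced independently and the
#' collection is invariant to execution order.
#'
#' @param params a [simulation_parameters()]; `n_events` defaults from it.
#' @param n_events number of completed events to collect.
#' @param base_seed base RNG seed.
#' @param record_snapshots store per-s configurations (needed for the
#'   centre-of-mass, aspect-ratio and shape-factor observables)?
#' @param progress print one line per event?
#' @param ... passed on to [run_event()].
#' @return A `pt_ensemble` tibble, one row per completed event, with the
#'   condition columns (`pore_radius`, `pore_epsilon`, `pull_force`), the
#'   seed bookkeeping, `total_time`, and list-columns `exit_times` (length-N
#'   numeric) and `snapshots`.
#' @export
run_ensemble <- function(params, n_events = params$n_events,
                         base_seed = params$rng_seed,
                         record_snapshots = FALSE, progress = FALSE, ...) {
  geom <- membrane_geometry(params)
  rows <- vector("list", n_events)
  for (ev in seq_len(n_events)) {
    cfg <- integrator_config(timestep = params$timestep,
                             rng_seed = base_seed, rng_stream = ev)
    e <- run_event(params, cfg, geom, record_snapshots = record_snapshots, ...)
    rows[[ev]] <- tibble::tibble(
      event = ev,
      pore_radius = params$pore_radius,
      pore_epsilon = params$pore_epsilon,
      pull_force = params$pull_force,
      seed = base_seed,
      stream = ev,
      attempts = unname(e$seed_info[["attempt"]]),
      n_discarded = e$n_discarded,
      equil_time = e$equil_steps * params$timestep,
      total_time = e$total_time,
      exit_times = list(e$exit_times),
      snapshots = list(e$snapshots))
    if (progress)
      message(sprintf("event %d/%d: tau = %.1f t_LJ (%d discarded)",
                      ev, n_events, e$total_time, e$n_discarded))
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "n_monomers") <- params$n_monomers
  class(out) <- c("pt_ensemble", class(out))
  out
}
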