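#' Polymer state: positions, velocities and time
#'
#' @param positions N x 3 matrix of bead coordinates (sigma units).
#' @param velocities N x 3 matrix (sigma/t_LJ); zeros if omitted.
#' @param time simulation time in t_LJ units.
#' @return A `polymer_state` object.
#' @export
polymer_state <- function(positions, velocities = NULL, time = 0) {
  positions <- as.matrix(positions)
  stopifnot(ncol(positions) == 3, all(is.finite(positions)))
  storage.mode(positions) <- "double"
  dimnames(positions) <- NULL
  if (is.null(velocities))
    velocities <- matrix(0, nrow(positions), 3)
  velocities <- as.matrix(velocities)
  stopifnot(dim(velocities)[1] == nrow(positions), ncol(velocities) == 3,
            all(is.finite(velocities)))
  storage.mode(velocities) <- "double"
  dimnames(velocities) <- NULL
  structure(list(positions = positions, velocities = velocities,
                 time = as.numeric(time)),
            class = "polymer_state")
}

#' @export
print.polymer_state <- function(x, ...) {
  cat(sprintf("<polymer_state> %d beads at t = %g t_LJ\n",
              nrow(x$positions), x$time))
  invisible(x)
}

#' Draw Maxwell-Boltzmann velocities
#'
#' Each Cartesian component is independent Gaussian with variance kT/m.
#'
#' @param n number of beads.
#' @param params a [simulation_parameters()] object.
#' @return n x 3 matrix of velocities.
#' @export
maxwell_velocities <- function(n, params) {
  matrix(rnorm(3 * n, sd = sqrt(params$kT / params$monomer_mass)), n, 3)
}

# internal: the flat model list handed to the C++ engine
.model_list <- function(params, geom) {
  list(
    n = params$n_monomers,
    sigma = params$sigma,
    mass = params$monomer_mass,
    kT = params$kT,
    xi = params$friction,
    fene_k = params$fene_k,
    fene_r0 = params$fene_r0,
    eps_mm = params$epsilon0,
    eps_pore = params$pore_epsilon,
    cutoff_wca = params$cutoff_wca,
    cutoff_pore = params$cutoff_pore,
    pull_force = params$pull_force,
    pore_shifted = identical(params$pore_dialect, "shifted"),
    geom = unclass(geom)
  )
}
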