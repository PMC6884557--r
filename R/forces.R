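# Scalar potentials (documented reference forms) plus the full per-bead
# force evaluation, which is delegated to the compiled engine.

#' WCA (truncated, shifted-up Lennard-Jones) pair energy
#'
#' `4 eps [ (sigma/r)^12 - (sigma/r)^6 ] + eps` for separations up to
#' `2^(1/6) sigma`,
#' zero beyond: purely repulsive excluded volume acting between all bead
#' pairs and between beads and the walls.
#'
#' @param r separation (sigma units); vectorised.
#' @param eps well depth (eps0 units).
#' @param sigma bead diameter.
#' @return Energy in eps0 units.
#' @export
wca_energy <- function(r, eps = 1, sigma = 1) {
  if (any(r <= 0)) stop("overlap: separation r must be positive")
  rc <- 2^(1/6) * sigma
  sr6 <- (sigma / r)^6
  ifelse(r <= rc, 4 * eps * (sr6^2 - sr6) + eps, 0)
}

#' Attractive monomer-pore Lennard-Jones energy
#'
#' The pore inner surface attracts beads through an LJ potential cut at
#' 2.5 sigma. Two dialects of the cutoff are provided: `"literal"` keeps the
#' plus-epsilon form `4 eps [(sigma/r)^12 - (sigma/r)^6] + eps`, which jumps
#' by about `0.984 eps` to zero at the cutoff; `"shifted"` (the default used
#' by the simulator) subtracts the LJ value at the cutoff instead, making
#' the potential continuous while changing the well depth by under 2%.
#'
#' @inheritParams wca_energy
#' @param dialect `"shifted"` or `"literal"`.
#' @return Energy in eps0 units.
#' @export
pore_lj_energy <- function(r, eps = 1, dialect = c("shifted", "literal"),
                           sigma = 1) {
  dialect <- match.arg(dialect)
  if (any(r <= 0)) stop("overlap: separation r must be positive")
  rc <- 2.5 * sigma
  sr6 <- (sigma / r)^6
  tail <- if (dialect == "literal") eps else {
    src6 <- (sigma / rc)^6
    -4 * eps * (src6^2 - src6)
  }
  ifelse(r <= rc, 4 * eps * (sr6^2 - sr6) + tail, 0)
}

#' FENE bond energy and force magnitude
#'
#' `U(r) = -k R0^2 / 2 * log(1 - r^2/R0^2)`, diverging at the maximal
#' extension `R0`; the restoring force magnitude is `k r / (1 - r^2/R0^2)`,
#' attractive along the bond.
#'
#' @param r bond length (sigma units); vectorised.
#' @param k spring constant (eps0/sigma^2).
#' @param r0 maximal extension (sigma units).
#' @return Energy in eps0 units (`fene_energy`) or force magnitude in
#'   eps0/sigma (`fene_force_mag`).
#' @export
fene_energy <- function(r, k = 30, r0 = 1.5) {
  if (any(r < 0)) stop("bond length must be non-negative")
  if (any(r >= r0)) stop("FENE bond overstretch: r >= R0")
  -0.5 * k * r0^2 * log(1 - r^2 / r0^2)
}

#' @rdname fene_energy
#' @export
fene_force_mag <- function(r, k = 30, r0 = 1.5) {
  if (any(r < 0)) stop("bond length must be non-negative")
  if (any(r >= r0)) stop("FENE bond overstretch: r >= R0")
  k * r / (1 - r^2 / r0^2)
}

#' Pulling force on a bead
#'
#' `f * x_hat` if the bead is inside the pore, zero elsewhere: the drive acts
#' only on the monomers currently within the pore.
#'
#' @param point 3-vector bead position.
#' @param geom a [membrane_geometry()] object.
#' @param f force magnitude (eps0/sigma).
#' @return Force 3-vector.
#' @export
external_force <- function(point, geom, f) {
  if (region_of(point, geom) == "pore") c(f, 0, 0) else c(0, 0, 0)
}

#' Total forces on every bead, with component breakdown
#'
#' Sums, per bead: WCA pair repulsion over all bead pairs (bonded neighbours
#' included, the standard combined FENE+WCA bond), FENE forces on adjacent
#' pairs, repulsive WCA wall forces through the bead-to-wall distance,
#' attractive pore LJ forces through the bead-to-cylinder distance, and the
#' pulling force on beads inside the pore. Pair forces obey Newton's third
#' law exactly.
#'
#' @param state a [polymer_state()].
#' @param geom a [membrane_geometry()].
#' @param params a [simulation_parameters()].
#' @param use_external logical; include the pulling force?
#' @return A `force_report` list: `total` (N x 3), per-component N x 3
#'   matrices `wca_pair`, `fene`, `wall`, `pore`, `external`, and the scalar
#'   `potential_energy` (the external force, being non-conservative, carries
#'   no potential term).
#' @export
total_forces <- function(state, geom, params, use_external = TRUE) {
  stopifnot(inherits(state, "polymer_state"),
            nrow(state$positions) == params$n_monomers)
  rep <- cpp_total_forces(state$positions, .model_list(params, geom),
                          use_external)
  structure(rep, class = "force_report")
}

#' @export
print.force_report <- function(x, ...) {
  cat(sprintf("<force_report> %d beads, potential energy %.6g eps0\n",
              nrow(x$total), x$potential_energy))
  invisible(x)
}

#' Equilibrium bond length of the combined FENE + WCA bond
#'
#' The separation at which WCA repulsion and FENE attraction cancel
#' (about 0.96 sigma for k = 30, R0 = 1.5).
#'
#' @param params a [simulation_parameters()].
#' @return Bond length in sigma units.
#' @export
equilibrium_bond_length <- function(params) {
  s <- params$sigma
  wca_f <- function(r) {
    sr6 <- (s / r)^6
    24 * params$epsilon0 * (2 * sr6^2 - sr6) / r
  }
  fene_f <- function(r) params$fene_k * r / (1 - r^2 / params$fene_r0^2)
  uniroot(function(r) wca_f(r) - fene_f(r),
          interval = c(0.8 * s, 2^(1/6) * s), tol = 1e-12)$root
}
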