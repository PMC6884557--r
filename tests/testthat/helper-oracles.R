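# Independent oracles used by the unit and acceptance tests. They share no
# code with the implementation paths they check.

# Brute-force distance to the membrane via its generating curves: for an
# axisymmetric surface the nearest surface point lies in the meridian plane
# of the query point, so minimising over densely sampled generating curves
# (wall faces: x = x_w, radius in [R_p, r_max]; cylinder: radius = R_p,
# x in the pore span; rim circles are the shared curve endpoints) is an
# exact reduction of minimising over a surface triangulation.
oracle_membrane_distances <- function(pts, geom, ds = 5e-4, r_max = 12) {
  rho <- sqrt((pts[, 2] - geom$pore_center[2])^2 +
              (pts[, 3] - geom$pore_center[3])^2)
  x <- pts[, 1]
  face_r <- seq(geom$pore_radius, r_max, by = ds)
  cyl_x <- seq(geom$cis_plane_x, geom$trans_plane_x, by = ds)
  wall <- pore <- numeric(nrow(pts))
  for (i in seq_len(nrow(pts))) {
    d_faces <- min(sqrt((x[i] - geom$cis_plane_x)^2 + (rho[i] - face_r)^2),
                   sqrt((x[i] - geom$trans_plane_x)^2 + (rho[i] - face_r)^2))
    wall[i] <- d_faces
    pore[i] <- min(sqrt((x[i] - cyl_x)^2 + (rho[i] - geom$pore_radius)^2))
  }
  list(wall = wall, pore = pore)
}

# Central-difference gradient of the potential energy (external force
# excluded: it is non-conservative).
oracle_numeric_forces <- function(positions, geom, params, h = 1e-6) {
  pot <- function(p) total_forces(polymer_state(p), geom, params,
                                  use_external = FALSE)$potential_energy
  grad <- matrix(0, nrow(positions), 3)
  for (i in seq_len(nrow(positions))) {
    for (k in 1:3) {
      pp <- pm <- positions
      pp[i, k] <- pp[i, k] + h
      pm[i, k] <- pm[i, k] - h
      grad[i, k] <- (pot(pp) - pot(pm)) / (2 * h)
    }
  }
  -grad
}

# Direct double-loop evaluation of the shape factor.
oracle_delta <- function(positions) {
  n <- nrow(positions)
  ctr <- colMeans(positions)
  rg2 <- 0
  for (i in seq_len(n)) rg2 <- rg2 + sum((positions[i, ] - ctr)^2)
  rg <- sqrt(rg2 / n)
  inv_sum <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j)
    inv_sum <- inv_sum + 1 / sqrt(sum((positions[i, ] - positions[j, ])^2))
  rg * inv_sum / n^2
}

# A bead chain near the pore with random jitter but safe separations, for
# gradient and symmetry checks.
random_chain_near_pore <- function(n, geom, spread = 0.12) {
  base_x <- geom$trans_plane_x + 0.5 - (seq_len(n) - 1) * 0.97
  cbind(base_x + runif(n, -spread, spread),
        geom$pore_center[2] + runif(n, -spread, spread),
        geom$pore_center[3] + runif(n, -spread, spread))
}

# Deterministic bead-filled ball fixture: cubic grid points inside a ball.
ball_fixture <- function(radius = 1, h = 0.15) {
  g <- seq(-radius, radius, by = h)
  pts <- as.matrix(expand.grid(x = g, y = g, z = g))
  pts[rowSums(pts^2) <= radius^2, , drop = FALSE]
}

# Collinear rod of n equally spaced beads.
rod_fixture <- function(n, spacing = 1) {
  cbind(seq_len(n) * spacing, rep(0, n), rep(0, n))
}
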