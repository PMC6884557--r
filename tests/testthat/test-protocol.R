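test_that("initial configuration threads the chain through the pore", {
  p <- simulation_parameters()
  g <- membrane_geometry(p)
  st <- build_initial_configuration(p, g)
  pos <- st$positions
  # bead 1 anchored exactly at the trans exit plane, on the axis
  expect_identical(pos[1, 1], g$trans_plane_x)
  expect_equal(pos[1, 2:3], g$pore_center[2:3])
  # with bond length ~0.96 sigma, beads 1..7 span the 6-sigma pore
  region <- region_of(pos, g)
  expect_identical(region[1:7], rep("pore", 7))
  expect_identical(region[8:50], rep("cis", 43))
  # bonds near equilibrium and well below the FENE limit
  d <- sqrt(rowSums(diff(pos)^2))
  expect_true(all(d < p$fene_r0))
  expect_true(all(abs(d - equilibrium_bond_length(p)) < 0.05))
  # no bead overlaps a membrane surface
  expect_true(all(wall_distance(pos, g) > 2^(1/6)))
  expect_true(all(pore_surface_distance(pos, g) > 2^(1/6) |
                  sqrt((pos[, 2] - 38)^2 + (pos[, 3] - 40)^2) < p$pore_radius))
  # beads inside the pore lie on the axis; cis beads are off-axis
  expect_true(all(pos[1:7, 2] == g$pore_center[2]))
  expect_true(all(pos[8:50, 2] != g$pore_center[2] |
                  pos[8:50, 3] != g$pore_center[3]))
})

test_that("equilibration pins the pore beads and relaxes only the tail", {
  p <- simulation_parameters(n_monomers = 25)
  g <- membrane_geometry(p)
  cfg <- integrator_config()
  st0 <- build_initial_configuration(p, g)
  pinned <- region_of(st0$positions, g) == "pore"
  pinned[1] <- TRUE
  set.seed(5)
  st1 <- equilibrate(st0, g, p, cfg)
  expect_identical(st1$positions[pinned, ], st0$positions[pinned, ])
  expect_false(isTRUE(all.equal(st1$positions[!pinned, ],
                                st0$positions[!pinned, ])))
  expect_gt(attr(st1, "equil_steps"), 0)
  # different seeds give different tails but identical pinned beads
  set.seed(6)
  st2 <- equilibrate(st0, g, p, cfg)
  expect_identical(st2$positions[pinned, ], st1$positions[pinned, ])
  expect_false(isTRUE(all.equal(st2$positions[!pinned, ],
                                st1$positions[!pinned, ])))
  # an already-equilibrated tail converges at the first full window
  set.seed(7)
  st3 <- equilibrate(polymer_state(st1$positions), g, p, cfg,
                     sample_every = 50L, window = 200L)
  expect_lte(attr(st3, "equil_steps"), 50L * 200L)
  # velocities are re-drawn from the Maxwell distribution on return
  expect_gt(sd(st1$velocities), 0)
})

test_that("equilibration failure to converge raises an error", {
  p <- simulation_parameters(n_monomers = 25)
  g <- membrane_geometry(p)
  st0 <- build_initial_configuration(p, g)
  set.seed(1)
  expect_error(equilibrate(st0, g, p, integrator_config(), max_steps = 100L),
               "did not converge")
})

test_that("events complete with monotone gap-free first-passage times", {
  p <- simulation_parameters(n_monomers = 20, pore_radius = 3,
                             pore_epsilon = 0.1)
  ens <- run_ensemble(p, n_events = 8L, base_seed = 12L)
  expect_identical(nrow(ens), 8L)
  # easy condition (wide pore, weak attraction, strong force): no discards
  expect_true(all(ens$attempts == 1L))
  expect_true(all(ens$n_discarded == 0L))
  for (ev in ens$exit_times) {
    expect_length(ev, 20)
    expect_true(all(is.finite(ev)))        # no gaps: every s was reached
    expect_true(all(diff(ev) >= 0))        # first-passage watermark
    expect_gt(ev[1], 0)
  }
  expect_equal(ens$total_time,
               vapply(ens$exit_times, function(x) x[20], 0))
})

test_that("ensembles are reproducible and streams independent", {
  p <- simulation_parameters(n_monomers = 20, pore_radius = 3,
                             pore_epsilon = 0.1)
  a <- run_ensemble(p, n_events = 3L, base_seed = 21L)
  b <- run_ensemble(p, n_events = 3L, base_seed = 21L)
  expect_identical(a$total_time, b$total_time)
  expect_identical(a$exit_times, b$exit_times)
  # a different base seed decorrelates every event
  c_ <- run_ensemble(p, n_events = 3L, base_seed = 22L)
  expect_false(any(c_$total_time == a$total_time))
  # event 2 alone can be reproduced from its (seed, stream) pair
  cfg <- integrator_config(timestep = p$timestep, rng_seed = 21L,
                           rng_stream = 2L)
  ev <- run_event(p, cfg)
  expect_identical(ev$exit_times, a$exit_times[[2]])
})

test_that("snapshots are captured at each first-passage instant", {
  p <- simulation_parameters(n_monomers = 15, pore_radius = 3,
                             pore_epsilon = 0.1)
  cfg <- integrator_config(rng_seed = 8, rng_stream = 1)
  ev <- run_event(p, cfg, record_snapshots = TRUE)
  g <- membrane_geometry(p)
  expect_length(ev$snapshots, 15)
  for (s in c(1, 7, 15)) {
    snap <- ev$snapshots[[s]]
    expect_identical(dim(snap), c(15L, 3L))
    # at the instant the count first reached s, at least s beads are past
    # the plane (more only if several crossed within one step)
    expect_gte(sum(snap[, 1] > g$trans_plane_x), s)
  }
})
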