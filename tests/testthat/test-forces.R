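params_default <- simulation_parameters()
geom_d <- membrane_geometry(params_default)

test_that("WCA energy has the shifted-minimum form", {
  expect_equal(wca_energy(2^(1/6)), 0)
  expect_equal(wca_energy(1), 1)        # 4(1-1) + eps
  expect_equal(wca_energy(1.5), 0)      # beyond cutoff
  expect_equal(wca_energy(1, eps = 3), 3)
  expect_error(wca_energy(-0.1), "overlap")
})

test_that("pore LJ dialects differ only by their cutoff treatment", {
  # literal form: zero at the LJ minimum, jump of ~0.9837 eps at the cutoff
  expect_equal(pore_lj_energy(2^(1/6), dialect = "literal"), 0)
  expect_equal(pore_lj_energy(2.5 - 1e-12, dialect = "literal"),
               4 * (0.4^12 - 0.4^6) + 1, tolerance = 1e-9)
  expect_equal(round(pore_lj_energy(2.5 - 1e-12, dialect = "literal"), 4),
               0.9837)
  # shifted form is continuous at the cutoff
  expect_equal(pore_lj_energy(2.5, dialect = "shifted"), 0)
  rs <- seq(1.05, 3, by = 1e-4)
  u <- pore_lj_energy(rs, eps = 5, dialect = "shifted")
  expect_lt(max(abs(diff(u))), 0.02)  # no jump anywhere on a fine grid
  # forces (well shape) identical: curves differ by a constant inside rc
  inside <- rs <= 2.5
  expect_equal(diff(range(pore_lj_energy(rs[inside], dialect = "literal") -
                          u[inside] / 5)), 0, tolerance = 1e-12)
})

test_that("FENE bond follows the logarithmic potential with divergence at R0", {
  expect_equal(fene_energy(0), 0)
  expect_equal(fene_force_mag(0), 0)
  # closed forms at r = 1, k = 30, R0 = 1.5
  expect_equal(fene_energy(1), -33.75 * log(5 / 9), tolerance = 1e-12)
  expect_equal(round(fene_energy(1), 2), 19.84)
  expect_equal(fene_force_mag(1), 30 / (5 / 9), tolerance = 1e-12)
  expect_gt(fene_force_mag(1.499), 1e3)
  expect_error(fene_energy(1.5), "overstretch")
  expect_error(fene_force_mag(1.6), "overstretch")
})

test_that("pulling force acts only inside the pore, along +x", {
  g <- geom_d
  expect_equal(external_force(g$pore_center, g, 2), c(2, 0, 0))
  expect_equal(external_force(c(g$cis_plane_x - 1, 38, 40), g, 2), c(0, 0, 0))
  expect_equal(external_force(c(g$trans_plane_x + 0.01, 38, 40), g, 2),
               c(0, 0, 0))
})

test_that("total forces decompose, balance and match the energy gradient", {
  set.seed(3)
  p <- simulation_parameters(n_monomers = 7, pore_epsilon = 3)
  g <- membrane_geometry(p)
  for (rep in 1:4) {
    pos <- random_chain_near_pore(7, g)
    st <- polymer_state(pos)
    fr <- total_forces(st, g, p)
    # total equals the sum of the components
    comp_sum <- fr$wca_pair + fr$fene + fr$wall + fr$pore + fr$external
    expect_equal(fr$total, comp_sum, tolerance = 1e-10)
    # internal pair forces conserve momentum
    expect_equal(colSums(fr$wca_pair), c(0, 0, 0), tolerance = 1e-10)
    expect_equal(colSums(fr$fene), c(0, 0, 0), tolerance = 1e-10)
    # analytic force = -grad U (central differences, external excluded)
    fa <- total_forces(st, g, p, use_external = FALSE)$total
    fn <- oracle_numeric_forces(pos, g, p)
    expect_lt(max(abs(fa - fn)) / max(abs(fa)), 1e-6)
  }
})

test_that("bonded WCA+FENE pair is force-free at the equilibrium length", {
  p <- simulation_parameters(n_monomers = 2, pore_epsilon = 0)
  g <- membrane_geometry(p)
  r_eq <- equilibrium_bond_length(p)
  expect_equal(round(r_eq, 2), 0.96)
  pos <- rbind(c(0, 0, 0), c(r_eq, 0, 0))  # far from the membrane
  fr <- total_forces(polymer_state(pos), g, p, use_external = FALSE)
  expect_equal(max(abs(fr$total)), 0, tolerance = 1e-9)
})

test_that("an isolated bead far from the membrane feels no force", {
  p <- simulation_parameters(n_monomers = 1)
  g <- membrane_geometry(p)
  fr <- total_forces(polymer_state(matrix(c(0, 0, 0), 1)), g, p)
  expect_equal(fr$total, matrix(0, 1, 3))
  expect_equal(fr$potential_energy, 0)
})

test_that("force field is mirror-symmetric about the pore axis", {
  p <- simulation_parameters(n_monomers = 4, pore_epsilon = 5)
  g <- membrane_geometry(p)
  set.seed(11)
  pos <- random_chain_near_pore(4, g)
  # reflect y about the axis plane
  pos_m <- pos
  pos_m[, 2] <- 2 * g$pore_center[2] - pos[, 2]
  f1 <- total_forces(polymer_state(pos), g, p)$total
  f2 <- total_forces(polymer_state(pos_m), g, p)$total
  expect_equal(f2[, 1], f1[, 1], tolerance = 1e-12)
  expect_equal(f2[, 2], -f1[, 2], tolerance = 1e-12)
  expect_equal(f2[, 3], f1[, 3], tolerance = 1e-12)
})

test_that("bead overlap and overstretch abort with bead indices", {
  p <- simulation_parameters(n_monomers = 2)
  g <- membrane_geometry(p)
  pos <- rbind(c(0, 0, 0), c(1e-12, 0, 0))
  expect_error(poretrans:::cpp_total_forces(pos, poretrans:::.model_list(p, g), TRUE),
               "beads 1 and 2")
})
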