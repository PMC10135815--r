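test_that("harmonic bond term matches the closed form", {
  expect_equal(bond_energy_force(0.38)$energy, 0)
  expect_equal(bond_energy_force(0.39)$energy, 2.0, tolerance = 1e-12)
  expect_equal(bond_energy_force(0.37)$energy, bond_energy_force(0.39)$energy,
               tolerance = 1e-12)
  expect_equal(bond_energy_force(0.39)$force, -400, tolerance = 1e-12)
  expect_error(bond_energy_force(-0.1))
})

test_that("LJ term follows the printed (no factor 4) convention", {
  expect_equal(lj_energy_force(1.0, 0.001, r_cut = Inf)$energy, 0)
  rmin <- 2^(1/6)
  expect_equal(lj_energy_force(rmin, 0.001, r_cut = Inf)$energy, -0.00025,
               tolerance = 1e-12)
  expect_equal(lj_energy_force(rmin, 0.001, r_cut = Inf)$force, 0,
               tolerance = 1e-12)
  # standard convention is exactly 4x the printed one at every r
  r <- seq(0.8, 4, by = 0.1)
  expect_equal(lj_energy_force(r, 0.001, mode = "standard_4eps", r_cut = Inf)$energy,
               4 * lj_energy_force(r, 0.001, r_cut = Inf)$energy,
               tolerance = 1e-12)
  # decay to zero from below
  expect_lt(lj_energy_force(5, 0.001, r_cut = Inf)$energy, 0)
  expect_gt(lj_energy_force(5, 0.001, r_cut = Inf)$energy, -1e-5)
  # truncation: zero beyond the cutoff, continuous (shifted) at it
  expect_equal(lj_energy_force(3.5, 0.001, r_cut = 3)$energy, 0)
  expect_error(lj_energy_force(1e-8, 0.001), "overlap")
})

test_that("Debye screening follows kappa = 3.2 sqrt(C_salt)", {
  expect_equal(kappa_from_salt(0.01), 0.32)
  expect_equal(kappa_from_salt(0), 0)
  expect_equal(kappa_from_salt(1.0), 3.2)
  expect_error(kappa_from_salt(-0.1), "negative")
})

test_that("Debye-Hueckel term matches direct evaluation", {
  expect_equal(dh_energy_force(1, 1, 1, kappa = 0, r_cut = Inf)$energy,
               138.94 / 80, tolerance = 1e-12)
  expect_equal(dh_energy_force(1, 1, 0, kappa = 0, r_cut = Inf)$energy, 0)
  expect_equal(dh_energy_force(1, 1, -1, kappa = 0.32, r_cut = Inf)$energy,
               -(138.94 / 80) * exp(-0.32), tolerance = 1e-12)
  # kappa -> 0 with B = 1 reduces to Coulomb / dielectric
  r <- c(0.5, 1, 2)
  expect_equal(dh_energy_force(r, 1, -1, kappa = 0, r_cut = Inf)$energy,
               -138.94 / (80 * r), tolerance = 1e-12)
})

test_that("two-bead configurations reproduce trivial totals", {
  # two beads, no bond, no charge, r = sigma, negligible shift
  topo <- structure(list(
    beads = data.frame(residue = c("G", "G"), mass = 1, charge = 0L,
                       is_insert = FALSE, chain_id = 1:2, index_in_chain = 1L),
    bonds = matrix(integer(0), ncol = 2), n_chains = 2L, chain_length = 1L,
    box = c(200, 200, 200)), class = "cg_topology")
  coords <- rbind(c(50, 50, 50), c(51, 50, 50))
  ff <- force_field(charge_mode = "no_charge", r_cut_lj = 90)
  e <- total_energy_forces(topo, coords, ff)
  expect_equal(e$energy, 0, tolerance = 1e-10)

  # straight 3-bead chain at exact r0 spacing, eps = 0, no charges
  topo3 <- replicate_system(chain_spec("GGG"), 1, c(50, 50, 50), seed = 1)$topology
  x3 <- rbind(c(10, 10, 10), c(10.38, 10, 10), c(10.76, 10, 10))
  e3 <- total_energy_forces(topo3, x3, force_field(eps = 0, eps_insert = 0,
                                                   charge_mode = "no_charge"))
  expect_equal(e3$energy, 0, tolerance = 1e-12)
})

test_that("engine energies and forces match the brute-force R oracle", {
  sys <- make_test_system(n_chains = 6, L = 5, box = c(6, 6, 6), seed = 3,
                          n_neg = 1, n_pos = 2)
  ff <- force_field(kappa = kappa_from_salt(0.01))
  oracle <- brute_energy_forces(sys$topology, sys$coords, ff)
  for (method in c("cell", "brute")) {
    got <- total_energy_forces(sys$topology, sys$coords, ff, method = method)
    expect_equal(got$energy, oracle$energy, tolerance = 1e-10)
    expect_equal(unname(got$components), unname(oracle$components),
                 tolerance = 1e-10)
    expect_equal(got$forces, oracle$forces, tolerance = 1e-10)
  }
})

test_that("insert pairs are evaluated on the reduced eps scale", {
  sys <- make_test_system(n_chains = 4, L = 6, box = c(7, 7, 7), seed = 5,
                          n_neg = 1, n_pos = 1, insertion_mode = "tail10")
  ff <- force_field(kappa = 0.32)
  oracle <- brute_energy_forces(sys$topology, sys$coords, ff)
  got <- total_energy_forces(sys$topology, sys$coords, ff)
  expect_equal(got$energy, oracle$energy, tolerance = 1e-10)
  expect_equal(got$forces, oracle$forces, tolerance = 1e-10)
})

test_that("cell-list path equals the brute-force path exactly", {
  sys <- make_test_system(n_chains = 20, L = 20, box = c(9, 9, 9), seed = 8,
                          n_neg = 3, n_pos = 4)  # 400 beads
  for (ff in list(force_field(kappa = 0.32),
                  force_field(charge_mode = "no_charge"))) {
    a <- total_energy_forces(sys$topology, sys$coords, ff, method = "cell")
    b <- total_energy_forces(sys$topology, sys$coords, ff, method = "brute")
    expect_equal(a$energy, b$energy, tolerance = 1e-14)
    expect_equal(a$forces, b$forces, tolerance = 1e-13)
  }
})

test_that("analytic forces are the negative numerical energy gradient", {
  sys <- make_test_system(n_chains = 5, L = 6, box = c(6, 6, 6), seed = 4,
                          n_neg = 2, n_pos = 1)
  ff <- force_field(kappa = 0.32)
  expect_lt(check_forces(sys$topology, sys$coords, ff, n_beads = 12), 1e-6)
})

test_that("energy is invariant under rigid and lattice translations", {
  sys <- make_test_system(n_chains = 5, L = 5, box = c(6, 6, 6), seed = 9,
                          n_neg = 1, n_pos = 1)
  ff <- force_field(kappa = 0.32)
  e0 <- total_energy_forces(sys$topology, sys$coords, ff)$energy
  shifted <- sweep(sys$coords, 2, c(1.3, -0.7, 2.9), "+")
  expect_equal(total_energy_forces(sys$topology, shifted, ff)$energy, e0,
               tolerance = 1e-9)
  # translate one bead by a full box vector
  lat <- sys$coords
  lat[7, 3] <- lat[7, 3] + sys$topology$box[3]
  expect_equal(total_energy_forces(sys$topology, lat, ff)$energy, e0,
               tolerance = 1e-9)
})

test_that("the no-charge mode zeroes the electrostatic term entirely", {
  sys <- make_test_system(n_chains = 4, L = 5, box = c(6, 6, 6), seed = 6,
                          n_neg = 2, n_pos = 2)
  e <- total_energy_forces(sys$topology, sys$coords,
                           force_field(charge_mode = "no_charge", kappa = 0.32))
  expect_equal(unname(e$components["dh"]), 0)
})
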