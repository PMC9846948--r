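test_that("two-atom Lennard-Jones and Coulomb limits are exact", {
  pars <- ff_params(data.frame(element = "Ar", epsilon = 0.5, sigma = 3.0),
                    vdw_cutoff = 15.5)
  two_at <- function(r, q = c(0, 0)) {
    molecular_system(data.frame(element = "Ar", mass = 39.95, charge = q,
                                x = c(0, r), y = 0, z = 0))
  }
  # LJ zero crossing at r = sigma
  expect_equal(nonbonded_energy(two_at(3.0), pars), 0, tolerance = 1e-12)
  # LJ minimum -epsilon at r = 2^(1/6) sigma
  expect_equal(nonbonded_energy(two_at(2^(1 / 6) * 3.0), pars), -0.5,
               tolerance = 1e-12)
  # pure Coulomb: +1e and -1e at 2 Angstrom
  pars0 <- ff_params(data.frame(element = "Ar", epsilon = 0, sigma = 3.0),
                     vdw_cutoff = 15.5, coulomb_method = "direct_sum")
  expect_equal(nonbonded_energy(two_at(2.0, c(1, -1)), pars0),
               -332.0637 / 2, tolerance = 1e-12)
  expect_error(nonbonded_energy(two_at(1e-9), pars), "overlapping")
  bad <- molecular_system(data.frame(element = "Xx", mass = 1, charge = 0,
                                     x = c(0, 2), y = 0, z = 0))
  expect_error(nonbonded_energy(bad, pars), "Xx")
})

test_that("vectorized energy equals the literal double-loop oracle", {
  pars <- ff_params(data.frame(element = "Ar", epsilon = 0.3, sigma = 2.5),
                    vdw_cutoff = 6.0, coulomb_method = "direct_sum")
  for (seed in 1:10) {
    sys <- random_cluster(30, seed)
    expect_equal(nonbonded_energy(sys, pars), naive_energy(sys, pars),
                 tolerance = 1e-12)
  }
})

test_that("energy is invariant under rigid motion and atom reordering", {
  pars <- ff_params(data.frame(element = "Ar", epsilon = 0.3, sigma = 2.5),
                    vdw_cutoff = 8.0)
  sys <- random_cluster(25, 99)
  e0 <- nonbonded_energy(sys, pars)
  # translation
  at <- sys$atoms; at$x <- at$x + 13.7; at$z <- at$z - 4.2
  expect_equal(nonbonded_energy(molecular_system(at), pars), e0, tolerance = 1e-9)
  # rotation about z by 37 degrees
  th <- 37 * pi / 180
  at2 <- sys$atoms
  x <- at2$x * cos(th) - at2$y * sin(th)
  at2$y <- at2$x * sin(th) + at2$y * cos(th); at2$x <- x
  expect_equal(nonbonded_energy(molecular_system(at2), pars), e0, tolerance = 1e-9)
  # permutation
  at3 <- sys$atoms[sample(nrow(sys$atoms)), ]
  expect_equal(nonbonded_energy(molecular_system(at3), pars), e0, tolerance = 1e-9)
})

test_that("enlarging the cutoff only deepens a purely attractive tail", {
  pars_at <- function(rc) ff_params(data.frame(element = "Ar", epsilon = 0.3,
                                               sigma = 2.5), vdw_cutoff = rc)
  # chain of atoms all beyond the LJ minimum: every pair attractive
  at <- data.frame(element = "Ar", mass = 39.95, charge = 0,
                   x = seq(0, 40, by = 4), y = 0, z = 0)
  sys <- molecular_system(at)
  es <- vapply(c(5, 9, 13, 17, 25), function(rc) nonbonded_energy(sys, pars_at(rc)),
               numeric(1))
  expect_true(all(diff(es) <= 1e-12))   # magnitudes never shrink
})

test_that("interaction-energy breakdown obeys its defining identity", {
  pars <- toy_lj_params(cutoff = 15.5, epsilon = 0.2, sigma = 3.0)
  # separation beyond the cutoff: no cross pairs, E_int exactly zero
  far <- adsorption_config(adsorbate_count = 5, separation = 20, seed = 2)
  bd <- interaction_energy(far, pars)
  expect_identical(bd$e_int, 0)
  expect_equal(bd$e_tot, bd$e_cry + bd$e_sol)
  # LJ-contact adsorbate: adhesion is negative
  near <- adsorption_config(adsorbate_count = 5,
                            separation = 2^(1 / 6) * 3.0, seed = 2)
  bdn <- interaction_energy(near, pars)
  expect_lt(bdn$e_int, 0)
  expect_equal(bdn$e_int, bdn$e_tot - (bdn$e_cry + bdn$e_sol), tolerance = 1e-9)
  # single adatom above a single fixed atom at the LJ minimum: e_int = -eps
  one <- molecular_system(data.frame(
    element = "Ar", mass = 39.95, charge = 0,
    x = 0, y = 0, z = c(0, 2^(1 / 6) * 3.0),
    molecule_id = 1:2, role = c("crystal", "water")))
  expect_equal(interaction_energy(one, pars)$e_int, -0.2, tolerance = 1e-12)
  expect_error(interaction_energy(subset_roles(near, "crystal"), pars),
               "solvent")
})

test_that("modified attachment energy implements E_att' = E_att - s E_int", {
  expect_equal(modified_attachment_energy(-250.08, 0), -250.08)
  expect_equal(modified_attachment_energy(-250.08, -50, 1), -200.08)
  expect_equal(modified_attachment_energy(-250.08, -50, 0.5), -225.08)
  expect_error(modified_attachment_energy(10, -50), "<= 0")
  # adsorption (E_int < 0, |s e_int| < |e_att|) always slows growth
  set.seed(5)
  for (trial in 1:50) {
    ea <- -runif(1, 50, 400)
    ei <- -runif(1, 0, 0.9 * abs(ea))
    expect_lt(abs(modified_attachment_energy(ea, ei)), abs(ea))
  }
})

test_that("toy attachment energy matches the direct lattice sum", {
  a <- 1.5; eps <- 0.25; sig <- 1.2; rc <- 3.2
  xt <- toy_crystal("cubic", a = a, repeats = c(5, 5, 5))
  pars <- toy_lj_params(cutoff = rc, epsilon = eps, sigma = sig)
  bd <- attachment_energy_toy(xt, c(1, 0, 0), pars)
  e_ref <- lattice_sum_attachment(a, eps, sig, rc)
  expect_equal(bd$e_att, e_ref, tolerance = 1e-6)
  expect_lt(bd$e_att, 0)
  expect_equal(bd$e_att, bd$e_latt - bd$e_slice, tolerance = 1e-12)
  # extensivity: doubling the in-plane supercell leaves per-cell e_att fixed
  xt2 <- toy_crystal("cubic", a = a, repeats = c(5, 10, 5))
  bd2 <- attachment_energy_toy(xt2, c(1, 0, 0), pars)
  expect_equal(bd2$e_att, bd$e_att, tolerance = 1e-9)
  # slice thickness spanning the whole crystal (with vacuum): e_att -> 0
  xtv <- toy_crystal("cubic", a = a, repeats = c(5, 5, 3), vacuum = 10)
  bdv <- attachment_energy_toy(xtv, c(0, 0, 1), pars,
                               slice_thickness = 3 * a + 0.1)
  expect_equal(bdv$e_att, 0, tolerance = 1e-9)
  # minimum-image guard
  expect_error(attachment_energy_toy(toy_crystal("cubic", a = a,
                                                 repeats = c(2, 2, 2)),
                                     c(1, 0, 0), pars), "minimum-image")
})
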