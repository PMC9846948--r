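test_that("profiles conserve mass per role and convert units correctly", {
  layers <- data.frame(center = c(22.3, 31.0), width = c(1.5, 2.5),
                       role = c("organic", "water"), mass = c(41.05, 18.015),
                       n_atoms = c(150, 300))
  fs <- layered_frames(layers, n_frames = 10, lx = 30, ly = 30, noise = 0.3,
                       seed = 5)
  prof <- mass_density_profile(fs, bin_width = 0.5)
  centers <- profile_bin_centers(prof)
  for (r in c("organic", "water")) {
    integ <- sum(prof$density[, r]) * prof$cross_section * prof$bin_width / 1.66053907
    truth <- sum(layers$mass[layers$role == r] * layers$n_atoms[layers$role == r])
    expect_equal(integ, truth, tolerance = 1e-3)
  }
  expect_true(all(prof$density >= 0))
  # single frame conserves mass to machine precision
  p1 <- mass_density_profile(fs$frames[[1]], bin_width = 0.5)
  for (r in c("organic", "water")) {
    integ <- sum(p1$density[, r]) * p1$cross_section * p1$bin_width / 1.66053907
    truth <- sum(fs$frames[[1]]$atoms$mass[fs$frames[[1]]$atoms$role == r])
    expect_equal(integ, truth, tolerance = 1e-6)
  }
})

test_that("all mass in one bin gives the delta-layer density", {
  at <- data.frame(element = "X", mass = 18.015, charge = 0,
                   x = runif(100, 0, 20), y = runif(100, 0, 20), z = 5.1,
                   role = "water")
  sys <- molecular_system(at, box = diag(c(20, 20, 10)), pbc = c(TRUE, TRUE, FALSE))
  prof <- mass_density_profile(sys, bin_width = 0.5, zlim = c(0, 10))
  d <- prof$density[, "water"]
  hot <- which(d > 0)
  expect_length(hot, 1)
  expect_equal(d[hot], 100 * 18.015 * 1.66053907 / (400 * 0.5), tolerance = 1e-9)
  # doubling the bin width conserves integrated mass exactly
  prof2 <- mass_density_profile(sys, bin_width = 1.0, zlim = c(0, 10))
  expect_equal(sum(prof2$density[, "water"]) * 1.0, sum(d) * 0.5, tolerance = 1e-12)
})

test_that("uniform box profiles are flat at the packing density", {
  w <- pack_solvent_box("water", 120, 1.0, 625, seed = 9, z_margin = 0)
  th <- w$box[3, 3]
  fs <- frame_set(lapply(1:5, function(i) w), window = c(1, 5))
  prof <- mass_density_profile(fs, bin_width = th / 8, zlim = c(0, th))
  d <- prof$density[, "water"]
  expect_equal(mean(d), 1.0, tolerance = 0.05)
  expect_lt(max(abs(d - 1.0)), 0.35)   # spatial fluctuation of a random packing
})

test_that("peaks are recovered at planted Gaussian centers", {
  layers <- data.frame(center = 22.3, width = 0.8, role = "organic",
                       mass = 41.05, n_atoms = 3000)
  fs <- layered_frames(layers, n_frames = 10, noise = 0.2, seed = 21)
  prof <- mass_density_profile(fs, bin_width = 0.5)
  pk <- peak_positions(prof, "organic")
  expect_gt(nrow(pk), 0)
  expect_lt(abs(pk$z[1] - 22.3), 0.25)   # within half a bin
  # two layers, equal mass, narrower (taller) one returned first
  two <- data.frame(center = c(23.9, 31.0), width = c(0.8, 2.4),
                    role = "organic", mass = 41.05, n_atoms = c(300, 300))
  fs2 <- layered_frames(two, n_frames = 10, noise = 0.1, seed = 22)
  pk2 <- peak_positions(mass_density_profile(fs2, bin_width = 0.5), "organic")
  expect_lt(abs(pk2$z[1] - 23.9), 0.5)
  expect_true(any(abs(pk2$z - 31.0) < 1.0))
  # flat profile: no peaks above the floor
  flat_at <- data.frame(element = "X", mass = 18, charge = 0,
                        x = runif(50, 0, 10), y = runif(50, 0, 10),
                        z = seq(0.1, 9.9, length.out = 50), role = "water")
  flat <- mass_density_profile(
    molecular_system(flat_at, box = diag(c(10, 10, 10)),
                     pbc = c(TRUE, TRUE, FALSE)),
    bin_width = 0.2, zlim = c(0, 10))
  pkf <- peak_positions(flat, "water")
  # evenly spread single atoms per bin: all bins equal, no local maxima
  expect_lte(nrow(pkf), 1)
})

test_that("profile translation shifts peaks exactly by the offset", {
  layers <- data.frame(center = 12.0, width = 1.0, role = "water",
                       mass = 18.015, n_atoms = 300)
  fs <- layered_frames(layers, n_frames = 3, noise = 0, seed = 8,
                       box_height = 60)
  prof <- mass_density_profile(fs, bin_width = 0.5, zlim = c(0, 60))
  shifted <- lapply(fs$frames, function(f) {
    at <- f$atoms; at$z <- at$z + 10   # two full bins
    molecular_system(at, box = f$box, pbc = f$pbc)
  })
  prof_s <- mass_density_profile(frame_set(shifted, window = c(1, 3)),
                                 bin_width = 0.5, zlim = c(0, 60))
  expect_equal(prof_s$density[21:120, "water"], prof$density[1:100, "water"],
               tolerance = 1e-12)
})

test_that("surface overlap is the mass fraction below the edge", {
  layers <- data.frame(center = c(10, 40), width = c(1, 1),
                       role = c("organic", "organic"), mass = 41.05,
                       n_atoms = c(200, 200))
  fs <- layered_frames(layers, n_frames = 4, noise = 0, seed = 31,
                       box_height = 60)
  prof <- mass_density_profile(fs, bin_width = 0.5, zlim = c(0, 60))
  # edge far above both layers -> 1; far below -> 0
  expect_equal(surface_overlap(prof, "organic", 59), 1, tolerance = 1e-9)
  expect_equal(surface_overlap(prof, "organic", 1), 0, tolerance = 1e-9)
  # edge between the two equal-mass layers -> 0.5
  expect_equal(surface_overlap(prof, "organic", 25), 0.5, tolerance = 1e-6)
  # half-embedded Gaussian at the edge -> ~0.5, and matches the generator truth
  one <- data.frame(center = 22.7, width = 1.5, role = "water", mass = 18.015,
                    n_atoms = 500)
  fso <- layered_frames(one, n_frames = 4, noise = 0, seed = 32, box_height = 60)
  po <- mass_density_profile(fso, bin_width = 0.5, zlim = c(0, 60))
  ov <- surface_overlap(po, "water", 22.7)
  expect_lt(abs(ov - 0.5), 0.06)
  truth <- attr(fso, "metadata")$overlap_fraction("water", 22.7)
  expect_lt(abs(ov - truth), 0.03)
  expect_error(surface_overlap(po, "water", 1000), "outside")
})

test_that("frame sets validate rosters and windows", {
  s <- molecular_system(data.frame(element = "X", mass = 1, charge = 0,
                                   x = 0, y = 0, z = 0))
  s2 <- molecular_system(data.frame(element = "Y", mass = 1, charge = 0,
                                    x = 0, y = 0, z = 0))
  expect_error(frame_set(list(s, s2)), "roster")
  expect_error(frame_set(list(s, s), window = c(3, 2)), "window")
  fs <- frame_set(rep(list(s), 8))
  expect_equal(fs$window, c(7, 8))   # final quarter by default
})
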