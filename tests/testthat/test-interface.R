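test_that("packed solvent boxes hit the density-determined thickness", {
  # n M / (N_A rho A): 500 waters at 1.0 g/cm^3 over 1495.7 A^2 -> 10.0 A
  M <- template_molar_mass(molecule_template("water"))
  th <- 500 * M * 1.66053907e-24 * 1e24 / (1.0 * 1495.7)
  expect_equal(th, 10.0, tolerance = 1e-3)
  w <- pack_solvent_box("water", count = 60, target_density = 0.9,
                        cross_section = 400, seed = 7)
  expect_equal(w$box[3, 3],
               60 * M * 1.66053907 / (0.9 * 400), tolerance = 1e-9)
  # realized density is exact by construction (count and volume fixed)
  rho <- sum(w$atoms$mass) * 1.66053907e-24 /
    (w$box[1, 1] * w$box[2, 2] * w$box[3, 3] * 1e-24)
  expect_equal(rho, 0.9, tolerance = 1e-3)
  expect_equal(nrow(w$atoms), 180)
  expect_equal(length(unique(w$atoms$molecule_id)), 60)
})

test_that("packing is seeded, collision-free and respects the margin", {
  a1 <- pack_solvent_box("water", 40, 0.8, 300, seed = 11)
  a2 <- pack_solvent_box("water", 40, 0.8, 300, seed = 11)
  a3 <- pack_solvent_box("water", 40, 0.8, 300, seed = 12)
  expect_identical(a1$atoms, a2$atoms)
  expect_false(identical(a1$atoms$x, a3$atoms$x))
  # single molecule: just the template atom count
  one <- pack_solvent_box("water", 1, 0.05, 50, seed = 1)
  expect_equal(nrow(one$atoms), 3)
  # min intermolecular distance >= 1.5 (in-plane periodic)
  at <- a1$atoms
  lx <- a1$box[1, 1]; ly <- a1$box[2, 2]
  dmin <- Inf
  for (m in unique(at$molecule_id)) {
    A <- as.matrix(at[at$molecule_id == m, c("x", "y", "z")])
    B <- as.matrix(at[at$molecule_id > m, c("x", "y", "z")])
    if (nrow(B) == 0) next
    dx <- outer(A[, 1], B[, 1], "-"); dx <- dx - lx * round(dx / lx)
    dy <- outer(A[, 2], B[, 2], "-"); dy <- dy - ly * round(dy / ly)
    dz <- outer(A[, 3], B[, 3], "-")
    dmin <- min(dmin, sqrt(min(dx^2 + dy^2 + dz^2)))
  }
  expect_gte(dmin, 1.5)
  expect_gte(min(at$z), 0.75)
  expect_lte(max(at$z), a1$box[3, 3] - 0.75)
  expect_error(pack_solvent_box("water", 500, 3.0, 100, seed = 1),
               "density|insert")
})

test_that("interface assembly stacks layers additively with conserved atoms", {
  xt <- toy_crystal("cubic", a = 4, repeats = c(5, 5, 5))
  slab <- cleave_slab(xt, depth = 20)
  org <- pack_solvent_box("mecn", 8, 0.5, slab$cross_section, seed = 3,
                          lx = slab$lx)
  wat <- pack_solvent_box("water", 30, 1.0, slab$cross_section, seed = 4,
                          lx = slab$lx)
  model <- assemble_interface(slab, org, wat, vacuum = 100)
  t_org <- org$box[3, 3]; t_wat <- wat$box[3, 3]
  expect_equal(model$height, 20 + t_org + t_wat + 100, tolerance = 1e-9)
  expect_equal(nrow(model$system$atoms),
               nrow(slab$system$atoms) + nrow(org$atoms) + nrow(wat$atoms))
  # layers ordered, roles preserved
  b <- model$layer_bounds
  expect_true(b$crystal[2] <= b$organic[1] + 1e-9)
  expect_true(b$organic[2] <= b$water[1] + 1e-9)
  at <- model$system$atoms
  expect_setequal(unique(at$role), c("crystal", "organic", "water"))
  # no cross-layer contact below 1.5 A
  for (pair in list(c("crystal", "organic"), c("organic", "water"))) {
    A <- as.matrix(at[at$role == pair[1], c("x", "y", "z")])
    B <- as.matrix(at[at$role == pair[2], c("x", "y", "z")])
    dz <- outer(A[, 3], B[, 3], "-")
    expect_gte(min(abs(dz)), 1.5 - 1e-9)
  }
  # at equal cross-section the thickness ratio equals the volume ratio
  # fixed by the packed masses and densities: (n_o M_o / rho_o)/(n_w M_w / rho_w)
  M_o <- template_molar_mass(molecule_template("mecn"))
  M_w <- template_molar_mass(molecule_template("water"))
  expect_equal(t_org / t_wat, (8 * M_o / 0.5) / (30 * M_w / 1.0),
               tolerance = 1e-9)
  # degenerate: no organic layer
  m2 <- assemble_interface(slab, water = wat, vacuum = 100)
  expect_equal(m2$height, 20 + t_wat + 100, tolerance = 1e-9)
  # mismatched cross-section is rejected
  bad <- pack_solvent_box("water", 10, 1.0, 123, seed = 1)
  expect_error(assemble_interface(slab, water = bad), "mismatch")
})

test_that("solvent-accessible ratio behaves like a roughness measure", {
  # dense flat layer with a large probe: envelope nearly flat, S -> ~1
  g <- expand.grid(x = seq(0, 19, 1), y = seq(0, 19, 1))
  flat <- molecular_system(
    data.frame(element = "Ar", mass = 39.95, charge = 0,
               x = g$x, y = g$y, z = 0, role = "crystal"),
    box = diag(c(20, 20, 10)), pbc = c(TRUE, TRUE, FALSE))
  s_flat <- solvent_accessible_ratio(flat, probe_radius = 2.0,
                                     grid_resolution = 0.2)
  expect_lt(abs(s_flat$s_ratio - 1), 0.05)
  expect_equal(s_flat$a_hkl, 400)
  # one adatom strictly increases the accessible area
  at2 <- rbind(flat$atoms,
               data.frame(element = "Ar", mass = 39.95, charge = 0,
                          x = 10, y = 10, z = 3.5,
                          molecule_id = nrow(flat$atoms) + 1, role = "crystal"))
  rough <- molecular_system(at2, box = flat$box, pbc = flat$pbc)
  s_rough <- solvent_accessible_ratio(rough, probe_radius = 2.0,
                                      grid_resolution = 0.2)
  expect_gt(s_rough$s_ratio, s_flat$s_ratio)
  # resolution refinement converges (Richardson-style contraction)
  s1 <- solvent_accessible_ratio(rough, 2.0, grid_resolution = 0.8)$s_ratio
  s2 <- solvent_accessible_ratio(rough, 2.0, grid_resolution = 0.4)$s_ratio
  s3 <- solvent_accessible_ratio(rough, 2.0, grid_resolution = 0.2)$s_ratio
  expect_lt(abs(s3 - s2), abs(s2 - s1) + 1e-9)
  # atom order does not change the geometry summary
  perm <- molecular_system(at2[sample(nrow(at2)), ], box = flat$box,
                           pbc = flat$pbc)
  s_perm <- solvent_accessible_ratio(perm, 2.0, grid_resolution = 0.2)
  expect_equal(s_perm$a_acc, s_rough$a_acc, tolerance = 1e-9)
  expect_error(solvent_accessible_ratio(
    molecular_system(flat$atoms[0, ], box = flat$box)), "empty|atom")
})

test_that("probe-accessible area of an isolated sphere is 4 pi (r+p)^2", {
  one <- molecular_system(data.frame(element = "Ar", mass = 39.95, charge = 0,
                                     x = 0, y = 0, z = 0))
  a <- probe_accessible_area(one, probe_radius = 1.0)
  expect_equal(a, 4 * pi * (1.88 + 1.0)^2, tolerance = 0.01)
  # two far-apart spheres: twice the single-sphere area
  two <- molecular_system(data.frame(element = "Ar", mass = 39.95, charge = 0,
                                     x = c(0, 50), y = 0, z = 0))
  expect_equal(probe_accessible_area(two, 1.0), 2 * a, tolerance = 0.01)
  # fully buried atom contributes nothing extra vs a tight shell
  expect_lt(probe_accessible_area(molecular_system(
    data.frame(element = "Ar", mass = 39.95, charge = 0,
               x = c(0, 0.2), y = 0, z = 0)), 1.0), 2 * a)
})

test_that("the emitted simulation protocol carries the fixed run settings", {
  p <- md_protocol()
  expect_equal(p$temperature_K, 298.15)
  expect_equal(p$vdw_cutoff_A, 15.5)
  expect_equal(p$duration_ps, 500)
  expect_equal(p$timestep_fs, 1)
  expect_equal(p$vacuum_A, 100)
  expect_equal(p$organic_water_volume_ratio, 1 / 3)
})
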