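# Helix/ring construction, clash analysis, dimer pairing, interface areas.

test_that("build_helix places n_units copies generated by the step", {
  set.seed(41)
  unit <- random_atoms(15)
  step <- rigid_transform(rotation_about_z(60), c(0, 0, 5))
  one <- build_helix(unit, step, 1)
  expect_equal(assembly_atoms(one, relabel_chains = FALSE)[, c("x", "y", "z")],
               unit[, c("x", "y", "z")])
  asm <- build_helix(unit, step, 6)
  expect_equal(nrow(assembly_atoms(asm)), 6L * nrow(unit))
  # placements are powers of the generator
  for (k in 0:5) {
    pk <- transform_power(step, k)
    expect_lt(max(abs(asm$placements[[k + 1]]$R - pk$R)), 1e-9)
  }
})

test_that("a 60-degree zero-rise helix closes onto its first copy", {
  set.seed(42)
  unit <- random_atoms(20)
  step <- rigid_transform(rotation_about_z(60))
  asm <- build_helix(unit, step, 6)
  copy7 <- apply_transform(compose_transform(step, asm$placements[[6]]), unit)
  expect_lt(max(abs(atom_coords(copy7) - atom_coords(unit))), 1e-6)
  # and with nonzero rise it never closes
  open_asm <- build_helix(unit, rigid_transform(rotation_about_z(60), c(0, 0, 2)), 6)
  copy7o <- apply_transform(compose_transform(open_asm$generator,
                                              open_asm$placements[[6]]), unit)
  expect_gt(max(abs(atom_coords(copy7o) - atom_coords(unit))), 1)
})

test_that("extracting the step from a built assembly rebuilds it exactly", {
  set.seed(43)
  unit <- random_atoms(30)
  step <- rigid_transform(rotation_about_axis(c(1, 1, 2), 50), c(1, 0, 2.5))
  asm <- build_helix(unit, step, 5)
  units <- lapply(asm$placements, function(p) apply_transform(p, unit))
  rec <- extract_step_transform(units[[2]], units[[3]], atom_names = NULL)
  asm2 <- build_helix(unit, rec, 5)
  dev <- max(abs(atom_coords(assembly_atoms(asm2)) -
                   atom_coords(assembly_atoms(asm))))
  expect_lt(dev, 1e-6)
})

test_that("closed rings use the 360/n rotation and equal radii", {
  set.seed(44)
  unit <- random_atoms(20)
  r6 <- build_closed_ring(unit, 6, 30)
  expect_equal(rotation_angle(r6$generator$R), 60, tolerance = 1e-9)
  r7 <- build_closed_ring(unit, 7, 30)
  expect_equal(rotation_angle(r7$generator$R), 360 / 7, tolerance = 1e-9)
  expect_equal(round(rotation_angle(r7$generator$R), 2), 51.43)
  # generator^n is the identity
  gn <- transform_power(r7$generator, 7)
  expect_lt(max(abs(gn$R - diag(3))), 1e-9)
  # every copy's centroid lies at the same distance from the z axis
  flat <- assembly_atoms(r7)
  cent <- dplyr::summarise(dplyr::group_by(flat, .data$copy),
                           r = sqrt(mean(.data$x)^2 + mean(.data$y)^2))
  expect_lt(diff(range(cent$r)), 1e-9)
})

test_that("grid clash counting equals the brute-force oracle", {
  set.seed(45)
  unit <- random_atoms(200, spread = 15)
  step <- rigid_transform(rotation_about_z(50), c(2, 1, 6))
  asm <- build_helix(unit, step, 3)
  for (cutoff in c(2, 3.5, 6)) {
    expect_equal(clash_count(asm, cutoff), clash_count_brute(asm, cutoff))
  }
})

test_that("clash counts are invariant under global rigid motion", {
  set.seed(46)
  unit <- random_atoms(80)
  asm <- build_helix(unit, rigid_transform(rotation_about_z(55), c(0, 0, 2)), 4)
  n0 <- clash_count(asm, 4)
  g <- random_transform()
  moved <- build_helix(apply_transform(g, unit),
                       compose_transform(g, compose_transform(asm$generator,
                                                              invert_transform(g))), 4)
  expect_equal(clash_count(moved, 4), n0)
})

test_that("can_extend distinguishes open, closed and infinite assemblies", {
  set.seed(47)
  unit <- random_atoms(50, spread = 10)
  # coincident copies clash at least once per atom
  closed <- build_helix(unit, rigid_transform(rotation_about_z(60)), 6)
  ext <- can_extend(closed)
  expect_false(ext$can_extend)
  expect_gte(ext$clashes, nrow(unit))
  # far-apart copies never clash
  far <- build_helix(unit, rigid_transform(diag(3) * 0 + diag(3), c(100, 0, 0)), 3)
  expect_true(can_extend(far, cutoff = 3)$can_extend)
  # straight helix with rise above the unit height extends indefinitely
  tall <- build_helix(unit, rigid_transform(rotation_about_z(30), c(0, 0, 25)), 6)
  expect_true(can_extend(tall)$can_extend)
})

test_that("pair_dimers recovers constructed dimer pairings", {
  set.seed(48)
  # two chains in contact -> one pair
  a <- random_atoms(30, spread = 6, chain = "A")
  b <- apply_transform(rigid_transform(diag(3), c(4, 0, 0)), random_atoms(30, spread = 6, chain = "B"))
  two <- dplyr::bind_rows(a, b)
  p <- pair_dimers(two)
  expect_equal(nrow(p), 1L)
  expect_setequal(c(p$chain_a, p$chain_b), c("A", "B"))

  # 12-chain assembly built from 6 copies of a known dimer
  truth <- make_ground_truth_assembly(unit = make_bead_dimer(n_beads = 60, seed = 5),
                                      seed = 5)
  flat <- assembly_atoms(truth$assembly)
  pairs <- pair_dimers(flat)
  expect_equal(nrow(pairs), 6L)
  # each pair is the A/B chains of one copy
  expect_setequal(paste(pairs$chain_a, pairs$chain_b),
                  paste(paste0("A", 1:6), paste0("B", 1:6)))
  # odd chain count warns and reports one unpaired chain
  expect_warning(p3 <- pair_dimers(flat[flat$chain != "B6", ]), "npaired")
  expect_equal(length(attr(p3, "unpaired")), 1L)
})

test_that("interface area matches the two-sphere closed form within 2%", {
  a <- new_atoms(matrix(c(0, 0, 0), 1), element = "C")
  for (d in c(1.5, 2.5, 4.0)) {
    b <- new_atoms(matrix(c(d, 0, 0), 1), element = "C")
    R <- 1.7 + 1.4
    analytic <- 4 * pi * R * (R - d / 2)
    numeric <- interface_area(a, b, probe = 1.4, n_points = 960)
    expect_lt(abs(numeric - analytic) / analytic, 0.02)
  }
})

test_that("interface area is zero for distant chains and symmetric", {
  set.seed(49)
  a <- random_atoms(40, spread = 8, chain = "A")
  b <- apply_transform(rigid_transform(diag(3), c(50, 0, 0)), random_atoms(40, spread = 8, chain = "B"))
  expect_equal(interface_area(a, b), 0)
  c2 <- apply_transform(rigid_transform(diag(3), c(10, 0, 0)), b)
  expect_equal(interface_area(a, c2), interface_area(c2, a), tolerance = 1e-9)
  expect_gt(interface_area(a, apply_transform(rigid_transform(diag(3), c(-45, 0, 0)), c2)), 0)
})

test_that("sasa of an isolated atom equals its accessible sphere", {
  at <- new_atoms(matrix(0, 1, 3), element = "O")
  R <- 1.52 + 1.4
  expect_equal(as.numeric(sasa(at)), 4 * pi * R^2, tolerance = 1e-6)
})
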