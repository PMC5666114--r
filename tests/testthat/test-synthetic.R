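# Synthetic ground truth: protomers, assemblies, noisy profiles, alignments.

test_that("bead protomers are deterministic with sensible dimensions", {
  p1 <- make_bead_protomer(n_beads = 230, extent = 28, seed = 9)
  p2 <- make_bead_protomer(n_beads = 230, extent = 28, seed = 9)
  expect_identical(as.data.frame(p1), as.data.frame(p2))
  expect_equal(nrow(p1), 230L)
  rg <- radius_of_gyration(p1)
  expect_gt(rg, 0.3 * 28 / 2)   # within the construction bounds
  expect_lt(rg, 0.5 * 28)
  p3 <- make_bead_protomer(n_beads = 230, extent = 28, seed = 10)
  expect_gt(max(abs(atom_coords(p3) - atom_coords(p1))), 1)
  hb <- make_bead_protomer(n_beads = 120, shape = "helix-bundle", seed = 9)
  expect_equal(nrow(hb), 120L)
})

test_that("mirror images scatter identically but are chirally distinct", {
  p <- make_bead_protomer(n_beads = 150, seed = 12)
  mirror <- p
  mirror$x <- -mirror$x
  q <- seq(0.01, 0.4, by = 0.01)
  expect_equal(debye_profile(mirror, q, bin_width = 0)$I,
               debye_profile(p, q, bin_width = 0)$I, tolerance = 1e-12)
  s <- kabsch_superpose(mirror, p, match = "index")
  expect_gt(s$rmsd, 1)  # no proper rotation superposes a chiral mirror image
})

test_that("the bead dimer has two touching antiparallel chains", {
  d <- make_bead_dimer(n_beads = 100, seed = 4)
  expect_setequal(unique(d$chain), c("A", "B"))
  expect_equal(nrow(d), 200L)
  a <- d[d$chain == "A", ]; b <- d[d$chain == "B", ]
  ca <- atom_coords(a); cb <- atom_coords(b)
  d2 <- sqrt(outer(rowSums(ca^2), rowSums(cb^2), "+") - 2 * ca %*% t(cb))
  expect_gt(sum(d2 < 5), 0)  # chains in contact across the interface
})

test_that("ground-truth assemblies record their exact generator", {
  truth <- make_ground_truth_assembly(seed = 1)
  sp <- screw_parameters(truth$generator)
  expect_equal(sp$angle_per_unit, 55, tolerance = 1e-9)
  expect_equal(abs(sp$rise_per_unit), 3, tolerance = 1e-9)
  expect_equal(clash_count(truth$assembly), 0L)
  # the open single-turn ring terminates: a seventh unit clashes
  expect_false(can_extend(truth$assembly)$can_extend)
  # a closed hexamer also terminates (copy 7 coincides with copy 1)
  closed <- make_ground_truth_assembly(angle_per_unit = 60, rise = 0, seed = 1)
  expect_false(can_extend(closed$assembly)$can_extend)
  # clashing parameter sets are refused
  expect_error(make_ground_truth_assembly(radius = 5, seed = 1), "clash")
})

test_that("the generator round-trips through the extraction pipeline", {
  truth <- make_ground_truth_assembly(unit = make_bead_dimer(n_beads = 60, seed = 2),
                                      seed = 2)
  units <- lapply(truth$assembly$placements, function(p) {
    apply_transform(p, truth$assembly$seed)
  })
  rec <- extract_step_transform(units[[3]], units[[4]], atom_names = NULL)
  expect_lt(max(abs(rec$R - truth$generator$R)), 1e-9)
  expect_lt(max(abs(rec$t - truth$generator$t)), 1e-9)
  sp <- screw_parameters(rec)
  expect_equal(sp$angle_per_unit, truth$params[["angle_per_unit"]], tolerance = 1e-9)
})

test_that("simulated profiles follow the stated noise model", {
  truth <- make_ground_truth_assembly(unit = make_bead_dimer(n_beads = 60, seed = 6),
                                      seed = 6)
  q <- seq(0.01, 0.3, by = 0.005)
  clean <- simulate_profile(truth$assembly, q = q, rel_noise = 0, baseline = 0)
  exact <- debye_profile(truth$assembly, q)
  expect_equal(clean$I, exact$I, tolerance = 1e-12)
  expect_false("sigma" %in% names(clean))

  n1 <- simulate_profile(truth$assembly, q = q, rel_noise = 0.02, seed = 3)
  n2 <- simulate_profile(truth$assembly, q = q, rel_noise = 0.02, seed = 3)
  expect_identical(n1, n2)
  expect_equal(n1$sigma, 0.02 * exact$I)
  # with a baseline, sigma has the affine form a*I + b
  nb <- simulate_profile(truth$assembly, q = q, rel_noise = 0.01, baseline = 5, seed = 3)
  expect_equal(nb$sigma, 0.01 * exact$I + 5)
})

test_that("synthetic alignments hit the requested substitution rate", {
  cons <- random_consensus(240, seed = 8)
  expect_equal(nchar(cons), 240L)
  msa0 <- make_synthetic_msa(cons, n_seqs = 10, sub_rate = 0, seed = 1)
  expect_true(all(msa0$seq == cons))

  msa <- make_synthetic_msa(cons, n_seqs = 50, sub_rate = 0.1, seed = 1)
  expect_identical(msa, make_synthetic_msa(cons, n_seqs = 50, sub_rate = 0.1, seed = 1))
  cvec <- strsplit(cons, "")[[1]]
  mism <- mean(vapply(msa$seq, function(s) {
    mean(strsplit(s, "")[[1]] != cvec)
  }, numeric(1)))
  se <- sqrt(0.1 * 0.9 / (50 * 240))
  expect_lt(abs(mism - 0.1), 3 * se)

  gapped <- make_synthetic_msa(cons, n_seqs = 20, sub_rate = 0.05, gap_rate = 0.1,
                               seed = 2)
  gfrac <- mean(vapply(gapped$seq, function(s) {
    mean(strsplit(s, "")[[1]] == "-")
  }, numeric(1)))
  expect_lt(abs(gfrac - 0.1), 3 * sqrt(0.1 * 0.9 / (20 * 240)))
})
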