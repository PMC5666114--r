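# Debye profiles, chi-square fitting, Guinier/Kratky/Porod descriptors.

test_that("single atoms and two-atom systems match closed forms", {
  q <- seq(0, 0.5, by = 0.01)
  one <- new_atoms(matrix(0, 1, 3), element = "C")
  p1 <- debye_profile(one, q, ff = c(C = 1), bin_width = 0)
  expect_equal(p1$I, rep(1, length(q)))

  d <- 7.3
  two <- new_atoms(rbind(c(0, 0, 0), c(d, 0, 0)), element = "C")
  p2 <- debye_profile(two, q, ff = c(C = 1), bin_width = 0)
  qd <- q * d
  expected <- 2 + 2 * ifelse(qd == 0, 1, sin(qd) / qd)
  expect_equal(p2$I, expected, tolerance = 1e-12)
})

test_that("I(0) equals the squared total scattering length", {
  set.seed(51)
  at <- random_atoms(100)
  f <- openring:::atom_form_factors(at)
  p <- debye_profile(at, c(0, 0.1), bin_width = 0)
  expect_equal(p$I[1], sum(f)^2, tolerance = 1e-9)
  expect_true(all(p$I > 0))
})

test_that("the histogram-binned Debye matches the brute-force double sum", {
  set.seed(52)
  beads <- random_atoms(500, spread = 30)
  q <- seq(0, 0.5, by = 0.005)
  exact <- debye_profile(beads, q, bin_width = 0)
  binned <- debye_profile(beads, q, bin_width = 0.1)
  expect_lt(max(abs(binned$I - exact$I) / exact$I), 1e-4)
  # binned error shrinks with the bin width
  coarse <- debye_profile(beads, q, bin_width = 0.4)
  expect_lt(max(abs(coarse$I - exact$I) / exact$I), 1e-3)
})

test_that("the symmetric-assembly shortcut equals the flat computation", {
  truth <- make_ground_truth_assembly(unit = make_bead_dimer(n_beads = 60, seed = 3),
                                      seed = 3)
  q <- seq(0.005, 0.3, by = 0.005)
  sym <- debye_profile(truth$assembly, q, bin_width = 0.1)
  flat <- debye_profile(assembly_atoms(truth$assembly), q, bin_width = 0.1)
  expect_equal(sym$I, flat$I, tolerance = 1e-9)
})

test_that("profiles are invariant under rigid motion of the particle", {
  set.seed(53)
  at <- random_atoms(150)
  q <- seq(0, 0.4, by = 0.01)
  p0 <- debye_profile(at, q, bin_width = 0)
  p1 <- debye_profile(apply_transform(random_transform(), at), q, bin_width = 0)
  expect_lt(max(abs(p1$I - p0$I) / p0$I), 1e-10)
})

test_that("doubling all form factors scales I by 4", {
  set.seed(54)
  at <- random_atoms(50)
  q <- seq(0, 0.3, by = 0.01)
  p1 <- debye_profile(at, q, ff = c(RES = 10), bin_width = 0)
  p2 <- debye_profile(at, q, ff = c(RES = 20), bin_width = 0)
  expect_equal(p2$I, 4 * p1$I, tolerance = 1e-12)
})

test_that("unknown elements are reported by name", {
  at <- new_atoms(matrix(0, 1, 3), element = "Xx")
  expect_error(debye_profile(at, 0.1), "Xx")
})

test_that("chi-square fitting finds the analytic scale", {
  set.seed(55)
  at <- random_atoms(80)
  q <- seq(0.01, 0.3, by = 0.005)
  model <- debye_profile(at, q)
  expt <- tibble::tibble(q = q, I = model$I, sigma = rep(1, length(q)))
  fit <- chi_square_fit(model, expt)
  expect_equal(fit$scale, 1, tolerance = 1e-12)
  expect_equal(fit$chi2, 0, tolerance = 1e-12)

  expt2 <- tibble::tibble(q = q, I = 2 * model$I, sigma = rep(1, length(q)))
  fit2 <- chi_square_fit(model, expt2)
  expect_equal(fit2$scale, 2, tolerance = 1e-12)
  expect_equal(fit2$chi2, 0, tolerance = 1e-12)

  # chi2 is invariant to rescaling the model (absorbed by the scale factor)
  model4 <- tibble::tibble(q = q, I = 4 * model$I)
  expt3 <- tibble::tibble(q = q, I = model$I * (1 + rnorm(length(q), sd = 0.02)),
                          sigma = 0.02 * model$I)
  expect_equal(chi_square_fit(model, expt3)$chi2,
               chi_square_fit(model4, expt3)$chi2, tolerance = 1e-9)

  # non-overlapping ranges are refused
  expect_error(chi_square_fit(model[model$q < 0.1, ], expt), "cover")
  expect_error(chi_square_fit(model, tibble::tibble(q = q, I = model$I)), "sigma")
})

test_that("chi2 at the generating model is calibrated to 1 under matched noise", {
  truth <- make_ground_truth_assembly(unit = make_bead_dimer(n_beads = 80, seed = 7),
                                      seed = 7)
  q <- seq(0.01, 0.3, by = 0.002)
  model <- debye_profile(truth$assembly, q)
  chis <- vapply(1:30, function(s) {
    e <- simulate_profile(truth$assembly, q = q, rel_noise = 0.02, seed = s)
    chi_square_fit(model, e)$chi2
  }, numeric(1))
  expect_lt(abs(mean(chis) - 1), 3 / sqrt(30))
})

test_that("Guinier analysis recovers exact and spherical radii of gyration", {
  q <- seq(0.002, 0.08, by = 0.002)
  Rg <- 30
  prof <- tibble::tibble(q = q, I = 100 * exp(-q^2 * Rg^2 / 3))
  g <- guinier_fit(prof)
  expect_equal(g$Rg, 30, tolerance = 1e-6)
  expect_equal(g$I0, 100, tolerance = 1e-6)

  # homogeneous bead sphere of radius 10: Rg = sqrt(3/5) * 10
  set.seed(56)
  gm <- matrix(rnorm(3 * 3000), ncol = 3)
  gm <- gm / sqrt(rowSums(gm^2)) * runif(3000)^(1 / 3) * 10
  sphere <- new_atoms(gm, is_bead = TRUE, element = "RES")
  ps <- debye_profile(sphere, seq(0.001, 0.12, by = 0.002), bin_width = 0)
  gs <- guinier_fit(ps)
  expect_lt(abs(gs$Rg - sqrt(3 / 5) * 10) / (sqrt(3 / 5) * 10), 0.02)

  expect_error(guinier_fit(prof[1:3, ]), "5")
})

test_that("Guinier estimates are unbiased under 1% noise", {
  q <- seq(0.002, 0.1, by = 0.001)
  Rg <- 25
  I0 <- 1000
  set.seed(57)
  ests <- vapply(1:100, function(i) {
    I <- I0 * exp(-q^2 * Rg^2 / 3)
    guinier_fit(tibble::tibble(q = q, I = I * (1 + rnorm(length(q), sd = 0.01)),
                               sigma = 0.01 * I))$Rg
  }, numeric(1))
  expect_lt(abs(mean(ests) - Rg) / Rg, 0.01)
})

test_that("Porod exponents of power laws are exact", {
  q <- seq(0.05, 0.5, by = 0.005)
  p4 <- kratky_porod(tibble::tibble(q = q, I = q^-4), porod_q_range = c(0.1, 0.5))
  expect_equal(p4$porod_exponent, 4, tolerance = 1e-9)
  p2 <- kratky_porod(tibble::tibble(q = q, I = q^-2), porod_q_range = c(0.1, 0.5))
  expect_equal(p2$porod_exponent, 2, tolerance = 1e-9)
  # Kratky curve is q^2 I
  expect_equal(p4$kratky$q2I, q^2 * q^-4)
  expect_error(kratky_porod(tibble::tibble(q = q, I = q^-4),
                            porod_q_range = c(0.49, 0.5)), "5 points")
})

test_that("a solid bead sphere approaches the Porod limit", {
  set.seed(58)
  gm <- matrix(rnorm(3 * 8000), ncol = 3)
  gm <- gm / sqrt(rowSums(gm^2)) * runif(8000)^(1 / 3) * 15
  sphere <- new_atoms(gm, is_bead = TRUE, element = "RES")
  prof <- debye_profile(sphere, seq(0.01, 0.7, by = 0.002), bin_width = 0.02)
  kp <- kratky_porod(prof, porod_q_range = c(0.2, 0.6))
  expect_lt(abs(kp$porod_exponent - 4), 0.3)
})

test_that("3-column profile files round-trip", {
  set.seed(59)
  prof <- tibble::tibble(q = seq(0.01, 0.2, by = 0.01))
  prof$I <- exp(-prof$q^2 * 100) * 1e5
  prof$sigma <- 0.02 * prof$I
  path <- tempfile(fileext = ".dat")
  write_saxs_profile(prof, path)
  back <- read_saxs_profile(path)
  expect_equal(back$q, prof$q, tolerance = 1e-7)
  expect_equal(back$I, prof$I, tolerance = 1e-6)
  expect_equal(back$sigma, prof$sigma, tolerance = 1e-6)
  # 2-column files come back without sigma
  write_saxs_profile(prof[, c("q", "I")], path)
  expect_false("sigma" %in% names(read_saxs_profile(path)))
})
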