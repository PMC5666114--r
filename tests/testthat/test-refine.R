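# Grid enumeration, refinement against synthetic profiles, model selection.

small_truth <- function(seed = 2) {
  make_ground_truth_assembly(unit = make_bead_dimer(n_beads = 50, seed = seed),
                             seed = seed)
}

test_that("grid specification and enumeration are exact", {
  s0 <- grid_spec(angle_half = 0, trans_half = 0)
  expect_equal(grid_size(s0), 1)
  g0 <- enumerate_grid(identity_transform(), s0)
  expect_equal(nrow(g0), 1L)

  s1 <- grid_spec(angle_half = c(2, 0, 0), trans_half = 0)
  expect_equal(grid_size(s1), 5)
  expect_equal(nrow(enumerate_grid(identity_transform(), s1)), 5L)

  s2 <- grid_spec(angle_half = 1, trans_half = 1)
  g2 <- enumerate_grid(identity_transform(), s2)
  expect_equal(nrow(g2), 3^6)
  expect_equal(nrow(dplyr::distinct(g2)), 3^6)
  # the center transform is on the grid
  expect_true(any(rowSums(abs(g2)) < 1e-9))
  # cap enforcement
  expect_error(enumerate_grid(identity_transform(), grid_spec(5, 3), cap = 100),
               "cap")
})

test_that("full-grid search ranks the generating point first with chi2 0", {
  truth <- small_truth()
  tp <- transform_to_params(truth$generator)
  q <- seq(0.01, 0.25, by = 0.005)
  # noiseless experiment: exact model profile with unit uncertainties
  model <- debye_profile(truth$assembly, q)
  expt <- tibble::tibble(q = q, I = model$I, sigma = 0.02 * model$I)
  spec <- grid_spec(angle_half = c(1, 0, 0), trans_half = c(0, 0, 1), n_units = 6)
  ref <- refine_against_saxs(truth$assembly$seed, truth$generator, spec, expt,
                             mode = "grid")
  expect_equal(unname(ref$best_params), unname(tp), tolerance = 1e-9)
  expect_equal(ref$best_fit$chi2, 0, tolerance = 1e-9)
  expect_equal(nrow(ref$results), 9L)
  expect_true(all(diff(dplyr::coalesce(ref$results$chi2, Inf)) >= -1e-12))
})

test_that("sweep refinement is deterministic and never worse than the center", {
  truth <- small_truth(seed = 4)
  tp <- transform_to_params(truth$generator)
  e <- simulate_profile(truth$assembly, q = seq(0.01, 0.3, by = 0.002),
                        rel_noise = 0.02, seed = 21)
  center <- params_to_transform(tp + c(1, -1, 1, -1, 1, -1))
  spec <- grid_spec(angle_half = 2, trans_half = 1, n_units = 6)
  r1 <- refine_against_saxs(truth$assembly$seed, center, spec, e)
  r2 <- refine_against_saxs(truth$assembly$seed, center, spec, e)
  expect_identical(r1$results, r2$results)
  ctr_row <- dplyr::filter(r1$results,
                           abs(.data$alpha - tp[["alpha"]] - 1) < 1e-9,
                           abs(.data$tz - tp[["tz"]] + 1) < 1e-9)
  expect_lte(r1$best_fit$chi2, min(ctr_row$chi2, na.rm = TRUE) + 1e-12)
  # recovery within one grid step on this low-dimensional scan
  expect_true(all(abs(r1$best_params - tp) <= spec$step + 1e-9))
})

test_that("clashing models are excluded from ranking but flagged", {
  truth <- small_truth(seed = 5)
  e <- simulate_profile(truth$assembly, q = seq(0.01, 0.25, by = 0.005),
                        rel_noise = 0.02, seed = 31)
  # pure-translation grid along x: short steps overlap the copies, long
  # steps separate them, so the grid mixes clashing and clash-free models
  center <- rigid_transform(diag(3), c(20, 0, 0))
  spec <- grid_spec(angle_half = 0, trans_half = c(20, 0, 0), trans_step = 10,
                    n_units = 3L)
  ref <- refine_against_saxs(truth$unit, center, spec, e, mode = "grid")
  expect_gt(ref$n_clash_excluded, 0)
  expect_lt(ref$n_clash_excluded, nrow(ref$results))
  expect_true(all(is.na(ref$results$chi2[ref$results$clashes > 0])))
  expect_true(all(ref$results$clashes[!is.na(ref$results$chi2)] == 0))
})

test_that("local refinement descends to an off-grid truth", {
  truth <- small_truth(seed = 6)
  tp <- transform_to_params(truth$generator)
  q <- seq(0.01, 0.3, by = 0.002)
  model <- debye_profile(truth$assembly, q)
  expt <- tibble::tibble(q = q, I = model$I, sigma = 0.02 * model$I)
  # starting at the noiseless truth stays there
  at_truth <- local_refine(truth$generator, truth$assembly$seed, expt, n_units = 6)
  expect_equal(at_truth$fit$chi2, 0, tolerance = 1e-9)
  expect_lt(max(abs(at_truth$params - tp)), 1e-9)
  # starting one grid step away converges to the truth
  start <- params_to_transform(tp + c(1, 0, -1, 0, 1, 0))
  ref <- local_refine(start, truth$assembly$seed, expt, n_units = 6)
  expect_lt(max(abs(ref$params - tp)), 0.05)
  expect_lt(ref$fit$chi2, 1e-4)
})

test_that("local refinement never increases chi2 on noisy data", {
  truth <- small_truth(seed = 7)
  tp <- transform_to_params(truth$generator)
  e <- simulate_profile(truth$assembly, q = seq(0.01, 0.3, by = 0.002),
                        rel_noise = 0.02, seed = 41)
  start <- params_to_transform(tp + c(1, -1, 0, 1, 0, -1))
  scorer <- openring:::make_generator_scorer(truth$assembly$seed, e, 6L, 3.5,
                                             form_factor_table(), 0.1)
  chi_start <- scorer(transform_to_params(start))$chi2
  ref <- local_refine(start, truth$assembly$seed, e, n_units = 6)
  expect_lte(ref$fit$chi2, chi_start + 1e-12)
})

test_that("model selection prefers the generating class", {
  truth <- small_truth(seed = 8)
  # experiment from a closed 6-ring of the same unit: ring6 wins with chi2 ~ 0
  unit0 <- truth$unit
  ring <- build_closed_ring(unit0, 6, 40)
  q <- seq(0.01, 0.25, by = 0.005)
  mring <- debye_profile(ring, q)
  ering <- tibble::tibble(q = q, I = mring$I, sigma = 0.02 * mring$I)
  sel <- model_selection(unit0, ering, classes = c("ring6", "ring7"),
                         ring_radii = seq(30, 50, by = 1))
  expect_equal(sel$table$class[1], "ring6")
  expect_lt(sel$table$best_chi2[1], 1e-6)
  # the 7-ring scan really used the 51.43-degree rotation
  expect_match(sel$table$best_parameter[sel$table$class == "ring7"], "51.43")
})

test_that("refinement results expose tidy, glance and autoplot methods", {
  truth <- small_truth(seed = 9)
  e <- simulate_profile(truth$assembly, q = seq(0.01, 0.2, by = 0.005),
                        rel_noise = 0.02, seed = 51)
  spec <- grid_spec(angle_half = c(1, 0, 0), trans_half = 0, n_units = 6)
  ref <- refine_against_saxs(truth$assembly$seed, truth$generator, spec, e,
                             mode = "grid")
  td <- tidy(ref)
  expect_true(all(c("alpha", "chi2", "clashes") %in% names(td)))
  gl <- glance(ref)
  expect_equal(gl$chi2, ref$best_fit$chi2)
  expect_s3_class(autoplot(ref), "ggplot")
  expect_s3_class(autoplot(ref$best_fit), "ggplot")
})
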