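# The core procedure: enumerate symmetric assemblies over a grid of
# inter-unit transforms, score each against a scattering profile by reduced
# chi-square, rank, compare model classes, and polish by local descent.

PARAM_NAMES <- c("alpha", "beta", "gamma", "tx", "ty", "tz")

#' Specify a refinement grid
#'
#' Six grid dimensions: three Euler angles (degrees) and three translation
#' components (Angstrom) of the inter-unit transform, each scanned at
#' `center - half_range, ..., center + half_range` in `step` increments. The
#' canonical scan varies angles in 1 degree and translations in 1 Angstrom
#' steps.
#'
#' @param angle_half,trans_half Half-ranges for the three angles (deg) and
#'   the three translations (A). Scalars or length-3 vectors.
#' @param angle_step,trans_step Step sizes (default 1 deg / 1 A).
#' @param n_units Copies per model (default 6).
#' @return List of class `grid_spec` with `half_range`, `step` (named
#'   6-vectors) and `n_units`; `grid_size()` gives the full product size.
#' @export
grid_spec <- function(angle_half = 5, trans_half = 3, angle_step = 1,
                      trans_step = 1, n_units = 6L) {
  half <- c(rep_len(angle_half, 3), rep_len(trans_half, 3))
  step <- c(rep_len(angle_step, 3), rep_len(trans_step, 3))
  names(half) <- names(step) <- PARAM_NAMES
  if (any(step <= 0)) abort("Grid steps must be positive.")
  structure(list(half_range = half, step = step, n_units = as.integer(n_units)),
            class = "grid_spec")
}

#' @rdname grid_spec
#' @param spec A `grid_spec`.
#' @export
grid_size <- function(spec) {
  prod(2 * floor(spec$half_range / spec$step) + 1)
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> n_units %d, full product size %s\n", x$n_units,
              format(grid_size(x), big.mark = ",")))
  print(tibble(param = PARAM_NAMES, half_range = unname(x$half_range),
               step = unname(x$step)))
  invisible(x)
}

#' Enumerate the full product grid around a center transform
#'
#' Deterministic lexicographic enumeration (alpha slowest, tz fastest) of
#' every lattice point of the grid; the center is always included. Refuses
#' grids larger than `cap`.
#'
#' @param center [rigid_transform] at the grid center.
#' @param spec [grid_spec()].
#' @param cap Maximum number of grid points (default 1e6).
#' @return Tibble with one row per transform, columns `alpha`, `beta`,
#'   `gamma` (deg), `tx`, `ty`, `tz` (A).
#' @export
enumerate_grid <- function(center, spec, cap = 1e6) {
  stopifnot(is_rigid_transform(center), inherits(spec, "grid_spec"))
  size <- grid_size(spec)
  if (size > cap) {
    abort(sprintf("Grid size %s exceeds the cap (%s); shrink ranges or raise `cap`.",
                  format(size, big.mark = ","), format(cap, big.mark = ",")))
  }
  ctr <- transform_to_params(center)
  axes <- lapply(PARAM_NAMES, function(p) {
    k <- floor(spec$half_range[[p]] / spec$step[[p]])
    ctr[[p]] + seq(-k, k) * spec$step[[p]]
  })
  names(axes) <- PARAM_NAMES
  out <- as_tibble(rev(expand.grid(rev(axes), KEEP.OUT.ATTRS = FALSE)))
  out[, PARAM_NAMES]
}

# Scoring closure for generator-symmetric models: precomputes the seed's
# coordinates, form factors and intra-unit histogram once, then scores a
# 6-parameter transform in a single pass per unit offset (the cross-distance
# set between copies i and j depends only on j - i, and the same pass counts
# clash pairs). The chi2 is evaluated directly on the experiment's q grid.
make_generator_scorer <- function(seed_unit, experiment, n_units, clash_cutoff,
                                  ff, bin_width) {
  U <- atom_coords(seed_unit)
  fvec <- atom_form_factors(seed_unit, ff)
  qe <- experiment$q
  Ie <- experiment$I
  s2 <- experiment$sigma^2
  h_intra <- pair_hist_weighted(U, fvec, bin_width) * n_units
  f2n <- n_units * sum(fvec^2)
  function(p) {
    R <- euler_to_rotation(p[["alpha"]], p[["beta"]], p[["gamma"]])
    tvec <- c(p[["tx"]], p[["ty"]], p[["tz"]])
    h <- h_intra
    Rk <- diag(3); tk <- c(0, 0, 0)
    clashes <- 0
    for (k in seq_len(n_units - 1)) {
      tk <- as.numeric(R %*% tk) + tvec
      Rk <- R %*% Rk
      Uk <- sweep(U %*% t(Rk), 2, tk, "+")
      res <- cross_hist_weighted(U, fvec, Uk, fvec, bin_width, clash_cutoff)
      clashes <- clashes + res$n_clash * (n_units - k)
      if (clashes == 0) h <- add_hist(h, res$hist * (n_units - k))
    }
    if (clashes > 0) {
      return(list(chi2 = NA_real_, scale = NA_real_, clashes = as.integer(clashes)))
    }
    Im <- as.numeric(hist_intensity_cpp(h, f2n, qe))
    cc <- sum(Ie * Im / s2) / sum(Im^2 / s2)
    chi2 <- sum((Ie - cc * Im)^2 / s2) / (length(Ie) - 1)
    list(chi2 = chi2, scale = cc, clashes = 0L)
  }
}

#' Refine the inter-unit transform against a scattering profile
#'
#' For each candidate transform, builds the symmetric `n_units`-copy
#' assembly, discards models with inter-unit steric clashes (flagged, not
#' scored), computes the Debye profile and the reduced chi-square against
#' the experiment, and ranks all scored models. Two scan modes:
#' `"sweep"` (default) runs axis-aligned 1-D scans through the grid,
#' repeated in passes until the incumbent stops moving — the scan style of
#' varying individual angles and translations around a starting geometry;
#' `"grid"` scores the full 6-D product grid (capped). Both are fully
#' deterministic.
#'
#' @param seed_unit Atom tibble of the repeating unit.
#' @param center [rigid_transform]: the starting inter-unit transform (for a
#'   crystal-derived start, use [extract_step_transform()]).
#' @param spec [grid_spec()].
#' @param experiment Profile tibble with `q`, `I`, `sigma`.
#' @param mode `"sweep"` or `"grid"`.
#' @param clash_cutoff Clash cutoff, A (`NULL` = resolution default).
#' @param ff,bin_width Scattering model, see [debye_profile()].
#' @param max_passes Sweep passes (default 6).
#' @param cap Grid cap for `mode = "grid"`.
#' @return Object of class `saxs_refinement`: `results` (ranked tibble with
#'   the six parameters, `chi2`, `scale`, `clashes`), `best_params`,
#'   `best_transform`, `best_fit`, `best_assembly`, `center`, `spec`,
#'   `n_clash_excluded`, `mode`.
#' @export
refine_against_saxs <- function(seed_unit, center, spec, experiment,
                                mode = c("sweep", "grid"), clash_cutoff = NULL,
                                ff = form_factor_table(), bin_width = 0.1,
                                max_passes = 6L, cap = 1e6) {
  mode <- match.arg(mode)
  validate_atoms(seed_unit)
  if (!has_sigma(experiment)) abort("Experimental profile must carry a sigma column.")
  clash_cutoff <- clash_cutoff %||% default_clash_cutoff(seed_unit)
  n_units <- spec$n_units
  ctr <- transform_to_params(center)

  scorer <- make_generator_scorer(seed_unit, experiment, n_units, clash_cutoff,
                                  ff, bin_width)
  seen <- new.env(parent = emptyenv())
  rows <- list()
  eval_point <- function(p) {
    key <- paste(sprintf("%.6f", p), collapse = "|")
    if (!is.null(seen[[key]])) return(seen[[key]])
    sc <- scorer(p)
    row <- c(as.list(p), sc)
    rows[[length(rows) + 1L]] <<- row
    seen[[key]] <- sc
    sc
  }

  if (mode == "grid") {
    g <- enumerate_grid(center, spec, cap = cap)
    for (i in seq_len(nrow(g))) {
      p <- unlist(g[i, PARAM_NAMES])
      eval_point(p)
    }
  } else {
    # (1) axis-aligned 1-D sweeps through the grid, repeated in passes
    axis_passes <- function(current) {
      for (pass in seq_len(max_passes)) {
        moved <- FALSE
        for (pn in PARAM_NAMES) {
          k <- floor(spec$half_range[[pn]] / spec$step[[pn]])
          if (k == 0) next
          cand_vals <- ctr[[pn]] + seq(-k, k) * spec$step[[pn]]
          scores <- vapply(cand_vals, function(v) {
            p <- current; p[[pn]] <- v
            sc <- eval_point(p)
            if (is.na(sc$chi2)) Inf else sc$chi2
          }, numeric(1))
          if (all(!is.finite(scores))) next
          best_v <- cand_vals[which.min(scores)]
          if (abs(best_v - current[[pn]]) > 1e-12) {
            current[[pn]] <- best_v
            moved <- TRUE
          }
        }
        if (!moved) break
      }
      current
    }
    axis_passes(ctr)

    # (2) steepest lattice pattern descent from the center: at each move,
    # score the entire +-1 cube of neighbors (729 - 1, batched in compiled
    # code) and step to the best. The chi2 valley is curved in the Euler
    # parameters, so greedy axis descent strands on its walls; full-cube
    # steepest descent follows the valley floor, including its 3+-parameter
    # diagonal directions. Guidance uses the full q grid with a coarser
    # 0.5 A histogram bin (relative error ~1e-5, far below the noise);
    # the reported ranking always uses `bin_width`. Fully deterministic.
    U <- atom_coords(seed_unit)
    fvec <- atom_form_factors(seed_unit, ff)
    guide_bin <- max(bin_width, 0.5)
    h_intra_g <- pair_hist_weighted(U, fvec, guide_bin) * n_units
    f2n <- n_units * sum(fvec^2)
    s2e <- experiment$sigma^2
    batch_chi2 <- function(P) {
      sc <- score_param_batch(U, fvec, experiment$q, experiment$I, s2e, P,
                              n_units, guide_bin, clash_cutoff, h_intra_g, f2n)
      ifelse(is.na(sc[, 1]), Inf, sc[, 1])
    }
    offs_cube <- as.matrix(expand.grid(rep(list(-1:1), 6)))
    offs_cube <- offs_cube[rowSums(abs(offs_cube)) > 0, , drop = FALSE]
    step_mat <- offs_cube * matrix(spec$step, nrow(offs_cube), 6, byrow = TRUE)
    current <- ctr
    f_cur <- batch_chi2(matrix(ctr, 1))
    for (move in seq_len(80)) {
      cand <- step_mat + matrix(current, nrow(step_mat), 6, byrow = TRUE)
      inbox <- apply(abs(cand - matrix(ctr, nrow(cand), 6, byrow = TRUE)) <=
                       matrix(spec$half_range + 1e-9, nrow(cand), 6, byrow = TRUE),
                     1, all)
      cand <- cand[inbox, , drop = FALSE]
      fc <- batch_chi2(cand)
      if (min(fc) >= f_cur - 1e-12) break
      current <- cand[which.min(fc), ]
      names(current) <- PARAM_NAMES
      f_cur <- min(fc)
    }

    # (3) final axis passes at full fidelity from the descent endpoint;
    # their evaluations (and the endpoint itself) enter the ranked results
    eval_point(current)
    axis_passes(current)
  }

  res <- dplyr::bind_rows(lapply(rows, as_tibble))
  n_excl <- sum(res$clashes > 0)
  scored <- res[!is.na(res$chi2), , drop = FALSE]
  if (!nrow(scored)) {
    abort("All candidate models clash at the given cutoff; widen the grid or center.")
  }
  res <- dplyr::arrange(res, dplyr::coalesce(.data$chi2, Inf))
  best <- res[1, ]
  best_p <- unlist(best[PARAM_NAMES])
  best_tr <- params_to_transform(best_p)
  best_asm <- build_helix(seed_unit, best_tr, n_units)
  best_fit <- chi_square_fit(
    debye_profile(best_asm, experiment$q, ff = ff, bin_width = bin_width),
    experiment, model_id = "grid best")
  structure(list(results = res, best_params = best_p, best_transform = best_tr,
                 best_fit = best_fit, best_assembly = best_asm,
                 center = center, spec = spec, n_clash_excluded = n_excl,
                 mode = mode),
            class = "saxs_refinement")
}

#' @export
print.saxs_refinement <- function(x, ...) {
  cat(sprintf("<saxs_refinement> %s scan: %d models scored, %d clash-excluded\n",
              x$mode, sum(!is.na(x$results$chi2)), x$n_clash_excluded))
  cat(sprintf("best chi2 = %.4f at (%s)\n", x$best_fit$chi2,
              paste(sprintf("%s=%.2f", PARAM_NAMES, x$best_params), collapse = ", ")))
  invisible(x)
}

#' @export
tidy.saxs_refinement <- function(x, ...) x$results

#' @export
glance.saxs_refinement <- function(x, ...) {
  tibble(chi2 = x$best_fit$chi2, scale = x$best_fit$scale,
         n_scored = sum(!is.na(x$results$chi2)),
         n_clash_excluded = x$n_clash_excluded, mode = x$mode,
         !!!as.list(x$best_params))
}

#' @export
autoplot.saxs_refinement <- function(object, ...) {
  autoplot(object$best_fit, ...)
}

#' Continuous local refinement of the inter-unit transform
#'
#' Derivative-free polish of the six transform parameters under the
#' symmetric-generator constraint: a restarted Nelder-Mead simplex descent
#' followed by a coordinate polish at the terminal step size (default
#' 0.01 degrees / Angstrom), rejecting clashing moves. The returned
#' chi-square never exceeds the starting one.
#'
#' @param start [rigid_transform] to polish (e.g. the grid best).
#' @param seed_unit Atom tibble of the unit.
#' @param experiment Profile tibble with sigma.
#' @param n_units Copies per model.
#' @param init_step Retained for interface stability; the simplex chooses
#'   its own initial scale.
#' @param min_step Step size of the final coordinate polish (default 0.01).
#' @param clash_cutoff,ff,bin_width As in [refine_against_saxs()].
#' @return List with `transform`, `params`, `fit` (class `saxs_fit`).
#' @export
local_refine <- function(start, seed_unit, experiment, n_units = 6L,
                         init_step = 0.5, min_step = 0.01, clash_cutoff = NULL,
                         ff = form_factor_table(), bin_width = 0.1) {
  clash_cutoff <- clash_cutoff %||% default_clash_cutoff(seed_unit)
  scorer <- make_generator_scorer(seed_unit, experiment, n_units, clash_cutoff,
                                  ff, bin_width)
  obj <- function(p) {
    sc <- scorer(p)
    if (is.na(sc$chi2)) Inf else sc$chi2
  }
  # Derivative-free simplex descent (Nelder-Mead, restarted once with a
  # fresh simplex), followed by a coordinate polish at the terminal step
  # size. The chi2 valley is strongly curved in the Euler parameters, so a
  # simplex tracks it where pure coordinate descent stalls; the polish
  # cleans up the last fraction of a step. Clashing points get a large
  # finite penalty.
  obj_nm <- function(pv) {
    names(pv) <- PARAM_NAMES
    f <- obj(pv)
    if (is.finite(f)) f else 1e6
  }
  base <- transform_to_params(start)
  f_base <- obj(base)
  nm <- stats::optim(base, obj_nm, method = "Nelder-Mead",
                     control = list(maxit = 3000, reltol = 1e-12))
  nm <- stats::optim(nm$par, obj_nm, method = "Nelder-Mead",
                     control = list(maxit = 3000, reltol = 1e-12))
  p <- nm$par; names(p) <- PARAM_NAMES
  f_cur <- obj(p)
  s <- min_step
  repeat {
    improved <- FALSE
    for (pn in PARAM_NAMES) {
      for (dir in c(1, -1)) {
        cand <- p; cand[[pn]] <- cand[[pn]] + dir * s
        fc <- obj(cand)
        if (fc < f_cur - 1e-15) { p <- cand; f_cur <- fc; improved <- TRUE }
      }
    }
    if (!improved) break
  }
  # non-improvement returns the start
  if (!(f_cur < f_base)) { p <- base; f_cur <- f_base }
  tr <- params_to_transform(p)
  asm <- build_helix(seed_unit, tr, n_units)
  fit <- chi_square_fit(debye_profile(asm, experiment$q, ff = ff, bin_width = bin_width),
                        experiment, model_id = "local refine")
  list(transform = tr, params = p, fit = fit)
}

#' Compare model classes: closed rings versus open helical segments
#'
#' Scores three candidate classes against an experimental profile and ranks
#' them by their best reduced chi-square: closed 6-rings over a radius scan
#' (per-unit rotation 60 degrees), closed 7-rings over the same scan
#' (per-unit rotation 360/7 = 51.43 degrees), and open helical segments
#' refined with [refine_against_saxs()]. Ring radii are scanned in 1 A
#' intervals; the seed unit is centered on its centroid before ring
#' placement so the radius is the distance of the unit center from the
#' symmetry axis. Clashing models are excluded in every class.
#'
#' @param seed_unit Atom tibble of the unit.
#' @param experiment Profile tibble with sigma.
#' @param classes Subset of `c("ring6", "ring7", "helix")`.
#' @param ring_radii Radius scan, Angstrom (default `seq(10, 60, 1)`).
#' @param helix_center Starting transform for the helix class (required if
#'   `"helix"` is among `classes`).
#' @param helix_spec [grid_spec()] for the helix class (default
#'   `grid_spec()`).
#' @param n_units Units per model for the ring-free helix class and ring6
#'   (ring7 always uses 7).
#' @param clash_cutoff,ff,bin_width As in [refine_against_saxs()].
#' @return Object of class `model_selection`: `table` (one row per class,
#'   ranked by best chi2), plus per-class detail in `fits`.
#' @export
model_selection <- function(seed_unit, experiment,
                            classes = c("ring6", "ring7", "helix"),
                            ring_radii = seq(10, 60, by = 1),
                            helix_center = NULL, helix_spec = grid_spec(),
                            n_units = 6L, clash_cutoff = NULL,
                            ff = form_factor_table(), bin_width = 0.1) {
  classes <- match.arg(classes, several.ok = TRUE)
  clash_cutoff <- clash_cutoff %||% default_clash_cutoff(seed_unit)
  ctr <- colMeans(atom_coords(seed_unit))
  unit0 <- apply_transform(rigid_transform(diag(3), -ctr), seed_unit)

  scan_rings <- function(n_ring) {
    rows <- purrr::map_dfr(ring_radii, function(r) {
      asm <- build_closed_ring(unit0, n_ring, r)
      ncl <- clash_count(asm, clash_cutoff)
      if (ncl > 0) return(tibble(radius = r, chi2 = NA_real_, clashes = ncl))
      fit <- chi_square_fit(
        debye_profile(asm, experiment$q, ff = ff, bin_width = bin_width),
        experiment)
      tibble(radius = r, chi2 = fit$chi2, clashes = 0L)
    })
    rows
  }

  fits <- list()
  tab <- list()
  for (cl in classes) {
    if (cl %in% c("ring6", "ring7")) {
      n_ring <- if (cl == "ring6") 6L else 7L
      rows <- scan_rings(n_ring)
      fits[[cl]] <- rows
      ok <- rows[!is.na(rows$chi2), ]
      best <- if (nrow(ok)) ok[which.min(ok$chi2), ] else NULL
      tab[[cl]] <- tibble(
        class = cl, best_chi2 = if (is.null(best)) NA_real_ else best$chi2,
        best_parameter = if (is.null(best)) NA_character_ else
          sprintf("radius=%g A, rotation=%.2f deg", best$radius, 360 / n_ring),
        n_models = nrow(rows), n_clash_excluded = sum(rows$clashes > 0))
    } else {
      if (is.null(helix_center)) abort("`helix_center` is required for the helix class.")
      ref <- refine_against_saxs(seed_unit, helix_center,
                                 spec = grid_spec(
                                   angle_half = helix_spec$half_range[["alpha"]],
                                   trans_half = helix_spec$half_range[["tx"]],
                                   angle_step = helix_spec$step[["alpha"]],
                                   trans_step = helix_spec$step[["tx"]],
                                   n_units = n_units),
                                 experiment, clash_cutoff = clash_cutoff,
                                 ff = ff, bin_width = bin_width)
      fits[[cl]] <- ref
      tab[[cl]] <- tibble(
        class = cl, best_chi2 = ref$best_fit$chi2,
        best_parameter = paste(sprintf("%s=%.2f", PARAM_NAMES, ref$best_params),
                               collapse = ", "),
        n_models = nrow(ref$results),
        n_clash_excluded = ref$n_clash_excluded)
    }
  }
  table <- dplyr::arrange(dplyr::bind_rows(tab), dplyr::coalesce(.data$best_chi2, Inf))
  structure(list(table = table, fits = fits), class = "model_selection")
}

#' @export
print.model_selection <- function(x, ...) {
  cat("<model_selection>\n")
  print(x$table)
  invisible(x)
}

#' @export
tidy.model_selection <- function(x, ...) x$table

#' @export
autoplot.model_selection <- function(object, ...) {
  ggplot2::ggplot(object$table,
                  ggplot2::aes(x = stats::reorder(.data$class, .data$best_chi2),
                               y = .data$best_chi2)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "model class", y = expression(best ~ chi^2)) +
    ggplot2::theme_minimal()
}
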