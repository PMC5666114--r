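# Synthetic ground truth: bead protomers and dimers, helical assemblies with
# a known generator, noisy scattering profiles, and alignments with a known
# consensus. Everything depends only on (parameters, seed).

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

#' Generate a bead protomer
#'
#' Samples `n_beads` coarse-grained beads uniformly inside a hard-edged
#' triaxial ellipsoid (shape `"blob"`), or along a four-strand helical bundle
#' (`"helix-bundle"`). The default axis ratios (1 : 0.71 : 0.79 of `extent`)
#' give a protomer whose proportions mirror a ~230-residue proteasome-like
#' subunit; random bead clouds are generically chiral, so mirror images are
#' distinguishable by superposition even though their scattering profiles
#' coincide. The hard ellipsoid boundary matters: it guarantees that units
#' whose surfaces are separated carry exactly zero clash pairs.
#'
#' @param n_beads Number of beads (>= 10); default 230.
#' @param shape `"blob"` or `"helix-bundle"`.
#' @param extent Largest diameter, Angstrom (default 28).
#' @param seed RNG seed.
#' @param chain Chain id.
#' @return Atom tibble of beads (`is_bead = TRUE`, element `"RES"`).
#' @export
make_bead_protomer <- function(n_beads = 230L, shape = c("blob", "helix-bundle"),
                               extent = 28, seed = 1L, chain = "A") {
  shape <- match.arg(shape)
  stopifnot(n_beads >= 10)
  semi <- extent / 2 * c(1, 0.71, 0.79)
  xyz <- with_seed(seed, {
    if (shape == "blob") {
      g <- matrix(stats::rnorm(3 * n_beads), ncol = 3)
      g <- g / sqrt(rowSums(g^2))
      r <- stats::runif(n_beads)^(1 / 3)
      sweep(g * r, 2, semi, "*")
    } else {
      # four offset helical strands filling a comparable envelope
      tpar <- seq(0, 4 * pi, length.out = ceiling(n_beads / 4))
      strands <- lapply(0:3, function(s) {
        ph <- s * pi / 2
        cbind(0.8 * semi[1] * cos(tpar + ph) * 0.5,
              0.8 * semi[2] * sin(tpar + ph) * 0.5,
              seq(-semi[3], semi[3], length.out = length(tpar)))
      })
      m <- do.call(rbind, strands)[seq_len(n_beads), , drop = FALSE]
      m + matrix(stats::rnorm(3 * n_beads, sd = 0.3), ncol = 3)
    }
  })
  xyz <- sweep(xyz, 2, colMeans(xyz))
  new_atoms(xyz, chain = chain, is_bead = TRUE, element = "RES", atom = "CA",
            resname = "ALA", source_label = sprintf("synthetic %s protomer", shape))
}

#' Generate a two-protomer bead dimer
#'
#' Builds a rigid two-chain unit of opposing protomers: chain A below, chain
#' B the same protomer flipped 180 degrees about x (antiparallel) and stacked
#' above it along z so the two chains touch across the z = 0 interface —
#' mimicking the tight dimer of opposing protomers that acts as the rigid
#' building block of the assembly.
#'
#' @param n_beads Beads per protomer (default 230).
#' @param extent Protomer diameter, Angstrom (default 28).
#' @param seed RNG seed.
#' @return Two-chain atom tibble (chains A and B).
#' @export
make_bead_dimer <- function(n_beads = 230L, extent = 28, seed = 1L) {
  p <- make_bead_protomer(n_beads, "blob", extent, seed, chain = "A")
  zoff <- extent / 2 * 0.79
  a <- apply_transform(rigid_transform(diag(3), c(0, 0, -zoff)), p)
  b <- apply_transform(rigid_transform(rotation_about_x(180), c(0, 0, zoff)), p)
  b$chain <- "B"
  out <- dplyr::bind_rows(a, b)
  attr(out, "source_label") <- "synthetic bead dimer"
  out
}

#' Generate a ground-truth helical assembly with a known generator
#'
#' Places the unit at `radius` along +x and applies a screw transform about z
#' (`angle_per_unit` degrees rotation, `rise` Angstrom translation) to
#' generate `n_units` copies. The exact generator is recorded so every
#' downstream stage (step extraction, screw parameters, grid refinement) can
#' be checked against truth. The defaults — 6 units at 55 degrees with a 3 A
#' rise — realize the open single-turn ring regime: the rise per turn is too
#' low to continue into a second turn and the residual 30-degree gap is too
#' tight for a seventh unit, so the construction is clash-free while one
#' more unit would collide with the first.
#'
#' The whole construction is expressed in a general lab frame: a fixed
#' `orientation` rotation (default Euler 25, 40, 15 degrees) is applied to
#' the assembly, so the helix axis is in general position — as for an
#' arbitrarily oriented crystal frame — and the generator's Euler-angle
#' parameterization is away from its gimbal degeneracy. Scattering profiles
#' are unaffected (the Debye sum is orientation-invariant).
#'
#' @param unit Atom tibble of the seed unit (default [make_bead_dimer()]
#'   with `seed`).
#' @param angle_per_unit Rotation per unit, degrees (default 55).
#' @param rise Rise per unit along the axis, Angstrom (default 3).
#' @param radius Distance of the unit from the axis, Angstrom (default 36).
#' @param n_units Number of units (default 6).
#' @param seed RNG seed (used for the default unit).
#' @param orientation 3x3 rotation fixing the lab frame (see above).
#' @param clash_cutoff Cutoff for the construction check (`NULL` =
#'   resolution default).
#' @return List of class `synthetic_truth`: `assembly`, `generator`,
#'   `params` (angle, rise, radius, n_units), `unit`, `seed`.
#' @export
make_ground_truth_assembly <- function(unit = NULL, angle_per_unit = 55,
                                       rise = 3, radius = 36, n_units = 6L,
                                       seed = 1L,
                                       orientation = euler_to_rotation(25, 40, 15),
                                       clash_cutoff = NULL) {
  unit <- unit %||% make_bead_dimer(seed = seed)
  lab <- rigid_transform(orientation, c(0, 0, 0))
  moved <- apply_transform(
    compose_transform(lab, rigid_transform(diag(3), c(radius, 0, 0))), unit)
  gen0 <- rigid_transform(rotation_about_z(angle_per_unit), c(0, 0, rise))
  gen <- compose_transform(lab, compose_transform(gen0, invert_transform(lab)))
  asm <- build_helix(moved, gen, n_units)
  nc <- clash_count(asm, clash_cutoff)
  if (nc > 0) {
    abort(sprintf(paste0("Ground-truth construction clashes (%d pair(s) under cutoff %.2f A); ",
                         "increase radius or reduce the unit size."),
                  nc, clash_cutoff %||% default_clash_cutoff(unit)))
  }
  structure(list(assembly = asm, generator = gen,
                 params = c(angle_per_unit = angle_per_unit, rise = rise,
                            radius = radius, n_units = n_units),
                 unit = unit, seed = seed), class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("<synthetic_truth> %d units, %.1f deg/unit, rise %.1f A, radius %.1f A (seed %s)\n",
              x$params[["n_units"]], x$params[["angle_per_unit"]],
              x$params[["rise"]], x$params[["radius"]], format(x$seed)))
  invisible(x)
}

#' Default q grid for simulated profiles
#'
#' Emulates the radial binning of a modern SEC-SAXS measurement on a photon
#' counting detector: 691 points from 0.005 to 0.35 1/Angstrom in 0.0005
#' steps.
#'
#' @return Numeric q vector, 1/Angstrom.
#' @export
default_q_grid <- function() seq(0.005, 0.35, by = 0.0005)

#' Simulate a noisy scattering profile
#'
#' Computes the exact model intensity of the input and adds Gaussian noise
#' with the q-dependent width `sigma(q) = a * I(q) + b`; the sigma column of
#' the output carries the *true* sigma, so the reduced chi-square of the
#' generating model against its own simulated profile is calibrated to
#' expectation 1. With `a = b = 0` the profile equals the noise-free Debye
#' profile.
#'
#' @param x Atom tibble or `assembly`.
#' @param q q grid (default [default_q_grid()]).
#' @param rel_noise Relative noise level `a` (default 0.02).
#' @param baseline Additive noise floor `b`, intensity units (default 0).
#' @param seed RNG seed.
#' @param ff,bin_width Passed to [debye_profile()].
#' @return Profile tibble with `q`, `I`, `sigma`.
#' @export
simulate_profile <- function(x, q = default_q_grid(), rel_noise = 0.02,
                             baseline = 0, seed = 1L,
                             ff = form_factor_table(), bin_width = 0.1) {
  stopifnot(rel_noise >= 0, baseline >= 0)
  model <- debye_profile(x, q, ff = ff, bin_width = bin_width)
  sigma <- rel_noise * model$I + baseline
  I_obs <- if (rel_noise == 0 && baseline == 0) model$I else {
    model$I + with_seed(seed, stats::rnorm(length(q), sd = 1)) * sigma
  }
  out <- tibble(q = q, I = I_obs, sigma = sigma)
  if (rel_noise == 0 && baseline == 0) out$sigma <- NULL
  attr(out, "label") <- sprintf("simulated (a=%g, b=%g, seed=%s)", rel_noise,
                                baseline, format(seed))
  out
}

AA20 <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]

#' Random amino-acid consensus sequence
#'
#' @param length Sequence length (default 240).
#' @param seed RNG seed.
#' @return Single character string.
#' @export
random_consensus <- function(length = 240L, seed = 1L) {
  paste(with_seed(seed, sample(AA20, length, replace = TRUE)), collapse = "")
}

#' Simulate a multiple sequence alignment from a known consensus
#'
#' Each sequence is the consensus with i.i.d. per-column substitutions
#' (uniform over the 19 other residues) at rate `sub_rate`, and gaps at rate
#' `gap_rate`. Used to test the consensus-recovery pipeline generatively.
#'
#' @param true_consensus Character string over the 20 amino acids.
#' @param n_seqs Number of sequences (default 50).
#' @param sub_rate Per-column substitution probability in \[0, 0.5).
#' @param gap_rate Per-column gap probability in \[0, 0.5).
#' @param seed RNG seed.
#' @return MSA tibble with columns `id`, `seq`.
#' @export
make_synthetic_msa <- function(true_consensus, n_seqs = 50L, sub_rate = 0.1,
                               gap_rate = 0, seed = 1L) {
  stopifnot(sub_rate >= 0, sub_rate < 0.5, gap_rate >= 0, gap_rate < 0.5)
  cons <- strsplit(true_consensus, "")[[1]]
  L <- length(cons)
  seqs <- with_seed(seed, {
    vapply(seq_len(n_seqs), function(i) {
      s <- cons
      sub <- stats::runif(L) < sub_rate
      if (any(sub)) {
        s[sub] <- vapply(s[sub], function(res) sample(setdiff(AA20, res), 1), "")
      }
      gap <- stats::runif(L) < gap_rate
      s[gap] <- "-"
      paste(s, collapse = "")
    }, "")
  })
  tibble(id = sprintf("syn%03d", seq_len(n_seqs)), seq = seqs)
}
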