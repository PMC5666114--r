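# Least-squares superposition (Kabsch) and the step-transform extraction used
# to measure inter-unit geometry in helical assemblies.

#' Kabsch least-squares superposition
#'
#' Finds the proper rotation + translation minimizing the RMSD between
#' matched atoms of `mobile` and `target`, by SVD of the cross-covariance
#' matrix with the determinant correction that excludes reflections.
#'
#' Atoms are matched either positionally (`match = "index"`, requiring equal
#' counts) or by `(chain-order, residue number, atom name)` after restricting
#' to a common atom-name selection (`match = "residue"`, the default, with
#' `atom_names = "CA"` — the convention used for all published-RMSD style
#' comparisons in this package). Sequence identity of matched residues is
#' checked; more than 2% residue-name mismatches abort.
#'
#' @param mobile,target Atom tibbles.
#' @param match `"residue"` or `"index"`.
#' @param atom_names Atom-name selection applied to both sets under residue
#'   matching (default CA).
#' @return A list of class `superposition`: `transform` (the
#'   [rigid_transform] mapping mobile onto target), `rmsd` (Angstrom),
#'   `n_atoms` (matched atoms used).
#' @examples
#' a <- new_atoms(matrix(rnorm(30), 10, 3))
#' s <- kabsch_superpose(apply_transform(rigid_transform(rotation_about_z(90)), a), a)
#' s$rmsd
#' @export
kabsch_superpose <- function(mobile, target, match = c("residue", "index"),
                             atom_names = "CA") {
  match <- match.arg(match)
  if (match == "residue") {
    m <- restrict_names(mobile, atom_names)
    t2 <- restrict_names(target, atom_names)
    pair <- match_residues(m, t2)
    P <- atom_coords(m)[pair$i, , drop = FALSE]
    Q <- atom_coords(t2)[pair$j, , drop = FALSE]
  } else {
    if (nrow(mobile) != nrow(target)) {
      abort(sprintf("Index matching needs equal atom counts (%d vs %d).",
                    nrow(mobile), nrow(target)))
    }
    P <- atom_coords(mobile)
    Q <- atom_coords(target)
  }
  n <- nrow(P)
  if (n < 3) abort("Superposition needs at least 3 matched atoms.")
  fit <- kabsch_fit(P, Q)
  structure(list(transform = fit$transform, rmsd = fit$rmsd, n_atoms = n),
            class = "superposition")
}

restrict_names <- function(atoms, atom_names) {
  if (is.null(atom_names)) return(atoms)
  out <- atoms[atoms$atom %in% atom_names, , drop = FALSE]
  out
}

# match atoms of two unit copies by (chain order, resno, insert, atom name)
match_residues <- function(a, b) {
  ca <- factor(a$chain, levels = unique(a$chain))
  cb <- factor(b$chain, levels = unique(b$chain))
  if (nlevels(ca) != nlevels(cb)) {
    abort(sprintf("Chain count mismatch: %d vs %d.", nlevels(ca), nlevels(cb)))
  }
  ka <- paste(as.integer(ca), a$resno, a$insert, a$atom)
  kb <- paste(as.integer(cb), b$resno, b$insert, b$atom)
  j <- match(ka, kb)
  keep <- !is.na(j)
  if (!any(keep)) abort("No atoms could be paired between the two sets.")
  unmatched <- sum(!keep) + sum(!(kb %in% ka))
  if (unmatched > 0) {
    inform(sprintf("Residue matching: %d unpaired atom(s) ignored.", unmatched))
  }
  i <- which(keep); j <- j[keep]
  mism <- mean(a$resname[i] != b$resname[j])
  if (mism > 0.02) {
    abort(sprintf("Matched residues differ in identity at %.1f%% of positions (> 2%%).",
                  100 * mism))
  }
  list(i = i, j = j)
}

# core Kabsch on paired coordinate matrices
kabsch_fit <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  P0 <- sweep(P, 2, cp); Q0 <- sweep(Q, 2, cq)
  H <- crossprod(P0, Q0)
  sv <- svd(H)
  if (sv$d[2] < 1e-10) abort("Degenerate (collinear) atom set: rotation is ill-defined.")
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tvec <- cq - as.numeric(R %*% cp)
  moved <- sweep(P %*% t(R), 2, tvec, "+")
  rmsd <- sqrt(mean(rowSums((moved - Q)^2)))
  list(transform = rigid_transform(R, tvec), rmsd = rmsd)
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("<superposition> rmsd %.4f A over %d atoms\n", x$rmsd, x$n_atoms))
  invisible(x)
}

#' @export
tidy.superposition <- function(x, ...) {
  p <- transform_to_params(x$transform)
  tibble(rmsd = x$rmsd, n_atoms = x$n_atoms,
         rotation_angle = rotation_angle(x$transform$R),
         alpha = p[["alpha"]], beta = p[["beta"]], gamma = p[["gamma"]],
         tx = p[["tx"]], ty = p[["ty"]], tz = p[["tz"]])
}

#' Extract the step transform between two unit copies
#'
#' Given two copies of the same unit (e.g. consecutive dimers of a helical
#' assembly), returns the rigid transform superposing `unit_i` onto `unit_j`
#' by least squares — the per-step generator of the assembly. A residual
#' RMSD above `rigid_tol` means the two units are not rigid copies; a
#' warning reports it.
#'
#' @param unit_i,unit_j Atom tibbles of the two copies.
#' @param rigid_tol Residual RMSD (Angstrom) above which to warn. Default 2.
#' @param atom_names Atom selection for matching (default CA).
#' @return A [rigid_transform] with attribute `rmsd` (the residual).
#' @export
extract_step_transform <- function(unit_i, unit_j, rigid_tol = 2, atom_names = "CA") {
  s <- kabsch_superpose(unit_i, unit_j, match = "residue", atom_names = atom_names)
  if (s$rmsd > rigid_tol) {
    warn(sprintf("Units are not rigid copies: residual rmsd %.2f A > %.2f A.",
                 s$rmsd, rigid_tol))
  }
  out <- s$transform
  attr(out, "rmsd") <- s$rmsd
  out
}

#' All-vs-first superposition RMSDs of a list of units
#'
#' Convenience wrapper measuring structural invariance across unit copies:
#' superposes every unit onto a reference and tabulates the RMSDs, the way
#' intra-dimer invariance is quantified across the dimers of a crystal helix.
#'
#' @param units List of atom tibbles.
#' @param reference Index of the reference unit (default 1).
#' @param atom_names Atom selection (default CA).
#' @return Tibble with `unit`, `rmsd`, `n_atoms`.
#' @export
superpose_all <- function(units, reference = 1L, atom_names = "CA") {
  ref <- units[[reference]]
  purrr::map_dfr(seq_along(units), function(i) {
    s <- kabsch_superpose(units[[i]], ref, atom_names = atom_names)
    tibble(unit = i, rmsd = s$rmsd, n_atoms = s$n_atoms)
  })
}

#' Orientation difference between two two-protomer dimers
#'
#' Quantifies how differently the upper protomers of two dimers sit once
#' their lower protomers are aligned: superposes the lower chain of `cmp`
#' onto the lower chain of `ref`, then measures the residual rotation
#' relating the upper chains, decomposed about `main_axis` into a twist
#' (shear about the axis) and a swing (closing hinge about a perpendicular
#' axis). Chains are matched CA-by-CA in order, truncated to the common
#' length; for distantly related protomers a curated residue correspondence
#' (e.g. from a structure alignment) should be applied beforehand.
#'
#' @param ref,cmp Two-chain atom tibbles, chains ordered (lower, upper).
#' @param main_axis Reference (ring/helix) axis direction; default z.
#' @return A [decompose_rotation()] result with an extra `lower_rmsd` field.
#' @export
dimer_orientation_difference <- function(ref, cmp, main_axis = c(0, 0, 1)) {
  ch_r <- split_chains(select_atoms(ref, atom_names = "CA"))
  ch_c <- split_chains(select_atoms(cmp, atom_names = "CA"))
  if (length(ch_r) != 2L || length(ch_c) != 2L) {
    abort("Both inputs must have exactly two chains (lower, upper).")
  }
  trunc_pair <- function(a, b) {
    n <- min(nrow(a), nrow(b))
    list(a = atom_coords(a)[seq_len(n), , drop = FALSE],
         b = atom_coords(b)[seq_len(n), , drop = FALSE])
  }
  lo <- trunc_pair(ch_c[[1]], ch_r[[1]])
  fit_lo <- kabsch_fit(lo$a, lo$b)
  moved_up <- apply_transform(fit_lo$transform, ch_c[[2]])
  up <- trunc_pair(moved_up, ch_r[[2]])
  fit_up <- kabsch_fit(up$a, up$b)
  out <- decompose_rotation(fit_up$transform, main_axis)
  out$lower_rmsd <- fit_lo$rmsd
  out
}
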