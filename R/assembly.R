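# Construction of helical segments and closed rings from a seed unit, plus
# the steric analyses that decide where an assembly terminates.

#' Build a helical assembly from a seed unit and a step transform
#'
#' Places `n_units` copies of `seed`: copy k (0-based) at `step^k`. The step
#' transform is the assembly's *generator*; its screw parameters (angle per
#' unit, rise per unit) are the helical parameters of the assembly. A step
#' whose rotation is 360/n about an axis with zero rise closes into a ring.
#'
#' @param seed Atom tibble of one unit (e.g. a dimer).
#' @param step [rigid_transform] from one unit to the next.
#' @param n_units Number of copies (>= 1).
#' @return An object of class `assembly`: `seed`, `placements` (list of
#'   transforms, first the identity), `generator`, `n_units`.
#' @export
build_helix <- function(seed, step, n_units) {
  validate_atoms(seed)
  stopifnot(is_rigid_transform(step), n_units >= 1)
  placements <- vector("list", n_units)
  placements[[1]] <- identity_transform()
  for (k in seq_len(n_units - 1)) {
    placements[[k + 1]] <- compose_transform(step, placements[[k]])
  }
  structure(list(seed = seed, placements = placements, generator = step,
                 n_units = as.integer(n_units)), class = "assembly")
}

#' Build a closed ring assembly
#'
#' Translates the seed by `radius` along +x (away from the z symmetry axis),
#' then places `n_units` copies by successive rotations of `360/n_units`
#' degrees about z. The per-unit rotation of a 7-ring is 360/7 = 51.43
#' degrees. The ring closes exactly: applying the generator `n_units` times
#' is the identity.
#'
#' @param seed Atom tibble of one unit.
#' @param n_units Integer >= 3.
#' @param radius Distance (Angstrom, >= 0) of the seed placement from the
#'   symmetry axis.
#' @return An `assembly` whose seed is the translated unit and whose
#'   generator is the 360/n rotation about z.
#' @export
build_closed_ring <- function(seed, n_units, radius) {
  validate_atoms(seed)
  stopifnot(n_units >= 3, radius >= 0)
  moved <- apply_transform(rigid_transform(diag(3), c(radius, 0, 0)), seed)
  gen <- rigid_transform(rotation_about_z(360 / n_units), c(0, 0, 0))
  out <- build_helix(moved, gen, n_units)
  attr(out, "ring_spec") <- list(n_units = as.integer(n_units), radius = radius)
  out
}

is_assembly <- function(x) inherits(x, "assembly")

#' @export
print.assembly <- function(x, ...) {
  cat(sprintf("<assembly> %d unit(s) x %d atoms", x$n_units, nrow(x$seed)))
  if (!is.null(x$generator)) {
    sp <- tryCatch(screw_parameters(x$generator), error = function(e) NULL)
    if (!is.null(sp)) {
      cat(sprintf("; generator %.2f deg/unit, rise %.2f A", sp$angle_per_unit, sp$rise_per_unit))
    }
  }
  cat("\n")
  invisible(x)
}

#' Expand an assembly into a flat atom tibble
#'
#' Applies each placement to the seed and stacks the copies. Chains are
#' relabeled `<chain><copy>` so every copy has distinct chain ids; a `copy`
#' column records the unit index (1-based).
#'
#' @param assembly An `assembly`.
#' @param relabel_chains Give each copy distinct chain ids (default TRUE).
#' @return Atom tibble with an extra `copy` column.
#' @export
assembly_atoms <- function(assembly, relabel_chains = TRUE) {
  stopifnot(is_assembly(assembly))
  purrr::map_dfr(seq_len(assembly$n_units), function(k) {
    a <- apply_transform(assembly$placements[[k]], assembly$seed)
    a$copy <- k
    if (relabel_chains) a$chain <- paste0(a$chain, k)
    a
  })
}

#' Coordinates of each unit copy
#'
#' @param assembly An `assembly`.
#' @return List of n x 3 matrices, one per copy.
#' @keywords internal
unit_coord_list <- function(assembly) {
  seed_xyz <- atom_coords(assembly$seed)
  lapply(assembly$placements, function(p) {
    sweep(seed_xyz %*% t(p$R), 2, p$t, "+")
  })
}

default_clash_cutoff <- function(atoms) {
  if (all(atoms$is_bead)) 3.5 else 2.5
}

#' Count inter-unit steric clashes in an assembly
#'
#' Number of atom pairs from *different* units closer than `cutoff`
#' (intra-unit pairs are ignored). Computed with a spatial cell grid; the
#' test suite verifies the grid against a brute-force double loop. Default
#' cutoffs sit at the short end of nonbonded contact distances so only
#' genuine overlap counts: 2.5 A between heavy atoms, 3.5 A between beads.
#'
#' @param assembly An `assembly`.
#' @param cutoff Distance cutoff, Angstrom; `NULL` picks the default for the
#'   seed's resolution.
#' @return Integer pair count.
#' @export
clash_count <- function(assembly, cutoff = NULL) {
  stopifnot(is_assembly(assembly))
  cutoff <- cutoff %||% default_clash_cutoff(assembly$seed)
  stopifnot(cutoff > 0)
  units <- unit_coord_list(assembly)
  n <- length(units)
  total <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      total <- total + count_close_pairs(units[[i]], units[[j]], cutoff)
    }
  }
  as.integer(total)
}

#' Can the assembly accept one more unit?
#'
#' Places a hypothetical next copy by one further application of the step
#' (the generator by default) and counts its clashes against every existing
#' copy. An open single-turn ring in the terminating regime returns `FALSE`:
#' the gap left after the last unit is too tight — the association of a
#' further unit would collide with the first — so the assembly is a defined
#' oligomer rather than a polymer.
#'
#' @param assembly An `assembly`.
#' @param step Step transform; defaults to the assembly's generator.
#' @param cutoff Clash cutoff, Angstrom (`NULL` = resolution default).
#' @return List with `can_extend` (logical) and `clashes` (pair count of the
#'   hypothetical unit against the existing assembly).
#' @export
can_extend <- function(assembly, step = NULL, cutoff = NULL) {
  stopifnot(is_assembly(assembly))
  step <- step %||% assembly$generator
  if (is.null(step)) abort("Assembly has no generator; supply `step`.")
  cutoff <- cutoff %||% default_clash_cutoff(assembly$seed)
  last <- assembly$placements[[assembly$n_units]]
  nxt <- compose_transform(step, last)
  seed_xyz <- atom_coords(assembly$seed)
  new_xyz <- sweep(seed_xyz %*% t(nxt$R), 2, nxt$t, "+")
  units <- unit_coord_list(assembly)
  clashes <- 0
  for (u in units) clashes <- clashes + count_close_pairs(new_xyz, u, cutoff)
  list(can_extend = clashes == 0, clashes = as.integer(clashes))
}

#' Pair chains into dimers by contact counts
#'
#' Identifies the dimer partition of a multi-chain structure: chains are
#' paired greedily in order of decreasing inter-chain contact count (atom
#' pairs closer than `contact_cutoff`), which recovers dimers whose internal
#' interface dominates every lateral contact — the situation in assemblies
#' of tightly coupled opposing protomers. Unpaired chains are reported.
#'
#' @param atoms Atom tibble with >= 2 chains.
#' @param contact_cutoff Contact distance, Angstrom (default 5).
#' @return Tibble with columns `chain_a`, `chain_b`, `contacts`; attribute
#'   `unpaired` lists chains left without a partner.
#' @export
pair_dimers <- function(atoms, contact_cutoff = 5) {
  validate_atoms(atoms)
  chains <- split_chains(atoms)
  ids <- names(chains)
  if (length(ids) < 2) abort("pair_dimers needs at least 2 chains.")
  if (length(ids) %% 2 == 1) warn("Odd chain count: one chain will stay unpaired.")
  xyz <- lapply(chains, atom_coords)
  combs <- utils::combn(length(ids), 2)
  w <- apply(combs, 2, function(ij) {
    count_close_pairs(xyz[[ij[1]]], xyz[[ij[2]]], contact_cutoff)
  })
  ord <- order(w, decreasing = TRUE)
  taken <- logical(length(ids))
  pairs <- list()
  for (k in ord) {
    if (w[k] <= 0) break
    i <- combs[1, k]; j <- combs[2, k]
    if (taken[i] || taken[j]) next
    taken[i] <- taken[j] <- TRUE
    pairs[[length(pairs) + 1]] <- tibble(chain_a = ids[i], chain_b = ids[j],
                                         contacts = as.integer(w[k]))
  }
  out <- if (length(pairs)) dplyr::bind_rows(pairs) else
    tibble(chain_a = character(), chain_b = character(), contacts = integer())
  attr(out, "unpaired") <- ids[!taken]
  if (any(!taken)) {
    inform(sprintf("pair_dimers: %d chain(s) unpaired (%s).",
                   sum(!taken), paste(ids[!taken], collapse = ", ")))
  }
  out
}

# van der Waals radii (A) used for surface calculations; beads get an
# effective residue radius.
VDW_RADII <- c(H = 1.20, D = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
               P = 1.80, SE = 1.90, RES = 3.00)
DEFAULT_VDW <- 1.70

element_radii <- function(element) {
  r <- VDW_RADII[toupper(element)]
  r[is.na(r)] <- DEFAULT_VDW
  unname(r)
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Numerical SASA with deterministic golden-spiral sphere sampling and the
#' package's van der Waals radius table (`H 1.20, C 1.70, N 1.55, O 1.52,
#' S 1.80, P 1.80, Se 1.90`, beads 3.00, default 1.70).
#'
#' @param atoms Atom tibble.
#' @param probe Probe radius, Angstrom (default 1.4, water).
#' @param n_points Sphere sample points per atom (default 960).
#' @return Total accessible area in A^2; per-atom areas as attribute
#'   `per_atom`.
#' @export
sasa <- function(atoms, probe = 1.4, n_points = 960L) {
  validate_atoms(atoms)
  stopifnot(probe > 0, n_points >= 100)
  per <- sasa_cpp(atom_coords(atoms), element_radii(atoms$element), probe,
                  as.integer(n_points))
  out <- sum(per)
  attr(out, "per_atom") <- per
  out
}

#' Buried interface area between two chains
#'
#' Full buried-area convention:
#' `SASA(a) + SASA(b) - SASA(a and b together)`, not halved. Ratios of
#' interface areas (such as comparing one dimer interface against the
#' corresponding interface of a reference assembly) are independent of this
#' convention.
#'
#' @param a,b Atom tibbles of the two sides.
#' @param probe Probe radius, Angstrom (default 1.4).
#' @param n_points Sphere sample points per atom (default 960).
#' @return Buried area, A^2.
#' @export
interface_area <- function(a, b, probe = 1.4, n_points = 960L) {
  both <- dplyr::bind_rows(a[, ATOM_COLS], b[, ATOM_COLS])
  as.numeric(sasa(a, probe, n_points) + sasa(b, probe, n_points) -
               sasa(both, probe, n_points))
}

#' Serialize an assembly's transforms to JSON
#'
#' Writes the generator (if any) and all placements alongside an exported
#' structure so a run can be reproduced exactly.
#'
#' @param assembly An `assembly`.
#' @param path Output JSON path.
#' @return Invisibly, the JSON string.
#' @export
assembly_to_json <- function(assembly, path = NULL) {
  stopifnot(is_assembly(assembly))
  rec <- list(
    n_units = assembly$n_units,
    convention = EULER_CONVENTION,
    generator = if (!is.null(assembly$generator))
      list(rotation = as.numeric(t(assembly$generator$R)),
           translation = assembly$generator$t),
    placements = lapply(assembly$placements, function(p)
      list(rotation = as.numeric(t(p$R)), translation = p$t)))
  js <- jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(path)) writeLines(js, path)
  invisible(as.character(js))
}
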