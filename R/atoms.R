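# Coordinate I/O and atom-table utilities. Atoms live in a plain tibble with
# one row per atom so every downstream step is an ordinary data-frame verb.

ATOM_COLS <- c("chain", "resno", "insert", "resname", "atom", "element",
               "x", "y", "z", "is_bead")

#' Construct an atom tibble
#'
#' The package represents a structure (atomic or coarse-grained) as a tibble
#' with one row per atom and columns `chain`, `resno`, `insert`, `resname`,
#' `atom`, `element`, `x`, `y`, `z` (Angstrom) and `is_bead`. This constructor
#' fills defaults and validates the invariants (finite coordinates, non-empty
#' chain ids).
#'
#' @param coords n x 3 numeric matrix of coordinates, Angstrom.
#' @param chain Chain identifier(s), recycled.
#' @param resno Residue numbers, recycled; defaults to 1..n.
#' @param resname Residue names (3-letter), recycled.
#' @param atom Atom names, recycled.
#' @param element Element symbols, recycled.
#' @param insert Insertion codes, recycled.
#' @param is_bead Logical flag for coarse-grained pseudo-atoms, recycled.
#' @param source_label Free-text provenance, stored as an attribute.
#' @return A tibble of atoms.
#' @export
new_atoms <- function(coords, chain = "A", resno = NULL, resname = "ALA",
                      atom = "CA", element = "C", insert = "",
                      is_bead = FALSE, source_label = "constructed") {
  coords <- matrix(as.numeric(coords), ncol = 3)
  n <- nrow(coords)
  out <- tibble(
    chain = rep_len(as.character(chain), n),
    resno = rep_len(as.integer(resno %||% seq_len(n)), n),
    insert = rep_len(as.character(insert), n),
    resname = rep_len(as.character(resname), n),
    atom = rep_len(as.character(atom), n),
    element = rep_len(as.character(element), n),
    x = coords[, 1], y = coords[, 2], z = coords[, 3],
    is_bead = rep_len(as.logical(is_bead), n))
  validate_atoms(out)
  attr(out, "source_label") <- source_label
  out
}

validate_atoms <- function(atoms) {
  miss <- setdiff(ATOM_COLS, names(atoms))
  if (length(miss)) abort(paste0("Atom table lacks column(s): ", paste(miss, collapse = ", ")))
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (nrow(atoms) && !all(is.finite(xyz))) abort("Atom coordinates must all be finite.")
  if (nrow(atoms) && any(!nzchar(atoms$chain) | is.na(atoms$chain))) {
    abort("Chain ids must be non-empty strings.")
  }
  invisible(atoms)
}

#' Extract the coordinate matrix of an atom tibble
#'
#' @param atoms Atom tibble.
#' @return n x 3 numeric matrix.
#' @export
atom_coords <- function(atoms) {
  unname(as.matrix(atoms[, c("x", "y", "z")]))
}

guess_format <- function(path) {
  p <- sub("\\.gz$", "", path, ignore.case = TRUE)
  if (grepl("\\.(cif|mmcif)$", p, ignore.case = TRUE)) return("cif")
  if (grepl("\\.(pdb|ent)$", p, ignore.case = TRUE)) return("pdb")
  # sniff: mmCIF files start with data_ blocks
  first <- tryCatch(readLines(path, n = 5, warn = FALSE), error = function(e) character())
  if (any(grepl("^data_|^loop_|^_atom_site", first))) "cif" else "pdb"
}

maybe_gunzip <- function(path) {
  if (!grepl("\\.gz$", path, ignore.case = TRUE)) return(path)
  tmp <- tempfile(fileext = sub("\\.gz$", "", basename(path)))
  writeLines(readLines(gzfile(path), warn = FALSE), tmp)
  tmp
}

#' Read a macromolecular structure
#'
#' Reads PDB or mmCIF coordinates (dialect auto-detected from the extension,
#' falling back to content sniffing; gzip-transparent) into an atom tibble.
#' Waters and non-protein heteroatoms are dropped by default; selenomethionine
#' (MSE) is kept and renamed to MET, retaining its Se atom for scattering.
#' Where alternate conformations are present, only the highest-occupancy
#' conformer of each atom is kept.
#'
#' @param path Path to a `.pdb`, `.ent`, `.cif` file (optionally `.gz`).
#' @param model_index 1-based model number for multi-model files.
#' @param include_hetero Keep non-water HETATM records other than MSE.
#' @return Atom tibble (see [new_atoms()]).
#' @export
read_structure <- function(path, model_index = 1L, include_hetero = FALSE) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  fmt <- guess_format(path)
  local_path <- maybe_gunzip(path)
  # bio3d emits chatty warnings for legal minimal files; errors still abort
  parsed <- tryCatch(
    suppressWarnings(
      if (fmt == "cif") bio3d::read.cif(local_path, multi = TRUE)
      else bio3d::read.pdb(local_path, multi = TRUE, rm.alt = FALSE)),
    error = function(e) abort(sprintf("Could not parse '%s' as %s: %s",
                                      path, toupper(fmt), conditionMessage(e))))
  n_models <- max(1L, nrow(parsed$xyz))
  if (model_index < 1L || model_index > n_models) {
    abort(sprintf("model_index %d out of range: file has %d model(s).", model_index, n_models))
  }
  at <- parsed$atom
  xyz <- matrix(parsed$xyz[model_index, ], ncol = 3, byrow = TRUE)
  at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]

  keep <- at$type == "ATOM" | at$resid == "MSE" |
    (include_hetero & at$type == "HETATM" & !(at$resid %in% c("HOH", "WAT", "DOD")))
  at <- at[keep, , drop = FALSE]
  if (!nrow(at)) abort(sprintf("No atoms retained from '%s'.", path))

  # highest-occupancy alternate conformer per atom
  occ <- ifelse(is.na(at$o), 1, at$o)
  key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "\r")
  ord <- order(key, -occ)
  at <- at[ord[!duplicated(key[ord])], , drop = FALSE]
  at <- at[order(match(at$chain, unique(at$chain)), at$resno), , drop = FALSE]

  element <- at$elesy
  bad <- is.na(element) | !nzchar(element)
  if (any(bad)) element[bad] <- element_from_name(at$elety[bad])
  resname <- ifelse(at$resid == "MSE", "MET", at$resid)

  out <- tibble(
    chain = as.character(at$chain),
    resno = as.integer(at$resno),
    insert = ifelse(is.na(at$insert), "", as.character(at$insert)),
    resname = resname,
    atom = as.character(at$elety),
    element = toupper(substr(element, 1, 1)) %s% tolower(substring(element, 2)),
    x = at$x, y = at$y, z = at$z,
    is_bead = FALSE)
  validate_atoms(out)
  attr(out, "source_label") <- basename(path)
  out
}

`%s%` <- function(a, b) paste0(a, b)

element_from_name <- function(name) {
  nm <- toupper(trimws(name))
  two <- c("SE", "FE", "ZN", "MG", "MN", "CA", "NA", "CL", "BR")
  out <- substr(nm, 1, 1)
  is_two <- substr(nm, 1, 2) %in% two & !grepl("^C[ABGDEZ]", nm) & !grepl("^N[ABGDEZ]", nm)
  out[is_two] <- substr(nm[is_two], 1, 2)
  out
}

#' Subset an atom tibble
#'
#' Filters by chain, atom name and/or element, like the fixed selections used
#' for published-RMSD comparisons (CA atoms of matched residues by default in
#' the superposition functions). An empty result is legal but triggers a
#' warning so silent empty selections cannot corrupt downstream counts.
#'
#' @param atoms Atom tibble.
#' @param chains Optional character vector of chain ids to keep.
#' @param atom_names Optional atom names to keep (e.g. `"CA"`).
#' @param heavy_only Drop hydrogens and deuteriums.
#' @return Atom tibble subset, original order preserved.
#' @export
select_atoms <- function(atoms, chains = NULL, atom_names = NULL, heavy_only = FALSE) {
  validate_atoms(atoms)
  keep <- rep(TRUE, nrow(atoms))
  if (!is.null(chains)) keep <- keep & atoms$chain %in% chains
  if (!is.null(atom_names)) keep <- keep & atoms$atom %in% atom_names
  if (heavy_only) keep <- keep & !(toupper(atoms$element) %in% c("H", "D"))
  out <- atoms[keep, , drop = FALSE]
  if (!nrow(out)) warn("select_atoms: selection is empty.")
  attr(out, "source_label") <- attr(atoms, "source_label")
  out
}

#' Coarse-grain a structure to one bead per residue
#'
#' Replaces each residue by a single pseudo-atom at its CA position, the
#' resolution used for grid-scan scattering scoring. The bead element label
#' `"RES"` maps to a per-residue effective scattering length in the form
#' factor table. Residues lacking a CA atom are skipped with a warning.
#'
#' @param atoms Atom tibble.
#' @return Atom tibble of beads (`is_bead = TRUE`).
#' @export
coarse_grain <- function(atoms) {
  validate_atoms(atoms)
  if (all(atoms$is_bead)) return(atoms)
  ca <- atoms[atoms$atom == "CA" & !atoms$is_bead, , drop = FALSE]
  n_res <- nrow(unique(atoms[!atoms$is_bead, c("chain", "resno", "insert")]))
  if (!nrow(ca)) abort("coarse_grain: no CA atoms found.")
  n_skip <- n_res - nrow(ca)
  if (n_skip > 0) warn(sprintf("coarse_grain: %d residue(s) lack a CA atom and were skipped.", n_skip))
  out <- ca
  out$atom <- "CA"
  out$element <- "RES"
  out$is_bead <- TRUE
  attr(out, "source_label") <- attr(atoms, "source_label")
  out
}

CHAIN_ALPHABET <- c(LETTERS, letters, as.character(0:9))

#' Write a structure or assembly to PDB or mmCIF
#'
#' Writes an atom tibble or an [assembly][build_helix] to disk. Assembly
#' copies are expanded and written as distinct chains; the copy-to-chain map
#' is returned invisibly. The fixed-column PDB dialect supports at most 62
#' single-character chain ids; larger assemblies must use mmCIF (`.cif`).
#'
#' @param x Atom tibble or assembly.
#' @param path Output path ending in `.pdb` or `.cif`.
#' @return Invisibly, a tibble mapping (copy, original chain) to the written
#'   chain id.
#' @export
write_structure <- function(x, path) {
  fmt <- guess_format(path)
  if (is_assembly(x)) {
    atoms <- assembly_atoms(x)
    src_chain <- paste(atoms$copy, atoms$chain)
  } else {
    validate_atoms(x)
    atoms <- x
    atoms$copy <- 1L
    src_chain <- paste(1L, atoms$chain)
  }
  uc <- unique(src_chain)
  if (fmt == "pdb" && length(uc) > length(CHAIN_ALPHABET)) {
    abort(sprintf("PDB supports at most %d chains (%d needed); write mmCIF (.cif) instead.",
                  length(CHAIN_ALPHABET), length(uc)))
  }
  new_chain <- if (length(uc) <= length(CHAIN_ALPHABET)) {
    CHAIN_ALPHABET[match(src_chain, uc)]
  } else {
    paste0("C", match(src_chain, uc))
  }
  chain_map <- tibble(copy = atoms$copy, chain = atoms$chain, written_chain = new_chain)
  chain_map <- chain_map[!duplicated(chain_map), ]

  if (fmt == "pdb") {
    bio3d::write.pdb(
      file = path,
      xyz = as.numeric(t(atom_coords(atoms))),
      resno = atoms$resno,
      resid = atoms$resname,
      chain = new_chain,
      insert = ifelse(nzchar(atoms$insert), atoms$insert, NA),
      elety = atoms$atom,
      eleno = seq_len(nrow(atoms)),
      # beads have no chemical element; written as carbon pseudo-atoms and
      # restored to beads by coarse_grain() after reading
      elesy = ifelse(atoms$is_bead, "C", substr(toupper(atoms$element), 1, 2)))
  } else {
    write_mmcif(atoms, new_chain, path)
  }
  invisible(chain_map)
}

# minimal mmCIF atom_site writer with the standard deposited column set
write_mmcif <- function(atoms, chain, path) {
  hdr <- c("data_openring", "#", "loop_",
           "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
           "_atom_site.label_atom_id", "_atom_site.label_alt_id",
           "_atom_site.label_comp_id", "_atom_site.label_asym_id",
           "_atom_site.label_entity_id", "_atom_site.label_seq_id",
           "_atom_site.pdbx_PDB_ins_code",
           "_atom_site.Cartn_x", "_atom_site.Cartn_y", "_atom_site.Cartn_z",
           "_atom_site.occupancy", "_atom_site.B_iso_or_equiv",
           "_atom_site.pdbx_formal_charge", "_atom_site.auth_seq_id",
           "_atom_site.auth_comp_id", "_atom_site.auth_asym_id",
           "_atom_site.auth_atom_id", "_atom_site.pdbx_PDB_model_num")
  elem <- ifelse(atoms$is_bead, "C", toupper(substr(atoms$element, 1, 2)))
  rows <- sprintf(
    "ATOM %d %s %s . %s %s 1 %d %s %.3f %.3f %.3f 1.00 0.00 ? %d %s %s %s 1",
    seq_len(nrow(atoms)), elem, atoms$atom, atoms$resname, chain, atoms$resno,
    ifelse(nzchar(atoms$insert), atoms$insert, "?"),
    atoms$x, atoms$y, atoms$z, atoms$resno, atoms$resname, chain, atoms$atom)
  writeLines(c(hdr, rows, "#"), path)
}

#' Split an atom tibble by chain
#'
#' @param atoms Atom tibble.
#' @return Named list of atom tibbles, one per chain, in order of appearance.
#' @export
split_chains <- function(atoms) {
  validate_atoms(atoms)
  split(atoms, factor(atoms$chain, levels = unique(atoms$chain)))
}

#' Radius of gyration of a set of coordinates
#'
#' Mass-unweighted radius of gyration about the centroid, in Angstrom.
#'
#' @param atoms Atom tibble or n x 3 matrix.
#' @return Numeric scalar, Angstrom.
#' @export
radius_of_gyration <- function(atoms) {
  m <- if (is.data.frame(atoms)) atom_coords(atoms) else as.matrix(atoms)
  ctr <- colMeans(m)
  sqrt(mean(rowSums(sweep(m, 2, ctr)^2)))
}
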