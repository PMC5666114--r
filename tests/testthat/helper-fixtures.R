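# Shared fixtures, built in code at test time.

random_rotation <- function() {
  ax <- stats::rnorm(3)
  rotation_about_axis(ax, stats::runif(1, -180, 180))
}

random_transform <- function(t_scale = 10) {
  rigid_transform(random_rotation(), stats::rnorm(3, sd = t_scale))
}

random_atoms <- function(n, spread = 20, chain = "A") {
  new_atoms(matrix(stats::runif(3 * n, -spread, spread), ncol = 3),
            chain = chain, is_bead = TRUE, element = "RES")
}

# a tiny 3-residue, 2-chain protein-like fixture written as PDB text
tiny_pdb_lines <- function() {
  c("ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1      11.639   6.071  -5.147  1.00  0.00           C",
    "ATOM      3  C   ALA A   1      10.938   6.992  -4.148  1.00  0.00           C",
    "ATOM      4  O   ALA A   1       9.931   7.615  -4.480  1.00  0.00           O",
    "ATOM      5  N   GLY A   2      11.475   7.088  -2.932  1.00  0.00           N",
    "ATOM      6  CA  GLY A   2      10.900   7.936  -1.890  1.00  0.00           C",
    "ATOM      7  C   GLY A   2      11.256   7.428  -0.496  1.00  0.00           C",
    "ATOM      8  O   GLY A   2      12.406   7.104  -0.215  1.00  0.00           O",
    "ATOM      9  N   SER B   1      10.272   7.366   0.398  1.00  0.00           N",
    "ATOM     10  CA  SER B   1      10.449   6.929   1.780  1.00  0.00           C",
    "ATOM     11  CB  SER B   1       9.224   7.334   2.608  1.00  0.00           C",
    "ATOM     12  H   SER B   1       9.416   7.693   0.112  1.00  0.00           H",
    "END")
}

write_tiny_pdb <- function(path = tempfile(fileext = ".pdb")) {
  writeLines(tiny_pdb_lines(), path)
  path
}

# brute-force O(N^2) clash-count oracle over an assembly's unit pairs
clash_count_brute <- function(assembly, cutoff) {
  units <- lapply(assembly$placements, function(p) {
    apply_transform(p, assembly$seed)
  })
  total <- 0L
  for (i in seq_along(units)) {
    for (j in seq_along(units)) {
      if (j <= i) next
      a <- atom_coords(units[[i]])
      b <- atom_coords(units[[j]])
      d <- sqrt(outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b))
      total <- total + sum(d < cutoff)
    }
  }
  total
}
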