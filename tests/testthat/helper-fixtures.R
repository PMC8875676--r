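# Shared fixture helpers: ad-hoc structures, rigid transforms, and an
# independent Monte-Carlo SASA oracle.

# Build a vs_structure from a bare atom specification. `atoms` is a
# data.frame with name, element, x, y, z and res_index; residue types
# default to ALA/CYS-compatible choices via `types` (three-letter, one per
# residue index).
bare_structure <- function(atoms, types) {
  n <- max(atoms$res_index)
  residues <- data.frame(res_index = seq_len(n), resno = seq_len(n),
                         chain = "A", type3 = types,
                         protein_pos = seq_len(n), stringsAsFactors = FALSE)
  new_structure(atoms, residues)
}

atom_row <- function(res_index, name, element, x, y, z) {
  data.frame(res_index = res_index, name = name, element = element,
             x = x, y = y, z = z, stringsAsFactors = FALSE)
}

# Deterministic proper rotation matrix from a seed.
random_rotation <- function(seed) {
  set.seed(seed)
  qr_d <- qr(matrix(rnorm(9), 3))
  R <- qr.Q(qr_d)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# Apply a rigid transform (rotation R then translation t) to all atoms.
rigid_transform <- function(structure, R, t = c(0, 0, 0)) {
  xyz <- as.matrix(structure$atoms[, c("x", "y", "z")]) %*% t(R)
  xyz <- sweep(xyz, 2, t, "+")
  structure$atoms$x <- xyz[, 1]
  structure$atoms$y <- xyz[, 2]
  structure$atoms$z <- xyz[, 3]
  structure
}

# Independent Monte-Carlo SASA oracle: per-atom accessible area estimated by
# rejection sampling of points on each expanded sphere.
mc_sasa_oracle <- function(xyz, radii, probe = 1.4, n_samples = 1e5, seed = 42) {
  set.seed(seed)
  n <- nrow(xyz)
  r <- radii + probe
  out <- numeric(n)
  for (k in seq_len(n)) {
    v <- matrix(rnorm(3 * n_samples), ncol = 3)
    v <- v / sqrt(rowSums(v^2))
    pts <- sweep(v * r[k], 2, xyz[k, ], "+")
    acc <- rep(TRUE, n_samples)
    for (m in seq_len(n)[-k]) {
      d2 <- rowSums(sweep(pts, 2, xyz[m, ], "-")^2)
      acc <- acc & d2 >= r[m]^2
    }
    out[k] <- mean(acc) * 4 * pi * r[k]^2
  }
  out
}

# Minimal fixed-column PDB line writer for handcrafted parser fixtures.
pdb_line <- function(record, serial, name, altloc, resname, chain, resno,
                     x, y, z, element) {
  sprintf("%-6s%5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, paste0(" ", name), altloc, resname, chain, resno,
          x, y, z, 1.00, 0.00, element)
}

# Surround one residue of a structure with a spherical shell of single-CA
# glycine "cage" residues (chain B) to make it genuinely buried while the
# original chain's secondary structure is untouched.
caged_structure <- function(structure, site, radius = 7, n_atoms = 80,
                            start_pos = 1000) {
  cb <- varstruct:::.atom_coord(structure, site, "CB")
  if (is.null(cb)) cb <- varstruct:::.atom_coord(structure, site, "CA")
  i <- seq_len(n_atoms) - 0.5
  phi <- acos(1 - 2 * i / n_atoms)
  theta <- pi * (1 + sqrt(5)) * i
  pts <- cbind(cb[1] + radius * sin(phi) * cos(theta),
               cb[2] + radius * sin(phi) * sin(theta),
               cb[3] + radius * cos(phi))
  n0 <- nrow(structure$residues)
  cage_atoms <- data.frame(res_index = n0 + seq_len(n_atoms), name = "CA",
                           element = "C", x = pts[, 1], y = pts[, 2],
                           z = pts[, 3], stringsAsFactors = FALSE)
  cage_res <- data.frame(res_index = n0 + seq_len(n_atoms),
                         resno = seq_len(n_atoms), chain = "B", type3 = "GLY",
                         protein_pos = start_pos + seq_len(n_atoms),
                         stringsAsFactors = FALSE)
  new_structure(rbind(structure$atoms[, c("res_index", "name", "element", "x", "y", "z")],
                      cage_atoms),
                rbind(structure$residues[, c("res_index", "resno", "chain", "type3", "protein_pos")],
                      cage_res),
                source_id = paste0(structure$source_id, "+cage"))
}
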