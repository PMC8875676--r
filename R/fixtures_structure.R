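# Deterministic structure generators for tests and examples.
#
# Backbones are grown from ideal internal coordinates (bond lengths/angles
# from Engh-Huber-style values) with the NeRF placement rule; side chains are
# simplified to CB plus one named terminal pseudo-atom per residue type --
# enough geometry for the accessibility, contact, bond and elastic-network
# code paths without a rotamer library.

.cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                            a[3] * b[1] - a[1] * b[3],
                            a[1] * b[2] - a[2] * b[1])

# NeRF: place atom D bonded to C, given chain A-B-C, bond length r,
# bond angle theta (B-C-D, degrees) and torsion phi (A-B-C-D, degrees).
.nerf <- function(A, B, C, r, theta, phi) {
  th <- theta * pi / 180; ph <- phi * pi / 180
  d <- r * c(-cos(th), sin(th) * cos(ph), sin(th) * sin(ph))
  bc <- .norm_vec(C - B)
  nv <- .norm_vec(.cross3(B - A, bc))
  M <- cbind(bc, .cross3(nv, bc), nv)
  as.numeric(C + M %*% d)
}

# Ideal backbone internal coordinates.
.BB <- list(n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231,
            ang_n_ca_c = 111.2, ang_ca_c_n = 116.2, ang_c_n_ca = 121.7,
            ang_ca_c_o = 120.5)

# Terminal side-chain pseudo-atom name and CB-terminal distance per type.
.SIDECHAIN_TIP <- list(
  CYS = c("SG", 1.81), SER = c("OG", 1.42), THR = c("OG1", 1.43),
  ASP = c("OD1", 2.40), ASN = c("OD1", 2.40), GLU = c("OE1", 3.60),
  GLN = c("OE1", 3.60), LYS = c("NZ", 4.60), ARG = c("NH1", 5.20),
  HIS = c("ND1", 2.20), PHE = c("CZ", 3.40), TYR = c("OH", 4.70),
  TRP = c("CZ", 3.90), LEU = c("CG", 1.53), ILE = c("CG", 1.53),
  MET = c("SD", 2.80), VAL = c("CG", 1.53), PRO = c("CG", 1.50)
)

# Build backbone atom coordinates for a torsion sequence.
# phi/psi: numeric vectors length n (phi[1] and psi[n] only affect O/next).
.build_backbone <- function(phi, psi, omega = NULL) {
  n <- length(phi)
  if (is.null(omega)) omega <- rep(180, n)
  N <- CA <- C <- O <- matrix(NA_real_, n, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(.BB$n_ca, 0, 0)
  ang <- .BB$ang_n_ca_c * pi / 180
  C[1, ] <- CA[1, ] + .BB$ca_c * c(-cos(ang), sin(ang), 0)
  for (i in seq_len(n)) {
    if (i > 1) {
      N[i, ] <- .nerf(N[i - 1, ], CA[i - 1, ], C[i - 1, ], .BB$c_n,
                      .BB$ang_ca_c_n, psi[i - 1])
      CA[i, ] <- .nerf(CA[i - 1, ], C[i - 1, ], N[i, ], .BB$n_ca,
                       .BB$ang_c_n_ca, omega[i - 1])
      C[i, ] <- .nerf(C[i - 1, ], N[i, ], CA[i, ], .BB$ca_c,
                      .BB$ang_n_ca_c, phi[i])
    }
  }
  for (i in seq_len(n)) {
    # carbonyl O in the peptide plane, anti to the next N
    psi_i <- if (i < n) psi[i] else -40
    O[i, ] <- .nerf(N[i, ], CA[i, ], C[i, ], .BB$c_o, .BB$ang_ca_c_o,
                    psi_i + 180)
  }
  list(N = N, CA = CA, C = C, O = O)
}

# CB and side-chain tip for one residue.
.place_sidechain <- function(type3, N, CA, C) {
  if (type3 == "GLY") return(NULL)
  CB <- .nerf(N, C, CA, 1.53, 110.1, 122.55)
  out <- list(CB = CB)
  tip <- .SIDECHAIN_TIP[[type3]]
  if (!is.null(tip)) {
    dirv <- .norm_vec(CB - CA)
    out[[tip[1]]] <- CB + as.numeric(tip[2]) * dirv
  }
  out
}

#' Generate a deterministic toy protein structure
#'
#' Builds an ideal-geometry backbone (helix: phi = -57, psi = -47; hairpin:
#' two antiparallel beta strands joined by a type-I' turn; cluster: seeded
#' random torsions giving a compact irregular chain) with simplified side
#' chains. Optional disulfide/salt-bridge plants move the relevant terminal
#' atoms (SG, OD1/NZ) of the named residue pairs into bonding distance.
#'
#' @param kind one of "helix", "sheet_hairpin", "cluster"
#' @param n_residues chain length (>= 4)
#' @param seed integer seed controlling sequence and (cluster) torsions
#' @param sequence optional one-letter sequence overriding the seeded draw
#' @param disulfide_pairs optional list of residue-index pairs to plant as
#'   disulfides (the residues are forced to CYS, SG atoms placed 2.05 A apart)
#' @param salt_bridge_pairs optional list of residue-index pairs planted as
#'   Asp/Lys salt bridges (OD1 and NZ placed 3.2 A apart)
#' @param path optional file path; when given, the structure is also written
#'   as a PDB file (deterministic bytes for a fixed spec)
#' @return a `vs_structure` (with attribute `path` when written)
#' @export
make_structure <- function(kind = c("helix", "sheet_hairpin", "cluster"),
                           n_residues = 12, seed = 1, sequence = NULL,
                           disulfide_pairs = NULL, salt_bridge_pairs = NULL,
                           path = NULL) {
  kind <- match.arg(kind)
  if (n_residues < 4) stop("n_residues must be >= 4")
  set.seed(seed)
  if (is.null(sequence)) {
    sequence <- sample(unname(AA3), n_residues, replace = TRUE)
  } else {
    sequence <- strsplit(sequence, "")[[1]]
    .check_aa(sequence, "sequence")
    if (length(sequence) != n_residues) n_residues <- length(sequence)
  }
  for (p in disulfide_pairs) sequence[p] <- "C"
  for (p in salt_bridge_pairs) { sequence[p[1]] <- "D"; sequence[p[2]] <- "K" }

  if (kind == "helix") {
    phi <- rep(-57, n_residues); psi <- rep(-47, n_residues)
  } else if (kind == "cluster") {
    basins <- matrix(c(-57, -47, -120, 130, -75, 150, -60, -30), ncol = 2, byrow = TRUE)
    pick <- sample(nrow(basins), n_residues, replace = TRUE)
    phi <- basins[pick, 1] + stats::runif(n_residues, -15, 15)
    psi <- basins[pick, 2] + stats::runif(n_residues, -15, 15)
  } else { # sheet_hairpin: strand / type-I'-like turn / strand
    half <- floor((n_residues - 2) / 2)
    phi <- numeric(n_residues); psi <- numeric(n_residues)
    phi[] <- -110; psi[] <- 130
    t1 <- half + 1; t2 <- half + 2
    phi[t1] <- 50; psi[t1] <- 45
    phi[t2] <- 90; psi[t2] <- -10
  }

  bb <- .build_backbone(phi, psi)
  type3 <- unname(AA1[sequence])
  atoms <- NULL
  for (i in seq_len(n_residues)) {
    coords <- list(N = bb$N[i, ], CA = bb$CA[i, ], C = bb$C[i, ], O = bb$O[i, ])
    sc <- .place_sidechain(type3[i], bb$N[i, ], bb$CA[i, ], bb$C[i, ])
    coords <- c(coords, sc)
    atoms <- rbind(atoms, data.frame(
      res_index = i, name = names(coords),
      element = .element_from_name(names(coords)),
      x = vapply(coords, `[`, numeric(1), 1),
      y = vapply(coords, `[`, numeric(1), 2),
      z = vapply(coords, `[`, numeric(1), 3),
      stringsAsFactors = FALSE))
  }
  rownames(atoms) <- NULL

  move_tip <- function(atoms, i, j, name_i, name_j, dist) {
    ai <- which(atoms$res_index == i & atoms$name == name_i)
    aj <- which(atoms$res_index == j & atoms$name == name_j)
    cbi <- which(atoms$res_index == i & atoms$name == "CB")
    cbj <- which(atoms$res_index == j & atoms$name == "CB")
    mid <- (as.numeric(atoms[cbi, c("x", "y", "z")]) +
            as.numeric(atoms[cbj, c("x", "y", "z")])) / 2
    d <- .norm_vec(as.numeric(atoms[cbj, c("x", "y", "z")]) -
                   as.numeric(atoms[cbi, c("x", "y", "z")]))
    atoms[ai, c("x", "y", "z")] <- mid - d * dist / 2
    atoms[aj, c("x", "y", "z")] <- mid + d * dist / 2
    atoms
  }
  for (p in disulfide_pairs) atoms <- move_tip(atoms, p[1], p[2], "SG", "SG", 2.05)
  for (p in salt_bridge_pairs) atoms <- move_tip(atoms, p[1], p[2], "OD1", "NZ", 3.2)

  residues <- data.frame(res_index = seq_len(n_residues),
                         resno = seq_len(n_residues), chain = "A",
                         type3 = type3, protein_pos = seq_len(n_residues),
                         stringsAsFactors = FALSE)
  s <- new_structure(atoms, residues,
                     source_id = sprintf("fixture-%s-%d-seed%d", kind, n_residues, seed))
  if (!is.null(path)) {
    write_structure_pdb(s, path)
    attr(s, "path") <- path
  }
  s
}

#' Write a structure as a PDB file
#'
#' @param structure a `vs_structure`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_structure_pdb <- function(structure, path) {
  a <- structure$atoms
  r <- structure$residues
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   resno = r$resno[a$res_index],
                   resid = r$type3[a$res_index],
                   chain = r$chain[a$res_index],
                   eleno = seq_len(nrow(a)),
                   elety = a$name,
                   elesy = a$element)
  invisible(path)
}
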