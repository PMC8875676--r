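# Secondary-structure assignment from backbone hydrogen bonds.
#
# Kabsch-Sander-style electrostatic hydrogen-bond energy between the C=O of
# residue i and the N-H of residue j:
#   E = 0.084 * 332 * (1/r_ON + 1/r_CH - 1/r_OH - 1/r_CN)  [kcal/mol]
# with a bond when E < -0.5 kcal/mol. Amide hydrogens are reconstructed
# geometrically (1.0 A from N, along the direction opposing the bisector of
# the C(prev)-N and CA-N bonds); missing carbonyl O atoms are rebuilt in the
# peptide plane. Ladders of i -> i+4 bonds give helix (H), inter-strand bond
# pairs give strand (E), everything else is coil (C).

.norm_vec <- function(v) v / sqrt(sum(v^2))

# Per-residue backbone coordinates incl. reconstructed H and O.
.backbone_geometry <- function(structure) {
  n <- n_residues(structure)
  res <- structure$residues
  geo <- vector("list", n)
  for (i in seq_len(n)) {
    geo[[i]] <- list(N = .atom_coord(structure, i, "N"),
                     CA = .atom_coord(structure, i, "CA"),
                     C = .atom_coord(structure, i, "C"),
                     O = .atom_coord(structure, i, "O"))
  }
  for (i in seq_len(n)) {
    g <- geo[[i]]
    # reconstruct O in the peptide plane if absent
    if (is.null(g$O) && !is.null(g$C) && !is.null(g$CA) &&
        i < n && res$chain[i + 1] == res$chain[i] && !is.null(geo[[i + 1]]$N)) {
      d <- .norm_vec(.norm_vec(g$C - g$CA) + .norm_vec(g$C - geo[[i + 1]]$N))
      geo[[i]]$O <- g$C + 1.23 * d
    }
    # reconstruct amide H (no donor for proline or chain starts)
    if (res$type3[i] != "PRO" && !is.null(g$N) && !is.null(g$CA) &&
        i > 1 && res$chain[i - 1] == res$chain[i] && !is.null(geo[[i - 1]]$C)) {
      d <- .norm_vec(.norm_vec(g$N - geo[[i - 1]]$C) + .norm_vec(g$N - g$CA))
      geo[[i]]$H <- g$N + 1.0 * d
    }
  }
  geo
}

# Hydrogen-bond energy matrix: hb[i, j] = energy of CO(i) ... HN(j) in
# kcal/mol, NA where undefined.
.hbond_energy_matrix <- function(structure) {
  geo <- .backbone_geometry(structure)
  n <- length(geo)
  hb <- matrix(NA_real_, n, n)
  q <- 0.084 * 332
  for (i in seq_len(n)) {
    gi <- geo[[i]]
    if (is.null(gi$C) || is.null(gi$O)) next
    for (j in seq_len(n)) {
      if (abs(i - j) < 2) next
      gj <- geo[[j]]
      if (is.null(gj$N) || is.null(gj$H)) next
      rON <- sqrt(sum((gi$O - gj$N)^2))
      rCH <- sqrt(sum((gi$C - gj$H)^2))
      rOH <- sqrt(sum((gi$O - gj$H)^2))
      rCN <- sqrt(sum((gi$C - gj$N)^2))
      if (min(rON, rCH, rOH, rCN) < 0.5) { hb[i, j] <- -9.9; next }
      hb[i, j] <- q * (1 / rON + 1 / rCH - 1 / rOH - 1 / rCN)
    }
  }
  hb
}

#' Hydrogen-bond energy between a donor and acceptor residue
#'
#' Exposes the electrostatic energy used by [assign_secondary_structure()]
#' (acceptor C=O of `i`, donor N-H of `j`).
#' @param structure a `vs_structure`
#' @param i acceptor residue index
#' @param j donor residue index
#' @return energy in kcal/mol (NA when the bond is undefined, e.g. proline
#'   donor or missing backbone atoms)
#' @export
hbond_energy <- function(structure, i, j) .hbond_energy_matrix(structure)[i, j]

#' Assign secondary structure (helix/strand/coil)
#'
#' @param structure a `vs_structure`
#' @param energy_cutoff hydrogen-bond energy threshold in kcal/mol
#'   (default -0.5; a bond exists when the energy is below it)
#' @return character vector (one of "H", "E", "C" per residue, in
#'   `res_index` order) with class `vs_secstruct`
#' @export
assign_secondary_structure <- function(structure, energy_cutoff = -0.5) {
  n <- n_residues(structure)
  res <- structure$residues
  ss <- rep("C", n)
  chains <- split(seq_len(n), res$chain)
  if (all(lengths(chains) < 5)) {
    warning("all chains shorter than 5 residues; assigning coil throughout")
    class(ss) <- "vs_secstruct"
    return(ss)
  }
  hb <- .hbond_energy_matrix(structure)
  bond <- !is.na(hb) & hb < energy_cutoff
  same_chain <- outer(res$chain, res$chain, "==")

  # helix: ladders of two consecutive i -> i+4 turns mark i+1 .. i+4
  t4 <- vapply(seq_len(n - 4), function(i) {
    bond[i, i + 4] && all(same_chain[i, i:(i + 4)])
  }, logical(1))
  for (i in seq_len(max(0, n - 5))) {
    if (t4[i] && t4[i + 1]) ss[(i + 1):(i + 5)] <- "H"
  }

  # strand: bridge between non-local residue pairs
  is_bridge <- function(i, j) {
    anti <- (bond[i, j] && bond[j, i]) ||
      (i > 1 && j < n && i + 1 <= n && j - 1 >= 1 &&
         bond[i - 1, j + 1] && bond[j - 1, i + 1])
    par <- (i > 1 && i + 1 <= n && bond[i - 1, j] && bond[j, i + 1]) ||
      (j > 1 && j + 1 <= n && bond[j - 1, i] && bond[i, j + 1])
    anti || par
  }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j - i < 3) next
    if (is_bridge(i, j)) {
      if (ss[i] != "H") ss[i] <- "E"
      if (ss[j] != "H") ss[j] <- "E"
    }
  }
  class(ss) <- "vs_secstruct"
  ss
}

#' @export
print.vs_secstruct <- function(x, ...) {
  cat("<vs_secstruct> ", paste(unclass(x), collapse = ""), "\n", sep = "")
  invisible(x)
}
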