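# Folding-stability change (ddG) estimation, labeling, alanine scanning and
# hotspot-patch detection.
#
# ddG convention: kcal/mol, positive = destabilizing. The stability backend
# is pluggable: any function f(structure, pos, ref_aa, alt_aa, context)
# returning a ddG honors the contract that a self-substitution scores exactly
# zero. The built-in estimator is a fast environment-based score (burial x
# hydrophobicity loss, packing x volume change, helix Gly/Pro penalty, buried
# charge introduction) — a desk-scale stability heuristic, not a force field.

#' Default weight configuration of the built-in ddG estimator
#'
#' Units are kcal/mol per normalized unit of each term: `w_hydro` multiplies
#' the (burial-weighted) hydrophobicity loss, `w_volume` the packing-weighted
#' absolute volume change (per 100 A^3), `w_helix` the Gly/Pro-in-helix
#' penalty, `w_charge` the buried-charge introduction/switch penalty.
#' @return named numeric vector
#' @export
ddg_weights_default <- function() {
  c(w_hydro = 1.2, w_volume = 0.8, w_helix = 1.5, w_charge = 1.8)
}

# Packing density: heavy-atom count within `radius` of the residue's CB (or
# CA for glycine), scaled by a typical buried-core count.
.packing_density <- function(structure, i, radius = 8) {
  center <- .atom_coord(structure, i, "CB")
  if (is.null(center)) center <- .atom_coord(structure, i, "CA")
  a <- structure$atoms
  h <- a$is_heavy
  d2 <- (a$x[h] - center[1])^2 + (a$y[h] - center[2])^2 + (a$z[h] - center[3])^2
  min(1, sum(d2 <= radius^2) / 60)
}

#' Built-in folding-stability change estimate
#'
#' @param structure a `vs_structure`
#' @param pos protein position of the substitution (must be covered by the
#'   structure)
#' @param ref_aa,alt_aa one-letter amino acids
#' @param sasa a `vs_sasa` for the structure (computed if omitted)
#' @param ss a `vs_secstruct` for the structure (computed if omitted)
#' @param weights named vector as [ddg_weights_default()]
#' @return ddG estimate in kcal/mol (positive destabilizing); exactly 0 for a
#'   self-substitution
#' @export
builtin_ddg <- function(structure, pos, ref_aa, alt_aa,
                        sasa = NULL, ss = NULL,
                        weights = ddg_weights_default()) {
  .check_aa(c(ref_aa, alt_aa))
  i <- match(pos, structure$residues$protein_pos)
  if (is.na(i))
    stop("coverage error: protein position ", pos,
         " is not covered by structure ", structure$source_id)
  if (ref_aa == alt_aa) return(0)
  if (is.null(sasa)) sasa <- shrake_rupley_sasa(structure)
  if (is.null(ss)) ss <- suppressWarnings(assign_secondary_structure(structure))
  rel <- sasa$residue$rel_sasa[sasa$residue$res_index == i]
  burial <- max(0, min(1, (0.35 - rel) / 0.35))  # 1 fully buried, 0 at rel >= 0.35
  hyd <- aa_hydrophobicity(); vol <- aa_volume()
  hydro_loss <- max(0, hyd[ref_aa] - hyd[alt_aa]) / diff(range(hyd))
  pack <- .packing_density(structure, i)
  vol_change <- abs(vol[alt_aa] - vol[ref_aa]) / 100
  helix_pen <- as.numeric(unclass(ss)[i] == "H" && alt_aa %in% c("G", "P"))
  charge_pen <- as.numeric(burial > 0.5 &&
                             (aa_charge(alt_aa) != 0 && aa_charge(ref_aa) == 0 ||
                              aa_charge(alt_aa) * aa_charge(ref_aa) < 0))
  unname(weights["w_hydro"] * hydro_loss * burial +
         weights["w_volume"] * vol_change * pack +
         weights["w_helix"] * helix_pen +
         weights["w_charge"] * charge_pen)
}

#' Label a stability change as neutral or high-impact
#'
#' Neutral iff -0.5 < ddG < 0.5 kcal/mol; the boundary values +-0.5 are
#' high-impact. Vectorized.
#'
#' @param ddg stability change(s), kcal/mol
#' @return character vector of "neutral" / "high_impact"
#' @export
label_from_ddg <- function(ddg) {
  if (any(!is.finite(ddg))) stop("non-finite ddG value")
  ifelse(ddg > -0.5 & ddg < 0.5, "neutral", "high_impact")
}

#' Alanine scan over all covered positions
#'
#' Substitutes every residue to alanine and records the backend's ddG;
#' alanine positions score 0 by the self-substitution contract. Backend
#' errors at individual positions are recorded and the scan continues.
#'
#' @param structure a `vs_structure`
#' @param backend function `(structure, pos, ref_aa, alt_aa, sasa, ss)` ->
#'   ddG; default wraps [builtin_ddg()]
#' @return data.frame: `protein_pos`, `ref_aa`, `ddg` (NA where the backend
#'   failed), `error` (message or NA)
#' @export
alanine_scan <- function(structure, backend = NULL) {
  sasa <- shrake_rupley_sasa(structure)
  ss <- suppressWarnings(assign_secondary_structure(structure))
  if (is.null(backend))
    backend <- function(structure, pos, ref_aa, alt_aa, sasa, ss)
      builtin_ddg(structure, pos, ref_aa, alt_aa, sasa, ss)
  res <- structure$residues
  out <- data.frame(protein_pos = res$protein_pos, ref_aa = res$aa,
                    ddg = NA_real_, error = NA_character_,
                    stringsAsFactors = FALSE)
  for (r in seq_len(nrow(res))) {
    val <- tryCatch(backend(structure, res$protein_pos[r], res$aa[r], "A", sasa, ss),
                    error = function(e) e)
    if (inherits(val, "error")) out$error[r] <- conditionMessage(val)
    else out$ddg[r] <- val
  }
  out
}

#' Detect hotspot patches from an alanine scan
#'
#' Positions whose alanine-scan ddG is at least `ddg_cutoff` are linked when
#' their minimum heavy-atom distance is at most `dist_cutoff`; patches are
#' the connected components of that graph (single linkage), singletons
#' included.
#'
#' @param scan data.frame from [alanine_scan()]
#' @param structure the `vs_structure` the scan was computed on
#' @param dist_cutoff link distance in Angstrom (default 6)
#' @param ddg_cutoff alanine-scan ddG threshold in kcal/mol (default 2)
#' @return data.frame: `protein_pos`, `ref_aa`, `ddg`, `patch_id` (1-based,
#'   ordered by smallest member position); zero rows when no position
#'   qualifies
#' @export
find_hotspot_patches <- function(scan, structure, dist_cutoff = 6, ddg_cutoff = 2) {
  qual <- which(!is.na(scan$ddg) & scan$ddg >= ddg_cutoff)
  out <- data.frame(protein_pos = integer(), ref_aa = character(),
                    ddg = numeric(), patch_id = integer(),
                    stringsAsFactors = FALSE)
  if (!length(qual)) return(out)
  pos <- scan$protein_pos[qual]
  idx <- match(pos, structure$residues$protein_pos)
  if (any(is.na(idx)))
    stop("scan positions not covered by structure: ",
         paste(pos[is.na(idx)], collapse = ","))
  k <- length(idx)
  adj <- matrix(FALSE, k, k)
  if (k > 1) {
    for (a in seq_len(k - 1)) for (b in seq((a + 1), k)) {
      adj[a, b] <- adj[b, a] <-
        min_heavy_atom_distance(structure, idx[a], idx[b]) <= dist_cutoff
    }
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  # renumber patches by smallest member position
  first_pos <- vapply(unique(comp), function(cid) min(pos[comp == cid]), numeric(1))
  remap <- match(comp, unique(comp)[order(first_pos)])
  out <- data.frame(protein_pos = pos, ref_aa = scan$ref_aa[qual],
                    ddg = scan$ddg[qual], patch_id = remap,
                    stringsAsFactors = FALSE)
  out[order(out$patch_id, out$protein_pos), ]
}
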