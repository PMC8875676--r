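# Protein structure container and PDB input.
#
# A `vs_structure` holds a flat atom table plus a residue table; all geometry
# (SASA, secondary structure, contacts, elastic networks) works off these two
# data frames. Residue identity is restricted to the 20 standard amino acids.

#' Construct a structure object from atom and residue tables
#'
#' @param atoms data.frame with columns `res_index`, `name`, `element`,
#'   `x`, `y`, `z` (coordinates in Angstrom)
#' @param residues data.frame with columns `res_index` (1-based, ordered),
#'   `resno` (author numbering), `chain`, `type3` (three-letter code),
#'   `protein_pos` (1-based position in the protein reference sequence)
#' @param source_id free-text provenance label
#' @return object of class `vs_structure`
#' @export
new_structure <- function(atoms, residues, source_id = "unknown") {
  stopifnot(is.data.frame(atoms), is.data.frame(residues))
  need_a <- c("res_index", "name", "element", "x", "y", "z")
  if (!all(need_a %in% names(atoms)))
    stop("atoms table missing columns: ", paste(setdiff(need_a, names(atoms)), collapse = ","))
  need_r <- c("res_index", "resno", "chain", "type3", "protein_pos")
  if (!all(need_r %in% names(residues)))
    stop("residues table missing columns: ", paste(setdiff(need_r, names(residues)), collapse = ","))
  if (!all(residues$type3 %in% names(AA3)))
    stop("non-standard residue type(s): ",
         paste(unique(setdiff(residues$type3, names(AA3))), collapse = ","))
  if (anyDuplicated(residues$protein_pos))
    stop("protein position mapping is not injective")
  coords <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(coords))) stop("non-finite atom coordinates")
  atoms$is_heavy <- atoms$element != "H"
  residues$aa <- unname(AA3[residues$type3])
  structure(list(atoms = atoms, residues = residues, source_id = source_id),
            class = "vs_structure")
}

#' @export
print.vs_structure <- function(x, ...) {
  cat(sprintf("<vs_structure> %s: %d residues, %d atoms (%d heavy), chains: %s\n",
              x$source_id, nrow(x$residues), nrow(x$atoms), sum(x$atoms$is_heavy),
              paste(unique(x$residues$chain), collapse = ",")))
  invisible(x)
}

#' Number of residues in a structure
#' @param structure a `vs_structure`
#' @export
n_residues <- function(structure) nrow(structure$residues)

#' One-letter sequence of the modeled residues
#' @param structure a `vs_structure`
#' @export
structure_sequence <- function(structure) structure$residues$aa

#' Protein reference-sequence positions covered by the structure
#' @param structure a `vs_structure`
#' @export
covered_positions <- function(structure) structure$residues$protein_pos

# Heavy-atom coordinate matrix for one residue (by res_index).
.res_heavy_coords <- function(structure, i) {
  a <- structure$atoms
  sel <- a$res_index == i & a$is_heavy
  as.matrix(a[sel, c("x", "y", "z"), drop = FALSE])
}

# Named backbone atom coordinate (3-vector) or NULL if absent.
.atom_coord <- function(structure, i, name) {
  a <- structure$atoms
  sel <- which(a$res_index == i & a$name == name)
  if (!length(sel)) return(NULL)
  as.numeric(a[sel[1], c("x", "y", "z")])
}

.element_from_name <- function(name) {
  stripped <- gsub("[0-9']", "", name)
  first <- toupper(substr(stripped, 1, 1))
  ifelse(first %in% c("C", "N", "O", "S", "H"), first, first)
}

#' Read a protein structure from a PDB file
#'
#' Parses ATOM records (via bio3d), dropping heteroatoms, waters, and
#' alternate-location duplicates (conformer A is kept). Only the 20 standard
#' amino acids are accepted; insertion codes are rejected. For multi-model
#' files only the first model is read.
#'
#' @param path PDB file path
#' @param offset integer added to author residue numbers to obtain 1-based
#'   protein reference-sequence positions (default 0: author numbering is
#'   already the reference numbering)
#' @return a [new_structure()] object
#' @export
read_pdb <- function(path, offset = 0L) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  pdb <- tryCatch(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE),
                  error = function(e) stop("failed to parse PDB file ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (!nrow(at)) stop("no polymer (ATOM) records in ", path)
  at <- at[is.na(at$alt) | at$alt %in% c("", "A"), , drop = FALSE]
  if (any(!is.na(at$insert) & at$insert != ""))
    stop("insertion codes present in ", path, "; curated input without insertion codes required")
  if (!all(at$resid %in% names(AA3)))
    stop("non-standard residue type(s) in ", path, ": ",
         paste(unique(setdiff(at$resid, names(AA3))), collapse = ","))
  at <- at[order(at$chain, at$resno), , drop = FALSE]
  key <- paste(at$chain, at$resno)
  res_index <- match(key, unique(key))
  element <- if ("elesy" %in% names(at) && any(nzchar(trimws(at$elesy)))) {
    e <- toupper(trimws(at$elesy))
    ifelse(nzchar(e), e, .element_from_name(at$elety))
  } else .element_from_name(at$elety)
  atoms <- data.frame(res_index = res_index, name = at$elety, element = element,
                      x = at$x, y = at$y, z = at$z, stringsAsFactors = FALSE)
  first <- !duplicated(res_index)
  residues <- data.frame(res_index = res_index[first],
                         resno = at$resno[first],
                         chain = at$chain[first],
                         type3 = at$resid[first],
                         protein_pos = at$resno[first] + as.integer(offset),
                         stringsAsFactors = FALSE)
  new_structure(atoms, residues, source_id = basename(path))
}

#' Minimum heavy-atom distance between two residues
#'
#' @param structure a `vs_structure`
#' @param i,j residue indices (`res_index`, 1-based); must differ
#' @return minimum pairwise Euclidean distance in Angstrom
#' @export
min_heavy_atom_distance <- function(structure, i, j) {
  if (i == j) stop("i and j must differ")
  ci <- .res_heavy_coords(structure, i)
  cj <- .res_heavy_coords(structure, j)
  if (!nrow(ci)) stop("residue index ", i, " not present or has no heavy atoms")
  if (!nrow(cj)) stop("residue index ", j, " not present or has no heavy atoms")
  d2 <- outer(rowSums(ci^2), rowSums(cj^2), "+") - 2 * ci %*% t(cj)
  sqrt(max(0, min(d2)))
}

# All-pairs minimum heavy-atom distance matrix (n x n, Inf-free, 0 diagonal).
.min_dist_matrix <- function(structure) {
  n <- n_residues(structure)
  coords <- lapply(seq_len(n), function(i) .res_heavy_coords(structure, i))
  m <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in seq((i + 1), n)) {
    ci <- coords[[i]]; cj <- coords[[j]]
    d2 <- outer(rowSums(ci^2), rowSums(cj^2), "+") - 2 * ci %*% t(cj)
    m[i, j] <- m[j, i] <- sqrt(max(0, min(d2)))
  }
  m
}

#' Detect disulfide bridges
#'
#' Pairs of cysteines whose SG-SG distance is at most `cutoff`; each cysteine
#' joins at most one pair (closest partner wins).
#'
#' @param structure a `vs_structure`
#' @param cutoff SG-SG distance threshold in Angstrom (default 2.5)
#' @return data.frame with columns `i`, `j` (res_index pairs, i < j) and
#'   `distance`; zero rows when none found
#' @export
detect_disulfides <- function(structure, cutoff = 2.5) {
  res <- structure$residues
  cys <- res$res_index[res$type3 == "CYS"]
  empty <- data.frame(i = integer(), j = integer(), distance = numeric())
  if (length(cys) < 2) return(empty)
  sg <- lapply(cys, function(i) .atom_coord(structure, i, "SG"))
  keep <- !vapply(sg, is.null, logical(1))
  cys <- cys[keep]; sg <- sg[keep]
  if (length(cys) < 2) return(empty)
  cand <- NULL
  for (a in seq_len(length(cys) - 1)) for (b in seq((a + 1), length(cys))) {
    d <- sqrt(sum((sg[[a]] - sg[[b]])^2))
    if (d <= cutoff) cand <- rbind(cand, data.frame(i = cys[a], j = cys[b], distance = d))
  }
  if (is.null(cand)) return(empty)
  cand <- cand[order(cand$distance), , drop = FALSE]
  used <- integer(); out <- NULL
  for (r in seq_len(nrow(cand))) {
    if (cand$i[r] %in% used || cand$j[r] %in% used) next
    out <- rbind(out, cand[r, ])
    used <- c(used, cand$i[r], cand$j[r])
  }
  rownames(out) <- NULL
  out
}

# Charged-group heavy atoms per residue type used for salt-bridge detection.
.SB_ATOMS <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"),
                  LYS = "NZ", ARG = c("NH1", "NH2", "NE"), HIS = c("ND1", "NE2"))

#' Detect salt bridges
#'
#' Pairs of one acidic (Asp/Glu) and one basic (Lys/Arg/His) residue with any
#' charged-group heavy atoms (Asp OD1/OD2, Glu OE1/OE2, Lys NZ, Arg
#' NH1/NH2/NE, His ND1/NE2) within `cutoff`.
#'
#' @param structure a `vs_structure`
#' @param cutoff atom-pair distance threshold in Angstrom (default 4.0)
#' @return data.frame with columns `i` (acidic res_index), `j` (basic
#'   res_index) and `distance` (closest qualifying atom pair)
#' @export
detect_salt_bridges <- function(structure, cutoff = 4.0) {
  res <- structure$residues
  acidic <- res$res_index[res$type3 %in% c("ASP", "GLU")]
  basic <- res$res_index[res$type3 %in% c("LYS", "ARG", "HIS")]
  out <- data.frame(i = integer(), j = integer(), distance = numeric())
  if (!length(acidic) || !length(basic)) return(out)
  grp_coords <- function(i) {
    nm <- .SB_ATOMS[[res$type3[res$res_index == i]]]
    a <- structure$atoms
    sel <- a$res_index == i & a$name %in% nm
    as.matrix(a[sel, c("x", "y", "z"), drop = FALSE])
  }
  for (i in acidic) for (j in basic) {
    ci <- grp_coords(i); cj <- grp_coords(j)
    if (!nrow(ci) || !nrow(cj)) next
    d2 <- outer(rowSums(ci^2), rowSums(cj^2), "+") - 2 * ci %*% t(cj)
    d <- sqrt(max(0, min(d2)))
    if (d <= cutoff) out <- rbind(out, data.frame(i = i, j = j, distance = d))
  }
  rownames(out) <- NULL
  out
}
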