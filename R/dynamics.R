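# Sequence-weighted elastic network model and vibrational entropy.
#
# A coarse-grained harmonic network on CA nodes: springs join CA pairs within
# a cutoff, with force constants scaled by a residue-type pair weight so the
# spectrum is sensitive to the amino-acid sequence (hydrophobic contacts
# stiffer than polar ones). The vibrational entropy score is
# S = -1/2 * sum(log lambda) over the 3N-6 internal modes; constant offsets
# are dropped because only differences between reference and variant enter
# the feature vector. A substitution changes only the node's type (and hence
# its spring weights), never the geometry, so a self-substitution gives an
# identical network and ddSvib of exactly zero, and swapping reference and
# variant flips the sign.

#' Residue-type pair weight table for the elastic network
#'
#' Weights are the outer product of a per-type stiffness scalar derived from
#' the bundled hydrophobicity descriptor, scaled into `range`; hydrophobic-
#' hydrophobic pairs are stiffest, polar-polar softest.
#'
#' @param range two-element numeric: weight bounds (default c(0.6, 1.4))
#' @return 20 x 20 symmetric matrix with one-letter dimnames
#' @export
enm_weight_table <- function(range = c(0.6, 1.4)) {
  hyd <- aa_hydrophobicity()
  w <- range[1] + (range[2] - range[1]) * (hyd - min(hyd)) / diff(base::range(hyd))
  outer(w, w)
}

#' Build a sequence-weighted elastic network from CA coordinates
#'
#' @param structure a `vs_structure` (>= 4 non-collinear CA atoms)
#' @param cutoff spring distance cutoff in Angstrom (default 10)
#' @param weights 20 x 20 residue-pair weight table (default
#'   [enm_weight_table()]; a table of all 1 gives the classical uniform
#'   anisotropic network model)
#' @param base_k base spring constant (arbitrary units, default 1)
#' @return object of class `vs_enm`: `coords` (n x 3), `k` (n x n symmetric
#'   spring-constant matrix, zero diagonal), `aa`, `cutoff`
#' @export
build_network <- function(structure, cutoff = 10, weights = enm_weight_table(),
                          base_k = 1) {
  res <- structure$residues
  coords <- t(vapply(res$res_index, function(i) {
    ca <- .atom_coord(structure, i, "CA")
    if (is.null(ca)) stop("residue index ", i, " has no CA atom")
    ca
  }, numeric(3)))
  n <- nrow(coords)
  if (n < 4) stop("degenerate network: at least 4 CA atoms required")
  sv <- svd(scale(coords, scale = FALSE))$d
  if (sv[2] < 1e-6 * sv[1]) stop("degenerate network: CA atoms are collinear")
  d <- as.matrix(stats::dist(coords))
  k <- matrix(0, n, n)
  within <- d <= cutoff & d > 0
  if (any(within)) {
    wpair <- weights[res$aa, res$aa]
    k[within] <- base_k * wpair[within]
  }
  structure(list(coords = coords, k = k, aa = res$aa,
                 protein_pos = res$protein_pos, cutoff = cutoff,
                 weights = weights, base_k = base_k),
            class = "vs_enm")
}

#' @export
print.vs_enm <- function(x, ...) {
  cat(sprintf("<vs_enm> %d nodes, %d springs, cutoff %.1f A\n",
              nrow(x$coords), sum(x$k > 0) / 2, x$cutoff))
  invisible(x)
}

# Assemble the 3N x 3N Hessian of the pairwise harmonic energy at equilibrium.
.enm_hessian <- function(net) {
  coords <- net$coords; k <- net$k
  n <- nrow(coords)
  H <- matrix(0, 3 * n, 3 * n)
  for (i in seq_len(n - 1)) for (j in seq((i + 1), n)) {
    if (k[i, j] <= 0) next
    rij <- coords[j, ] - coords[i, ]
    d2 <- sum(rij^2)
    blk <- k[i, j] * (rij %o% rij) / d2
    ii <- (3 * i - 2):(3 * i); jj <- (3 * j - 2):(3 * j)
    H[ii, ii] <- H[ii, ii] + blk
    H[jj, jj] <- H[jj, jj] + blk
    H[ii, jj] <- H[ii, jj] - blk
    H[jj, ii] <- H[jj, ii] - blk
  }
  H
}

#' Normal-mode spectrum of an elastic network
#'
#' Eigen-decomposition of the 3N x 3N Hessian. A connected, non-collinear
#' network has exactly 6 numerically zero eigenvalues (rigid-body modes);
#' more indicates a disconnected network, which is an error.
#'
#' @param net a `vs_enm`
#' @param zero_tol eigenvalues below `zero_tol * max(eigenvalue)` count as
#'   zero (default 1e-8)
#' @return object of class `vs_modes`: `values` (3N eigenvalues, ascending),
#'   `n_zero`
#' @export
mode_spectrum <- function(net, zero_tol = 1e-8) {
  H <- .enm_hessian(net)
  ev <- sort(eigen(H, symmetric = TRUE, only.values = TRUE)$values)
  scale <- max(abs(ev))
  n_zero <- if (scale == 0) length(ev) else sum(abs(ev) < zero_tol * scale)
  if (n_zero > 6) {
    g <- igraph::graph_from_adjacency_matrix(net$k > 0, mode = "undirected")
    comp <- igraph::components(g)
    if (comp$no > 1)
      stop(sprintf("disconnected elastic network: %d components (sizes %s) give %d zero modes",
                   comp$no, paste(comp$csize, collapse = ","), n_zero))
    stop(sprintf("underconstrained elastic network: connected but %d zero modes (floppy nodes); increase the cutoff",
                 n_zero))
  }
  structure(list(values = ev, n_zero = n_zero), class = "vs_modes")
}

#' @export
print.vs_modes <- function(x, ...) {
  cat(sprintf("<vs_modes> %d eigenvalues, %d zero modes, largest %.4g\n",
              length(x$values), x$n_zero, max(x$values)))
  invisible(x)
}

#' Vibrational entropy score of a mode spectrum
#'
#' S = -1/2 * sum(log lambda) over the nonzero modes, dimensionless up to the
#' constant offsets dropped from the harmonic-oscillator entropy (only
#' differences between spectra are consumed downstream).
#'
#' @param spec a `vs_modes` with exactly 6 zero modes
#' @return numeric entropy score
#' @export
vibrational_entropy <- function(spec) {
  if (spec$n_zero != 6)
    stop("expected exactly 6 zero modes, found ", spec$n_zero)
  lam <- spec$values[(spec$n_zero + 1):length(spec$values)]
  if (any(lam <= 0))
    stop("nonpositive nonzero eigenvalue; spectrum is numerically unusable")
  -0.5 * sum(log(lam))
}

#' Vibrational-entropy difference of a substitution (ddSvib)
#'
#' S(network with the variant residue type at the node) minus S(reference
#' network), on identical geometry — only the node's spring weights change.
#'
#' @param structure a `vs_structure`
#' @param pos protein position of the substitution
#' @param alt_aa one-letter variant amino acid
#' @param cutoff,weights,base_k passed to [build_network()]
#' @return ddSvib (dimensionless); exactly 0 for a self-substitution
#' @export
delta_delta_svib <- function(structure, pos, alt_aa, cutoff = 10,
                             weights = enm_weight_table(), base_k = 1) {
  .check_aa(alt_aa, "alt_aa")
  i <- match(pos, structure$residues$protein_pos)
  if (is.na(i))
    stop("coverage error: protein position ", pos,
         " is not covered by structure ", structure$source_id)
  if (structure$residues$aa[i] == alt_aa) return(0)
  net_ref <- build_network(structure, cutoff, weights, base_k)
  net_var <- net_ref
  aa_var <- net_ref$aa
  aa_var[i] <- alt_aa
  # rebuild spring constants with the mutated type (geometry unchanged)
  wpair <- weights[aa_var, aa_var]
  k <- matrix(0, nrow(net_ref$k), ncol(net_ref$k))
  within <- net_ref$k > 0
  k[within] <- base_k * wpair[within]
  net_var$k <- k
  net_var$aa <- aa_var
  vibrational_entropy(mode_spectrum(net_var)) -
    vibrational_entropy(mode_spectrum(net_ref))
}
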