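# Shrake-Rupley solvent-accessible surface area.
#
# Deterministic implementation: test points are a golden-spiral set on the
# unit sphere, identical for every atom and every run, so results are exactly
# reproducible and invariant under rigid-body transforms of the structure to
# within the point-set discretization.

# Golden-spiral point set on the unit sphere (n x 3 matrix).
.sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# Canonical molecule-fixed frame: principal axes of the heavy-atom cloud,
# ordered by decreasing variance, signs fixed by third-moment skewness (or
# largest projection when the skewness vanishes), right-handed. Computing
# SASA in this frame makes the fixed test-point set rotate with the
# molecule, so results are rigid-transform invariant to machine precision.
.canonical_coords <- function(xyz) {
  center <- colMeans(xyz)
  xc <- sweep(xyz, 2, center)
  ev <- eigen(crossprod(xc) / nrow(xc), symmetric = TRUE)
  E <- ev$vectors  # columns ordered by decreasing eigenvalue
  for (k in 1:3) {
    pr <- xc %*% E[, k]
    s3 <- sum(pr^3)
    if (abs(s3) > 1e-9) {
      if (s3 < 0) E[, k] <- -E[, k]
    } else if (pr[which.max(abs(pr))] < 0) E[, k] <- -E[, k]
  }
  if (det(E) < 0) E[, 3] <- -E[, 3]
  xc %*% E
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Computes per-atom SASA over heavy atoms with a fixed golden-spiral test
#' point set, aggregates per residue, and normalizes by the theoretical
#' maximum accessible area of each residue type to give relative SASA.
#'
#' @param structure a `vs_structure`
#' @param n_sphere_points number of surface test points per atom (>= 100;
#'   default 960)
#' @param probe_radius solvent probe radius in Angstrom (default 1.4, water)
#' @return object of class `vs_sasa`: list with `residue` (data.frame:
#'   `res_index`, `protein_pos`, `aa`, `sasa` in A^2, `rel_sasa`), `atom_sasa`
#'   (numeric per heavy atom), and `total` (A^2, equal to the sum of the
#'   per-residue values)
#' @export
shrake_rupley_sasa <- function(structure, n_sphere_points = 960, probe_radius = 1.4) {
  stopifnot(inherits(structure, "vs_structure"))
  if (n_sphere_points < 100) stop("n_sphere_points must be >= 100")
  a <- structure$atoms
  heavy <- which(a$is_heavy)
  if (!length(heavy)) stop("structure has no heavy atoms")
  el <- a$element[heavy]
  unknown <- setdiff(unique(el), names(VDW_RADII))
  if (length(unknown)) {
    bad <- heavy[el %in% unknown][1]
    stop(sprintf("no van der Waals radius for element '%s' (atom %s of residue index %d)",
                 a$element[bad], a$name[bad], a$res_index[bad]))
  }
  xyz <- .canonical_coords(as.matrix(a[heavy, c("x", "y", "z")]))
  radii <- VDW_RADII[el] + probe_radius
  pts <- .sphere_points(n_sphere_points)
  n <- length(heavy)
  atom_sasa <- numeric(n)
  # neighbor cutoff: two expanded spheres can only intersect within this range
  max_r <- max(radii)
  for (k in seq_len(n)) {
    center <- xyz[k, ]
    d2 <- rowSums((xyz - matrix(center, n, 3, byrow = TRUE))^2)
    nb <- which(d2 < (radii[k] + max_r)^2 & seq_len(n) != k)
    nb <- nb[d2[nb] < (radii[k] + radii[nb])^2]
    test <- pts * radii[k]
    test <- sweep(test, 2, center, "+")
    if (length(nb)) {
      acc <- rep(TRUE, n_sphere_points)
      for (m in nb) {
        if (!any(acc)) break
        dd <- rowSums((test[acc, , drop = FALSE] -
                        matrix(xyz[m, ], sum(acc), 3, byrow = TRUE))^2)
        acc[acc] <- dd >= radii[m]^2
      }
      frac <- sum(acc) / n_sphere_points
    } else frac <- 1
    atom_sasa[k] <- frac * 4 * pi * radii[k]^2
  }
  res_idx <- a$res_index[heavy]
  per_res <- vapply(structure$residues$res_index,
                    function(i) sum(atom_sasa[res_idx == i]), numeric(1))
  rel <- per_res / MAX_SASA[structure$residues$aa]
  out <- list(residue = data.frame(res_index = structure$residues$res_index,
                                   protein_pos = structure$residues$protein_pos,
                                   aa = structure$residues$aa,
                                   sasa = per_res,
                                   rel_sasa = unname(rel),
                                   stringsAsFactors = FALSE),
              atom_sasa = atom_sasa,
              total = sum(per_res))
  class(out) <- "vs_sasa"
  out
}

#' @export
print.vs_sasa <- function(x, ...) {
  cat(sprintf("<vs_sasa> %d residues, total %.1f A^2, %d buried (rel < %.2f)\n",
              nrow(x$residue), x$total, sum(x$residue$rel_sasa < BURIED_RSA), BURIED_RSA))
  invisible(x)
}
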