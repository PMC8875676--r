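# Structure parsing, solvent accessibility, secondary structure and contacts.

test_that("read_pdb parses fixtures, strips heteroatoms, keeps altloc A", {
  path <- tempfile(fileext = ".pdb")
  make_structure("helix", 12, seed = 1,
                 sequence = strrep("A", 12), path = path)
  s <- read_pdb(path)
  expect_equal(n_residues(s), 12)
  # poly-alanine: N, CA, C, O, CB per residue
  expect_equal(as.integer(table(s$atoms$res_index)), rep(5L, 12))
  expect_equal(structure_sequence(s), rep("A", 12))

  # water + one ALA: only the ALA survives
  hoh <- c(pdb_line("ATOM", 1, "N", " ", "ALA", "A", 1, 0, 0, 0, "N"),
           pdb_line("ATOM", 2, "CA", " ", "ALA", "A", 1, 1.46, 0, 0, "C"),
           pdb_line("ATOM", 3, "C", " ", "ALA", "A", 1, 2.0, 1.2, 0, "C"),
           pdb_line("HETATM", 4, "O", " ", "HOH", "A", 2, 9, 9, 9, "O"),
           "END")
  f2 <- tempfile(fileext = ".pdb")
  writeLines(hoh, f2)
  s2 <- read_pdb(f2)
  expect_equal(n_residues(s2), 1)
  expect_equal(s2$residues$type3, "ALA")

  # altloc A/B duplicates collapse to conformer A
  alt <- c(pdb_line("ATOM", 1, "N", " ", "ALA", "A", 1, 0, 0, 0, "N"),
           pdb_line("ATOM", 2, "CA", "A", "ALA", "A", 1, 1.46, 0, 0, "C"),
           pdb_line("ATOM", 3, "CA", "B", "ALA", "A", 1, 1.90, 0, 0, "C"),
           pdb_line("ATOM", 4, "C", " ", "ALA", "A", 1, 2.0, 1.2, 0, "C"),
           "END")
  f3 <- tempfile(fileext = ".pdb")
  writeLines(alt, f3)
  s3 <- read_pdb(f3)
  expect_equal(n_residues(s3), 1)
  ca <- s3$atoms[s3$atoms$name == "CA", ]
  expect_equal(nrow(ca), 1)
  expect_equal(ca$x, 1.46, tolerance = 1e-6)

  # non-standard residue and empty files are rejected
  bad <- c(pdb_line("ATOM", 1, "N", " ", "MSE", "A", 1, 0, 0, 0, "N"), "END")
  f4 <- tempfile(fileext = ".pdb"); writeLines(bad, f4)
  expect_error(read_pdb(f4), "non-standard")
  f5 <- tempfile(fileext = ".pdb")
  writeLines(c(pdb_line("HETATM", 1, "O", " ", "HOH", "A", 1, 0, 0, 0, "O"), "END"), f5)
  expect_error(read_pdb(f5), "no polymer")
})

test_that("isolated and unoccluded atoms reach the closed-form sphere area", {
  s1 <- bare_structure(atom_row(1, "CB", "C", 0, 0, 0), "ALA")
  p1 <- shrake_rupley_sasa(s1)
  expect_equal(p1$total, 4 * pi * (1.7 + 1.4)^2, tolerance = 1e-9)

  # two far-apart atoms: no occlusion, areas add
  s2 <- bare_structure(rbind(atom_row(1, "CB", "C", 0, 0, 0),
                             atom_row(2, "SG", "S", 50, 0, 0)),
                       c("ALA", "CYS"))
  p2 <- shrake_rupley_sasa(s2)
  expect_equal(p2$total, 4 * pi * (1.7 + 1.4)^2 + 4 * pi * (1.8 + 1.4)^2,
               tolerance = 1e-9)
  expect_error(shrake_rupley_sasa(s1, n_sphere_points = 50), ">= 100")
  sx <- bare_structure(atom_row(1, "FE", "FE", 0, 0, 0), "ALA")
  expect_error(shrake_rupley_sasa(sx), "van der Waals")
})

test_that("cluster SASA matches a Monte-Carlo rejection oracle within 2%", {
  set.seed(7)
  xyz <- matrix(rnorm(15, sd = 1.6), ncol = 3)
  els <- c("C", "N", "O", "S", "C")
  atoms <- do.call(rbind, lapply(1:5, function(i)
    atom_row(i, els[i], els[i], xyz[i, 1], xyz[i, 2], xyz[i, 3])))
  s <- bare_structure(atoms, rep("GLY", 5))
  got <- shrake_rupley_sasa(s, n_sphere_points = 960)$atom_sasa
  oracle <- mc_sasa_oracle(xyz, unname(c(C = 1.7, N = 1.55, O = 1.52, S = 1.8)[els]),
                           n_samples = 2e5, seed = 99)
  expect_equal(got, oracle, tolerance = 0.02)
})

test_that("SASA is rigid-transform invariant and additive over residues", {
  s <- make_structure("cluster", 8, seed = 3)
  p <- shrake_rupley_sasa(s)
  expect_equal(p$total, sum(p$residue$sasa))
  st <- rigid_transform(s, random_rotation(11), c(5.3, -2.1, 40))
  pt <- shrake_rupley_sasa(st)
  expect_equal(pt$residue$sasa, p$residue$sasa, tolerance = 1e-6)
  expect_equal(pt$total, p$total, tolerance = 1e-6)
})

test_that("SASA is converged at the default point count", {
  # quadrupling the test points moves no atom's accessible area by more
  # than 1% of its full expanded-sphere area (the discretization scale;
  # a per-atom relative bound diverges as the accessible patch vanishes)
  s <- make_structure("cluster", 8, seed = 5)
  a960 <- shrake_rupley_sasa(s, 960)$atom_sasa
  a3840 <- shrake_rupley_sasa(s, 3840)$atom_sasa
  radii <- c(C = 1.7, N = 1.55, O = 1.52, S = 1.8)
  sphere <- 4 * pi * (radii[s$atoms$element[s$atoms$is_heavy]] + 1.4)^2
  expect_true(all(abs(a960 - a3840) / sphere < 0.01))
})

test_that("secondary structure classifies helix, lone strand and hairpin", {
  hel <- make_structure("helix", 12, seed = 1)
  ss_h <- assign_secondary_structure(hel)
  expect_gte(sum(unclass(ss_h) == "H"), 8)

  # fully extended single strand: no hydrogen-bond partner, all coil
  # (first strand of a long hairpin, isolated)
  flat <- make_structure("sheet_hairpin", 30, seed = 1)
  keep <- flat$atoms$res_index <= 12
  s_half <- new_structure(flat$atoms[keep, ], flat$residues[1:12, ])
  ss_e <- assign_secondary_structure(s_half)
  expect_true(all(unclass(ss_e) == "C"))

  hp <- make_structure("sheet_hairpin", 12, seed = 2)
  ss_hp <- assign_secondary_structure(hp)
  expect_true(all(unclass(ss_hp)[c(3, 4, 9, 10)] == "E"))

  # every residue gets exactly one class
  for (s in list(hel, hp)) {
    cls <- unclass(assign_secondary_structure(s))
    expect_length(cls, n_residues(s))
    expect_true(all(cls %in% c("H", "E", "C")))
  }

  short <- make_structure("helix", 4, seed = 1)
  expect_warning(ss_s <- assign_secondary_structure(short), "shorter")
  expect_true(all(unclass(ss_s) == "C"))
})

test_that("hairpin strand hydrogen bonds verify against the energy formula", {
  hp <- make_structure("sheet_hairpin", 12, seed = 2)
  # independent evaluation of the electrostatic model for the cross-strand
  # bond CO(3) ... HN(10), using the documented H reconstruction
  co <- function(i, nm) varstruct:::.atom_coord(hp, i, nm)
  nrm <- function(v) v / sqrt(sum(v^2))
  H10 <- co(10, "N") +
    nrm(nrm(co(10, "N") - co(9, "C")) + nrm(co(10, "N") - co(10, "CA")))
  E <- 0.084 * 332 * (1 / sqrt(sum((co(3, "O") - co(10, "N"))^2)) +
                      1 / sqrt(sum((co(3, "C") - H10)^2)) -
                      1 / sqrt(sum((co(3, "O") - H10)^2)) -
                      1 / sqrt(sum((co(3, "C") - co(10, "N"))^2)))
  expect_lt(E, -0.5)
  expect_equal(hbond_energy(hp, 3, 10), E, tolerance = 1e-9)
})

test_that("minimum heavy-atom distance is exact, symmetric, brute-force equal", {
  s <- bare_structure(rbind(atom_row(1, "CB", "C", 0, 0, 0),
                            atom_row(2, "CB", "C", 3, 4, 0)),
                      c("ALA", "ALA"))
  expect_equal(min_heavy_atom_distance(s, 1, 2), 5)
  expect_equal(min_heavy_atom_distance(s, 2, 1), 5)
  expect_error(min_heavy_atom_distance(s, 1, 1), "differ")
  expect_error(min_heavy_atom_distance(s, 1, 9), "not present")

  cl <- make_structure("cluster", 10, seed = 9)
  a <- cl$atoms[cl$atoms$is_heavy, ]
  for (pair in list(c(1, 5), c(2, 9), c(3, 10), c(7, 8))) {
    ai <- as.matrix(a[a$res_index == pair[1], c("x", "y", "z")])
    aj <- as.matrix(a[a$res_index == pair[2], c("x", "y", "z")])
    brute <- min(apply(ai, 1, function(p) apply(aj, 1, function(q) sqrt(sum((p - q)^2)))))
    expect_equal(min_heavy_atom_distance(cl, pair[1], pair[2]), brute, tolerance = 1e-12)
  }
})

test_that("disulfide detection honors cutoff and closest-partner pairing", {
  s <- make_structure("cluster", 10, seed = 3, disulfide_pairs = list(c(2, 7)))
  d <- detect_disulfides(s)
  expect_equal(nrow(d), 1)
  expect_equal(c(d$i, d$j), c(2, 7))
  expect_equal(d$distance, 2.05, tolerance = 1e-6)

  # SG atoms 4.0 A apart: none
  far <- s
  sg <- which(far$atoms$res_index == 7 & far$atoms$name == "SG")
  sg2 <- which(far$atoms$res_index == 2 & far$atoms$name == "SG")
  dirv <- as.numeric(far$atoms[sg, c("x", "y", "z")]) -
          as.numeric(far$atoms[sg2, c("x", "y", "z")])
  dirv <- dirv / sqrt(sum(dirv^2))
  far$atoms[sg, c("x", "y", "z")] <-
    as.numeric(far$atoms[sg2, c("x", "y", "z")]) + dirv * 4.0
  expect_equal(nrow(detect_disulfides(far)), 0)

  # three CYS with SG distances 2.0 / 2.4 / 5.0: only the 2.0 pair survives
  tri <- bare_structure(rbind(atom_row(1, "SG", "S", 0, 0, 0),
                              atom_row(2, "SG", "S", 2.0, 0, 0),
                              atom_row(3, "SG", "S", -2.4, 0, 0)),
                        c("CYS", "CYS", "CYS"))
  d3 <- detect_disulfides(tri)
  expect_equal(nrow(d3), 1)
  expect_equal(sort(c(d3$i, d3$j)), c(1, 2))
})

test_that("salt-bridge detection requires a charged pair and matches brute force", {
  s <- make_structure("cluster", 10, seed = 4, salt_bridge_pairs = list(c(3, 8)))
  b <- detect_salt_bridges(s)
  expect_equal(nrow(b), 1)
  expect_equal(c(b$i, b$j), c(3, 8))

  # ASP near SER is not a salt bridge
  ns <- bare_structure(rbind(atom_row(1, "OD1", "O", 0, 0, 0),
                             atom_row(2, "OG", "O", 3.2, 0, 0)),
                       c("ASP", "SER"))
  expect_equal(nrow(detect_salt_bridges(ns)), 0)

  # brute force over qualifying atom pairs on an 8-residue fixture
  cl <- make_structure("cluster", 8, seed = 21,
                       salt_bridge_pairs = list(c(1, 6)))
  got <- detect_salt_bridges(cl)
  groups <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"),
                 LYS = "NZ", ARG = c("NH1", "NH2", "NE"), HIS = c("ND1", "NE2"))
  res <- cl$residues
  brute <- NULL
  for (i in res$res_index[res$type3 %in% c("ASP", "GLU")])
    for (j in res$res_index[res$type3 %in% c("LYS", "ARG", "HIS")]) {
      ai <- cl$atoms[cl$atoms$res_index == i &
                       cl$atoms$name %in% groups[[res$type3[i]]], c("x", "y", "z")]
      aj <- cl$atoms[cl$atoms$res_index == j &
                       cl$atoms$name %in% groups[[res$type3[j]]], c("x", "y", "z")]
      if (!nrow(ai) || !nrow(aj)) next
      dmin <- min(apply(as.matrix(ai), 1, function(p)
        apply(as.matrix(aj), 1, function(q) sqrt(sum((p - q)^2)))))
      if (dmin <= 4.0) brute <- rbind(brute, data.frame(i = i, j = j))
    }
  expect_equal(nrow(got), if (is.null(brute)) 0 else nrow(brute))
  if (!is.null(brute)) expect_equal(got[, c("i", "j")], brute,
                                    ignore_attr = TRUE)
})
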