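# Structural-event rules engine.

# fixture: poly-leucine helix whose mid residue is buried inside an
# occluding shell (chain B), leaving the helix hydrogen bonds untouched
helix_site <- local({
  base <- make_structure("helix", 24, seed = 13, sequence = strrep("L", 24))
  s <- caged_structure(base, 12, radius = 6.0, n_atoms = 80)
  sasa <- shrake_rupley_sasa(s)
  ss <- assign_secondary_structure(s)
  list(s = s, sasa = sasa, ss = ss, site = 12,
       disulf = detect_disulfides(s), salt = detect_salt_bridges(s))
})

test_that("the chosen helix site really is buried and helical", {
  abs_sasa <- helix_site$sasa$residue$sasa[helix_site$site]
  # buried regardless of which residue type normalizes it
  expect_lt(abs_sasa / 104, 0.09)  # even glycine's small maximum
  expect_equal(unclass(helix_site$ss)[helix_site$site], "H")
})

test_that("spec-style flag combinations fire on constructed contexts", {
  hs <- helix_site
  # buried Leu -> Pro in a helix: proline intro + helix penalty + SS change
  rep1 <- evaluate_rules(hs$s, hs$sasa, hs$ss, hs$disulf, hs$salt,
                         hs$site, "L", "P")
  expect_true(all(c("BURIED_PRO_INTRO", "HELIX_PENALTY_GLY_PRO",
                    "SS_CHANGE_GLY_PRO") %in% rep1$fired))

  # exposed Ser -> Ala in a coil with no bonds: nothing fires
  coil <- make_structure("cluster", 8, seed = 55, sequence = "SSSSSSSS")
  sasa_c <- shrake_rupley_sasa(coil)
  ss_c <- suppressWarnings(assign_secondary_structure(coil))
  exposed <- which(sasa_c$residue$rel_sasa >= 0.2)[1]
  rep2 <- evaluate_rules(coil, sasa_c, ss_c,
                         detect_disulfides(coil), detect_salt_bridges(coil),
                         exposed, "S", "A")
  expect_length(rep2$fired, 0)

  # disulfide-bonded Cys -> Ser: breakage flagged with the partner recorded
  sdb <- make_structure("cluster", 10, seed = 3, disulfide_pairs = list(c(2, 7)))
  rep3 <- evaluate_rules(sdb, shrake_rupley_sasa(sdb),
                         suppressWarnings(assign_secondary_structure(sdb)),
                         detect_disulfides(sdb), detect_salt_bridges(sdb),
                         2, "C", "S")
  expect_true("DISULFIDE_BREAK" %in% rep3$fired)
  expect_equal(rep3$context$partners$disulfide, 7)

  # salt-bridged Asp -> Ala loses the acidic charge
  ssb <- make_structure("cluster", 10, seed = 4, salt_bridge_pairs = list(c(3, 8)))
  rep4 <- evaluate_rules(ssb, shrake_rupley_sasa(ssb),
                         suppressWarnings(assign_secondary_structure(ssb)),
                         detect_disulfides(ssb), detect_salt_bridges(ssb),
                         3, "D", "A")
  expect_true("SALT_BRIDGE_BREAK" %in% rep4$fired)
  # ... but Asp -> Glu keeps it
  rep5 <- evaluate_rules(ssb, shrake_rupley_sasa(ssb),
                         suppressWarnings(assign_secondary_structure(ssb)),
                         detect_disulfides(ssb), detect_salt_bridges(ssb),
                         3, "D", "E")
  expect_false("SALT_BRIDGE_BREAK" %in% rep5$fired)
})

test_that("self-substitutions never fire and distant context is irrelevant", {
  hs <- helix_site
  for (aa in c("L", "G", "P", "D")) {
    rep <- evaluate_rules(hs$s, hs$sasa, hs$ss, hs$disulf, hs$salt,
                          hs$site, aa, aa)
    expect_length(rep$fired, 0)
  }
  # permuting residue identities far from the site changes nothing
  s2 <- hs$s
  far <- c(1, 2, 23, 24)
  s2$residues$type3[far] <- c("TRP", "ASP", "LYS", "GLY")
  s2$residues$aa[far] <- c("W", "D", "K", "G")
  rep_a <- evaluate_rules(hs$s, hs$sasa, hs$ss, hs$disulf, hs$salt,
                          hs$site, "L", "D")
  rep_b <- evaluate_rules(s2, hs$sasa, hs$ss, hs$disulf, hs$salt,
                          hs$site, "L", "D")
  expect_equal(rep_a$fired, rep_b$fired)
})

test_that("all 380 ordered substitutions at a buried helix site match a truth-table oracle", {
  hs <- helix_site
  aa <- aa_alphabet()
  abs_sasa <- hs$sasa$residue$sasa[hs$site]
  # independent oracle with its own property tables (buried helix site,
  # no disulfide or salt-bridge membership)
  MAXS <- c(A = 129, R = 274, N = 195, D = 193, C = 167, Q = 225, E = 223,
            G = 104, H = 224, I = 197, L = 201, K = 236, M = 224, F = 240,
            P = 159, S = 155, T = 172, W = 285, Y = 263, V = 174)
  PHOB <- c("A", "C", "F", "I", "L", "M", "V", "W", "Y")
  PHIL <- c("D", "E", "H", "K", "N", "Q", "R")
  CHG <- function(x) ifelse(x %in% c("D", "E"), -1, ifelse(x %in% c("K", "R", "H"), 1, 0))
  oracle <- function(r, a) {
    if (r == a) return(character())
    buried <- abs_sasa / MAXS[r] < 0.09
    out <- character()
    if (buried && a == "P" && r != "P") out <- c(out, "BURIED_PRO_INTRO")
    if (buried && r == "G" && a != "G") out <- c(out, "BURIED_GLY_REPLACED")
    if (buried && a %in% PHIL && !(r %in% PHIL)) out <- c(out, "BURIED_HYDROPHILIC_INTRO")
    if (buried && CHG(a) != 0 && CHG(r) == 0) out <- c(out, "BURIED_CHARGE_INTRO")
    if (buried && CHG(a) * CHG(r) < 0) out <- c(out, "BURIED_CHARGE_SWITCH")
    if (a %in% c("G", "P") && !(r %in% c("G", "P"))) out <- c(out, "SS_CHANGE_GLY_PRO")
    if (buried && CHG(r) != 0 && CHG(a) == 0) out <- c(out, "BURIED_CHARGE_REPLACED")
    if ((abs_sasa / MAXS[r] < 0.09) != (abs_sasa / MAXS[a] < 0.09))
      out <- c(out, "EXPOSURE_SWITCH")
    if (!buried && r %in% PHIL && a %in% PHOB)
      out <- c(out, "EXPOSED_HYDROPHILIC_TO_HYDROPHOBIC")
    if (a %in% c("G", "P")) out <- c(out, "HELIX_PENALTY_GLY_PRO")
    out
  }
  n_checked <- 0; n_bad <- 0
  for (r in aa) for (a in aa) {
    if (r == a) next
    got <- sort(evaluate_rules(hs$s, hs$sasa, hs$ss, hs$disulf, hs$salt,
                               hs$site, r, a)$fired)
    if (!identical(got, sort(oracle(r, a)))) n_bad <- n_bad + 1
    n_checked <- n_checked + 1
  }
  expect_equal(n_checked, 380)
  expect_equal(n_bad, 0)
})

test_that("exposure-switch flag detects threshold crossing by renormalization", {
  # a partially occluded site: absolute SASA buried for tryptophan's large
  # maximum but exposed for glycine's small one
  base <- make_structure("helix", 24, seed = 13, sequence = strrep("L", 24))
  s <- caged_structure(base, 12, radius = 6.2, n_atoms = 80)
  sasa <- shrake_rupley_sasa(s)
  abs_sasa <- sasa$residue$sasa[12]
  expect_lt(abs_sasa / 285, 0.09)
  expect_gte(abs_sasa / 104, 0.09)
  ss <- assign_secondary_structure(s)
  rep <- evaluate_rules(s, sasa, ss, detect_disulfides(s),
                        detect_salt_bridges(s), 12, "W", "G")
  expect_true("EXPOSURE_SWITCH" %in% rep$fired)
  # and the reverse direction switches the other way
  rep2 <- evaluate_rules(s, sasa, ss, detect_disulfides(s),
                         detect_salt_bridges(s), 12, "G", "W")
  expect_true("EXPOSURE_SWITCH" %in% rep2$fired)
})
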