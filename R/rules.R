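# Structural-event checklist for one substitution ("red flags").
#
# All checks run on the wild-type structure context — burial state, secondary
# structure, disulfide and salt-bridge partners — so no mutant model is
# needed. Burial means relative SASA < 0.09 (missense3D convention), where
# relative SASA is the position's absolute SASA divided by the maximum
# accessible area of the *claimed* reference residue type, so the checks
# depend only on (context, ref_aa, alt_aa). The predicted exposure class of
# the variant keeps the absolute SASA and renormalizes by the variant type's
# maximum; the exposure-switch flag fires when that crosses the threshold.

#' The twelve structural-event flags
#' @return character vector of flag names
#' @export
rule_flags <- function() {
  c("DISULFIDE_BREAK", "BURIED_PRO_INTRO", "BURIED_GLY_REPLACED",
    "BURIED_HYDROPHILIC_INTRO", "BURIED_CHARGE_INTRO", "BURIED_CHARGE_SWITCH",
    "SS_CHANGE_GLY_PRO", "BURIED_CHARGE_REPLACED", "EXPOSURE_SWITCH",
    "EXPOSED_HYDROPHILIC_TO_HYDROPHOBIC", "SALT_BRIDGE_BREAK",
    "HELIX_PENALTY_GLY_PRO")
}

#' Evaluate the structural-event rules for one substitution
#'
#' @param structure a `vs_structure`
#' @param sasa a `vs_sasa` computed on `structure`
#' @param ss a `vs_secstruct` computed on `structure`
#' @param disulfides data.frame from [detect_disulfides()]
#' @param salt_bridges data.frame from [detect_salt_bridges()]
#' @param pos protein position of the substitution (must be covered)
#' @param ref_aa,alt_aa one-letter amino acids
#' @return object of class `vs_rule_report`: list with `fired` (character
#'   vector of flags), `context` (burial state, relative SASAs, SS class,
#'   bond partners)
#' @export
evaluate_rules <- function(structure, sasa, ss, disulfides, salt_bridges,
                           pos, ref_aa, alt_aa) {
  .check_aa(c(ref_aa, alt_aa))
  i <- match(pos, structure$residues$protein_pos)
  if (is.na(i))
    stop("coverage error: protein position ", pos,
         " is not covered by structure ", structure$source_id)
  abs_sasa <- sasa$residue$sasa[sasa$residue$res_index == i]
  rsa_ref <- abs_sasa / MAX_SASA[ref_aa]
  rsa_alt <- abs_sasa / MAX_SASA[alt_aa]
  buried <- rsa_ref < BURIED_RSA
  ss_i <- unclass(ss)[i]
  in_disulf <- nrow(disulfides) > 0 && i %in% c(disulfides$i, disulfides$j)
  sb_row <- if (nrow(salt_bridges)) salt_bridges[salt_bridges$i == i | salt_bridges$j == i, ] else salt_bridges
  in_salt <- nrow(sb_row) > 0
  chg_ref <- aa_charge(ref_aa); chg_alt <- aa_charge(alt_aa)

  fired <- character()
  if (ref_aa != alt_aa) {
    if (in_disulf && ref_aa == "C" && alt_aa != "C")
      fired <- c(fired, "DISULFIDE_BREAK")
    if (buried && alt_aa == "P" && ref_aa != "P")
      fired <- c(fired, "BURIED_PRO_INTRO")
    if (buried && ref_aa == "G" && alt_aa != "G")
      fired <- c(fired, "BURIED_GLY_REPLACED")
    if (buried && alt_aa %in% AA_HYDROPHILIC && !(ref_aa %in% AA_HYDROPHILIC))
      fired <- c(fired, "BURIED_HYDROPHILIC_INTRO")
    if (buried && chg_alt != 0 && chg_ref == 0)
      fired <- c(fired, "BURIED_CHARGE_INTRO")
    if (buried && chg_ref * chg_alt < 0)
      fired <- c(fired, "BURIED_CHARGE_SWITCH")
    if (ss_i %in% c("H", "E") && alt_aa %in% c("G", "P") && !(ref_aa %in% c("G", "P")))
      fired <- c(fired, "SS_CHANGE_GLY_PRO")
    if (buried && chg_ref != 0 && chg_alt == 0)
      fired <- c(fired, "BURIED_CHARGE_REPLACED")
    if ((rsa_ref < BURIED_RSA) != (rsa_alt < BURIED_RSA))
      fired <- c(fired, "EXPOSURE_SWITCH")
    if (!buried && ref_aa %in% AA_HYDROPHILIC && alt_aa %in% AA_HYDROPHOBIC)
      fired <- c(fired, "EXPOSED_HYDROPHILIC_TO_HYDROPHOBIC")
    if (in_salt) {
      acidic_member <- any(sb_row$i == i)
      lost <- (acidic_member && !(alt_aa %in% c("D", "E"))) ||
              (!acidic_member && !(alt_aa %in% c("K", "R", "H")))
      if (lost) fired <- c(fired, "SALT_BRIDGE_BREAK")
    }
    if (ss_i == "H" && alt_aa %in% c("G", "P"))
      fired <- c(fired, "HELIX_PENALTY_GLY_PRO")
  }
  partners <- list(
    disulfide = if (in_disulf) setdiff(unlist(disulfides[disulfides$i == i | disulfides$j == i, c("i", "j")]), i) else integer(),
    salt_bridge = if (in_salt) setdiff(unlist(sb_row[, c("i", "j")]), i) else integer())
  structure(list(pos = pos, ref_aa = ref_aa, alt_aa = alt_aa,
                 fired = fired,
                 context = list(buried = unname(buried),
                                rsa_ref = unname(rsa_ref),
                                rsa_alt = unname(rsa_alt),
                                abs_sasa = abs_sasa,
                                ss = ss_i, partners = partners)),
            class = "vs_rule_report")
}

#' @export
print.vs_rule_report <- function(x, ...) {
  cat(sprintf("<vs_rule_report> %s%d%s [%s, %s]: %s\n",
              x$ref_aa, x$pos, x$alt_aa,
              if (x$context$buried) "buried" else "exposed", x$context$ss,
              if (length(x$fired)) paste(x$fired, collapse = ";") else "no flags"))
  invisible(x)
}
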