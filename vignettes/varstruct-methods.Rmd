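---
title: "varstruct: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{varstruct: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`varstruct` annotates missense single-nucleotide variants of configured genes
— typically ADME pharmacogenes, whose structures are few enough to curate by
hand — directly on protein 3D structures. This vignette explains the models
behind each stage, the tunable parameters and their defaults, what the
synthetic-data generators do and do not emulate, and the design decisions
taken where more than one reasonable choice existed.

## Pipeline overview

For each gene the annotation database holds a curated structure
(`structure.pdb`, author numbering equal to protein reference numbering), the
protein reference sequence, a genome-to-protein codon map, a PSI-BLAST ASCII
PSSM, and optionally an FTMap-style drug-hotspot summary and precomputed
hotspot patches. Each VCF record is mapped to a protein substitution,
and covered missense variants receive: a stability-change estimate (ΔΔG), a
vibrational-entropy change (ΔΔS~vib~), a twelve-item structural-event
checklist, a 12-feature vector, a random-forest class prediction, and
hotspot/drug-site membership. Every input ALT allele produces exactly one
output record; variants the pipeline cannot process (non-SNVs, positions
outside structure coverage, data errors) are reported with a status instead
of being dropped.

## Genome-to-protein mapping

Coordinates are 1-based GRCh37 throughout; one transcript per gene. The codon
map stores, for every protein position, the three genomic coordinates of its
codon in translation order together with the coding-strand codon. For
minus-strand genes the coordinates descend and the stored codon is already
the reverse complement of the plus-strand bases, so a VCF allele is mapped by
complementing it once and substituting in place. `validate_codon_map()`
re-translates every codon against the reference protein sequence and checks
coordinate uniqueness; `annotate_gene()` refuses to annotate a gene whose map
fails this QC. A VCF REF base that contradicts the codon map is a hard,
per-variant error (reported as `non_processed`), since it means the input was
called against a different assembly or transcript.

## Solvent accessibility

SASA uses the Shrake–Rupley method: 960 golden-spiral test points per heavy
atom (probe 1.4 Å; van der Waals radii C 1.7, N 1.55, O 1.52, S 1.8 Å). Two
numerical choices matter:

* The golden-spiral point set is deterministic, so results are exactly
  reproducible. Because a lab-fixed point set would make results depend
  slightly on the molecule's orientation, coordinates are first expressed in
  a canonical frame (principal axes of the heavy-atom cloud, signs fixed by
  the third moment). This makes SASA rigid-transform invariant to machine
  precision.
* Quadrupling the point count moves no atom's area by more than 1% *of the
  atom's full sphere area*. A bound relative to the atom's own accessible
  area is not meaningful for nearly buried atoms, whose accessible patch can
  be arbitrarily small while the absolute discretization error stays at the
  ~0.5%-of-sphere scale.

Relative SASA divides by a per-residue-type theoretical maximum; relative
SASA below 0.09 is "buried" (the missense3D convention, which the rules
engine adopts). The mutant residue's SASA is approximated by max-SASA
scaling of the reference residue's absolute SASA rather than side-chain
rebuilding; with that approximation the SASA-ratio feature reduces to
maxSASA(alt)/maxSASA(ref), which stays defined even for a fully buried
site.

## Secondary structure

Assignment uses the Kabsch–Sander electrostatic hydrogen-bond energy
(0.084·332·(1/r~ON~ + 1/r~CH~ − 1/r~OH~ − 1/r~CN~) kcal/mol, bond when below
−0.5). Amide hydrogens are reconstructed 1.0 Å from N along the direction
opposing the bisector of the C(prev)–N and CA–N bonds; missing carbonyl
oxygens are rebuilt in the peptide plane. Ladders of two consecutive i→i+4
bonds mark helix; paired inter-strand bonds (antiparallel or parallel bridge
patterns) mark strand; everything else is coil. The rule engine only needs
the three-state H/E/C classes, so finer DSSP classes (3~10~, π, turns,
bends) are deliberately out of scope. Chains shorter than five residues are
assigned coil with a warning.

## Stability change (ΔΔG)

The stability backend is pluggable: any function of (structure, position,
ref, alt) returning kcal/mol with positive = destabilizing and exactly zero
for a self-substitution. The built-in estimator is a fast, deterministic
environment score — a weighted sum of burial-weighted hydrophobicity loss,
packing-weighted volume change (heavy-atom contacts within 8 Å of CB),
a Gly/Pro-in-helix penalty, and a buried-charge penalty, with weights
(1.2, 0.8, 1.5, 1.8 kcal/mol per normalized unit) exposed as configuration.
It is an ordinal screening heuristic, not a force field: it ranks
burial/packing insults sensibly but does not reproduce experimental ΔΔG
magnitudes, and force-field backends (e.g. FoldX, if licensed and installed)
can be substituted under the same contract.

Labels follow the ±0.5 kcal/mol convention: neutral iff −0.5 < ΔΔG < 0.5,
with the boundary values themselves high-impact ("beyond the threshold"
read as inclusive).

Hotspot patches are found by alanine-scanning every position with the
backend, keeping positions with ΔΔG ≥ 2 kcal/mol, linking pairs whose
minimum heavy-atom distance is ≤ 6 Å, and taking connected components
(single linkage). "Cluster of residues at most 6 Å apart" is ambiguous
between all-pairs and chained proximity; connected components were chosen
because they are order-independent and match the "patch" reading. Signed
ΔΔG (not |ΔΔG|) qualifies a position, since alanine truncation of a hotspot
residue is expected to destabilize.

## Vibrational entropy (ΔΔS~vib~)

Conformational flexibility enters through a sequence-weighted anisotropic
elastic network on CA nodes: springs join pairs within 10 Å, with force
constant base·w(type~i~)·w(type~j~), where the per-type stiffness scalar is
an affine map of the bundled hydrophobicity descriptor into [0.6, 1.4] —
hydrophobic–hydrophobic contacts stiffest, polar–polar softest. The entropy
score is S = −½ Σ ln λ over the 3N−6 internal modes of the mass-free
Hessian; all constant offsets of the harmonic-oscillator entropy are dropped
because only the difference between variant and reference networks is
consumed. A substitution changes only the mutated node's type (hence its
spring weights), never the geometry, which guarantees two exact contracts:
self-substitutions give 0, and A→B equals −(B→A) on the same geometry.
Eigenvalues below 10⁻⁸ of the largest count as zero; a connected,
non-collinear network must have exactly six. Networks that are connected but
mechanically underconstrained (e.g. a dangling chain end with one contact)
are reported as errors rather than silently producing extra zero modes.

This is a deliberately desk-scale stand-in for all-atom coarse-grained mode
calculators: it preserves the sequence sensitivity and the contracts that
the feature consumer relies on, not any particular published force field.

## Structural-event rules

Twelve boolean events are evaluated per substitution on the *wild-type*
context only (no mutant model): disulfide breakage, buried Pro introduction,
buried Gly replacement, buried hydrophilic introduction, buried charge
introduction, buried charge switch, Gly/Pro secondary-structure disruption,
buried charge replacement, exposure switch, exposed
hydrophilic→hydrophobic, salt-bridge breakage, and the Gly/Pro helix
penalty. Conventions:

* Polarity classes: hydrophilic = {D,E,H,K,N,Q,R} (charged plus amide
  polar), hydrophobic = {A,C,F,I,L,M,V,W,Y}, neutral = {G,P,S,T}. With this
  classification an exposed Ser→Ala fires nothing, which is the intended
  behavior for chemically mild substitutions.
* Charges: {D,E} negative, {K,R,H} positive; a "switch" is a buried position
  exchanging opposite formal charges.
* Burial uses the claimed reference residue's max-SASA normalization of the
  site's absolute SASA, so flags depend only on (context, ref, alt).
* The exposure switch compares burial classes when the *same* absolute SASA
  is renormalized by the variant type's maximum. (Scaling the absolute value
  by maxSASA(alt)/maxSASA(ref) and then renormalizing would cancel exactly
  and the flag could never fire.)
* Disulfide pairs are CYS SG–SG ≤ 2.5 Å, each cysteine in at most one pair
  (closest partner); salt bridges are acidic/basic side-chain group atoms
  within 4.0 Å. A substitution breaks a bridge when it loses the required
  charge class, so Asp→Glu preserves a bridge while Asp→Ala breaks it.
* Self-substitutions never fire (the two Gly/Pro flags therefore require
  alt ≠ ref even though their trigger is formally "alt is G or P").

## Sequence features and the feature vector

The fixed 12-feature order is: ΔΔG, ΔΔS~vib~, SASA ratio, PSSM score of the
variant, PSSM self score, Sneath-style dissimilarity, Grantham distance,
BLOSUM62 score, volume difference (BIGC670101, alt − ref), hydrophobicity
difference (JOND750101, alt − ref), total-SASA difference, and the reference
residue's relative SASA. Only eleven of these are forced by the modeling
framework; the twelfth (reference relative SASA) is a declared choice and
can be dropped (`feature_names(include_rsa = FALSE)`) to run an 11-feature
model. AAindex descriptors enter as differences so identity maps to zero and
reversal negates. A schema checksum travels with every trained model and is
re-verified at prediction time.

The Grantham matrix is generated from the published composition/polarity/
volume properties and formula (mean distance scaled to 100, rounded), which
reproduces the published integers (L–I 5, R–L 102, G–W 184, maximum C–W
215). The Sneath slot is filled by a clearly labeled *synthetic* stand-in —
a 0–100-scaled distance over bundled physicochemical descriptors — because
the original 1966 table is not redistributable here; `substitution_scores()`
accepts a user-supplied table to restore the published index.

## Classifier

Training records are mutations with experimental ΔΔG; the binary label is
always re-derived from the stored ΔΔG via the ±0.5 rule. Outlier filtering
drops records whose robust z-score (median/MAD) exceeds 3 on the computed
ΔΔG or ΔΔS~vib~ features; with fewer than 10 records filtering is skipped.
The forest uses 1000 trees, minimum leaf size 42, maximum depth 60,
mtry = √p, bootstrap sampling, and a fixed seed; splitting and 10-fold
cross-validation are stratified by label (the labels are typically
imbalanced, and stratification stabilizes the minority class). The positive
class is high_impact throughout; ROC curves sweep unique score thresholds
with tie grouping, so the trapezoid AUC equals the Mann–Whitney rank
statistic exactly.

## Synthetic data: what it does and does not show

The generators exist so the entire pipeline can be built and tested offline:

* `make_structure()` grows ideal-geometry backbones (helix φ=−57°, ψ=−47°;
  hairpin strands φ=−110°, ψ=130° around a type-I'-like turn, chosen so the
  strands actually form cross-strand hydrogen bonds; "cluster" chains draw
  torsions from Ramachandran basins) with simplified side chains (CB plus
  one named terminal atom). Bond/angle values are ideal, so generated
  structures exercise every geometric code path but contain no packing
  defects, no missing atoms, and no crystallographic noise.
* `make_toy_gene()` lays a seeded codon choice for a protein onto
  GRCh37-style coordinates with one intron gap, on either strand, and emits
  variant sets with known outcomes.
* `simulate_training_set()` draws neutral ΔΔG uniformly inside (−0.45,
  0.45) and high-impact magnitudes from 0.55 + Exp(mean 1.5) truncated at
  12 kcal/mol (the spread of published compilations), with a configurable
  class balance (default 0.5), feature noise (ΔΔG feature = true value +
  N(0, 0.1)), and label noise (default 0.1: the experimental value is
  redrawn from the opposite class, emulating curation error while keeping
  the label/ΔΔG invariant intact).

Tests passing on these fixtures demonstrate internal correctness —
geometry against Monte-Carlo and brute-force oracles, spectra against
finite-difference Hessians, mapping round trips, classifier recovery of a
known generative rule — but not accuracy on real proteins: real structures
have packing, waters, cofactor context and experimental error that no
ideal-geometry fixture reproduces, and the built-in ΔΔG estimator is a
heuristic. Problem sizes in the test and acceptance suites (clusters of
5–20 residues, helices up to 24 residues, 2000 simulated training records,
10⁶ Monte-Carlo samples, 100 random hotspot fixtures) were chosen as the
smallest sizes at which each property is non-trivially exercised.

## Known limitations

Single-nucleotide, single-isoform, single-structure annotation only; indels
and multi-nucleotide variants are reported as `unsupported`. All rules run
on the wild-type structure, so mutant-model criteria (cavity volume,
clashes) are out of scope. The built-in ΔΔG and the elastic-network entropy
are screening-quality stand-ins behind pluggable contracts. PSSMs are
consumed, never computed; drug-hotspot tables are consumed as prepared
summaries.
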