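Package: varstruct
Title: Structure-Based Annotation of Missense Variants in Drug-Metabolism Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Annotates missense single-nucleotide variants of configured genes
    (typically ADME pharmacogenes) on protein 3D structures. Maps GRCh37 VCF
    records onto protein positions through a per-gene codon map, computes
    structural and sequence features (Shrake-Rupley solvent accessibility,
    backbone hydrogen-bond secondary structure, a folding-stability change
    estimate, elastic-network vibrational entropy differences, PSSM and
    substitution-matrix scores), evaluates a checklist of deleterious
    structural events (buried charge or proline introduction, disulfide and
    salt-bridge breakage, exposure switches), detects alanine-scan hotspot
    patches and drug-binding hotspots, classifies variants as neutral or
    high-impact with a random forest, and writes per-gene CSV and HTML
    reports. Includes deterministic fixture generators so the whole pipeline
    can be exercised without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    vcfR,
    Biostrings,
    seqinr,
    ranger,
    igraph,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    pracma,
    jsonlite
Config/testthat/edition: 3
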