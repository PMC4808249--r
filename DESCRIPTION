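Package: ccprofiler
Title: Conformational Change Profiling of Apo/Holo Protein Structure Pairs
Version: 0.9.0
Authors@R:
    person("Structural", "Bioinformatics", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computes per-residue conformational change profiles (CCPs) from a
    pair of protein structures representing the same protein before and after
    binding. A 21-residue window is slid along a reference sequence and the
    residues observed in both states are rigidly superposed (least-squares or
    iteratively reweighted) to yield a local RMSD at every position. Companion
    per-position tracks are computed on the same reference ruler: a potential
    binding-target-site profile from heavy-atom distance cutoffs, two-state
    secondary structure (Kabsch-Sander assignment merged to helix/strand/coil
    with disorder and null overlays), an entropy-based conservation profile
    with independent-count sequence weighting, and a windowed Kyte-Doolittle
    hydropathy sum. The package also enumerates valid before/after pairs from
    a set of PDB files, extracts and categorises binding targets, and ships a
    deterministic synthetic-structure generator (hinge-rotated backbones,
    planted ligands, deleted coordinate ranges, synthetic alignments) so that
    the whole pipeline is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
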