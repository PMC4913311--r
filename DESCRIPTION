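Package: hybridfold
Title: Protein Fold Recognition with Sequence-Structure Hybrid Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fold recognition by profile-profile alignment of evolutionary
    hybrid profiles that combine amino-acid frequencies from a multiple
    sequence alignment with two structural tracks computed from coordinates:
    the 16-letter Protein Blocks structural alphabet and ten solvent
    accessibility classes. Provides backbone dihedral computation and Protein
    Blocks assignment, a deterministic Shrake-Rupley solvent accessible
    surface area implementation with relative-accessibility discretization,
    profile construction with Henikoff weighting and substitution-matrix
    pseudocounts, semi-global dynamic programming alignment with
    position-specific affine gap penalties and a clustered-conservation
    correlation score, template databank building and ranked search with
    annotated alignment rendering, decoy-based model quality utilities, a
    fold-weighted ROC evaluation bench, and deterministic synthetic fixture
    generators (toy backbones, mutated alignments, toy fold databanks).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
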