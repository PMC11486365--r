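Package: torsionspace
Title: Torsion-Angle Analysis and Comparison of Nucleic Acid 3D Structures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes torsion, pseudo-torsion and sugar-pucker pseudorotation
    parameters of RNA, DNA and hybrid 3D structures read from PDB or
    PDBx/mmCIF files, and compares structures in torsion-angle space using
    the mean of circular quantities (MCQ) and the longest continuous segment
    under an MCQ threshold (LCS-TA). Supports single-structure angle tables
    and circular statistics, model-versus-target comparison with per-residue
    dissimilarity and coverage summaries, and model-versus-model ensemble
    analysis via MCQ dissimilarity matrices, classical multidimensional
    scaling, k-medoids clustering and average-linkage dendrograms. Includes
    a synthetic chain builder that places full-atom polynucleotide
    coordinates from prescribed torsion angles for download-free testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    bio3d,
    cluster,
    jsonlite,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
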