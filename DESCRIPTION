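Package: zcnt
Title: Copy Number Phylogenetics Under the Zero-Agnostic Transformation Model
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Infers tumor phylogenies from single-cell copy number profiles
    under the zero-agnostic copy number transformation (ZCNT) model, a
    relaxation of the classical copy number transformation (CNT) model in
    which interval amplification and deletion events may also alter
    zero-copy loci. Provides the delta-profile representation of copy number
    profiles, the closed-form ZCNT distance (a metric), exact and relaxed
    solvers for the ZCNT small parsimony problem including a linear-time
    2-approximation, a dynamic program for the multiple-median problem,
    neighbor-joining plus nearest-neighbor-interchange tree search for the
    large parsimony problem, a CNT-event simulator with ground truth, and
    tree-comparison statistics (Robinson-Foulds distance, sibling
    dissimilarity, clonal discordance).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
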