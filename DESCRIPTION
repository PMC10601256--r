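Package: triplexlens
Title: Prediction and Trajectory Analysis of Parallel RNA:DNA Triple Helices
Version: 0.1.0
Authors@R:
    person("triplexlens", "developers", email = "triplexlens@example.org",
           role = c("aut", "cre"))
Description: Tools for studying lncRNA:DNA triple helices formed in the
    parallel (pyrimidine) motif. Provides a canonical-code scanner for
    triplex target sites on promoter duplexes (U.A-T and C+.G-C triplets),
    an idealized three-strand triplex builder with a seeded synthetic
    trajectory generator (planted hydrogen-bond occupancies, Gaussian
    coordinate noise, optional terminal fraying), multi-model PDB
    trajectory input/output, Kabsch-superposition RMSD, geometric
    hydrogen-bond detection with in-register/out-of-register occurrence
    maps, pairwise Lennard-Jones plus Coulomb interaction energies with a
    per-base-pair-level decomposition into hydrogen-bond, cross and
    stacking terms, and small qPCR quantification utilities (delta-delta-Ct,
    ChIP double normalization, CLIP RNA recovery).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
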