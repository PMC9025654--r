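Package: introspectr
Title: Motif-Guided Targeted Database Building for Immunopeptidome Mass
    Spectrometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds small, motif-targeted peptide databases for second-round
    HLA class I immunopeptidome database searches.  Peptides identified at 1%
    FDR in a first, unspecific-digestion search are deconvoluted into binding
    motifs by a simulated-annealing Gibbs sampler, position-specific scoring
    matrices (PSSMs) are trained per motif and peptide length, and the full
    9-11-mer search space of a proteome is filtered at a motif-score
    threshold.  All first-round peptides are injected into the targeted
    database so that the refined search retains a single global FDR.  Includes
    frequency-profile Pearson-correlation evaluation, a synthetic ground-truth
    generator, and a toy target-decoy simulation of the sensitivity mechanism.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    graphics,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
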