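Package: diazodiv
Title: Diversity and Activity of Alternative Nitrogenases from Amplicons,
    Isotopes and Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying canonical (Mo) and alternative (Fe-only, V)
    nitrogenases in environmental samples. Implements a quality-control
    cascade for long-read nifD/anfD/vnfD amplicons (size selection,
    translated homology screen, homopolymer and ambiguity filters,
    reference-based bimera detection, stop-codon screening and alignment
    trimming), OTU clustering with Chao1/Shannon/rarefaction diversity
    statistics and internal-standard error estimation, the isotopic
    acetylene reduction assay (ISARA) two-endmember mixing model with
    Monte-Carlo uncertainty, conserved cofactor-ligand motif analysis, and
    minimum-gene-set genome screening for nitrogenase isozymes. A synthetic
    data generator (in-silico PCR, error-bearing circular-consensus-like
    reads, chimeras, internal-standard spike-ins, isotope and rate data)
    provides fully reproducible inputs with recorded ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    jsonlite,
    stats,
    utils,
    vegan,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
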