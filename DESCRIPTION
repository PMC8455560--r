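Package: crmkit
Title: Analysis Toolkit for Cis-Regulatory Module Landscapes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computational toolkit for dissecting the cis-regulatory
    landscape of a developmental gene: in-silico double restriction
    digestion and fragment-based 4C-seq viewpoint profiling with sliding
    window RPM normalisation and genotype subtraction, ATAC-seq style
    binned RPKM tracks, bidirectional-best-hit detection of orthologous
    enhancer modules across genomes, alignment block trimming and
    VISTA-style windowed conservation calling, position weight matrix
    binding-site identification with exact score-distribution p-values,
    disruptive mutagenesis design with de-novo site verification, and
    2^-ddCq expression quantification with the exact two-tailed
    Mann-Whitney test. Includes a seeded synthetic-data generator for
    every pipeline input so all stages can be exercised end-to-end with
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    methods,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
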