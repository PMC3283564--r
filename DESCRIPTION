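Package: cloneflux
Title: Gene Flow and Speciation Analysis on Clonal Genealogies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to study incipient speciation in clonally reproducing
    microbes from whole-genome data. Simulates clonal genealogies with
    homologous recombination under a coalescent-with-gene-conversion model,
    quantifies recombination flux between lineages relative to the model's
    neutral prior and its change through coalescent time, estimates r/m,
    scans genomes for differentiation with sliding-window Hudson F_ST,
    computes Nei-Gojobori dN/dS and McDonald-Kreitman tests on codon
    alignments, and reconstructs minimum gain/loss histories of variable
    genome segments by parsimony.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    ape,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    seqinr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
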