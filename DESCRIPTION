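Package: phylodemog
Title: Phylogeographic Diversity Statistics, Demographic Inference and
    Refugia Hypothesis Testing for Haplotype Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for the phylogeographic and demographic analysis of
    mitochondrial haplotype alignments: haplotype and nucleotide
    diversity, Watterson's theta and effective population size
    conversion, Tajima's D and Fu's Fs neutrality tests with coalescent
    P-values, mismatch distributions with sudden-expansion model fitting
    (SSD and Harpending's raggedness with parametric bootstrap),
    hierarchical analysis of molecular variance (AMOVA) with
    Phi-statistics and permutation tests, statistical-parsimony
    haplotype networks with a 95 percent connection limit, a structured
    coalescent simulator over population trees with HKY+Gamma mutation,
    and a Slatkin-Maddison minimum-sorting-events test of competing
    glacial-refugia demographic models.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
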