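Package: hapconserv
Title: Conservation Priority Assessment from Haplotype Diversity and
    Richness Partitioning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for ranking populations for conservation from aligned
    mitochondrial (or other haploid) sequence data. Computes the standard
    haplotype-level diversity panel (polymorphic, singleton and
    parsimony-informative sites; haplotype diversity Hd; nucleotide
    diversity Pi; mean pairwise differences K), pairwise population
    p-distances, Hudson-type Fst and island-model gene flow, and haplotype
    sharing summaries. Implements two priority-assessment models: a
    composite genetic-diversity score obtained by projecting standardized
    (Hd, Pi, K) onto the first principal component of their correlation
    matrix, and an equal-share haplotype-richness decomposition of each
    population's genetic contribution into within-population diversity and
    between-population distinctiveness components, overall or stratified by
    evolutionary clade. Includes a deterministic synthetic-alignment
    generator with exactly specified haplotype incidence for validation and
    teaching.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    seqinr,
    stats,
    utils
Suggests:
    ape,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
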