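Package: clonedecay
Title: Mutation Accumulation and Fitness Analysis in Clonal Hybrid Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for testing clonal-decay (Muller's ratchet) predictions in
    sexual-asexual hybrid complexes such as Cobitis loaches. Provides a
    forward-time simulator of a three-species complex with diploid and
    triploid gynogenetic clones carrying planted private mutations and
    loss-of-heterozygosity events; SNP classification into intraspecific,
    fixed interspecific and private asexual categories with codon masking and
    synonymity annotation; Nei-Gojobori pathway dN/dS with Jukes-Cantor
    correction and a simulated-hybrid null; Kimura two-parameter mtDNA
    distances; site-frequency and clone-sharing spectra; per-individual
    heterozygosity, LOH and private-SNP accounting with constrained quadratic
    fits; amino-acid radicality scoring from PAM100/BLOSUM90; group-comparison
    statistics (binomial likelihood-ratio, permutation, contingency,
    correlation, variance and Kolmogorov-Smirnov permutation tests); and
    fitness-proxy phenotype indices (condition factor, somatic indices,
    fecundity, growth back-calculation).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    vcfR,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
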