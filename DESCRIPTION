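Package: mutspectra
Title: Mutation Spectra from Polarized Population Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers germline mutation spectra from population variant data in
    any diploid species. Builds an ancestral genome in reference coordinates
    from MAF alignment blocks, polarizes biallelic SNVs against it, counts
    strand-collapsed K-mer single-nucleotide mutation spectra and sequential
    dinucleotide mutation (SDM) spectra per sample, normalizes them by
    ancestral K-mer targets followed by median-of-ratios sample factors, and
    provides downstream analyses: principal component analysis, derived-allele-
    frequency binned mutation-type fractions (pulse analysis), per-type
    chi-square enrichment tests between populations, and rank-1 nonnegative
    matrix factorization with cosine matching against an SBS signature
    catalogue. A synthetic-data module generates truth-tracked genomes, VCFs
    and MAF fixtures, and a subcommand CLI wires the stages into a pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    vcfR,
    jsonlite,
    yaml,
    optparse,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
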