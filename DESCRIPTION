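Package: scaffinv
Title: Mate-Pair Scaffolding and Population Inversion Analysis for Circular Microbial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Closes draft microbial genome assemblies with mate-pair libraries and
    detects genomic inversions segregating within a not-quite-clonal cell population.
    Provides a seeded simulator for circular chromosomes carrying inverted-repeat-flanked
    inversion loci at specified population frequencies, an exact unique short-read mapper,
    accumulation of the contig-pair orientation-count (From::To) table, greedy scaffold
    closure into a circular chromosome with gap estimation, discordant-pair inversion
    calling with Wilson confidence intervals on per-locus population frequencies, and
    genome summary statistics (GC content, coding fraction, gene-category percentages).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    stats,
    utils
Suggests:
    BiocGenerics,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
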