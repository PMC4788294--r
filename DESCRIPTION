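Package: lohmapper
Title: Mapping and Classification of Mitotic Recombination Events from SNP-Microarray LOH Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for high-resolution mapping of mitotic
    recombination in hybrid yeast diploids assayed with allele-specific
    two-channel SNP microarrays. Normalizes per-probe hybridization ratios,
    calls per-marker zygosity and copy states, segments chromosomes into
    loss-of-heterozygosity (LOH) runs, pairs red/white sister sectors into
    four-chromatid allele counts, classifies crossover-associated gene
    conversion tracts (3:1, 4:0, hybrid, complex) and their inferred lesion
    origin (single- versus double-sister-chromatid breaks), measures
    conversion-tract lengths, and tests recombination breakpoints for
    association with genomic element classes via window-based chi-square
    enrichment with false-discovery-rate correction. A seeded simulator
    generates diploid genomes, sectored colonies and sub-cultured isolates
    with known ground truth so every stage is testable without array data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
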