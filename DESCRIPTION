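Package: kaspanel
Title: SNP Filtering, KASP Marker Design, Core Collections and DNA
    Fingerprints for Variety Identification
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: A pipeline for building SNP-based variety-identification
    systems from multi-sample VCF genotypes and a reference genome, as
    used for germplasm panels of the edible mushroom Grifola frondosa.
    Implements GATK-style hard filtering and high-quality SNP screening,
    flank-conservation and flank-uniqueness filters, lightweight variant
    annotation (genomic region and coding effect, substitution spectrum),
    per-locus diversity statistics including polymorphic information
    content (PIC), allele-sharing distances, neighbor-joining trees and
    genotype PCA, core-collection selection by maximizing
    entry-to-nearest-entry distance, KASP (Kompetitive Allele-Specific
    PCR) assay design with FAM/VIC-tailed allele-specific primers under
    nearest-neighbor melting-temperature constraints, greedy set-cover
    selection of a minimal fully-discriminating core marker set with its
    saturation curve, and DNA fingerprint tables. Includes a
    Balding-Nichols population simulator emitting standard VCF/FASTA/GFF3
    fixtures so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    Biostrings,
    VariantAnnotation,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    ape,
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
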