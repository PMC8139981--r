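Package: bathymet
Title: Gene Catalogs, Functional Structure and Genome Abundance for
    Deep-Ocean Metagenomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for gene-centric and genome-centric analysis of
    bathypelagic (deep-ocean) shotgun metagenomes. Builds non-redundant
    gene catalogs by greedy nucleotide-identity clustering with
    short-sequence coverage control, integrates catalogs against a
    reference to partition exclusive, mixed and sample-specific genes,
    quantifies functional community structure from rarefied abundance
    tables (Bray-Curtis, NMDS, PERMANOVA variance partitioning),
    profiles energy-metabolism marker genes normalized by the recA
    single-copy gene as a per-cell copy proxy, scores genome bins for
    KEGG-module completeness, taxonomic novelty and metabolic traits,
    and estimates genome abundance across samples by competitive read
    recruitment expressed as reads per genomic kilobase and sample
    gigabase (RPKG). Ships a synthetic-community simulator with full
    ground truth (cluster membership, planted lifestyle effects,
    per-cell marker copy numbers, read origins) so every stage of the
    pipeline can be validated against known answers.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    Rcpp,
    S4Vectors,
    jsonlite,
    rtracklayer,
    stats,
    utils,
    vegan
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
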