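Package: allokin
Title: Tracing the Diploid Ancestry of Allotetraploid Subgenomes with
    Array SNP Markers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to identify the closest wild diploid relatives of the
    component subgenomes of an allotetraploid from SNP array markers and
    genome assemblies. Implements in-silico genotyping of Axiom-style
    71 bp probe sets against assemblies with a mismatch-bounded ungapped
    placement search, subgenome-dissected calling for polyploids,
    concordance checks between in-silico and array calls, panel merging
    with polymorphism/MAF/missingness filtering, identity-by-state
    similarity and principal coordinates analysis, neighbor-joining
    trees with bootstrap support and sister-group queries, and windowed
    counting of lineage-specific variants from VCF input. A synthetic
    allotetraploid panel generator with full ground truth (parents,
    tree, variants) supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    ape,
    jsonlite,
    stats,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
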