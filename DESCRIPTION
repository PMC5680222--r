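Package: emqtl
Title: Genome-Wide Expression-Methylation QTL Discovery, Biclustering and
    Annotation Enrichment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for expression-methylation quantitative trait locus (emQTL)
    analysis in tumor cohorts: a genome-wide Pearson correlation screen between
    CpG methylation beta values and gene expression with Bonferroni discovery
    and independent-cohort validation, hierarchical biclustering of the
    resulting CpG-by-gene significance matrix into cliques with directional
    sub-clusters, hypergeometric and permutation enrichment of CpG sets against
    chromatin-state segmentations, transcription-factor ChIP-seq peaks and
    chromatin-interaction loops, cis (local) CpG-gene pairing, and
    expression-based scoring of lymphocyte infiltration. A synthetic cohort
    generator plants known emQTL cliques with matching annotation tracks so the
    full pipeline can be exercised and benchmarked without access to patient
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    IRanges,
    S4Vectors,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
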