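Package: polysomics
Title: Multi-Layer Post-Transcriptional Analysis of Paired Transcriptome and Translatome Time Courses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for paired total-RNA (transcriptome) and
    polysomal-RNA (translatome) sequencing across an ordered series of age
    groups. Provides count filtering at a library-size-derived CPM threshold,
    TMM/CPM normalization, correlation-based outlier detection, a simplified
    empirical-Bayes batch adjustment, moderated differential expression over
    pairwise age contrasts, regulatory-mode classification of paired
    total/polysome changes into abundance, translation and buffering via
    per-gene analysis of partial variance, alternative-splicing event
    enumeration with percent-spliced-in (PSI) quantification and an empirical
    delta-PSI test, alternative-polyadenylation site grouping with positional
    psi quantification, temporal trajectory clustering with a circular
    self-organizing map and BIC model selection, and hypergeometric
    over-representation plus permutation gene-set enrichment analysis. A
    synthetic-data module generates annotations, transcript abundances and
    paired count matrices with planted, recoverable ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    edgeR,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    fgsea
Suggests:
    jsonlite,
    limma,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
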