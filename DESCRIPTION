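Package: epimem
Title: Assessment of Engineered Epigenetic Memory and Its Specificity
Version: 0.1.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to assess persistence and specificity of CRISPR-dCas9
    epigenome editing from desk-side data: differential promoter methylation
    from array-style beta values with a probe-count promoter rule, persistence
    concordance across timepoints, H3K27ac promoter peak-loss analysis from
    narrowPeak files (top-N selection, naive-overlap reproducibility,
    control-specific peaks, library-size-normalised fold change),
    PAM-constrained mismatch-tolerant off-target enumeration with flank
    expansion and interval intersection, per-CpG methylation calling from
    bisulfite amplicon clone reads, ddCq relative expression, and an
    integrative per-gene off-target triage. A synthetic-data module generates
    toy genomes, annotations, beta matrices, peak sets, bisulfite clones and
    Cq tables with known planted ground truth so the whole pipeline can be
    exercised end to end without any external accession.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
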