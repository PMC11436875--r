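Package: ncmendel
Title: Cell Type-Aware Nomination of Non-Coding Mendelian Disease Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Prioritizes non-coding candidate variants for Mendelian disease
    cohorts by combining pedigree-based inheritance searches (de novo,
    dominant, dominant with incomplete penetrance, homozygous recessive,
    compound heterozygous) with hard population-frequency, conservation and
    call-quality filters and restriction to disease-relevant single-cell ATAC
    peak sets. Aggregates candidates into recurrently hit peaks and genes,
    tests peak enrichment by size-matched region permutation, links peaks to
    genes by accessibility-expression correlation with FDR control and DORC
    scoring, evaluates cluster labelings with homogeneity, completeness,
    V-measure and purity, normalizes predicted accessibility-difference (SAD)
    scores, and tests cis allelic imbalance with an exact two-sided binomial
    test. Ships a fully seeded synthetic-cohort generator with planted truth
    so the entire pipeline is testable without access-restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml,
    vcfR,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
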