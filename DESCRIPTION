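Package: velcall
Title: Variant Enhancer Locus Calling from Paired H3K27ac ChIP-Seq Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Differential active-enhancer analysis for paired tumor/normal
    H3K27ac ChIP-seq cohorts. Classifies peaks into promoters and enhancers
    by TSS distance, quantifies region signal as reads per million mapped
    reads (RPM) with fragment extension, calls per-patient variant enhancer
    loci (VELs) by fold change, merges them across patients and scores
    recurrence with Benjamini-Hochberg-corrected paired t-tests, selects a
    recurrence threshold from the cumulative significant fraction, and
    detects subgroup-specific gain VELs. Includes ROSE-style super-enhancer
    stitching with a slope-1 tangent cutoff, variant super-enhancer locus
    (VSEL) calling, super-enhancer gene recurrence, core-regulatory-circuitry
    degree networks for super-enhancer-associated transcription factors, and
    a seeded negative-binomial simulator of paired cohorts with planted
    variant loci for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    generics,
    stats,
    utils,
    withr,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
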