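Package: smadscan
Title: Strand-Aware Scanning and Design of SMAD Composite DNA Motifs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the grammar of SMAD composite DNA motifs: two SMAD
    binding elements separated by a short spacer and bound by two SMAD MH1
    domains in a defined relative orientation. Provides strand-aware exact
    occurrence detection for the canonical SMAD binding elements (SBE,
    pGC-SBE, npGC-SBE, pSBE, 5GC), binding-mode classification
    (face-to-face, face-to-back, back-to-back), a BMP/TGF-beta
    responsiveness predicate, screening of ChIP-seq-like peak regions for
    composite-positive regions, spacer (linker) base-composition profiling
    with per-position information content, functional genomic-region
    assignment with abundance-normalized enrichment, Hill-equation fitting
    of fraction-bound titrations under parameter constraints, a synthetic
    luciferase reporter insert generator with predicted responsiveness
    labels, and seed-reproducible synthetic data generators (planted-motif
    peak sets, enriched linker samples, noisy binding curves) for
    benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    methods,
    minpack.lm,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
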