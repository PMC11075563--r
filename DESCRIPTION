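Package: woodpop
Title: Population-Genomic Summaries, Coalescent Simulation and Synteny
    Assignment for Avian Resequencing Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the downstream population-genomic analyses of a
    small resequencing panel against a de novo genome assembly:
    depth-percentile variant filtering of VCFs, diversity estimators
    (segregating sites, per-site Watterson's theta, nucleotide
    diversity), the folded site-frequency-spectrum flattening transform,
    mitogenome alignment statistics (haplotype diversity, p-distance),
    genotype PCA and identity-by-state hierarchical clustering, and
    alignment-based synteny chromosome assignment. A built-in Hudson
    coalescent simulator with constant-size, exponential-growth and
    two-deme demographies generates synthetic VCFs, mitogenome
    alignments and whole-genome alignment coordinate tables with known
    truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    vcfR,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
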