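Package: hybridcross
Title: Diagnostic Markers, Hybrid Classification and Siring Asymmetry for
    Two-Species Hybrid Zones
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for identifying first-generation hybrids between two
    diverged species from small panels of diagnostic nuclear markers and a
    maternally inherited mitochondrial marker. Implements diagnostic-site
    discovery from parental haplotype panels, per-locus population-genetic
    screens (Tajima's D, the Hudson-Kaplan four-gamete test), two hybrid
    indices (a diagnostic-allele index and a maximum-likelihood index with
    profile-likelihood confidence intervals), exact genotype probabilities
    for F1, backcross and F2 pedigree classes with strict maternal mtDNA
    inheritance, an exact two-sided binomial test of siring asymmetry,
    AIC/Akaike-weight ranking of isolation-with-migration model fits with
    demographic rescaling, and seeded simulators for Mendelian crosses and
    two-population isolation-with-migration coalescent sequence data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
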