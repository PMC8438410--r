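Package: ssrcore
Title: SSR Diversity, Molecular Identity Cards and Core Collection
    Extraction for Germplasm Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing codominant SSR (microsatellite) genotype
    matrices of germplasm collections: per-locus diversity statistics (Na,
    Ne, Ho, He, Nei's gene diversity, Shannon index, PIC), allele-sharing
    distances and UPGMA dendrograms, single-character molecular identity
    cards with greedy PIC-ordered selection of a minimal discriminating
    marker set, and stepwise-clustering extraction of core collections with
    random pseudo-core benchmarking. Includes a seeded generator of
    synthetic SSR populations (Balding-Nichols subpopulation structure,
    inbreeding, missing bands) and a packaged reference panel of 164
    Akebia trifoliata accessions typed at 11 SSR markers.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: jsonlite, stats, utils
Suggests: ape, testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
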