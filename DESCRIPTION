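Package: triplo4
Title: Fourth-Chromosome Trisomy Genetics for Drosophila Stocks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Exact cross calculus, forward stock simulation, and
    experimental-design tools for trisomy of the small fourth chromosome of
    Drosophila melanogaster. Models meiosis in triplo-4 flies as a paired
    bivalent plus an unpaired univalent (with optional Sturtevant-style
    preferential pairing and segregation biases), computes exact progeny-class
    distributions for arbitrary crosses with a genotype-to-phenotype rules
    engine covering Minute haploinsufficiency, recessive and dominant markers,
    deficiencies and balancer lethality, simulates closed laboratory stocks
    forward in time under spontaneous nondisjunction and viability selection,
    and fits segregation-distortion parameters from progeny counts by maximum
    likelihood. Includes the RpS3A[57g] tester-based diagnosis of trisomic
    parents and power calculations for designing disomic-stock recovery
    crosses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
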