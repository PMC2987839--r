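Package: mutlab
Title: Fluctuation Analysis, Mutation Spectra, and Polymerase Processivity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantitative toolkit for spontaneous-mutagenesis studies in
    budding yeast. Estimates spontaneous mutation rates and confidence
    limits from Luria-Delbruck fluctuation assays (method of the median,
    Ma-Sandri-Sarkar maximum likelihood, and the P0 method), compares
    mutation spectra with a Monte Carlo Pearson chi-squared homogeneity
    test on 2xN tables, computes per-class error rates from lacZ
    forward-mutation fidelity assays, converts gel-lane band intensities
    into per-position termination probabilities for processive DNA
    synthesis and 3'-to-5' excision, and generates synthetic data with
    the statistical structure each analysis assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: stats, utils, graphics
Suggests: testthat (>= 3.0.0), withr, jsonlite, optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
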