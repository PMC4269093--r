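Package: wfdrift
Title: Global Spectral Solution of the Wright-Fisher Random Drift Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for random genetic drift of two alleles at a single diploid
    locus. Implements the global solution of the Kolmogorov forward
    (Fokker-Planck) equation for the Wright-Fisher diffusion as a Gegenbauer
    polynomial spectral series plus explicit Dirac point masses at the absorbing
    boundaries, together with the exact discrete Wright-Fisher Markov chain.
    Derived quantities include fixation, loss and coexistence probabilities,
    absorption-time moments, n-th frequency moments and heterozygosity, with a
    small command-line interface for tabulated output.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    pracma,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
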