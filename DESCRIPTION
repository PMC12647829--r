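Package: grclayer
Title: Spiking Network Model of the Cerebellar Granular Layer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generative three-dimensional reconstruction and conductance-based
    leaky integrate-and-fire simulation of the cerebellar granular layer
    microcircuit (mossy fibers/glomeruli, granule cells, Golgi cells) with
    tunable feedforward and feedback inhibition. Includes a dichotomized-
    Gaussian generator of spatially correlated binary mossy-fiber activity
    patterns, sensory stimulation protocols, rate-based response analysis
    (dF/F analog, response probability, multisensory categorization), a
    single-layer perceptron decoder for pattern-separation assays, and
    population coding metrics (sparseness, coding-space expansion,
    population correlation).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
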