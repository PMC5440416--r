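Package: cpannr
Title: Counter-Propagation Neural Networks for QSAR Modelling and Read-Across
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Training, prediction and validation of counter-propagation
    artificial neural networks (CPANN), a Kohonen self-organizing map
    augmented with a supervised output (Grossberg) layer, for quantitative
    structure-activity modelling of toxicity endpoints.  Provides descriptor
    standardization with reusable normalization factors, leave-one-out,
    leave-many-out, repeated leave-many-out and Y-scrambling validation, an
    applicability domain based on Euclidean distance to the central neuron,
    top-maps, descriptor level plots and response surfaces,
    neuron-to-neuron Euclidean and continuous-Tanimoto similarity maps, and
    a read-across workflow that predicts a compound's endpoint from the
    experimental values of structural analogues found on the same or
    neighbouring map neurons.  Models, datasets and reports round-trip
    through plain-text files, and a command-line interface exposes the full
    pipeline for scripted use.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, grDevices, graphics, utils, tools
Suggests: testthat (>= 3.0.0), ChemmineR, jsonlite, withr, knitr, rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
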