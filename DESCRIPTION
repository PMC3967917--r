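Package: brainnull
Title: Generative Null Models and Multiscale Diagnostics for Brain Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A battery of thirteen synthetic network models (non-embedded
    and spatially embedded, static and growing) for use as null models in
    the statistical inference of anatomical brain network structure,
    together with a multiscale diagnostics suite (degree distribution,
    assortativity, hierarchy, topological Rentian scaling, box-counting
    fractal dimension, modularity, path metrics), a nine-characteristic
    difference metric for model-to-data comparison, and derivative-free
    fitting of model parameters to a target diagnostics panel. Includes a
    synthetic "pseudo-brain" fixture generator with bilateral 3-D
    coordinates, plain-text graph and coordinate readers/writers, and a
    command-line front-end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
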