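Package: ecoleash
Title: Evolutionary Dynamics of Cooperation and Host Control in the Microbiome
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates the coevolution of cooperation between a host and the
    members of one niche of its microbiome, using replicator dynamics on
    discretized trait distributions. Hosts evolve investment in cooperation
    and in a control (enforcement) mechanism that preferentially benefits
    more-cooperative symbionts; symbionts evolve cooperation under
    within-host competition across multiple symbiont generations per host
    generation, with immigration from an environmental pool. Includes an
    extension in which symbionts can decouple cooperation from the trait the
    host monitors (escape from control), an individual-based variant with an
    influx of costly pathogens, and a parameter-sweep driver that classifies
    evolutionary outcomes across relatedness and benefit-to-cost gradients.
License: MIT + file LICENSE
Depends: R (>= 4.0)
Imports: methods, stats, utils, jsonlite, yaml
Encoding: UTF-8
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'cli.R'
    'ecoleash-package.R'
    'engine.R'
    'escape.R'
    'ibm.R'
    'io.R'
    'modelCore.R'
    'params.R'
    'populations.R'
    'sweeps.R'
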