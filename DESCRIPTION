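Package: periaxon
Title: Double-Cable Myelinated Axon Model with Peri-Axonal Potassium Accumulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates thin myelinated brain axons as a double-cable
    (axolemma + myelin) compartment model with explicit peri-axonal
    potassium dynamics, under extracellular high-frequency stimulation
    from a monopolar point source. Tracks potassium released through
    nodal and juxtaparanodal channels into the nanometre-scale
    peri-axonal space, its clearance by Fickian diffusion and the Na/K
    pump, and the resulting dynamic potassium reversal potential.
    Reproduces intermittent depolarization block of single axons and
    desynchronized firing across an axon bundle, with induction-ratio
    and synchronization-ratio metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    deSolve
Config/testthat/edition: 3
RoxygenNote: 7.3.3
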