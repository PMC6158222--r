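Package: neuroscaffold
Title: Domain-Agnostic Meta-Model, Morphology Interpreters and a Reference
    Simulation Engine for Neuroscience Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A headless middleware core for neuroscience modelling tools. It
    provides a domain-agnostic meta-model (types, variables, values) with
    single inheritance and composition, path-based addressing and validation;
    canonical JSON serialization of models and projects; model interpreters
    for SWC neuronal morphologies, Wavefront OBJ meshes and a small network
    dialect; an instantiation engine that expands models into addressable
    instance trees with capability injection and lazy (on-demand) resolution
    of imported types; a reference leaky integrate-and-fire simulator with an
    experiment lifecycle (parameter sweeps, watched state variables, CSV
    export); and deterministic synthetic-fixture generators with a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
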