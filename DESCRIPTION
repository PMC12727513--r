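Package: rsk
Title: Catalytic Motif Scaffolding and De Novo Enzyme Design Metrics
Version: 0.1.0
Authors@R: person("rsk", "maintainers", email = "rsk@example.org",
    role = c("aut", "cre"))
Description: Tools for scaffolding catalytic amino-acid arrays into de novo
    protein backbones and for evaluating the resulting enzyme designs.
    Builds artificial motif libraries by rotamer inversion (functional
    groups fixed in space, backbone solved from the chi angles), selects
    backbone-compatible rotamers from a backbone-dependent rotamer library,
    places ideal helical fragments on the inverted-rotamer frames and
    enumerates clash-free fragment assemblies ranked by rotamer probability
    and fragment abundance. Provides binding-pocket enforcement geometry
    (entry-channel placeholder helix, flat-bottom guiding potential with
    analytic gradients, alpha-carbon burial and ligand-clash metrics), a
    deterministic skeleton of the iterative sequence-design/relax/predict
    refinement loop with pluggable stage adapters, and a design-evaluation
    suite: motif RMSDs with symmetric-sidechain handling, spatial
    aggregation propensity, core contact density, a stability regression,
    ensemble flexibility metrics, SAXS shape descriptors, and enzyme
    kinetics analysis (Michaelis-Menten and two-pKa fits, rate
    acceleration, kinetic-resolution selectivity relations).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
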