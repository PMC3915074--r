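Package: simdex
Title: Indexing and Description of Biomolecular Simulation Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for describing, indexing and sharing biomolecular
    simulation data. Provides controlled-vocabulary dictionaries (force
    fields, QM methods, basis sets, thermostats, ...) loaded from CSV with
    cross-dictionary links and prefix search; a logical model of virtual
    experiments decomposed into process groups, processes and tasks with
    method parameter sets and molecular-system composition; parsers for a
    documented set of simulation file dialects (topology, MD output, QM
    output); flattening of experiments into attribute-value-unit triplets
    with derived annotations and conjunctive queries; a catalogue of common
    data elements with a survey-score recommendation rule; XML and HTML
    experiment serialization plus relational DDL generation; descriptors
    for derived analysis datasets (dimensions, variables, provenance,
    currency); and a deterministic synthetic fixture generator so the full
    pipeline is testable without real simulation data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    xml2
Suggests:
    DBI,
    RSQLite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
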