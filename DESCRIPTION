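Package: cwldag
Title: Execute Common Workflow Language Pipelines as Task Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A lightweight, self-contained execution engine for pipelines
    written in a defined subset of the Common Workflow Language (CWL) v1.0.
    Workflow descriptors are loaded and validated, each run request (a job
    file with a unique run identifier, workflow path and output folder) is
    translated into a directed acyclic task graph with synthetic dispatcher
    and cleanup endpoints, and the graph is executed by a dependency-gated
    scheduler with a configurable pool of concurrent workers. Supports
    pausing and resuming runs, restarting individual steps or whole
    subgraphs, crash recovery from a persisted run-state store, staging of
    input files into isolated working directories, CWL v1.0 command-line
    binding, glob/stdout output collection, and atomic delivery of declared
    outputs to the run's output folder. Includes generators for synthetic
    test workflows, among them a five-step pipeline shaped like a ChIP-Seq
    analysis (align, sort, index, peak calling, coverage) built from stub
    text-transform commands.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    yaml,
    jsonlite,
    digest,
    parallel,
    tools,
    utils,
    stats
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
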