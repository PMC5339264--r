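Package: dockscreen
Title: Chunked Docking-Based Virtual Screening Engine
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale engine for docking-based virtual screening of
    molecular libraries. Reads multi-record SDF (MDL V2000) files with a
    record-boundary-aware chunked reader, pipes chunks of molecules to an
    external docking executable over standard input/output with configurable
    parallelism and per-chunk retries, checkpoints scored poses as part
    files, and selects the top-N hits by collecting lightweight ID/score
    pairs and sorting them serially. Ships a deterministic mock docking
    backend so the whole pipeline is testable without docking software, a
    synthetic SDF library generator, and weak-scaling-efficiency and speedup
    metrics including estimation from aggregate benchmark figures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    parallel,
    utils
Suggests:
    ChemmineR,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
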