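Package: benchmarkmeta
Title: Validation and Tooling for the BENCHMARK Connectomics Imaging Metadata Standard
Version: 1.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A reference implementation of the BENCHMARK v1.1 Image and
    Experimental Metadata Standard for electron-microscopy and X-ray
    microtomography connectomics datasets. Provides a machine-readable
    registry of the standard's 18 metadata classes and enumerations, a
    rules engine that validates metadata bundles against the standard's
    structural and cross-entity constraints (required fields, closed
    enumerations, hierarchical subset rules for creators, licenses and
    identifiers, coordinate-frame consistency, persistent-identifier
    syntax), canonical JSON serialization with lossless round-trip,
    compliance inspection of the four sanctioned volumetric image
    container layouts (OME-Zarr v2, Neuroglancer precomputed, N5 and
    cloud-volume), a deterministic fixture generator for bundles,
    targeted rule mutants and on-disk container stores, and an in-memory
    faceted catalog over validated bundles.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
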