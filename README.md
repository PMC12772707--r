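# benchmarkmeta

Tooling for the **BENCHMARK v1.1 Image and Experimental Metadata Standard**
for electron-microscopy (EM) and X-ray microtomography (XRM/XNH)
connectomics datasets.

Petascale volumetric neuroimaging datasets — the raw material of
connectomes — are produced by a growing number of labs, each with its own
ad-hoc metadata. The BENCHMARK standard makes such datasets FAIR by fixing
a typed model of 18 metadata classes arranged hierarchically
(`Project → Collection → Experiment → Channel`, with each experiment bound
to exactly one `CoordinateFrame` carrying per-axis `[min, max]` extents and
an anisotropy-aware voxel resolution), closed enumerations for restricted
fields, and a short list of sanctioned chunked container formats for the
voxels themselves (OME-Zarr v2, Neuroglancer precomputed, N5,
cloud-volume).

This package is a reference implementation for archive maintainers,
data-standards developers and dataset producers:

* **schema registry** — the full machine-readable standard
  (`load_registry()`, `describe_class()`, `list_enum_members()`), the
  single source of truth everything else introspects;
* **validator** — a rules engine (`validate_bundle()`) producing structured
  reports with stable rule codes covering required fields, closed enums,
  cardinalities, dangling references, degenerate extents,
  channel/experiment coordinate-frame agreement, the hierarchical subset
  rules for creators/licenses/identifiers, and persistent-identifier syntax
  (ORCID/ISNI via the ISO 7064 mod 11-2 check character, DOI, ROR, RRID,
  …);
* **canonical JSON I/O** — `read_bundle()` / `write_bundle()` with
  lossless round-trip and byte-stable canonical form;
* **container compliance** — `detect_format()`, `parse_container()`,
  `cross_check_channel()`: metadata-only inspection of the four sanctioned
  volumetric layouts, cross-checked against channel and frame metadata;
* **fixture generator** — `generate_bundle()`, `mutate_bundle()`,
  `generate_container()`: deterministic, platform-stable synthesis of valid
  bundles, one-defect mutants for every error-severity rule, and tiny
  on-disk container stores — no external download needed to test the whole
  standard;
* **catalog** — `index_bundles()` / `query_catalog()`: an in-memory faceted
  index (species, modality, year, contributor, region, public) over
  validated bundles.

A thin command-line front end ships at `inst/cli/benchmark`
(`describe`, `enums`, `validate`, `convert`, `generate`, `generate-volume`,
`inspect-volume`, `query`).

## Worked example

```r
library(benchmarkmeta)
reg <- load_registry()

# a deterministic two-collection project exercising all 18 classes
b <- generate_bundle(reg, fixture_recipe(seed = 11, n_collections = 2))
b
#> <benchmark_bundle> standard 1.1
#>   Project          1
#>   Collection       2
#>   Experiment       2
#>   Channel          2
#>   CoordinateFrame  2

validate_bundle(reg, b)
#> <validation report> 0 error(s), 0 warning(s); VALID

# inject a license outside the project's license set
mut <- mutate_bundle(reg, b, "SUBSET_LICENSE")
validate_bundle(reg, mut$bundle)
#> <validation report> 1 error(s), 0 warning(s); INVALID
#>   [e] SUBSET_LICENSE  project/proj-11/collections/proj-11-coll-1:
#>       Collection licenses element 'CC0-1.0' is not among the parent
#>       Project's licenses

# a tiny on-disk precomputed store, parsed back from its metadata files
d <- generate_container("NEUROGLANCER_PRECOMPUTED", "uint8",
                        c(64, 64, 32), c(4, 4, 40), seed = 11,
                        out_tree = file.path(tempdir(), "store"))
d
#> <container> NEUROGLANCER_PRECOMPUTED uint8 - 1 scale(s)
#>    64x64x32 voxels @ 4,4,40 nm

query_catalog(index_bundles(reg, list(b)), list(species = "Drosophila"))
#>   project_id                                         title    species ...
#> 1    proj-11 Dense connectome of the Drosophila optic lobe drosophila ...
```

The validation report lists one entry per finding: a rule code from the
closed registry (`validation_rules()`), the entity path of the defect, and
a severity — a bundle is valid iff it has zero error-severity findings.
The container descriptor shows what the store's own metadata declares
(dtype, per-scale extent and resolution); `cross_check_channel()` compares
it against the channel's `DataType` and the frame's `VoxelSize`/extent.

## Documentation

The methods vignette (`vignettes/benchmark-metadata.Rmd`) describes the
metadata model, the severity policy, the canonical serialization choices,
what the fixture generator does and does not emulate, and known
limitations. Function-level documentation is in the roxygen comments.
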