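---
title: "Validating connectomics imaging metadata with benchmarkmeta"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating connectomics imaging metadata with benchmarkmeta}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(benchmarkmeta)
```

## The metadata model

Electron-microscopy (EM) and X-ray microtomography (XRM/XNH) connectomics
datasets are petascale volumetric images from which neuron- and synapse-level
wiring diagrams are derived. The BENCHMARK v1.1 Image and Experimental
Metadata Standard describes such datasets with 18 typed classes arranged in a
strict hierarchy:

* a **Project** is the highest-level object (title, contributors, species,
  taxonomy, licenses, funding, publications, modalities);
* a project owns one or more **Collections** (a set of experiments, e.g. from
  one publication);
* a collection owns one or more **Experiments**, each bound to exactly one
  **CoordinateFrame** — the per-axis `[min, max]` extent of a 3-D volume plus
  its voxel resolution (an **ImageResolution**: per-axis and not assumed
  isotropic);
* an experiment owns one or more **Channels** — single 3-D volumes carrying
  exactly one data type (raw imagery, segmentation, or annotation) and
  referencing the experiment's frame.

Supporting classes (Contributor, License, Funding, Publication, Link,
Taxonomy, BrainLocation, DataLocation, the light- and electron-microscopy
acquisition blocks, ImageOrientation, Landmark) hang off these levels. The
package ships this model as a machine-readable registry
(`load_registry()`); validation, serialization, the fixture generator and
the CLI all introspect the registry rather than hard-coding structure, so
the registry JSON is the single source of truth.

### Authored field lists

The standard prints complete field tables only for some classes
(Contributor, License, Funding, Project, Taxonomy, CoordinateFrame,
Publication, Link). For the rest it states a count and a prose description.
Counts alone are not validatable, so the registry freezes a named field list
for each such class, matching the stated count and description; each class
descriptor carries a `provenance` note saying whether its list is printed or
authored. Three stated counts exceed the printed rows, and the registry
resolves each with a documented placeholder: `Project.AdditionalInformation`
(36th field), `Contributor.ContributorRole` (11th; the class description
names role specification), and `License.RightsIdentifier` /
`License.RightsIdentifierDOI` plus `Publication.PMCID`, which the class
descriptions name outright. One printed datatype is treated as an erratum:
`Taxonomy.GenBankCommonName` is stored as `String`, since its own printed
description ("a simplified and recognizable name") contradicts the printed
`Integer` type.

Enumerations whose member lists the standard does not print (`Species`,
`DataType`, `GeneralModality`, `ImagingModalityGeneral`, `VoxelUnit`) ship
as documented provisional lists so the registry stays closed; `Species`
seeds the organisms the standard names as exemplars, and
`ImagingModalitySpecific` carries the 21 printed technique abbreviations.
`DataType` enumerates storage scalar types (`uint8` … `float64`) so that a
channel's single data type can be compared directly against a container's
declared voxel dtype. The `GRDI` member is stored as printed, with `GRID`
accepted as an alias and normalized on read.

## Validation rules and severity policy

`validate_bundle()` is a rules engine: every finding is a report entry with
a stable rule code, an entity path and a severity — never an exception,
because untrusted archive submissions must not abort ingest. Errors are
violations of the standard's hard constraints: missing required fields,
values outside closed enumerations or declared types, empty
must-be-at-least-one relationships (`CARDINALITY`), dangling ID references,
degenerate frame extents (min not < max, non-positive resolution), channel
frames differing from their experiment's (`COORD_MISMATCH`), and the
hierarchical subset rules: a child's creators, licenses and identifiers must
each be a subset of its parent's. Warnings cover quarantined unknown
fields, malformed persistent identifiers, and the standard's
recommended-but-not-required practices (shared reference-frame labels
within a project).

Two subset-rule details are design choices. Element equality is
identifier-first (a contributor's `NameIdentifier`, a license's
`RightsIdentifier`) with a case-folded, whitespace-trimmed name fallback;
identifiers in scope are ASCII, so full Unicode normal-form folding is not
applied. And because `Project` prints a single `Creator` field and no
`Identifiers` field, the project-level comparison sets are defined as: its
creator set is `Creator` plus every `Contributor` entry whose `Creator` flag
is true, and its identifier set is the `UniqueIdentifier` URI plus the
project `ID`. Without this, any collection crediting a second project
member would violate the rule the standard plainly intends to permit.

Persistent identifiers are checked syntactically only — offline and
deterministic, no DOI/ORCID/ROR resolution. ORCID and ISNI use the ISO 7064
mod 11-2 check character (recomputed, not pattern-matched); DOI, ROR, RRID,
PMID, arXiv, ISBN and GRID-form identifiers use their published syntax.

## Canonical serialization

The standard names no serialization; JSON is this package's choice
(the standard's prototype service is RESTful, and JSON is the interchange
lingua franca). One document is one bundle: the five hierarchical classes
live in per-class tables keyed by ID, supporting classes stay inline in
their owners, and inline children found inside reference fields are hoisted
to ID references on read, so nested and referenced forms parse identically.
Canonical form fixes everything a byte-comparison needs: UTF-8, table keys
sorted in C collation, entity keys in registry declaration order (matching
the standard's table presentation, not alphabetical), dates ISO-8601 with
bare years normalized to `YYYY`, and numbers in R's default shortest
decimal form (up to 15 significant digits, which round-trips every value
the generator emits). Writing is a fixpoint — `write(read(write(b)))` is
byte-identical to `write(b)` — and this is property-tested across seeds.

## Container compliance

The standard sanctions four container layouts for raw imagery: OME-Zarr
(Zarr specification v2), Neuroglancer precomputed, N5, and cloud-volume.
Compliance here is metadata-only: the standard governs format choice, not
pixel values, so chunks are never decoded; the presence of at least one
chunk object is probed at warning level. Detection is by sentinel files
(`.zattrs` with `multiscales`; `info` with `scales`; `attributes.json` with
an `n5` key); ambiguity or absence fails with a specific code, and a
`zarr.json` root (Zarr v3) is rejected with a versioned message since the
standard pins v2. Cloud-volume reads and writes the precomputed layout, so
such stores are detected as precomputed with a provenance note rather than
given a fifth parser. The standard does not pin an OME-Zarr metadata
version within Zarr v2; v0.4 `multiscales` is assumed and documented here.

`cross_check_channel()` ties a store to its metadata: dtype must equal the
channel's `DataType`; scale-0 resolution must equal the frame's `VoxelSize`
within relative tolerance `1e-6` after unit conversion (nm/µm/mm); and the
scale-0 extent must equal the frame extent in voxels, `(max − min) /
resolution` per axis, rounded to the nearest integer with a half-voxel
tolerance (floating-point spans like `6400/4` must not fail on
representation error).

## The fixture generator

`generate_bundle()` emits the study conditions every suite runs under: a
project hierarchy mirroring an archive data model (project → collections →
experiments with their own frames → channels), exercising all 18 classes —
contributors with valid generated ORCIDs, CC-BY-4.0 licensing, funding,
publications, taxonomy with real NCBI taxonomy IDs for the exemplar
species, EM acquisition blocks on raw channels and one correlative
light-microscopy block with orientation and landmarks. Voxel resolutions
are drawn from realistic EM values (4×4×40 nm, 8 nm isotropic, 4×4×30 nm)
and frame extents from 16–128 voxels per axis, desk-scale stand-ins for
petascale stores. Child creators, licenses and identifiers are built as
subsets of their parents', so generated bundles validate with zero errors:
the generator and validator are mutual oracles, and `mutate_bundle()`
completes the pair by injecting exactly one defect per error-severity rule
code at a known path.

Randomness comes from a package-internal Lehmer (minstd) generator, not
R's RNG: output is byte-identical across platforms, independent of locale
and clock (dates are fixed epoch-derived values), and generation never
perturbs the session RNG state. The generator aims at structural realism
only — field-value distributions of real archives (text length, author
counts, modality mixes) are not modeled, so passing suites demonstrate rule
coverage and determinism, not robustness to the full messiness of
hand-written metadata.

## Problem sizes and suites

The shipped suites use sizes chosen to exercise every rule while staying
interactive: the mutation suite validates one mutant per catalog rule on a
2×2×2-hierarchy bundle plus 50 seeded single- and double-sized valid
bundles; round-trip integrity runs over 100 seeded bundles; the container
suite covers the three distinct on-disk layouts at 64×64×32 voxels; catalog
equivalence compares faceted queries against a brute-force scan over
8-bundle fixture sets. `scripts/acceptance.R` recomputes all of these from
scratch at run time and writes the resulting counts as JSON.

## Known limitations

* Field names for classes without printed tables are this package's
  authored choices; interchange with another implementation requires
  agreeing on the registry JSON (which is shipped precisely so it can be
  exchanged).
* BrainLocation consistency with an established reference frame is
  recommended by the standard but not precisely defined; only the weaker
  mixed-label warning is implemented.
* The catalog indexes only facets derivable from printed fields; specimen
  age and sex are motivated as queries by the standard's prose but exist in
  no printed class, so they are not facets.
* Identifier checks are syntactic; a well-formed but nonexistent ORCID
  passes.
* No YAML/CSV dialects, no HTTP service, no pixel-data validation, and no
  provenance/immutable-log tracking — the standard flags compression
  standardization and provenance as future work.
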