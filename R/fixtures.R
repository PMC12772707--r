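# Deterministic generator of valid bundles, targeted rule mutants, and tiny
# on-disk container stores. Structural realism only: the hierarchy, classes
# and constraints of real archive projects are exercised, not the statistics
# of real field values.
#
# Randomness comes from a package-internal Lehmer generator (minstd), not
# from R's RNG: outputs are byte-identical across platforms and generation
# never touches the session RNG state. Dates are fixed epoch-derived values,
# never the clock.

lcg_new <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1L, !is.na(seed))
  env <- new.env(parent = emptyenv())
  env$state <- (abs(trunc(seed)) %% 2147483646) + 1
  env
}

lcg_next <- function(env) {
  env$state <- (16807 * env$state) %% 2147483647
  env$state
}

rint <- function(env, lo, hi) lo + (lcg_next(env) %% (hi - lo + 1))
pick <- function(env, xs) xs[[rint(env, 1L, length(xs))]]

.words <- c("axon", "dendrite", "soma", "synapse", "glia", "cortex",
            "lamina", "medulla", "lobula", "calyx", "mushroom", "antennal",
            "optic", "ventral", "nerve", "cord", "neuropil", "tract",
            "column", "layer", "bouton", "spine", "myelin", "node")

.person_names <- c("Ada Carver", "Ben Ochoa", "Cleo Mbeki", "Dana Vogel",
                   "Eli Haruki", "Fay Lindqvist", "Gus Moreau", "Ivy Okafor")

words <- function(env, n) {
  paste(vapply(seq_len(n), function(i) pick(env, .words), ""), collapse = " ")
}

# Species exemplars with their NCBI taxonomy IDs and common names.
.species_table <- list(
  list(species = "Drosophila", taxid = 7227L,
       name = "Drosophila melanogaster", common = "fruit fly"),
  list(species = "Mus musculus", taxid = 10090L,
       name = "Mus musculus", common = "house mouse"),
  list(species = "C. elegans", taxid = 6239L,
       name = "Caenorhabditis elegans", common = "roundworm"),
  list(species = "Homo sapiens", taxid = 9606L,
       name = "Homo sapiens", common = "human")
)

#' Create a fixture recipe
#'
#' @param seed Integer seed; the same recipe always yields byte-identical
#'   output.
#' @param n_collections,n_experiments_per_collection,n_channels_per_experiment
#'   Positive counts shaping the project hierarchy.
#' @param violation_kind Optional rule code; when set,
#'   \code{\link{generate_bundle}} output is passed through
#'   \code{\link{mutate_bundle}}.
#' @return A \code{benchmark_recipe} list.
#' @export
fixture_recipe <- function(seed, n_collections = 1L,
                           n_experiments_per_collection = 1L,
                           n_channels_per_experiment = 1L,
                           violation_kind = NULL) {
  counts <- c(n_collections, n_experiments_per_collection,
              n_channels_per_experiment)
  if (any(!is.finite(counts)) || any(counts < 1) ||
      any(counts != trunc(counts))) {
    stop("counts must be positive integers", call. = FALSE)
  }
  structure(list(seed = seed, n_collections = as.integer(n_collections),
                 n_experiments_per_collection =
                   as.integer(n_experiments_per_collection),
                 n_channels_per_experiment =
                   as.integer(n_channels_per_experiment),
                 violation_kind = violation_kind),
            class = "benchmark_recipe")
}

#' Generate a deterministic, standard-conformant metadata bundle
#'
#' Emits a project hierarchy mirroring the archive data model: one project
#' owning collections, each owning experiments with their own coordinate
#' frames, each owning channels. Every one of the 18 registered classes is
#' exercised at least once; child creators, licenses and identifiers are
#' constructed as subsets of their parents', so the output validates with
#' zero errors (the generator and the validator are mutual oracles).
#'
#' @inheritParams describe_class
#' @param recipe A \code{benchmark_recipe} from \code{\link{fixture_recipe}},
#'   or a bare seed.
#' @return A \code{benchmark_bundle}.
#' @export
generate_bundle <- function(registry, recipe) {
  if (is.numeric(recipe)) recipe <- fixture_recipe(recipe)
  stopifnot(inherits(recipe, "benchmark_recipe"))
  rng <- lcg_new(recipe$seed)
  sp <- pick(rng, .species_table)
  year <- 2015L + rint(rng, 0L, 9L)
  pid <- sprintf("proj-%d", recipe$seed)
  doi <- sprintf("https://doi.org/10.60533/%s", pid)

  contributors <- lapply(seq_len(3L), function(i) {
    nm <- .person_names[[rint(rng, 1L, length(.person_names))]]
    orcid_digits <- paste(vapply(1:15, function(j)
      as.character(rint(rng, 0L, 9L)), ""), collapse = "")
    orcid <- paste0(orcid_digits, iso7064_mod11_2_check(orcid_digits))
    build_entity(registry, "Contributor", list(
      Name = nm,
      Email = paste0(gsub(" ", ".", tolower(nm)), "@example.org"),
      Creator = i <= 2L,
      ContributorType = if (i == 1L) "ProjectLeader" else "Researcher",
      NameType = "Personal",
      NameIdentifier = paste(substring(orcid, c(1, 5, 9, 13), c(4, 8, 12, 16)),
                             collapse = "-"),
      NameIdentifierScheme = "ORCID",
      Affiliation = "Example Institute of Connectomics",
      AffiliationIdentifier = "01aaaaa11",
      AffiliationIdentifierScheme = "ROR",
      ContributorRole = if (i == 1L) "conceived the project" else "analysis"
    ))
  })

  cc_by <- build_entity(registry, "License", list(
    Rights = "Creative Commons Attribution 4.0 International",
    RightsURI = "https://creativecommons.org/licenses/by/4.0/",
    RightsIdentifier = "CC-BY-4.0",
    RightsIdentifierDOI = "https://doi.org/10.70533/cc-by-4.0"
  ))
  funding <- build_entity(registry, "Funding", list(
    FundingEntity = "National Connectomics Fund",
    AwardIdentifier = sprintf("NCF-%04d", rint(rng, 1000L, 9999L)),
    FundingReferenceIdentifier = "01bbbbb22",
    FundingReferenceIdentifierType = "ROR",
    AwardTitle = paste("Mapping the", words(rng, 2))
  ))
  publication <- build_entity(registry, "Publication", list(
    Name = paste("A dense reconstruction of the", words(rng, 2)),
    URI = doi,
    Authors = vapply(contributors, function(ct) ct$fields$Name[[1L]], ""),
    RelatedIdentifier = sprintf("10.60533/%s-paper", pid),
    RelatedIdentifierType = "DOI",
    RelationType = "IsDocumentedBy",
    Citation = sprintf("Example et al. (%d)", year),
    PMCID = sprintf("PMC%07d", rint(rng, 1L, 9999999L))
  ))
  taxonomy <- build_entity(registry, "Taxonomy", list(
    TaxonomyID = sp$taxid, CurrentName = sp$name,
    GenBankCommonName = sp$common, NCBIBlastName = sp$common,
    Rank = "species", GeneticCode = "Standard",
    MitochondrialGeneticCode = "Invertebrate Mitochondrial",
    CommonName = sp$common
  ))
  portal <- build_entity(registry, "Link", list(
    Name = "archive portal", URI = sprintf("https://example.org/%s", pid)))

  tables <- list(Project = list(), Collection = list(), Experiment = list(),
                 Channel = list(), CoordinateFrame = list())
  all_channel_ids <- character(0)
  all_experiment_ids <- character(0)
  collection_ids <- character(0)
  region <- pick(rng, c("mushroom body", "optic lobe", "antennal lobe",
                        "ventral nerve cord"))

  for (ci in seq_len(recipe$n_collections)) {
    cid <- sprintf("%s-coll-%d", pid, ci)
    experiment_ids <- character(0)
    for (ei in seq_len(recipe$n_experiments_per_collection)) {
      eid <- sprintf("%s-exp-%d-%d", pid, ci, ei)
      fid <- sprintf("%s-cf-%d-%d", pid, ci, ei)
      res <- pick(rng, list(c(4, 4, 40), c(8, 8, 8), c(4, 4, 30)))
      vox <- c(pick(rng, c(32, 64, 128)), pick(rng, c(32, 64, 128)),
               pick(rng, c(16, 32, 64)))
      frame <- build_entity(registry, "CoordinateFrame", list(
        `@id` = fid,
        Xs = c(0, vox[[1L]] * res[[1L]]),
        Ys = c(0, vox[[2L]] * res[[2L]]),
        Zs = c(0, vox[[3L]] * res[[3L]]),
        VoxelSize = list(X = res[[1L]], Y = res[[2L]], Z = res[[3L]],
                         Unit = "nm")
      ))
      tables$CoordinateFrame[[fid]] <- frame

      channel_ids <- character(0)
      for (ki in seq_len(recipe$n_channels_per_experiment)) {
        chid <- sprintf("%s-chan-%d-%d-%d", pid, ci, ei, ki)
        raw <- ki == 1L
        ch_fields <- list(
          Name = paste(if (raw) "raw" else "segmentation", words(rng, 1)),
          Description = paste("A", words(rng, 3), "volume"),
          ID = chid,
          Creator = list(contributors[[1L]]),
          License = list(cc_by),
          Identifiers = doi,
          ChannelType = if (raw) "RawData" else "Segmentation",
          DataType = if (raw) "uint8" else "uint64",
          ImageResolution = list(X = res[[1L]], Y = res[[2L]], Z = res[[3L]],
                                 Unit = "nm"),
          CoordinateFrame = fid,
          StorageFormat = pick(rng, c("OME_ZARR_V2",
                                      "NEUROGLANCER_PRECOMPUTED", "N5")),
          StorageURI = sprintf("s3://example/%s", chid),
          DataLocation = list(
            Origin = c(0, 0, 0),
            Extent = vox * res,
            ImageResolution = list(X = res[[1L]], Y = res[[2L]],
                                   Z = res[[3L]], Unit = "nm"),
            CoordinateFrame = fid,
            StorageURI = sprintf("s3://example/%s", chid)),
          DateCreated = sprintf("%d-0%d-01", year, rint(rng, 1L, 9L)),
          Version = "1.0"
        )
        first_channel <- ci == 1L && ei == 1L && ki == 1L
        if (first_channel) {
          # correlative light-microscopy block so the LM import classes are
          # always exercised, even in a single-channel bundle
          ch_fields$LightMicroscopySpecific <- list(
            MicroscopeType = "light-sheet",
            MicroscopeManufacturerAndModel = "ExampleLight XL",
            ObjectiveMagnification = 20, ObjectiveNA = 1.0,
            ExcitationWavelength = 488, EmissionWavelength = 525,
            ImageOrientation = list(XAngle = 0, YAngle = 0, ZAngle = 90,
                                    Convention = "xyz-extrinsic"),
            Landmarks = list(list(Name = region, Position = c(1, 2, 3))),
            AcquisitionDate = sprintf("%d-02-01", year))
        }
        if (raw) {
          ch_fields$ElectronMicroscopySpecific <- list(
            MicroscopeMake = "ExampleScope", MicroscopeModel = "ES-9000",
            MicroscopeRRID = "RRID:SCR_999999",
            ImagingTechnique = "FIB_SEM",
            AcceleratingVoltage = 1.5, BeamCurrent = 0.8,
            DwellTime = 1.2, SectionThickness = res[[3L]],
            Magnification = 8000, Detector = "in-column SE",
            TiltScheme = "none", AcquisitionDate = sprintf("%d-01-15", year),
            Operator = contributors[[2L]]$fields$Name[[1L]],
            Notes = "fixture store")
        }
        tables$Channel[[chid]] <- build_entity(registry, "Channel", ch_fields)
        channel_ids <- c(channel_ids, chid)
      }

      tables$Experiment[[eid]] <- build_entity(registry, "Experiment", list(
        Name = paste("experiment", words(rng, 2)),
        Description = paste("Imaging of the", region),
        ID = eid,
        Creator = list(contributors[[1L]], contributors[[2L]]),
        License = list(cc_by),
        Identifiers = doi,
        Protocol = sprintf("dx.doi.org/10.17504/protocols.io.%s",
                           words(rng, 1)),
        CoordinateFrame = fid,
        Channels = channel_ids,
        DateCreated = sprintf("%d-03-01", year),
        Keywords = c("connectomics", sp$species),
        BrainLocation = list(Position = c(10, 20, 30),
                             Orientation = c(0, 0, 0),
                             RegionName = region,
                             ReferenceFrame = "specimen-frame-1")
      ))
      experiment_ids <- c(experiment_ids, eid)
      all_channel_ids <- c(all_channel_ids, channel_ids)
    }

    tables$Collection[[cid]] <- build_entity(registry, "Collection", list(
      Name = paste("collection", words(rng, 2)),
      Description = paste("Experiments on the", region),
      ID = cid,
      Creator = list(contributors[[1L]], contributors[[2L]]),
      Contributor = list(contributors[[2L]]),
      License = list(cc_by),
      Identifiers = doi,
      Publications = list(publication),
      Links = list(portal),
      Experiments = experiment_ids,
      DateCreated = sprintf("%d-04-01", year),
      Keywords = c("connectomics"),
      Version = "1.0",
      PointOfContact = list(contributors[[1L]])
    ))
    collection_ids <- c(collection_ids, cid)
    all_experiment_ids <- c(all_experiment_ids, experiment_ids)
  }

  tables$Project[[pid]] <- build_entity(registry, "Project", list(
    Title = paste("Dense connectome of the", sp$species, region),
    ShortTitle = sprintf("%s %s", sp$species, region),
    ID = pid,
    Keywords = c("connectomics", "electron microscopy", sp$species),
    Description = paste0("Volumetric EM imaging of ", sp$name, " ", region,
                         " with dense segmentation."),
    Public = TRUE,
    Year = as.character(year),
    Publications = list(publication),
    Links = list(portal),
    License = list(cc_by),
    Creator = contributors[[1L]],
    PointOfContact = list(contributors[[1L]]),
    Contributor = contributors,
    Acknowledgements = "We thank the working group.",
    Funding = list(funding),
    Species = sp$species,
    Taxonomy = list(taxonomy),
    DateCreated = sprintf("%d-01-01", year),
    Channels = all_channel_ids,
    Experiments = all_experiment_ids,
    Collections = collection_ids,
    Media = sprintf("https://example.org/%s/flythrough.mp4", pid),
    DataTypes = c("uint8", "uint64"),
    Image = list(portal),
    TechnicalInfo = "Aligned and contrast-normalized volume.",
    Methods = "https://protocols.example.org/em-prep",
    SocialMedia = "https://example.org/lab",
    GeneralModality = "Connectivity",
    ImagingModalities = "EM",
    ImagingModalitySpecific = "FIB_SEM",
    ImageLocations = list(list(Position = c(10, 20, 30),
                               Orientation = c(0, 0, 0),
                               RegionName = region,
                               ReferenceFrame = "specimen-frame-1")),
    Version = "1.0",
    UniqueIdentifier = list(Name = "dataset DOI", URI = doi),
    DateModified = sprintf("%d-06-01", year)
  ))

  bundle <- structure(
    list(standard_version = registry$version,
         projects = names(tables$Project),
         entities = tables,
         extras = list()),
    class = "benchmark_bundle")
  if (!is.null(recipe$violation_kind)) {
    bundle <- mutate_bundle(registry, bundle, recipe$violation_kind,
                            seed = recipe$seed)$bundle
  }
  bundle
}

#' Rule codes covered by the mutation catalog
#'
#' One targeted mutant exists for every error-severity structural rule.
#' @return Character vector of mutable rule codes.
#' @export
mutation_catalog <- function() {
  c("REQ_MISSING", "TYPE_MISMATCH", "ENUM_INVALID", "CARDINALITY",
    "SUBSET_CREATORS", "SUBSET_LICENSE", "SUBSET_IDENTIFIERS",
    "COORD_MISMATCH", "EXTENT_DEGENERATE", "REF_DANGLING")
}

#' Inject exactly one targeted defect into a valid bundle
#'
#' @inheritParams describe_class
#' @param bundle A valid \code{benchmark_bundle}.
#' @param rule_code One of \code{\link{mutation_catalog}}.
#' @param seed Seed choosing the defect site when several are available.
#' @return List with \code{bundle} (the mutant) and \code{path} (the entity
#'   path at which the named violation is expected to fire).
#' @export
mutate_bundle <- function(registry, bundle, rule_code, seed = 1) {
  stopifnot(inherits(bundle, "benchmark_bundle"))
  if (!rule_code %in% mutation_catalog()) {
    stop("rule code '", rule_code, "' is not in the mutation catalog: ",
         paste(mutation_catalog(), collapse = ", "), call. = FALSE)
  }
  rng <- lcg_new(seed)
  pid <- sort_c(names(bundle$entities$Project))[[1L]]
  proj <- bundle$entities$Project[[pid]]
  ppath <- paste0("project/", pid)
  cid <- pick(rng, sort_c(as.character(proj$fields$Collections)))
  coll <- bundle$entities$Collection[[cid]]
  cpath <- paste0(ppath, "/collections/", cid)
  eid <- pick(rng, sort_c(as.character(coll$fields$Experiments)))
  expm <- bundle$entities$Experiment[[eid]]
  epath <- paste0(cpath, "/experiments/", eid)
  chid <- pick(rng, sort_c(as.character(expm$fields$Channels)))
  chpath <- paste0(epath, "/channels/", chid)

  path <- switch(rule_code,
    REQ_MISSING = {
      bundle$entities$Project[[pid]]$fields$Title <- NULL
      ppath
    },
    TYPE_MISMATCH = {
      bundle$entities$Project[[pid]]$fields$Public <-
        raw_value("maybe", "Project.Public: expected Boolean")
      ppath
    },
    ENUM_INVALID = {
      bundle$entities$Channel[[chid]]$fields$ChannelType <- "Janitor"
      chpath
    },
    CARDINALITY = {
      bundle$entities$Collection[[cid]]$fields$Experiments <- character(0)
      cpath
    },
    SUBSET_CREATORS = {
      foreign <- build_entity(registry, "Contributor",
                              list(Name = "Zed Outsider"))
      bundle$entities$Experiment[[eid]]$fields$Creator <-
        c(bundle$entities$Experiment[[eid]]$fields$Creator, list(foreign))
      epath
    },
    SUBSET_LICENSE = {
      cc0 <- build_entity(registry, "License", list(
        Rights = "CC0 1.0 Universal",
        RightsURI = "https://creativecommons.org/publicdomain/zero/1.0/",
        RightsIdentifier = "CC0-1.0"))
      bundle$entities$Collection[[cid]]$fields$License <-
        c(bundle$entities$Collection[[cid]]$fields$License, list(cc0))
      cpath
    },
    SUBSET_IDENTIFIERS = {
      bundle$entities$Collection[[cid]]$fields$Identifiers <-
        c(bundle$entities$Collection[[cid]]$fields$Identifiers,
          "https://example.org/not-in-project")
      cpath
    },
    COORD_MISMATCH = {
      fid <- as.character(expm$fields$CoordinateFrame)[[1L]]
      alt <- paste0(fid, "-alt")
      altframe <- bundle$entities$CoordinateFrame[[fid]]
      altframe$id <- alt
      bundle$entities$CoordinateFrame[[alt]] <- altframe
      bundle$entities$Channel[[chid]]$fields$CoordinateFrame <- alt
      chpath
    },
    EXTENT_DEGENERATE = {
      fid <- as.character(expm$fields$CoordinateFrame)[[1L]]
      bundle$entities$CoordinateFrame[[fid]]$fields$Xs <- c(5, 5)
      paste0("coordinate_frame/", fid)
    },
    REF_DANGLING = {
      ids <- as.character(expm$fields$Channels)
      ids[[1L]] <- paste0(ids[[1L]], "-missing")
      bundle$entities$Experiment[[eid]]$fields$Channels <- ids
      epath
    })
  list(bundle = bundle, path = path, rule_code = rule_code)
}

#' Write a tiny on-disk container store fixture
#'
#' Writes the sentinel and metadata files (and one placeholder chunk object)
#' of the requested container format such that \code{\link{detect_format}}
#' and \code{\link{parse_container}} recover the declared values exactly.
#' Desk-scale only: per-axis extent is capped at 128 voxels.
#'
#' @param format_kind \code{"OME_ZARR_V2"}, \code{"NEUROGLANCER_PRECOMPUTED"},
#'   \code{"CLOUDVOLUME"} or \code{"N5"}.
#' @param dtype Voxel dtype name (\code{uint8} ... \code{float64}).
#' @param extent_triple Extent in voxels, (x, y, z), each within 1..128.
#' @param resolution_triple Voxel resolution (x, y, z) in nanometers.
#' @param seed Seed for the placeholder chunk payload.
#' @param out_tree Directory to create the store in.
#' @param num_scales Number of multiscale levels (downsampled by 2 in x, y).
#' @return The \code{benchmark_container} descriptor re-parsed from disk.
#' @export
generate_container <- function(format_kind, dtype, extent_triple,
                               resolution_triple, seed, out_tree,
                               num_scales = 1L) {
  format_kind <- match.arg(format_kind, .format_kinds)
  if (!dtype %in% .supported_dtypes) {
    stop("unsupported dtype '", dtype, "'; supported: ",
         paste(.supported_dtypes, collapse = ", "), call. = FALSE)
  }
  extent <- as.numeric(extent_triple)
  res <- as.numeric(resolution_triple)
  stopifnot(length(extent) == 3L, length(res) == 3L)
  if (any(extent < 1) || any(extent > 128)) {
    stop("extent per axis must be within 1..128 (desk-scale fixtures)",
         call. = FALSE)
  }
  dir.create(out_tree, recursive = TRUE, showWarnings = FALSE)
  rng <- lcg_new(seed)
  payload <- paste(vapply(1:8, function(i) as.character(rint(rng, 0L, 9L)),
                          ""), collapse = "")
  scale_extent <- function(s) {
    pmax(c(ceiling(extent[[1L]] / 2^s), ceiling(extent[[2L]] / 2^s),
           extent[[3L]]), 1)
  }
  scale_res <- function(s) c(res[[1L]] * 2^s, res[[2L]] * 2^s, res[[3L]])
  wj <- function(rel, obj) {
    p <- file.path(out_tree, rel)
    dir.create(dirname(p), recursive = TRUE, showWarnings = FALSE)
    writeLines(as.character(jsonlite::toJSON(obj, auto_unbox = TRUE,
                                             digits = NA, pretty = 2)), p)
  }
  kind <- sub("^CLOUDVOLUME$", "NEUROGLANCER_PRECOMPUTED", format_kind)
  if (kind == "OME_ZARR_V2") {
    inv <- names(.zarr_dtypes)[match(dtype, .zarr_dtypes)]
    wj(".zgroup", list(zarr_format = 2L))
    wj(".zattrs", list(multiscales = list(list(
      version = "0.4", name = "volume",
      axes = list(list(name = "z", type = "space", unit = "nanometer"),
                  list(name = "y", type = "space", unit = "nanometer"),
                  list(name = "x", type = "space", unit = "nanometer")),
      datasets = lapply(seq_len(num_scales) - 1L, function(s) list(
        path = as.character(s),
        coordinateTransformations = list(list(
          type = "scale",
          scale = rev(scale_res(s))))))))))
    for (s in seq_len(num_scales) - 1L) {
      ex <- scale_extent(s)
      wj(file.path(s, ".zarray"), list(
        zarr_format = 2L, shape = rev(ex), chunks = rev(pmin(ex, 64)),
        dtype = inv, compressor = NULL, fill_value = 0L, filters = NULL,
        order = "C"))
      chunk <- file.path(out_tree, s, "0.0.0")
      writeLines(payload, chunk)
    }
  } else if (kind == "NEUROGLANCER_PRECOMPUTED") {
    wj("info", list(
      type = "image", data_type = dtype, num_channels = 1L,
      scales = lapply(seq_len(num_scales) - 1L, function(s) {
        ex <- scale_extent(s)
        rs <- scale_res(s)
        list(key = paste(rs, collapse = "_"), resolution = rs, size = ex,
             chunk_sizes = list(pmin(ex, 64)), encoding = "raw",
             voxel_offset = c(0L, 0L, 0L))
      })))
    if (format_kind == "CLOUDVOLUME") {
      wj("provenance", list(description = "cloud-volume fixture store",
                            owners = list(), processing = list(),
                            sources = list()))
    }
    for (s in seq_len(num_scales) - 1L) {
      rs <- scale_res(s)
      ex <- scale_extent(s)
      dir.create(file.path(out_tree, paste(rs, collapse = "_")),
                 showWarnings = FALSE)
      writeLines(payload, file.path(out_tree, paste(rs, collapse = "_"),
                                    sprintf("0-%d_0-%d_0-%d", ex[[1L]],
                                            ex[[2L]], ex[[3L]])))
    }
  } else {
    wj("attributes.json", list(n5 = "2.5.1"))
    for (s in seq_len(num_scales) - 1L) {
      ex <- scale_extent(s)
      wj(file.path(paste0("s", s), "attributes.json"), list(
        dimensions = ex, blockSize = pmin(ex, 64), dataType = dtype,
        resolution = scale_res(s), units = list("nm", "nm", "nm")))
      writeLines(payload, file.path(out_tree, paste0("s", s), "0"))
    }
  }
  parse_container(out_tree, detect_format(out_tree))
}
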