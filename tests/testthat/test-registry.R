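test_that("registry holds the standard's eighteen classes and resolves each", {
  expect_s3_class(reg, "benchmark_registry")
  expect_identical(reg$version, "1.1")
  expect_length(reg$classes, 18L)
  for (cn in names(reg$classes)) {
    expect_identical(describe_class(reg, cn)$name, cn)
  }
})

test_that("per-class field counts match the standard's stated counts", {
  counts <- c(Project = 36L, Collection = 18L, Experiment = 20L,
              Channel = 19L, CoordinateFrame = 4L, BrainLocation = 4L,
              DataLocation = 5L, LightMicroscopySpecific = 28L,
              ElectronMicroscopySpecific = 14L, Taxonomy = 8L,
              ImageOrientation = 4L, Landmark = 2L, Contributor = 11L,
              License = 4L, Funding = 5L, Publication = 8L, Link = 2L,
              ImageResolution = 4L)
  for (cn in names(counts)) {
    expect_identical(length(describe_class(reg, cn)$fields),
                     unname(counts[[cn]]),
                     info = cn)
  }
})

test_that("printed field lists are reproduced in order", {
  expect_identical(names(describe_class(reg, "Link")$fields),
                   c("Name", "URI"))
  expect_identical(names(describe_class(reg, "CoordinateFrame")$fields),
                   c("Xs", "Ys", "Zs", "VoxelSize"))
  expect_identical(names(describe_class(reg, "Taxonomy")$fields)[1:3],
                   c("TaxonomyID", "CurrentName", "GenBankCommonName"))
  expect_identical(names(describe_class(reg, "License")$fields)[1:2],
                   c("Rights", "RightsURI"))
})

test_that("required flags follow the standard's Required column", {
  proj <- describe_class(reg, "Project")$fields
  req <- names(Filter(function(f) f$required, proj))
  expect_setequal(req, c("Title", "ShortTitle", "ID", "Keywords",
                         "Description", "Public", "Year", "License",
                         "Creator", "PointOfContact", "Contributor",
                         "Species", "DateCreated", "Channels", "Experiments",
                         "Collections", "GeneralModality",
                         "ImagingModalities", "Version"))
  contrib <- describe_class(reg, "Contributor")$fields
  expect_true(contrib$Name$required)
  expect_false(contrib$Email$required)
  tax <- describe_class(reg, "Taxonomy")$fields
  expect_true(tax$TaxonomyID$required)
  expect_false(any(vapply(tax[-1L], `[[`, TRUE, "required")))
})

test_that("enum member lists are reproduced exactly and in order", {
  expect_identical(list_enum_members(reg, "RelationType"),
                   c("IsCitedBy", "IsDocumentedBy"))
  expect_identical(list_enum_members(reg, "NameIdentifierScheme"),
                   c("GRDI", "ISNI", "ORCID", "ROR", "RRID", "Other"))
  expect_identical(list_enum_members(reg, "RelatedIdentifierType"),
                   c("arXiv", "DOI", "ISBN", "PMID", "Other"))
  expect_length(list_enum_members(reg, "ContributorType"), 10L)
  expect_true("ProjectLeader" %in% list_enum_members(reg, "ContributorType"))
  expect_identical(list_enum_members(reg, "ChannelType"),
                   c("RawData", "Segmentation", "Annotation"))
  expect_length(list_enum_members(reg, "ImagingModalitySpecific"), 21L)
})

test_that("membership is case-sensitive and the empty string never matches", {
  expect_true(enum_is_member(reg, "ContributorType", "Researcher"))
  expect_false(enum_is_member(reg, "ContributorType", "researcher"))
  for (en in names(reg$enums)) {
    expect_false(enum_is_member(reg, en, ""))
  }
})

test_that("unknown class and enum names raise not-found errors naming valid options", {
  expect_error(describe_class(reg, "NoSuchClass"), "unknown class.*Project")
  expect_error(list_enum_members(reg, "NoSuchEnum"), "unknown enum")
})

test_that("every field datatype resolves within the registry", {
  for (cd in reg$classes) {
    for (f in cd$fields) {
      dt <- benchmarkmeta:::parse_datatype(f$datatype, reg)
      expect_true(dt$kind %in% c("primitive", "enum", "class"),
                  info = paste(cd$name, f$name))
    }
  }
})
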