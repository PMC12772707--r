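test_that("required-field and enum rules fire at entity level; minimal Link is valid", {
  p <- build_entity(reg, "Project", list(ID = "p1"))
  rep <- validate_entity(reg, p)
  expect_true("REQ_MISSING" %in% error_codes(rep))
  expect_true(any(grepl("Title", vapply(rep$violations, `[[`, "", "message"))))
  expect_true(validate_entity(reg, minimal_link())$valid)
})

test_that("report invariants hold: valid iff zero errors; counts consistent", {
  rep <- validate_bundle(reg, small_bundle(3))
  expect_identical(rep$valid, rep$counts[["error"]] == 0L)
  mut <- mutate_bundle(reg, small_bundle(3), "REQ_MISSING")$bundle
  rep2 <- validate_bundle(reg, mut)
  expect_false(rep2$valid)
  expect_identical(rep2$counts[["error"]],
                   sum(vapply(rep2$violations, `[[`, "", "severity") == "error"))
})

test_that("every rule code a report carries is drawn from the closed registry", {
  rules <- validation_rules()
  for (code in mutation_catalog()) {
    expect_true(code %in% rules$code)
    expect_identical(rules$severity[rules$code == code], "error")
  }
})

test_that("subset constraint: empty child passes, non-subset elements each violate", {
  cc_by <- build_entity(reg, "License", list(
    Rights = "CC BY 4.0", RightsURI = "u", RightsIdentifier = "CC-BY-4.0"))
  cc0 <- build_entity(reg, "License", list(
    Rights = "CC0", RightsURI = "u0", RightsIdentifier = "CC0-1.0"))
  parent <- build_entity(reg, "Project", list(ID = "p", License = list(cc_by)))
  same <- build_entity(reg, "Collection", list(ID = "c", License = list(cc_by)))
  expect_length(check_subset_constraint(reg, same, parent, "licenses"), 0L)
  other <- build_entity(reg, "Collection", list(ID = "c", License = list(cc0)))
  vs <- check_subset_constraint(reg, other, parent, "licenses")
  expect_length(vs, 1L)
  expect_identical(vs[[1L]]$rule_code, "SUBSET_LICENSE")
  none <- build_entity(reg, "Collection", list(ID = "c"))
  expect_length(check_subset_constraint(reg, none, parent, "licenses"), 0L)
})

test_that("subset equality is identifier-first with case-folded name fallback", {
  a <- build_entity(reg, "Contributor", list(Name = "Jane  Doe"))
  b <- build_entity(reg, "Contributor", list(Name = "JANE  DOE "))
  parent <- build_entity(reg, "Experiment", list(ID = "e", Creator = list(a)))
  child <- build_entity(reg, "Channel", list(ID = "c", Creator = list(b)))
  expect_length(check_subset_constraint(reg, child, parent, "creators"), 0L)
  # same name but differing identifiers are different people
  a2 <- build_entity(reg, "Contributor",
                     list(Name = "Jane Doe", NameIdentifier = "X1"))
  b2 <- build_entity(reg, "Contributor",
                     list(Name = "Jane Doe", NameIdentifier = "X2"))
  parent2 <- build_entity(reg, "Experiment", list(ID = "e", Creator = list(a2)))
  child2 <- build_entity(reg, "Channel", list(ID = "c", Creator = list(b2)))
  expect_length(check_subset_constraint(reg, child2, parent2, "creators"), 1L)
})

test_that("coordinate consistency compares frames by ID and flags mismatches", {
  mk_ch <- function(id, fid) build_entity(reg, "Channel", list(
    ID = id, CoordinateFrame = fid))
  ex <- build_entity(reg, "Experiment", list(ID = "e", CoordinateFrame = "cf1",
                                             Channels = c("a", "b", "c")))
  chans <- list(a = mk_ch("a", "cf1"), b = mk_ch("b", "cf1"),
                c = mk_ch("c", "cf1"))
  expect_length(check_coordinate_consistency(reg, ex, chans), 0L)
  chans$b <- mk_ch("b", "cf2")
  vs <- check_coordinate_consistency(reg, ex, chans)
  expect_length(vs, 1L)
  expect_identical(vs[[1L]]$rule_code, "COORD_MISMATCH")
  expect_match(vs[[1L]]$entity_path, "channels/b$")
})

test_that("degenerate frame extents are flagged", {
  f <- build_entity(reg, "CoordinateFrame", list(
    `@id` = "cf", Xs = c(5, 5), Ys = c(0, 1), Zs = c(0, 1),
    VoxelSize = list(X = 1, Y = 1, Z = 1, Unit = "nm")))
  rep <- validate_entity(reg, f)
  expect_identical(error_codes(rep), "EXTENT_DEGENERATE")
  g <- build_entity(reg, "ImageResolution",
                    list(X = 0, Y = 4, Z = 40, Unit = "nm"))
  expect_identical(error_codes(validate_entity(reg, g)), "EXTENT_DEGENERATE")
})

test_that("dangling references and empty cardinalities surface in bundle reports", {
  b <- small_bundle(5)
  pid <- names(b$entities$Project)
  b$entities$Project[[pid]]$fields$Collections <- "no-such-collection"
  rep <- validate_bundle(reg, b)
  expect_true("REF_DANGLING" %in% error_codes(rep))
  b2 <- small_bundle(5)
  b2$entities$Project[[pid]]$fields$Collections <- character(0)
  expect_true("CARDINALITY" %in% error_codes(validate_bundle(reg, b2)))
})

test_that("warning-severity findings: unknown fields and malformed identifiers", {
  ct <- build_entity(reg, "Contributor", list(
    Name = "A", NameIdentifier = "0000-0002-1825-0090",
    NameIdentifierScheme = "ORCID", Wig = 1))
  rep <- validate_entity(reg, ct)
  wc <- vapply(rep$violations, `[[`, "", "rule_code")
  expect_setequal(wc, c("ID_SYNTAX", "UNKNOWN_FIELD"))
  expect_true(rep$valid)  # warnings only
})

test_that("validation is deterministic: identical bundle gives byte-identical report", {
  b <- small_bundle(9, 2, 2, 2)
  r1 <- validate_bundle(reg, b)
  r2 <- validate_bundle(reg, b)
  expect_identical(jsonlite::toJSON(r1$violations),
                   jsonlite::toJSON(r2$violations))
})

test_that("adding an optional valid field to a valid bundle never adds an error", {
  b <- small_bundle(4)
  expect_true(validate_bundle(reg, b)$valid)
  pid <- names(b$entities$Project)
  b$entities$Project[[pid]]$fields$TechnicalInfo <- "extra detail"
  b$entities$Project[[pid]]$fields$Acknowledgements <- "thanks"
  cid <- names(b$entities$Collection)[[1L]]
  b$entities$Collection[[cid]]$fields$Version <- "2.0"
  expect_true(validate_bundle(reg, b)$valid)
})

test_that("subset rule is transitive along the full hierarchy in generated bundles", {
  for (s in c(21, 22)) {
    b <- small_bundle(s, 2, 2, 2)
    rep <- validate_bundle(reg, b)
    expect_false(any(grepl("^SUBSET_", error_codes(rep))))
  }
})
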