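test_that("a minimal document parses to one entity per hierarchy level", {
  doc <- list(
    StandardVersion = "1.1",
    Projects = list(p1 = list(ID = "p1", Title = "t", Collections = list("c1"),
                              Experiments = list("e1"), Channels = list("k1"))),
    Collections = list(c1 = list(ID = "c1", Experiments = list("e1"))),
    Experiments = list(e1 = list(ID = "e1", CoordinateFrame = "cf1",
                                 Channels = list("k1"))),
    Channels = list(k1 = list(ID = "k1", CoordinateFrame = "cf1")),
    CoordinateFrames = list(cf1 = list(Xs = list(0, 1), Ys = list(0, 1),
                                       Zs = list(0, 1))))
  b <- read_bundle(reg, doc)
  expect_identical(bundle_size(b), 5L)
  expect_identical(b$projects, "p1")
  expect_identical(b$entities$CoordinateFrame$cf1$id, "cf1")
})

test_that("nested inline children normalize to the same bundle as referenced form", {
  canonical <- write_bundle(reg, small_bundle(1))
  d <- jsonlite::fromJSON(canonical, simplifyVector = FALSE)
  eid <- names(d$Experiments)[[1L]]
  chid <- d$Experiments[[eid]]$Channels[[1L]]
  d$Experiments[[eid]]$Channels <- list(d$Channels[[chid]])
  d$Channels[[chid]] <- NULL
  expect_identical(write_bundle(reg, read_bundle(reg, d)), canonical)
})

test_that("duplicate IDs and non-object documents are parse errors", {
  canonical <- write_bundle(reg, small_bundle(1))
  d <- jsonlite::fromJSON(canonical, simplifyVector = FALSE)
  eid <- names(d$Experiments)[[1L]]
  chid <- d$Experiments[[eid]]$Channels[[1L]]
  d$Experiments[[eid]]$Channels <- list(d$Channels[[chid]])  # now twice
  expect_error(read_bundle(reg, d), "duplicate Channel ID")
  expect_error(read_bundle(reg, "[1, 2, 3]"), "parse error")
})

test_that("unknown top-level keys are quarantined and re-emitted verbatim", {
  doc <- paste0('{"StandardVersion":"1.1","Projects":{},"XCustom":{"a":[1,2]}}')
  b <- read_bundle(reg, doc)
  expect_named(b$extras, "XCustom")
  expect_match(write_bundle(reg, b), '"XCustom"')
})

test_that("canonical serialization is a fixpoint and re-reads structurally equal", {
  for (s in c(2, 8)) {
    b <- small_bundle(s, 2, 1, 2)
    txt <- write_bundle(reg, b)
    b2 <- read_bundle(reg, txt)
    expect_identical(write_bundle(reg, b2), txt)          # write o read fixpoint
    expect_equal(b2$entities, b$entities)                 # read o write identity
    expect_identical(bundle_size(b2), bundle_size(b))
  }
})

test_that("decimal fractions survive the round trip exactly", {
  f <- build_entity(reg, "CoordinateFrame", list(
    `@id` = "cf", Xs = c(0.1, 6400.3), Ys = c(0, 1), Zs = c(0, 1),
    VoxelSize = list(X = 0.1, Y = 4, Z = 40, Unit = "nm")))
  b <- structure(list(standard_version = "1.1", projects = character(0),
                      entities = list(Project = list(), Collection = list(),
                                      Experiment = list(), Channel = list(),
                                      CoordinateFrame = list(cf = f)),
                      extras = list()),
                 class = "benchmark_bundle")
  b2 <- read_bundle(reg, write_bundle(reg, b))
  expect_identical(b2$entities$CoordinateFrame$cf$fields$Xs[[1L]], 0.1)
  expect_identical(b2$entities$CoordinateFrame$cf$fields$VoxelSize$fields$X, 0.1)
})

test_that("writing a bundle holding a type-violating value is a serialization error", {
  b <- small_bundle(1)
  pid <- names(b$entities$Project)
  b$entities$Project[[pid]]$fields$Public <-
    benchmarkmeta:::raw_value("maybe", "Project.Public: expected Boolean")
  expect_error(write_bundle(reg, b), "serialization error")
})
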