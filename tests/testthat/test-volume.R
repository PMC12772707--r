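store <- function(fmt, ..., dir = tempfile("store-")) {
  generate_container(fmt, ..., out_tree = dir)
  dir
}

test_that("sentinel-based detection identifies each sanctioned format exclusively", {
  oz <- store("OME_ZARR_V2", "uint8", c(32, 32, 32), c(4, 4, 40), seed = 1)
  pc <- store("NEUROGLANCER_PRECOMPUTED", "uint8", c(32, 32, 32),
              c(4, 4, 40), seed = 1)
  n5 <- store("N5", "uint8", c(32, 32, 32), c(4, 4, 40), seed = 1)
  cv <- store("CLOUDVOLUME", "uint8", c(32, 32, 32), c(4, 4, 40), seed = 1)
  expect_identical(detect_format(oz)[[1L]], "OME_ZARR_V2")
  expect_identical(detect_format(pc)[[1L]], "NEUROGLANCER_PRECOMPUTED")
  expect_identical(detect_format(n5)[[1L]], "N5")
  k <- detect_format(cv)
  expect_identical(k[[1L]], "NEUROGLANCER_PRECOMPUTED")
  expect_identical(attr(k, "note"), "cloud-volume layout")
})

test_that("empty trees, Zarr v3 stores and ambiguous stores are rejected", {
  empty <- tempfile(); dir.create(empty)
  expect_error(detect_format(empty), "UNRECOGNIZED_FORMAT")
  z3 <- tempfile(); dir.create(z3)
  writeLines('{"zarr_format": 3}', file.path(z3, "zarr.json"))
  expect_error(detect_format(z3), "version 2 of the Zarr specification")
  amb <- store("NEUROGLANCER_PRECOMPUTED", "uint8", c(8, 8, 8), c(4, 4, 40),
               seed = 1)
  writeLines('{"n5": "2.5.1"}', file.path(amb, "attributes.json"))
  expect_error(detect_format(amb), "FORMAT_AMBIGUOUS")
})

test_that("parsers recover the generator's declared values for every format", {
  for (fmt in c("OME_ZARR_V2", "NEUROGLANCER_PRECOMPUTED", "N5")) {
    dir <- tempfile()
    d <- generate_container(fmt, "uint16", c(64, 48, 32), c(8, 8, 30),
                            seed = 2, out_tree = dir)
    expect_identical(d$dtype, "uint16", info = fmt)
    expect_identical(d$num_scales, 1L)
    expect_equal(d$scales[[1L]]$extent, c(64, 48, 32), info = fmt)
    expect_equal(d$scales[[1L]]$resolution, c(8, 8, 30), info = fmt)
    expect_true(d$chunk_present)
  }
})

test_that("multiscale stores report every level with downsampled x/y", {
  dir <- tempfile()
  d <- generate_container("OME_ZARR_V2", "uint8", c(64, 64, 16), c(4, 4, 40),
                          seed = 3, out_tree = dir, num_scales = 2)
  expect_identical(d$num_scales, 2L)
  expect_equal(d$scales[[2L]]$extent, c(32, 32, 16))
  expect_equal(d$scales[[2L]]$resolution, c(8, 8, 40))
})

test_that("missing mandatory container keys are malformed-container errors", {
  dir <- store("NEUROGLANCER_PRECOMPUTED", "uint8", c(8, 8, 8), c(4, 4, 40),
               seed = 1)
  info <- jsonlite::fromJSON(file.path(dir, "info"), simplifyVector = FALSE)
  info$data_type <- NULL
  writeLines(as.character(jsonlite::toJSON(info, auto_unbox = TRUE)),
             file.path(dir, "info"))
  expect_error(parse_container(dir, "NEUROGLANCER_PRECOMPUTED"),
               "CONTAINER_MALFORMED.*data_type")
  dir2 <- store("OME_ZARR_V2", "uint8", c(8, 8, 8), c(4, 4, 40), seed = 1)
  unlink(file.path(dir2, "0", ".zarray"))
  expect_error(parse_container(dir2, "OME_ZARR_V2"), "CONTAINER_MALFORMED")
})

frame_for <- function(extent, res) {
  build_entity(reg, "CoordinateFrame", list(
    `@id` = "cf1",
    Xs = c(0, extent[[1L]] * res[[1L]]), Ys = c(0, extent[[2L]] * res[[2L]]),
    Zs = c(0, extent[[3L]] * res[[3L]]),
    VoxelSize = list(X = res[[1L]], Y = res[[2L]], Z = res[[3L]], Unit = "nm")))
}

chan_for <- function(dtype) {
  build_entity(reg, "Channel", list(
    ID = "ch1", ChannelType = "RawData", DataType = dtype,
    ImageResolution = list(X = 4, Y = 4, Z = 40, Unit = "nm"),
    CoordinateFrame = "cf1"))
}

test_that("cross-check passes when frame extent over resolution matches voxels", {
  # 6400 nm span at 4 nm/voxel = 1600 voxels
  dir <- tempfile()
  d <- generate_container("NEUROGLANCER_PRECOMPUTED", "uint8", c(64, 64, 64),
                          c(4, 4, 40), seed = 1, out_tree = dir)
  vs <- cross_check_channel(reg, chan_for("uint8"),
                            frame_for(c(64, 64, 64), c(4, 4, 40)), d)
  expect_length(vs, 0L)
})

test_that("dtype, resolution and extent mismatches each fire their single rule", {
  dir <- tempfile()
  d <- generate_container("N5", "uint16", c(32, 32, 32), c(4, 4, 40),
                          seed = 1, out_tree = dir)
  cf <- frame_for(c(32, 32, 32), c(4, 4, 40))
  expect_identical(vapply(cross_check_channel(reg, chan_for("uint8"), cf, d),
                          `[[`, "", "rule_code"), "DTYPE_MISMATCH")
  cf_res <- frame_for(c(32, 32, 32), c(4, 4, 30))
  expect_identical(vapply(cross_check_channel(reg, chan_for("uint16"),
                                              cf_res, d),
                          `[[`, "", "rule_code"), "RESOLUTION_MISMATCH")
  cf_ext <- frame_for(c(64, 32, 32), c(4, 4, 40))
  expect_identical(vapply(cross_check_channel(reg, chan_for("uint16"),
                                              cf_ext, d),
                          `[[`, "", "rule_code"), "EXTENT_MISMATCH")
})

test_that("unit conversion aligns micrometer frames with nanometer stores", {
  dir <- tempfile()
  d <- generate_container("NEUROGLANCER_PRECOMPUTED", "uint8", c(10, 10, 10),
                          c(500, 500, 1000), seed = 1, out_tree = dir)
  cf <- build_entity(reg, "CoordinateFrame", list(
    `@id` = "cf1", Xs = c(0, 5), Ys = c(0, 5), Zs = c(0, 10),
    VoxelSize = list(X = 0.5, Y = 0.5, Z = 1, Unit = "um")))
  expect_length(cross_check_channel(reg, chan_for("uint8"), cf, d), 0L)
})

test_that("a store without chunk objects raises the warning-level probe", {
  dir <- store("N5", "uint8", c(8, 8, 8), c(4, 4, 40), seed = 1)
  unlink(file.path(dir, "s0", "0"))
  d <- parse_container(dir, "N5")
  vs <- cross_check_channel(reg, chan_for("uint8"),
                            frame_for(c(8, 8, 8), c(4, 4, 40)), d)
  expect_identical(vapply(vs, `[[`, "", "rule_code"), "CHUNK_MISSING")
  expect_identical(vs[[1L]]$severity, "warning")
})

test_that("generator argument checks: dtype and desk-scale extent cap", {
  expect_error(generate_container("N5", "complex128", c(8, 8, 8),
                                  c(4, 4, 40), 1, tempfile()),
               "unsupported dtype")
  expect_error(generate_container("N5", "uint8", c(512, 8, 8),
                                  c(4, 4, 40), 1, tempfile()),
               "desk-scale")
  d <- generate_container("N5", "uint8", c(1, 1, 1), c(4, 4, 40), 1,
                          tempfile())
  expect_equal(d$scales[[1L]]$extent, c(1, 1, 1))
})
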