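# Compliance inspection of the four sanctioned volumetric container layouts.
# The standard governs the choice of container format, not pixel values, so
# only the small JSON metadata files are read -- chunks are never decoded.

.format_kinds <- c("OME_ZARR_V2", "NEUROGLANCER_PRECOMPUTED", "N5",
                   "CLOUDVOLUME")

volume_error <- function(code, message) {
  stop(structure(
    class = c("benchmark_volume_error", "error", "condition"),
    list(message = paste0(code, ": ", message), call = NULL,
         rule_code = code)))
}

#' Detect which sanctioned container format a store uses
#'
#' Detection is sentinel-based: a root \code{.zattrs} with a
#' \code{multiscales} key (next to \code{.zgroup}) marks OME-Zarr v2; a root
#' \code{info} JSON with a \code{scales} key marks Neuroglancer precomputed
#' (cloud-volume stores, which write that same layout plus a
#' \code{provenance} file, are detected as precomputed with a provenance
#' note); a root \code{attributes.json} with an \code{n5} version key marks
#' N5. A root \code{zarr.json} (Zarr specification v3) is rejected with a
#' versioned message.
#'
#' @param store_tree Path to the store's root directory.
#' @return Format kind string (\code{"OME_ZARR_V2"},
#'   \code{"NEUROGLANCER_PRECOMPUTED"} or \code{"N5"}), with attribute
#'   \code{note} set to \code{"cloud-volume layout"} when a provenance file
#'   marks a cloud-volume store.
#' @export
detect_format <- function(store_tree) {
  if (!dir.exists(store_tree)) {
    volume_error("UNRECOGNIZED_FORMAT",
                 paste0("store '", store_tree, "' is not a readable directory"))
  }
  has <- function(f) file.exists(file.path(store_tree, f))
  read_json_quiet <- function(f) {
    tryCatch(jsonlite::fromJSON(file.path(store_tree, f),
                                simplifyVector = FALSE),
             error = function(e) NULL)
  }
  if (has("zarr.json")) {
    volume_error("UNRECOGNIZED_FORMAT", paste(
      "store uses Zarr specification v3; the standard sanctions version 2",
      "of the Zarr specification (to be updated when appropriate)"))
  }
  matches <- character(0)
  note <- NULL
  if (has(".zattrs")) {
    za <- read_json_quiet(".zattrs")
    if (!is.null(za$multiscales)) matches <- c(matches, "OME_ZARR_V2")
  }
  if (has("info")) {
    info <- read_json_quiet("info")
    if (!is.null(info$scales)) {
      matches <- c(matches, "NEUROGLANCER_PRECOMPUTED")
      if (has("provenance")) note <- "cloud-volume layout"
    }
  }
  if (has("attributes.json")) {
    at <- read_json_quiet("attributes.json")
    if (!is.null(at$n5)) matches <- c(matches, "N5")
  }
  if (length(matches) == 0L) {
    volume_error("UNRECOGNIZED_FORMAT",
                 "no sanctioned container format sentinel found")
  }
  if (length(matches) > 1L) {
    volume_error("FORMAT_AMBIGUOUS", paste(
      "sentinels of multiple formats present:",
      paste(matches, collapse = ", ")))
  }
  structure(matches, note = note)
}

# dtype spellings: numpy-style names <-> zarr v2 typestrings
.zarr_dtypes <- c(`|u1` = "uint8", `<u2` = "uint16", `<u4` = "uint32",
                  `<u8` = "uint64", `|i1` = "int8", `<i2` = "int16",
                  `<i4` = "int32", `<i8` = "int64",
                  `<f4` = "float32", `<f8` = "float64")
.supported_dtypes <- c("uint8", "uint16", "uint32", "uint64",
                       "float32", "float64")

.unit_to_nm <- c(nm = 1, um = 1e3, mm = 1e6,
                 nanometer = 1, micrometer = 1e3, millimeter = 1e6)

malformed <- function(key, why) {
  volume_error("CONTAINER_MALFORMED", paste0(key, ": ", why))
}

need <- function(obj, key, where) {
  if (is.null(obj[[key]])) malformed(paste0(where, ".", key), "mandatory key absent")
  obj[[key]]
}

read_store_json <- function(store_tree, rel) {
  p <- file.path(store_tree, rel)
  if (!file.exists(p)) malformed(rel, "file absent")
  tryCatch(jsonlite::fromJSON(p, simplifyVector = FALSE),
           error = function(e) malformed(rel, conditionMessage(e)))
}

#' Parse a container store's metadata into a descriptor
#'
#' @param store_tree Path to the store's root directory.
#' @param format_kind Format kind from \code{\link{detect_format}} (the
#'   cloud-volume kind parses as precomputed).
#' @return A \code{benchmark_container}: \code{format_kind}, \code{dtype}
#'   (numpy-style name), \code{num_scales}, and \code{scales} -- one entry
#'   per scale with \code{resolution} (x, y, z), \code{unit}, \code{extent}
#'   (x, y, z voxels), \code{chunk} shape, plus \code{chunk_present} for the
#'   warning-level completeness probe on scale 0.
#' @export
parse_container <- function(store_tree, format_kind) {
  kind <- sub("^CLOUDVOLUME$", "NEUROGLANCER_PRECOMPUTED", format_kind[[1L]])
  parsed <- switch(kind,
    OME_ZARR_V2 = parse_ome_zarr(store_tree),
    NEUROGLANCER_PRECOMPUTED = parse_precomputed(store_tree),
    N5 = parse_n5(store_tree),
    volume_error("UNRECOGNIZED_FORMAT",
                 paste0("unknown format kind '", format_kind, "'")))
  structure(c(list(format_kind = format_kind[[1L]]), parsed),
            class = "benchmark_container")
}

num_triple <- function(x, key) {
  v <- suppressWarnings(as.numeric(unlist(x)))
  if (length(v) != 3L || anyNA(v)) malformed(key, "expected 3 numbers")
  if (grepl("size|dimension|shape", key) && any(v <= 0)) {
    malformed(key, "extents must be positive")
  }
  v
}

parse_ome_zarr <- function(store_tree) {
  za <- read_store_json(store_tree, ".zattrs")
  ms <- need(za, "multiscales", ".zattrs")
  if (length(ms) < 1L) malformed(".zattrs.multiscales", "empty")
  ms <- ms[[1L]]
  axes <- need(ms, "axes", ".zattrs.multiscales[0]")
  axis_names <- vapply(axes, function(a) tolower(a$name %||% ""), "")
  perm <- match(c("x", "y", "z"), axis_names)
  if (anyNA(perm)) malformed(".zattrs.multiscales[0].axes",
                             "x, y and z axes must be declared")
  unit <- axes[[perm[[1L]]]]$unit %||% "nanometer"
  datasets <- need(ms, "datasets", ".zattrs.multiscales[0]")
  if (length(datasets) < 1L) malformed(".zattrs.multiscales[0].datasets", "empty")
  dtype <- NULL
  scales <- lapply(seq_along(datasets), function(i) {
    ds <- datasets[[i]]
    where <- sprintf(".zattrs.multiscales[0].datasets[%d]", i - 1L)
    path <- need(ds, "path", where)
    ct <- need(ds, "coordinateTransformations", where)
    sc <- NULL
    for (tr in ct) if (identical(tr$type, "scale")) sc <- tr$scale
    if (is.null(sc)) malformed(paste0(where, ".coordinateTransformations"),
                               "no scale transformation")
    res_axes <- num_triple(sc[perm], paste0(where, ".scale"))
    zarray <- read_store_json(store_tree, file.path(path, ".zarray"))
    shape <- suppressWarnings(as.numeric(unlist(
      need(zarray, "shape", paste0(path, "/.zarray")))))
    chunks <- suppressWarnings(as.numeric(unlist(
      need(zarray, "chunks", paste0(path, "/.zarray")))))
    dt <- need(zarray, "dtype", paste0(path, "/.zarray"))
    mapped <- .zarr_dtypes[[dt]] %||% NULL
    if (is.null(mapped)) malformed(paste0(path, "/.zarray.dtype"),
                                   paste0("unsupported typestring '", dt, "'"))
    if (is.null(dtype)) dtype <<- mapped
    if (length(shape) != length(axis_names)) {
      malformed(paste0(path, "/.zarray.shape"), "rank differs from axes")
    }
    if (any(shape <= 0) || any(chunks <= 0)) {
      malformed(paste0(path, "/.zarray"), "shape and chunks must be positive")
    }
    list(resolution = res_axes, unit = unname(unit),
         extent = shape[perm], chunk = chunks[perm], path = path)
  })
  list(dtype = dtype, num_scales = length(scales), scales = scales,
       chunk_present = chunk_probe(store_tree, scales[[1L]]$path,
                                   exclude = "^\\."))
}

parse_precomputed <- function(store_tree) {
  info <- read_store_json(store_tree, "info")
  dtype <- need(info, "data_type", "info")
  if (!dtype %in% .supported_dtypes) {
    malformed("info.data_type", paste0("unsupported dtype '", dtype, "'"))
  }
  need(info, "num_channels", "info")
  raw_scales <- need(info, "scales", "info")
  if (length(raw_scales) < 1L) malformed("info.scales", "empty")
  scales <- lapply(seq_along(raw_scales), function(i) {
    s <- raw_scales[[i]]
    where <- sprintf("info.scales[%d]", i - 1L)
    res <- num_triple(need(s, "resolution", where), paste0(where, ".resolution"))
    size <- num_triple(need(s, "size", where), paste0(where, ".size"))
    cs <- need(s, "chunk_sizes", where)
    chunk <- num_triple(cs[[1L]], paste0(where, ".chunk_sizes[0]"))
    key <- s$key %||% as.character(i - 1L)
    # precomputed resolutions are in nanometers by convention
    list(resolution = res, unit = "nm", extent = size, chunk = chunk,
         path = key)
  })
  list(dtype = dtype, num_scales = length(scales), scales = scales,
       chunk_present = chunk_probe(store_tree, scales[[1L]]$path))
}

parse_n5 <- function(store_tree) {
  root <- read_store_json(store_tree, "attributes.json")
  need(root, "n5", "attributes.json")
  dirs <- list.dirs(store_tree, recursive = FALSE, full.names = FALSE)
  sdirs <- sort(dirs[grepl("^s[0-9]+$", dirs)])
  if (length(sdirs) < 1L) malformed("(root)", "no scale datasets s0, s1, ...")
  dtype <- NULL
  scales <- lapply(sdirs, function(sd) {
    at <- read_store_json(store_tree, file.path(sd, "attributes.json"))
    where <- paste0(sd, "/attributes.json")
    dims <- num_triple(need(at, "dimensions", where), paste0(where, ".dimensions"))
    block <- num_triple(need(at, "blockSize", where), paste0(where, ".blockSize"))
    dt <- need(at, "dataType", where)
    if (!dt %in% .supported_dtypes) {
      malformed(paste0(where, ".dataType"), paste0("unsupported dtype '", dt, "'"))
    }
    if (is.null(dtype)) dtype <<- dt
    res <- if (!is.null(at$resolution)) {
      num_triple(at$resolution, paste0(where, ".resolution"))
    } else {
      c(1, 1, 1)
    }
    unit <- if (!is.null(at$units)) unlist(at$units)[[1L]] else "nm"
    list(resolution = res, unit = unit, extent = dims, chunk = block,
         path = sd)
  })
  list(dtype = dtype, num_scales = length(scales), scales = scales,
       chunk_present = chunk_probe(store_tree, scales[[1L]]$path))
}

# Warning-level completeness probe: at least one non-metadata object under
# the scale-0 prefix.
chunk_probe <- function(store_tree, scale_path, exclude = "attributes|^\\.") {
  dir <- file.path(store_tree, scale_path)
  if (!dir.exists(dir)) return(FALSE)
  files <- list.files(dir, all.files = TRUE, no.. = TRUE)
  any(!grepl(exclude, files) & !grepl("\\.json$", files))
}

#' @export
print.benchmark_container <- function(x, ...) {
  cat("<container>", x$format_kind, x$dtype, "-", x$num_scales, "scale(s)\n")
  for (s in x$scales) {
    cat("  ", paste(s$extent, collapse = "x"), "voxels @",
        paste(s$resolution, collapse = ","), s$unit, "\n")
  }
  invisible(x)
}

#' Cross-check a channel and its coordinate frame against a container
#'
#' Compares the container's voxel dtype with the channel's \code{DataType},
#' its scale-0 resolution with the frame's \code{VoxelSize} (after unit
#' conversion, to relative tolerance 1e-6), and its scale-0 extent with the
#' frame extent in voxels, \code{(max - min) / resolution} per axis, rounded
#' to the nearest integer with a half-voxel tolerance. Absence of any chunk
#' object is reported as a warning-level completeness probe.
#'
#' @inheritParams describe_class
#' @param channel Channel entity.
#' @param coordinate_frame CoordinateFrame entity the channel references.
#' @param descriptor \code{benchmark_container} from
#'   \code{\link{parse_container}}.
#' @return List of violations (possibly empty).
#' @export
cross_check_channel <- function(registry, channel, coordinate_frame,
                                descriptor) {
  stopifnot(inherits(descriptor, "benchmark_container"))
  path <- default_path(channel)
  vs <- list()
  dtype <- channel$fields$DataType
  if (is.character(dtype) && dtype != descriptor$dtype) {
    vs[[length(vs) + 1L]] <- violation("DTYPE_MISMATCH", path, paste0(
      "channel DataType '", dtype, "' vs container dtype '",
      descriptor$dtype, "'"))
  }
  s0 <- descriptor$scales[[1L]]
  vres <- coordinate_frame$fields$VoxelSize
  if (inherits(vres, "benchmark_entity")) {
    frame_nm <- resolution_nm(c(vres$fields$X, vres$fields$Y, vres$fields$Z),
                              vres$fields$Unit)
    store_nm <- resolution_nm(s0$resolution, s0$unit)
    if (!is.null(frame_nm) && !is.null(store_nm)) {
      rel <- abs(store_nm - frame_nm) / pmax(abs(frame_nm), .Machine$double.eps)
      if (any(rel > 1e-6)) {
        vs[[length(vs) + 1L]] <- violation("RESOLUTION_MISMATCH", path, paste0(
          "frame VoxelSize (", paste(frame_nm, collapse = ","),
          ") nm vs container scale-0 resolution (",
          paste(store_nm, collapse = ","), ") nm"))
      } else {
        axes <- list(coordinate_frame$fields$Xs, coordinate_frame$fields$Ys,
                     coordinate_frame$fields$Zs)
        if (all(vapply(axes, function(a) is.numeric(a) && length(a) == 2L,
                       TRUE))) {
          # frame extents are in the frame's unit; compare in nm
          unit_f <- .unit_to_nm[[vres$fields$Unit %||% "nm"]] %||% 1
          span_nm <- vapply(1:3, function(i) {
            (axes[[i]][[2L]] - axes[[i]][[1L]]) * unit_f
          }, 0)
          want <- span_nm / frame_nm
          # nearest integer, half-voxel tolerance
          if (any(abs(want - round(want)) > 0.5 + 1e-9) ||
              any(round(want) != s0$extent)) {
            vs[[length(vs) + 1L]] <- violation("EXTENT_MISMATCH", path, paste0(
              "frame extent in voxels (", paste(round(want), collapse = ","),
              ") vs container scale-0 extent (",
              paste(s0$extent, collapse = ","), ")"))
          }
        }
      }
    }
  }
  if (!isTRUE(descriptor$chunk_present)) {
    vs[[length(vs) + 1L]] <- violation("CHUNK_MISSING", path,
      "no chunk object found under scale 0")
  }
  vs
}

resolution_nm <- function(res, unit) {
  if (!is.numeric(res) || length(res) != 3L || anyNA(res)) return(NULL)
  f <- .unit_to_nm[[unit %||% "nm"]]
  if (is.null(f)) return(NULL)
  res * f
}

#' Inspect a volume store end to end
#'
#' Convenience wrapper: detect the format, parse the container metadata and,
#' when channel and frame entities are supplied, cross-check them.
#'
#' @inheritParams cross_check_channel
#' @param store_tree Path to the store's root directory.
#' @return List with \code{descriptor} and \code{report}
#'   (a \code{benchmark_report}).
#' @export
inspect_volume <- function(store_tree, registry = NULL, channel = NULL,
                           coordinate_frame = NULL) {
  kind <- detect_format(store_tree)
  desc <- parse_container(store_tree, kind)
  vs <- if (!is.null(channel) && !is.null(coordinate_frame)) {
    cross_check_channel(registry, channel, coordinate_frame, desc)
  } else {
    list()
  }
  list(descriptor = desc, report = new_report(vs))
}
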