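# Canonical JSON serialization of metadata bundles.
#
# A bundle document is one JSON object:
#   { "StandardVersion": "1.1",
#     "Projects":         { "<id>": {...}, ... },
#     "Collections":      { ... },
#     "Experiments":      { ... },
#     "Channels":         { ... },
#     "CoordinateFrames": { ... } }
# Hierarchical entities live in per-class tables keyed by ID and refer to each
# other by string ID; supporting classes (Contributor, License, ...) stay
# inline in their owners. On read, inline children found inside reference
# fields are hoisted into the tables and replaced by their IDs, so the nested
# and referenced forms parse to the same bundle.

.table_classes <- c(Projects = "Project", Collections = "Collection",
                    Experiments = "Experiment", Channels = "Channel",
                    CoordinateFrames = "CoordinateFrame")

#' Read a metadata bundle from a JSON document
#'
#' @inheritParams describe_class
#' @param document A file path, a JSON string, or an already-parsed list.
#' @return A \code{benchmark_bundle}: \code{standard_version}, \code{projects}
#'   (project IDs), \code{entities} (per-class tables keyed by ID) and
#'   \code{extras} (quarantined unknown top-level keys). Type problems in
#'   field values do not abort the read; they surface as \code{TYPE_MISMATCH}
#'   when the bundle is validated.
#' @export
read_bundle <- function(registry, document) {
  doc <- parse_document(document)
  if (!is.list(doc) || (length(doc) > 0L && is.null(names(doc)))) {
    stop("bundle parse error: document root must be a JSON object",
         call. = FALSE)
  }
  env <- new.env(parent = emptyenv())
  env$tables <- stats::setNames(
    replicate(length(.table_classes), list(), simplify = FALSE),
    unname(.table_classes))
  env$anon <- 0L

  extras <- list()
  version <- "1.1"
  for (key in names(doc)) {
    if (key == "StandardVersion") {
      version <- as.character(doc[[key]])[1L]
    } else if (key %in% names(.table_classes)) {
      cls <- .table_classes[[key]]
      tbl <- doc[[key]]
      if (!is.list(tbl)) {
        stop("bundle parse error: '", key, "' must be an object or array",
             call. = FALSE)
      }
      keyed <- !is.null(names(tbl)) && all(nzchar(names(tbl)))
      for (i in seq_along(tbl)) {
        obj <- tbl[[i]]
        if (keyed && is.list(obj) && is.null(obj[["@id"]]) &&
            is.null(obj[["ID"]])) {
          obj[["@id"]] <- names(tbl)[[i]]
        }
        ingest_entity(registry, cls, obj, env,
                      key_hint = if (keyed) names(tbl)[[i]] else NULL)
      }
    } else {
      extras[[key]] <- doc[[key]]
    }
  }
  structure(
    list(standard_version = version,
         projects = sort(names(env$tables$Project)),
         entities = env$tables,
         extras = extras),
    class = "benchmark_bundle"
  )
}

parse_document <- function(document) {
  if (is.list(document)) return(document)
  stopifnot(is.character(document), length(document) == 1L)
  txt <- if (file.exists(document) && !grepl("[{\\[]", substr(document, 1, 1))) {
    readChar(document, file.size(document), useBytes = TRUE)
  } else {
    document
  }
  if (!validUTF8(txt)) {
    stop("bundle parse error: document is not valid UTF-8", call. = FALSE)
  }
  tryCatch(
    jsonlite::fromJSON(txt, simplifyVector = FALSE),
    error = function(e) {
      stop("bundle parse error: ", conditionMessage(e), call. = FALSE)
    }
  )
}

# Build an entity leniently, hoist any inline children out of reference
# fields, and register it in its class table. Returns the entity ID.
ingest_entity <- function(registry, cls, obj, env, key_hint = NULL) {
  if (!is.list(obj)) {
    stop("bundle parse error: ", cls, " entry must be a JSON object",
         call. = FALSE)
  }
  ent <- build_entity(registry, cls, obj, strict = FALSE)
  if (is.null(ent$id)) {
    ent$id <- key_hint %||% {
      env$anon <- env$anon + 1L
      sprintf("anon-%s-%d", tolower(cls), env$anon)
    }
  }
  ent <- hoist_references(registry, ent, env)
  if (!is.null(env$tables[[cls]][[ent$id]])) {
    stop("bundle parse error: duplicate ", cls, " ID '", ent$id, "'",
         call. = FALSE)
  }
  env$tables[[cls]][[ent$id]] <- ent
  ent$id
}

# Replace inline entities in reference fields by their IDs (registering them),
# and recurse into inline supporting-class values.
hoist_references <- function(registry, ent, env) {
  desc <- describe_class(registry, ent$class_name)
  for (fn in names(ent$fields)) {
    f <- desc$fields[[fn]]
    val <- ent$fields[[fn]]
    if (is_raw_value(val)) next
    dt <- resolve_datatype(registry, f$datatype)
    if (dt$kind != "class") next
    if (isTRUE(f$reference)) {
      to_id <- function(item) {
        if (inherits(item, "benchmark_entity")) {
          ingest_entity(registry, dt$base, c(item$fields, item$extras,
                                             if (!is.null(item$id))
                                               list(`@id` = item$id)),
                        env)
        } else {
          as.character(item)
        }
      }
      if (dt$is_list) {
        ent$fields[[fn]] <- vapply(val, to_id, "", USE.NAMES = FALSE)
      } else {
        ent$fields[[fn]] <- to_id(val)
      }
    } else {
      if (dt$is_list) {
        ent$fields[[fn]] <- lapply(val, function(item) {
          if (inherits(item, "benchmark_entity")) {
            hoist_references(registry, item, env)
          } else item
        })
      } else if (inherits(val, "benchmark_entity")) {
        ent$fields[[fn]] <- hoist_references(registry, val, env)
      }
    }
  }
  ent
}

#' Write a metadata bundle as canonical JSON
#'
#' Canonical form: UTF-8, top-level tables in fixed order with entity IDs
#' sorted lexicographically (C collation), entity keys in registry field
#' order, dates ISO-8601, and numbers in R's shortest default decimal form.
#' Writing is a fixpoint: \code{write(read(write(b)))} equals \code{write(b)}
#' byte for byte.
#'
#' @inheritParams describe_class
#' @param bundle A \code{benchmark_bundle}.
#' @param path Optional file path; when given the document is written there
#'   (UTF-8, trailing newline) and the path returned invisibly.
#' @return The canonical JSON document as a single string (unless \code{path}
#'   is given).
#' @export
write_bundle <- function(registry, bundle, path = NULL) {
  stopifnot(inherits(bundle, "benchmark_bundle"))
  out <- list(StandardVersion = jsonlite::unbox(bundle$standard_version))
  for (key in names(.table_classes)) {
    tbl <- bundle$entities[[.table_classes[[key]]]]
    if (length(tbl) == 0L) next
    ids <- sort_c(names(tbl))
    out[[key]] <- stats::setNames(
      lapply(ids, function(id) entity_to_tree(registry, tbl[[id]])), ids)
  }
  for (key in sort_c(names(bundle$extras))) {
    out[[key]] <- raw_to_tree(bundle$extras[[key]])
  }
  txt <- jsonlite::toJSON(out, auto_unbox = FALSE, digits = NA,
                          pretty = 2, null = "null", na = "null")
  txt <- paste0(as.character(txt), "\n")
  if (!is.null(path)) {
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeChar(txt, con, eos = NULL)
    return(invisible(path))
  }
  txt
}

# Locale-independent lexicographic sort (byte order) for canonical output.
sort_c <- function(x) {
  if (length(x) == 0L) return(character(0))
  old <- Sys.getlocale("LC_COLLATE")
  on.exit(suppressWarnings(Sys.setlocale("LC_COLLATE", old)), add = TRUE)
  suppressWarnings(Sys.setlocale("LC_COLLATE", "C"))
  sort(x, method = "radix")
}

# Entity -> JSON-ready tree (keys in registry order, extras after).
entity_to_tree <- function(registry, ent) {
  desc <- describe_class(registry, ent$class_name)
  out <- list()
  if (!is.null(ent$id) && !"ID" %in% names(ent$fields)) {
    out[["@id"]] <- jsonlite::unbox(ent$id)
  }
  for (f in desc$fields) {
    if (!f$name %in% names(ent$fields)) next
    val <- ent$fields[[f$name]]
    if (is_raw_value(val)) {
      stop("serialization error: ", ent$class_name, ".", f$name,
           " holds a value violating its declared type (", val$problem, ")",
           call. = FALSE)
    }
    out[[f$name]] <- value_to_tree(registry, f, val)
  }
  for (nm in sort_c(names(ent$extras))) {
    out[[nm]] <- raw_to_tree(ent$extras[[nm]])
  }
  out
}

value_to_tree <- function(registry, f, val) {
  dt <- resolve_datatype(registry, f$datatype)
  if (dt$kind == "class" && isTRUE(f$reference)) {
    ids <- as.character(val)
    if (dt$is_list) return(lapply(ids, jsonlite::unbox))
    return(jsonlite::unbox(ids[[1L]]))
  }
  if (dt$kind == "class") {
    if (dt$is_list) {
      return(lapply(val, function(e) entity_to_tree(registry, e)))
    }
    return(entity_to_tree(registry, val))
  }
  if (dt$is_list) {
    return(lapply(as.vector(val), function(v) jsonlite::unbox(scalar_out(v))))
  }
  jsonlite::unbox(scalar_out(val))
}

scalar_out <- function(v) {
  if (is.double(v)) {
    # force shortest decimal text via as.character at write time
    return(structure(v, class = class(v)))
  }
  v
}

# Extras round-trip verbatim: parsed JSON -> same JSON.
raw_to_tree <- function(x) {
  if (is.list(x)) {
    return(lapply(x, raw_to_tree))
  }
  if (is.null(x)) return(NULL)
  if (length(x) == 1L) return(jsonlite::unbox(x))
  lapply(as.list(x), jsonlite::unbox)
}

#' @export
print.benchmark_bundle <- function(x, ...) {
  cat("<benchmark_bundle> standard", x$standard_version, "\n")
  for (cls in names(x$entities)) {
    cat(sprintf("  %-16s %d\n", cls, length(x$entities[[cls]])))
  }
  invisible(x)
}

#' Count entities held in a bundle's tables
#'
#' @param bundle A \code{benchmark_bundle}.
#' @return Total number of entities across the per-class tables.
#' @export
bundle_size <- function(bundle) {
  sum(vapply(bundle$entities, length, 0L))
}
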