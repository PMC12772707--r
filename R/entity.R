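#' Construct a typed metadata entity
#'
#' Builds an instance of one of the registered classes from a named list of
#' field values, coercing primitives per the package's coercion table
#' (string to int/float only when lossless; int to float always; bare years
#' accepted for Date fields and normalized to \code{YYYY}). Field names not
#' declared for the class are never silently dropped: they are quarantined in
#' the entity's \code{extras} and reported as warnings by validation.
#'
#' Reference fields (e.g. an experiment's \code{CoordinateFrame}) accept
#' string IDs; inline nested objects are also accepted and are hoisted to
#' ID references when a document is read into a bundle.
#'
#' @inheritParams describe_class
#' @param class_name Registered class to instantiate.
#' @param field_values Named list of field values.
#' @param strict When \code{TRUE} (default) an uncoercible primitive value is
#'   a type error naming the field and expected type; when \code{FALSE} the
#'   offending raw value is retained and flagged at validation time.
#' @return A \code{benchmark_entity}: list with \code{class_name},
#'   \code{fields} (declared fields present, in registry order),
#'   \code{extras} (quarantined unknown fields) and \code{id} (entity ID when
#'   the class carries one, or one supplied via the reserved \code{"@id"} key).
#' @examples
#' reg <- load_registry()
#' build_entity(reg, "Link", list(Name = "BossDB", URI = "https://bossdb.org"))
#' @export
build_entity <- function(registry, class_name, field_values, strict = TRUE) {
  desc <- describe_class(registry, class_name)
  if (is.null(field_values)) field_values <- list()
  stopifnot(is.list(field_values))
  vals <- field_values
  id <- NULL
  if ("@id" %in% names(vals)) {
    id <- as.character(vals[["@id"]])[1L]
    vals[["@id"]] <- NULL
  }
  fields <- list()
  extras <- list()
  for (nm in names(vals)) {
    if (nm %in% names(desc$fields)) next
    extras[[nm]] <- vals[[nm]]
  }
  for (f in desc$fields) {
    if (!f$name %in% names(vals)) next
    raw <- vals[[f$name]]
    coerced <- coerce_field_value(registry, class_name, f, raw, strict)
    fields[[f$name]] <- coerced
  }
  if (is.null(id) && "ID" %in% names(fields) && is.character(fields$ID)) {
    id <- fields$ID[[1L]]
  }
  structure(
    list(class_name = class_name, fields = fields, extras = extras, id = id),
    class = "benchmark_entity"
  )
}

# Internal marker wrapped around values that failed lenient coercion, so
# validation can report TYPE_MISMATCH instead of the build aborting.
raw_value <- function(x, problem) {
  structure(list(value = x, problem = problem), class = "benchmark_raw_value")
}

is_raw_value <- function(x) inherits(x, "benchmark_raw_value")

type_error <- function(class_name, field, expected, strict, raw) {
  msg <- paste0(class_name, ".", field, ": expected ", expected)
  if (strict) stop(msg, call. = FALSE)
  raw_value(raw, msg)
}

# Internal: coerce one field value to its canonical in-memory representation.
coerce_field_value <- function(registry, class_name, f, raw, strict) {
  dt <- resolve_datatype(registry, f$datatype)

  if (dt$kind == "class" && isTRUE(f$reference)) {
    # string ID(s), or inline object(s) built recursively (hoisted later)
    return(coerce_reference(registry, class_name, f, dt, raw, strict))
  }

  if (dt$is_list) {
    items <- if (is.list(raw)) raw else as.list(raw)
    out <- lapply(items, function(item) {
      coerce_scalar(registry, class_name, f, dt, item, strict)
    })
    bad <- vapply(out, is_raw_value, TRUE)
    if (any(bad)) {
      if (strict) stop(out[[which(bad)[1L]]]$problem, call. = FALSE)
      return(raw_value(raw, out[[which(bad)[1L]]]$problem))
    }
    if (dt$kind == "class") return(out)
    return(unlist(out, use.names = FALSE) %||% vector(scalar_mode(dt$base), 0L))
  }
  coerce_scalar(registry, class_name, f, dt, raw, strict)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

scalar_mode <- function(base) {
  switch(base, Int = "integer", Float = "double", Boolean = "logical",
         "character")
}

coerce_reference <- function(registry, class_name, f, dt, raw, strict) {
  one <- function(item) {
    if (is.character(item) && length(item) == 1L) return(item)
    if (is.list(item) && !inherits(item, "benchmark_entity")) {
      return(build_entity(registry, dt$base, item, strict = strict))
    }
    if (inherits(item, "benchmark_entity")) return(item)
    type_error(class_name, f$name,
               paste0(dt$base, " ID or inline object"), strict, item)
  }
  if (dt$is_list) {
    items <- if (is.list(raw) && !inherits(raw, "benchmark_entity")) {
      raw
    } else if (is.character(raw)) {
      as.list(raw)
    } else {
      list(raw)
    }
    out <- lapply(items, one)
    if (all(vapply(out, is.character, TRUE))) {
      out <- unlist(out, use.names = FALSE) %||% character(0)
    }
    out
  } else {
    if (is.character(raw) && length(raw) > 1L) {
      return(type_error(class_name, f$name,
                        paste0("single ", dt$base, " reference"), strict, raw))
    }
    one(if (is.list(raw) && length(raw) == 1L && is.character(raw[[1L]]))
      raw[[1L]] else raw)
  }
}

coerce_scalar <- function(registry, class_name, f, dt, item, strict) {
  expected <- dt$base
  if (is.list(item) && length(item) == 1L && !inherits(item, "benchmark_entity") &&
      dt$kind != "class") {
    item <- item[[1L]]
  }
  if (dt$kind == "class") {
    if (inherits(item, "benchmark_entity")) return(item)
    if (is.list(item)) {
      return(build_entity(registry, dt$base, item, strict = strict))
    }
    return(type_error(class_name, f$name, paste0(dt$base, " object"),
                      strict, item))
  }
  if (dt$kind == "enum") {
    if (!is.character(item) || length(item) != 1L) {
      return(type_error(class_name, f$name, paste0(dt$base, " member"),
                        strict, item))
    }
    # alias normalization only; non-members pass through to validation
    return(normalize_enum_value(registry, dt$base, item))
  }
  switch(expected,
    String = {
      if (is.character(item) && length(item) == 1L) return(item)
      type_error(class_name, f$name, "String", strict, item)
    },
    Boolean = {
      if (is.logical(item) && length(item) == 1L && !is.na(item)) return(item)
      type_error(class_name, f$name, "Boolean", strict, item)
    },
    Int = {
      v <- lossless_int(item)
      if (!is.null(v)) return(v)
      type_error(class_name, f$name, "Int", strict, item)
    },
    Float = {
      v <- lossless_float(item)
      if (!is.null(v)) return(v)
      type_error(class_name, f$name, "Float", strict, item)
    },
    Date = {
      v <- normalize_date(item)
      if (!is.null(v)) return(v)
      type_error(class_name, f$name, "Date (YYYY or YYYY-MM-DD)", strict, item)
    }
  )
}

# Coercion table: string -> int/float only when lossless; int -> float always.
lossless_int <- function(x) {
  if (length(x) != 1L) return(NULL)
  if (is.integer(x) && !is.na(x)) return(x)
  if (is.numeric(x) && !is.na(x) && x == trunc(x) && abs(x) < .Machine$integer.max) {
    return(as.integer(x))
  }
  if (is.character(x) && grepl("^-?[0-9]+$", x)) {
    v <- suppressWarnings(as.integer(x))
    if (!is.na(v)) return(v)
  }
  NULL
}

lossless_float <- function(x) {
  if (length(x) != 1L) return(NULL)
  if (is.numeric(x) && !is.na(x)) return(as.numeric(x))
  if (is.character(x)) {
    v <- suppressWarnings(as.numeric(x))
    # round-trip check keeps the coercion lossless
    if (!is.na(v) && isTRUE(all.equal(as.character(v), trimws(x))) ||
        (!is.na(v) && grepl("^-?[0-9]*\\.?[0-9]+([eE][+-]?[0-9]+)?$", trimws(x)))) {
      return(v)
    }
  }
  NULL
}

# ISO-8601 calendar dates; bare years normalized to "YYYY".
normalize_date <- function(x) {
  if (is.numeric(x) && length(x) == 1L && !is.na(x) && x == trunc(x) &&
      x >= 1000 && x <= 9999) {
    return(sprintf("%04d", as.integer(x)))
  }
  if (!is.character(x) || length(x) != 1L) return(NULL)
  x <- trimws(x)
  if (grepl("^[0-9]{4}$", x)) return(x)
  if (grepl("^[0-9]{4}-[0-9]{2}-[0-9]{2}$", x)) {
    d <- as.Date(x, format = "%Y-%m-%d")
    if (!is.na(d) && format(d, "%Y-%m-%d") == x) return(x)
  }
  NULL
}

#' @export
print.benchmark_entity <- function(x, ...) {
  cat("<", x$class_name, ">",
      if (!is.null(x$id)) paste0(" id=", x$id) else "", "\n", sep = "")
  cat("  fields:", paste(names(x$fields), collapse = ", "), "\n")
  if (length(x$extras)) {
    cat("  extras (quarantined):", paste(names(x$extras), collapse = ", "), "\n")
  }
  invisible(x)
}
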