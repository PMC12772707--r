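#' Load the bundled BENCHMARK v1.1 schema registry
#'
#' The registry is the single machine-readable source of truth for the
#' standard: its 18 metadata classes (fields, datatypes, required flags) and
#' all enumerations. Every other part of the package -- entity construction,
#' validation, canonical serialization, the fixture generator and the CLI --
#' introspects this object rather than hard-coding structure.
#'
#' @param path Optional path to an alternative schema-definition JSON file;
#'   defaults to the definition shipped with the package.
#' @return An object of class \code{benchmark_registry} with elements
#'   \code{version} (standard version string, \code{"1.1"}),
#'   \code{classes} (named list of class descriptors) and
#'   \code{enums} (named list of ordered member character vectors).
#' @examples
#' reg <- load_registry()
#' length(reg$classes)              # 18
#' names(describe_class(reg, "Link")$fields)
#' @export
load_registry <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "benchmark_schema_v1_1.json",
                        package = "benchmarkmeta")
  }
  if (!nzchar(path) || !file.exists(path)) {
    stop("bundled schema definition not found", call. = FALSE)
  }
  def <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) {
      stop("malformed schema definition: ", conditionMessage(e), call. = FALSE)
    }
  )
  for (key in c("version", "classes", "enums")) {
    if (is.null(def[[key]])) {
      stop("malformed schema definition: missing '", key, "'", call. = FALSE)
    }
  }
  enums <- lapply(def$enums, function(m) vapply(m, as.character, ""))
  aliases <- lapply(def$enum_aliases, function(a) {
    vapply(a, as.character, "")
  })
  classes <- lapply(names(def$classes), function(cn) {
    cd <- def$classes[[cn]]
    fields <- lapply(cd$fields, function(f) {
      list(
        name        = f$name,
        description = if (is.null(f$description)) "" else f$description,
        datatype    = f$datatype,
        required    = isTRUE(f$required),
        reference   = isTRUE(f$reference)
      )
    })
    names(fields) <- vapply(fields, `[[`, "", "name")
    if (anyDuplicated(names(fields))) {
      stop("malformed schema definition: duplicate field names in class ",
           cn, call. = FALSE)
    }
    structure(
      list(name = cn, fields = fields,
           description = if (is.null(cd$description)) "" else cd$description,
           provenance  = if (is.null(cd$provenance)) "" else cd$provenance),
      class = "benchmark_class_descriptor"
    )
  })
  names(classes) <- names(def$classes)

  reg <- structure(
    list(version = def$version, classes = classes, enums = enums,
         enum_aliases = aliases),
    class = "benchmark_registry"
  )
  check_registry_closure(reg)
  reg
}

# Internal: every declared datatype must resolve to a primitive, a registered
# enum, or a registered class (possibly list-of).
check_registry_closure <- function(reg) {
  for (cd in reg$classes) {
    for (f in cd$fields) {
      dt <- parse_datatype(f$datatype, reg)
      if (dt$kind == "unknown") {
        stop("malformed schema definition: field ", cd$name, ".", f$name,
             " has unresolvable datatype '", f$datatype, "'", call. = FALSE)
      }
    }
  }
  invisible(reg)
}

.primitives <- c("String", "Int", "Float", "Boolean", "Date")

#' Parse a registry datatype declaration
#'
#' Datatype strings are either a primitive (\code{String}, \code{Int},
#' \code{Float}, \code{Boolean}, \code{Date}), the name of a registered
#' enumeration or class, or \code{[T]} for a list of any of those. Enum names
#' shadow class names on lookup (no name is both in the shipped registry).
#'
#' @param datatype Datatype declaration string, e.g. \code{"[Contributor]"}.
#' @param registry Optionally, a registry used to classify the base name; when
#'   omitted the base name's kind is \code{"primitive"} only if it is one, and
#'   \code{"unknown"} otherwise.
#' @return A list with \code{base} (base type name), \code{is_list} (logical)
#'   and \code{kind} (\code{"primitive"}, \code{"enum"}, \code{"class"} or
#'   \code{"unknown"}).
#' @keywords internal
parse_datatype <- function(datatype, registry = NULL) {
  is_list <- grepl("^\\[.*\\]$", datatype)
  base <- if (is_list) substr(datatype, 2L, nchar(datatype) - 1L) else datatype
  kind <- if (base %in% .primitives) {
    "primitive"
  } else if (!is.null(registry)) {
    if (base %in% names(registry$enums)) "enum"
    else if (base %in% names(registry$classes)) "class"
    else "unknown"
  } else {
    "unknown"
  }
  list(base = base, is_list = is_list, kind = kind)
}

# Internal: datatype resolution against a specific registry, erroring on
# unresolvable names (registry closure makes this unreachable for shipped
# definitions).
resolve_datatype <- function(registry, datatype) {
  dt <- parse_datatype(datatype, registry)
  if (dt$kind == "unknown") {
    stop("unresolvable datatype '", datatype, "'", call. = FALSE)
  }
  dt
}

#' Describe a registered metadata class
#'
#' @param registry A \code{benchmark_registry} from \code{\link{load_registry}}.
#' @param class_name Name of one of the 18 registered classes.
#' @return The class descriptor: ordered \code{fields} (each with
#'   \code{name}, \code{description}, \code{datatype}, \code{required},
#'   \code{reference}), the class \code{description} and a \code{provenance}
#'   note saying whether the field list is printed in the standard or authored
#'   to its stated count.
#' @examples
#' reg <- load_registry()
#' desc <- describe_class(reg, "Taxonomy")
#' length(desc$fields)  # 8
#' @export
describe_class <- function(registry, class_name) {
  stopifnot(inherits(registry, "benchmark_registry"))
  if (length(class_name) != 1L || !class_name %in% names(registry$classes)) {
    stop("unknown class '", class_name, "'; registered classes: ",
         paste(names(registry$classes), collapse = ", "), call. = FALSE)
  }
  registry$classes[[class_name]]
}

#' List the members of a registered enumeration
#'
#' Member order is the registry's declaration order; membership is
#' case-sensitive (\code{\link{enum_is_member}}).
#'
#' @inheritParams describe_class
#' @param enum_name Name of a registered enumeration.
#' @return Character vector of members in registry order.
#' @examples
#' reg <- load_registry()
#' list_enum_members(reg, "RelationType")
#' @export
list_enum_members <- function(registry, enum_name) {
  stopifnot(inherits(registry, "benchmark_registry"))
  if (length(enum_name) != 1L || !enum_name %in% names(registry$enums)) {
    stop("unknown enum '", enum_name, "'; registered enums: ",
         paste(names(registry$enums), collapse = ", "), call. = FALSE)
  }
  registry$enums[[enum_name]]
}

#' Test enum membership (case-sensitive)
#'
#' @inheritParams list_enum_members
#' @param value Candidate member string.
#' @return \code{TRUE} iff \code{value} is exactly one of the enum's members.
#' @export
enum_is_member <- function(registry, enum_name, value) {
  members <- list_enum_members(registry, enum_name)
  length(value) == 1L && is.character(value) && value %in% members
}

# Internal: normalize accepted aliases (e.g. GRID -> GRDI) to the registered
# member; returns the value unchanged when no alias applies.
normalize_enum_value <- function(registry, enum_name, value) {
  al <- registry$enum_aliases[[enum_name]]
  if (!is.null(al) && length(value) == 1L && value %in% names(al)) {
    unname(al[[value]])
  } else {
    value
  }
}

# Internal: nearest member by case-insensitive match then edit distance,
# used to suggest fixes for enum near-misses.
nearest_enum_member <- function(registry, enum_name, value) {
  members <- list_enum_members(registry, enum_name)
  ci <- members[tolower(members) == tolower(value)]
  if (length(ci) > 0L) return(ci[[1L]])
  d <- utils::adist(value, members, ignore.case = TRUE)
  members[[which.min(d)]]
}

#' @export
print.benchmark_registry <- function(x, ...) {
  cat("<benchmark_registry> standard version", x$version, "\n")
  cat(" ", length(x$classes), "classes:",
      paste(names(x$classes), collapse = ", "), "\n")
  cat(" ", length(x$enums), "enums:",
      paste(names(x$enums), collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.benchmark_class_descriptor <- function(x, ...) {
  cat("<class>", x$name, "-", length(x$fields), "fields\n")
  for (f in x$fields) {
    cat(sprintf("  %-28s %-28s %s\n", f$name, f$datatype,
                if (f$required) "required" else "optional"))
  }
  invisible(x)
}
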