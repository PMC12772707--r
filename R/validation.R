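# Rules engine for metadata bundles.
#
# Every finding is a report entry, never an exception: validation of
# untrusted metadata must not abort (archive-ingest use case). Severity
# policy: missing required fields, type and enum violations, cardinality,
# subset, coordinate-frame, degenerate-extent and dangling-reference rules
# are errors; quarantined unknown fields, malformed persistent identifiers
# and mixed reference-frame labels are warnings.

.rule_registry <- data.frame(
  code = c("REQ_MISSING", "TYPE_MISMATCH", "ENUM_INVALID", "CARDINALITY",
           "SUBSET_CREATORS", "SUBSET_LICENSE", "SUBSET_IDENTIFIERS",
           "COORD_MISMATCH", "EXTENT_DEGENERATE", "REF_DANGLING",
           "UNKNOWN_FIELD", "ID_SYNTAX", "FRAME_REFERENCE_MIXED",
           "DTYPE_MISMATCH", "RESOLUTION_MISMATCH", "EXTENT_MISMATCH",
           "CONTAINER_MALFORMED", "UNRECOGNIZED_FORMAT", "FORMAT_AMBIGUOUS",
           "CHUNK_MISSING"),
  severity = c("error", "error", "error", "error",
               "error", "error", "error",
               "error", "error", "error",
               "warning", "warning", "warning",
               "error", "error", "error",
               "error", "error", "error",
               "warning"),
  description = c(
    "A field the registry marks required is absent",
    "A field value cannot be represented in the field's declared type",
    "An enum-typed field holds a value outside the closed member list",
    "A must-be-at-least-one relationship is empty",
    "A child's creators are not a subset of its parent's",
    "A child's licenses are not a subset of its parent's",
    "A child's identifiers are not a subset of its parent's",
    "A channel's coordinate frame differs from its experiment's",
    "An axis extent has min >= max, or a voxel resolution is not positive",
    "An ID reference does not resolve inside the bundle",
    "A field name not declared for the class (quarantined, not dropped)",
    "A persistent identifier fails its scheme's syntax check",
    "Experiments of one project carry differing reference-frame labels",
    "Container voxel dtype differs from the channel's DataType",
    "Container scale-0 resolution differs from the frame's VoxelSize",
    "Container scale-0 extent differs from the frame extent in voxels",
    "A container metadata file is missing a mandatory key or unparsable",
    "No sanctioned container format sentinel is present",
    "Sentinels of more than one container format are present",
    "No chunk object found in the store (completeness probe)"
  ),
  stringsAsFactors = FALSE
)

#' The closed registry of validation rule codes
#'
#' @return Data frame with columns \code{code}, \code{severity},
#'   \code{description}; every \code{rule_code} a report can carry is drawn
#'   from this table.
#' @export
validation_rules <- function() .rule_registry

violation <- function(code, path, message) {
  sev <- .rule_registry$severity[match(code, .rule_registry$code)]
  if (is.na(sev)) stop("unknown rule code: ", code, call. = FALSE)
  list(rule_code = code, entity_path = path, severity = sev, message = message)
}

#' Assemble violations into a validation report
#'
#' @param violations List of violation records.
#' @return A \code{benchmark_report}: \code{violations} sorted by entity
#'   path then rule code then message (deterministic), per-severity
#'   \code{counts}, and \code{valid} which is \code{TRUE} iff the error
#'   count is zero.
#' @export
new_report <- function(violations = list()) {
  if (length(violations) > 0L) {
    key <- vapply(violations, function(v) {
      paste(v$entity_path, v$rule_code, v$message, sep = "\r")
    }, "")
    violations <- violations[order(key, method = "radix")]
  }
  sev <- vapply(violations, `[[`, "", "severity")
  counts <- c(error = sum(sev == "error"), warning = sum(sev == "warning"))
  structure(
    list(violations = violations, counts = counts,
         valid = counts[["error"]] == 0L),
    class = "benchmark_report"
  )
}

merge_reports <- function(...) {
  new_report(unlist(lapply(list(...), function(r) {
    if (inherits(r, "benchmark_report")) r$violations else r
  }), recursive = FALSE))
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat("<validation report>",
      x$counts[["error"]], "error(s),",
      x$counts[["warning"]], "warning(s);",
      if (x$valid) "VALID" else "INVALID", "\n")
  for (v in x$violations) {
    cat(sprintf("  [%s] %-20s %s: %s\n", substr(v$severity, 1, 1),
                v$rule_code, v$entity_path, v$message))
  }
  invisible(x)
}

#' Validate a single entity against the registry
#'
#' Checks required-field presence, declared types, closed enum membership
#' (with a nearest-member suggestion on near-misses), quarantined unknown
#' fields, coordinate-frame/resolution geometry, and persistent-identifier
#' syntax, recursing into inline child entities.
#'
#' @inheritParams describe_class
#' @param entity A \code{benchmark_entity}.
#' @param path Entity path used in the report (defaults to
#'   \code{<class>/<id>}).
#' @return A \code{benchmark_report}.
#' @export
validate_entity <- function(registry, entity,
                            path = default_path(entity)) {
  new_report(entity_violations(registry, entity, path))
}

default_path <- function(entity) {
  paste0(tolower(entity$class_name), "/", entity$id %||% "?")
}

entity_violations <- function(registry, entity, path) {
  desc <- describe_class(registry, entity$class_name)
  vs <- list()
  add <- function(v) vs[[length(vs) + 1L]] <<- v

  for (f in desc$fields) {
    present <- f$name %in% names(entity$fields)
    if (f$required && !present) {
      add(violation("REQ_MISSING", path,
                    paste0(entity$class_name, ".", f$name, " is required")))
      next
    }
    if (!present) next
    val <- entity$fields[[f$name]]
    if (is_raw_value(val)) {
      add(violation("TYPE_MISMATCH", path, val$problem))
      next
    }
    dt <- resolve_datatype(registry, f$datatype)
    if (dt$kind == "enum") {
      vals <- as.character(val)
      for (v in vals) {
        if (!enum_is_member(registry, dt$base, v)) {
          add(violation("ENUM_INVALID", path, paste0(
            entity$class_name, ".", f$name, ": '", v, "' is not a member of ",
            dt$base, "; nearest member is '",
            nearest_enum_member(registry, dt$base, v), "'")))
        }
      }
    } else if (dt$kind == "class" && !isTRUE(f$reference)) {
      children <- if (dt$is_list) val else list(val)
      for (i in seq_along(children)) {
        child <- children[[i]]
        if (!inherits(child, "benchmark_entity")) next
        sub <- if (dt$is_list) {
          paste0(path, "/", tolower(f$name), "/", i)
        } else {
          paste0(path, "/", tolower(f$name))
        }
        vs <- c(vs, entity_violations(registry, child, sub))
        add <- function(v) vs[[length(vs) + 1L]] <<- v
      }
    }
  }

  for (nm in names(entity$extras)) {
    add(violation("UNKNOWN_FIELD", path, paste0(
      "field '", nm, "' is not declared for ", entity$class_name,
      "; value quarantined")))
  }

  vs <- c(vs, geometry_violations(entity, path))
  c(vs, identifier_violations(registry, entity, path))
}

# CoordinateFrame axes must be [min, max] with min < max; resolutions > 0.
geometry_violations <- function(entity, path) {
  vs <- list()
  if (entity$class_name == "CoordinateFrame") {
    for (ax in c("Xs", "Ys", "Zs")) {
      v <- entity$fields[[ax]]
      if (is.null(v) || is_raw_value(v)) next
      if (length(v) != 2L) {
        vs[[length(vs) + 1L]] <- violation("EXTENT_DEGENERATE", path, paste0(
          ax, " must be a [min, max] pair, got length ", length(v)))
      } else if (!(v[[1L]] < v[[2L]])) {
        vs[[length(vs) + 1L]] <- violation("EXTENT_DEGENERATE", path, paste0(
          ax, ": min (", v[[1L]], ") is not < max (", v[[2L]], ")"))
      }
    }
  }
  if (entity$class_name == "ImageResolution") {
    for (ax in c("X", "Y", "Z")) {
      v <- entity$fields[[ax]]
      if (is.null(v) || is_raw_value(v)) next
      if (!(v > 0)) {
        vs[[length(vs) + 1L]] <- violation("EXTENT_DEGENERATE", path, paste0(
          "voxel resolution ", ax, " must be > 0, got ", v))
      }
    }
  }
  vs
}

# Identifier-bearing field pairs: (value field, scheme field or fixed scheme).
identifier_violations <- function(registry, entity, path) {
  pairs <- switch(entity$class_name,
    Contributor = list(c("NameIdentifier", "NameIdentifierScheme"),
                       c("AffiliationIdentifier", "AffiliationIdentifierScheme")),
    Funding = list(c("FundingReferenceIdentifier",
                     "FundingReferenceIdentifierType")),
    Publication = list(c("RelatedIdentifier", "RelatedIdentifierType")),
    NULL)
  vs <- list()
  for (p in pairs %||% list()) {
    val <- entity$fields[[p[[1L]]]]
    scheme <- entity$fields[[p[[2L]]]]
    if (is.null(val) || is_raw_value(val)) next
    if (is.null(scheme) || is_raw_value(scheme)) next
    if (!scheme %in% identifier_schemes()) next  # non-member: ENUM_INVALID fires
    res <- validate_identifier(scheme, val)
    if (!res$valid) {
      vs[[length(vs) + 1L]] <- violation("ID_SYNTAX", path, paste0(
        entity$class_name, ".", p[[1L]], ": '", val,
        "' fails ", scheme, " syntax (", res$message, ")"))
    }
  }
  vs
}

#' Validate a whole metadata bundle
#'
#' Runs per-entity validation over every entity in the bundle plus the
#' cross-entity rules of the standard: reference resolution, must-be-at-
#' least-one cardinalities, the hierarchical subset constraints on creators,
#' licenses and identifiers, channel/experiment coordinate-frame agreement,
#' and the recommended (warning-level) shared reference-frame check.
#' Violation ordering is deterministic: entity path, then rule code.
#'
#' @inheritParams describe_class
#' @param bundle A \code{benchmark_bundle} from \code{\link{read_bundle}} or
#'   \code{\link{generate_bundle}}.
#' @return A \code{benchmark_report}; \code{$valid} iff zero errors.
#' @export
validate_bundle <- function(registry, bundle) {
  stopifnot(inherits(bundle, "benchmark_bundle"))
  vs <- list()
  visited <- new.env(parent = emptyenv())
  mark <- function(cls, id) {
    assign(paste0(cls, "\r", id), TRUE, envir = visited)
  }
  seen <- function(cls, id) {
    exists(paste0(cls, "\r", id), envir = visited)
  }
  lookup <- function(cls, id) bundle$entities[[cls]][[id]]

  ref_ids <- function(ent, field) {
    v <- ent$fields[[field]]
    if (is.null(v) || is_raw_value(v)) character(0) else as.character(v)
  }

  check_refs <- function(ent, path, field, cls) {
    ids <- ref_ids(ent, field)
    ok <- character(0)
    for (id in ids) {
      if (is.null(lookup(cls, id))) {
        vs[[length(vs) + 1L]] <<- violation("REF_DANGLING", path, paste0(
          ent$class_name, ".", field, ": no ", cls, " with ID '", id,
          "' in bundle"))
      } else {
        ok <- c(ok, id)
      }
    }
    ok
  }

  check_card <- function(ent, path, field, what) {
    if (!field %in% names(ent$fields)) return(invisible())  # REQ_MISSING fires
    v <- ent$fields[[field]]
    n <- if (is_raw_value(v)) 0L else length(v)
    if (n < 1L) {
      vs[[length(vs) + 1L]] <<- violation("CARDINALITY", path, paste0(
        ent$class_name, ".", field, ": must be at least one ", what))
    }
  }

  for (pid in sort_c(names(bundle$entities$Project))) {
    proj <- lookup("Project", pid)
    ppath <- paste0("project/", pid)
    mark("Project", pid)
    vs <- c(vs, entity_violations(registry, proj, ppath))
    check_card(proj, ppath, "Collections", "Collection")
    check_card(proj, ppath, "Experiments", "Experiment")
    check_card(proj, ppath, "Channels", "Channel")
    check_card(proj, ppath, "PointOfContact", "point of contact")
    check_card(proj, ppath, "Contributor", "contributor")
    check_refs(proj, ppath, "Experiments", "Experiment")
    check_refs(proj, ppath, "Channels", "Channel")

    frame_labels <- character(0)
    for (cid in check_refs(proj, ppath, "Collections", "Collection")) {
      coll <- lookup("Collection", cid)
      cpath <- paste0(ppath, "/collections/", cid)
      mark("Collection", cid)
      vs <- c(vs, entity_violations(registry, coll, cpath))
      check_card(coll, cpath, "Experiments", "Experiment")
      vs <- c(vs, subset_violations(registry, coll, proj, cpath))

      for (eid in check_refs(coll, cpath, "Experiments", "Experiment")) {
        expm <- lookup("Experiment", eid)
        epath <- paste0(cpath, "/experiments/", eid)
        mark("Experiment", eid)
        vs <- c(vs, entity_violations(registry, expm, epath))
        check_card(expm, epath, "Channels", "Channel")
        vs <- c(vs, subset_violations(registry, expm, coll, epath))

        bl <- expm$fields$BrainLocation
        if (inherits(bl, "benchmark_entity") &&
            is.character(bl$fields$ReferenceFrame)) {
          frame_labels <- c(frame_labels, bl$fields$ReferenceFrame)
        }

        frame <- NULL
        fid <- check_refs(expm, epath, "CoordinateFrame", "CoordinateFrame")
        if (length(fid) == 1L) {
          frame <- lookup("CoordinateFrame", fid)
          if (!seen("CoordinateFrame", fid)) {
            mark("CoordinateFrame", fid)
            vs <- c(vs, entity_violations(
              registry, frame, paste0("coordinate_frame/", fid)))
          }
        }

        channels <- list()
        for (chid in check_refs(expm, epath, "Channels", "Channel")) {
          ch <- lookup("Channel", chid)
          chpath <- paste0(epath, "/channels/", chid)
          if (!seen("Channel", chid)) {
            mark("Channel", chid)
            vs <- c(vs, entity_violations(registry, ch, chpath))
          }
          vs <- c(vs, subset_violations(registry, ch, expm, chpath))
          check_refs(ch, chpath, "CoordinateFrame", "CoordinateFrame")
          channels[[chid]] <- ch
        }
        # frame geometry already validated at its own path above
        vs <- c(vs, check_coordinate_consistency(registry, expm, channels,
                                                 frame = NULL,
                                                 path = epath))
      }
    }
    if (length(unique(frame_labels)) > 1L) {
      vs[[length(vs) + 1L]] <- violation("FRAME_REFERENCE_MIXED", ppath, paste0(
        "experiments carry differing reference-frame labels: ",
        paste(sort_c(unique(frame_labels)), collapse = ", ")))
    }
  }

  # entities not reachable from any project are still validated
  for (cls in names(bundle$entities)) {
    for (id in sort_c(names(bundle$entities[[cls]]))) {
      if (seen(cls, id)) next
      vs <- c(vs, entity_violations(registry, lookup(cls, id),
                                    paste0(tolower(cls), "/", id)))
    }
  }
  new_report(vs)
}

# --- subset constraints ----------------------------------------------------

facet_fields <- c(creators = "Creator", licenses = "License",
                  identifiers = "Identifiers")

#' Check the hierarchical subset constraint on one facet
#'
#' The standard permits collections, experiments and channels to carry their
#' own creators, licenses and identifiers so long as each is a subset of the
#' owning parent's. Element equality is identifier-first (a contributor's
#' NameIdentifier, a license's RightsIdentifier) with a case-folded,
#' whitespace-trimmed name fallback.
#'
#' @inheritParams describe_class
#' @param child,parent \code{benchmark_entity} values exposing the facet.
#' @param facet One of \code{"creators"}, \code{"licenses"},
#'   \code{"identifiers"}.
#' @param path Entity path attributed to violations (defaults to the child's).
#' @return List of \code{SUBSET_*} violations, one per child element absent
#'   from the parent; an empty child facet never violates.
#' @export
check_subset_constraint <- function(registry, child, parent, facet,
                                    path = default_path(child)) {
  facet <- match.arg(facet, names(facet_fields))
  child_keys <- facet_keys(child, facet)
  parent_keys <- facet_keys(parent, facet)
  code <- paste0("SUBSET_", switch(facet, creators = "CREATORS",
                                   licenses = "LICENSE",
                                   identifiers = "IDENTIFIERS"))
  vs <- list()
  for (k in names(child_keys)) {
    if (!k %in% names(parent_keys)) {
      vs[[length(vs) + 1L]] <- violation(code, path, paste0(
        child$class_name, " ", facet, " element '", child_keys[[k]],
        "' is not among the parent ", parent$class_name, "'s ", facet))
    }
  }
  vs
}

subset_violations <- function(registry, child, parent, path) {
  unlist(lapply(names(facet_fields), function(facet) {
    check_subset_constraint(registry, child, parent, facet, path = path)
  }), recursive = FALSE)
}

# Named vector: normalized equality key -> display label.
facet_keys <- function(entity, facet) {
  field <- facet_fields[[facet]]
  val <- entity$fields[[field]]
  if (entity$class_name == "Project" && facet == "creators") {
    # the project's creator set: its Creator plus any contributor whose
    # Creator flag marks them a dataset creator
    flagged <- Filter(function(ct) {
      inherits(ct, "benchmark_entity") && isTRUE(ct$fields$Creator)
    }, entity$fields$Contributor %||% list())
    val <- c(list(val), flagged)
  }
  if (entity$class_name == "Project" && facet == "identifiers") {
    # the project level carries its persistent identifier in UniqueIdentifier
    ui <- entity$fields$UniqueIdentifier
    uris <- if (inherits(ui, "benchmark_entity")) {
      as.character(ui$fields$URI %||% character(0))
    } else character(0)
    val <- c(uris, entity$fields$ID %||% character(0))
  }
  if (is.null(val) || is_raw_value(val)) return(character(0))
  items <- if (is.list(val)) val else as.list(as.character(val))
  if (inherits(val, "benchmark_entity")) items <- list(val)
  keys <- character(0)
  for (item in items) {
    if (inherits(item, "benchmark_entity")) {
      lab <- switch(item$class_name,
        Contributor = item$fields$NameIdentifier %||%
          (item$fields$Name %||% "")[1L],
        License = item$fields$RightsIdentifier %||%
          item$fields$Rights %||% "",
        item$id %||% "")
    } else {
      lab <- as.character(item)[1L]
    }
    if (is.null(lab) || length(lab) == 0L || is.na(lab) || !nzchar(lab)) next
    keys[normalize_label(lab)] <- lab
  }
  keys
}

# Equality normalization for subset checks: UTF-8, trimmed, case-folded.
normalize_label <- function(x) tolower(trimws(enc2utf8(x)))

#' Check channel/experiment coordinate-frame agreement
#'
#' Every channel of an experiment must reference the experiment's (single)
#' coordinate frame; frames are compared by ID. When the frame entity itself
#' is supplied its axis extents are additionally checked for degeneracy.
#'
#' @inheritParams describe_class
#' @param experiment Experiment entity (one \code{CoordinateFrame} reference).
#' @param channels Named list of channel entities keyed by channel ID.
#' @param frame Optional resolved \code{CoordinateFrame} entity.
#' @param path Experiment path used as the violation path prefix.
#' @return List of \code{COORD_MISMATCH} / \code{EXTENT_DEGENERATE}
#'   violations.
#' @export
check_coordinate_consistency <- function(registry, experiment, channels,
                                         frame = NULL,
                                         path = default_path(experiment)) {
  vs <- list()
  eid <- experiment$fields$CoordinateFrame
  eid <- if (is.null(eid) || is_raw_value(eid)) NA_character_ else
    as.character(eid)[1L]
  for (chid in names(channels)) {
    ch <- channels[[chid]]
    cid <- ch$fields$CoordinateFrame
    cid <- if (is.null(cid) || is_raw_value(cid)) NA_character_ else
      as.character(cid)[1L]
    if (!is.na(eid) && !is.na(cid) && !identical(cid, eid)) {
      vs[[length(vs) + 1L]] <- violation(
        "COORD_MISMATCH", paste0(path, "/channels/", chid), paste0(
          "channel frame '", cid, "' differs from experiment frame '",
          eid, "'"))
    }
  }
  if (!is.null(frame)) {
    vs <- c(vs, geometry_violations(frame, paste0("coordinate_frame/",
                                                  frame$id %||% "?")))
  }
  vs
}
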