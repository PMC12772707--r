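# In-memory faceted index over validated bundles, approximating the
# programmatic metadata access of an archive's query service. Only bundles
# with zero validation errors are indexable; indexing the same bundle set
# always rebuilds the identical catalog.

.catalog_facets <- c("species", "modality", "year", "contributor",
                     "region", "public")

#' Build a catalog over validated metadata bundles
#'
#' @inheritParams describe_class
#' @param bundles List of \code{benchmark_bundle} objects.
#' @return A \code{benchmark_catalog} indexing every project by the facets
#'   \code{species}, \code{modality}, \code{year}, \code{contributor},
#'   \code{region} and \code{public}; string facet values are case-folded.
#'   A bundle with validation errors is rejected with its report printed in
#'   the error message.
#' @export
index_bundles <- function(registry, bundles) {
  if (inherits(bundles, "benchmark_bundle")) bundles <- list(bundles)
  entries <- list()
  for (i in seq_along(bundles)) {
    b <- bundles[[i]]
    rep <- validate_bundle(registry, b)
    if (!rep$valid) {
      msgs <- vapply(rep$violations[vapply(rep$violations, `[[`, "",
                                           "severity") == "error"],
                     function(v) paste0(v$rule_code, " @ ", v$entity_path),
                     "")
      stop("bundle ", i, " has ", rep$counts[["error"]],
           " validation error(s) and cannot be indexed:\n  ",
           paste(msgs, collapse = "\n  "), call. = FALSE)
    }
    for (pid in sort_c(names(b$entities$Project))) {
      entries[[pid]] <- project_facets(registry, b, pid)
    }
  }
  structure(list(entries = entries[sort_c(names(entries))],
                 facets = .catalog_facets),
            class = "benchmark_catalog")
}

project_facets <- function(registry, bundle, pid) {
  proj <- bundle$entities$Project[[pid]]
  f <- proj$fields
  contribs <- c(list(f$Creator), f$PointOfContact, f$Contributor)
  contrib_names <- unique(unlist(lapply(contribs, function(ct) {
    if (inherits(ct, "benchmark_entity")) as.character(ct$fields$Name)
  })))
  regions <- unlist(lapply(f$ImageLocations, function(bl) {
    if (inherits(bl, "benchmark_entity")) bl$fields$RegionName
  }))
  for (eid in as.character(f$Experiments %||% character(0))) {
    ex <- bundle$entities$Experiment[[eid]]
    bl <- ex$fields$BrainLocation
    if (inherits(bl, "benchmark_entity")) {
      regions <- c(regions, bl$fields$RegionName)
    }
  }
  year <- suppressWarnings(as.integer(substr(f$Year %||% "", 1L, 4L)))
  list(
    project_id = pid,
    title = f$Title %||% "",
    species = normalize_label(as.character(f$Species %||% character(0))),
    modality = normalize_label(as.character(
      f$ImagingModalities %||% character(0))),
    year = year,
    contributor = normalize_label(contrib_names %||% character(0)),
    region = normalize_label(unique(regions) %||% character(0)),
    public = isTRUE(f$Public),
    n_collections = length(f$Collections),
    n_experiments = length(f$Experiments),
    n_channels = length(f$Channels)
  )
}

#' Query a catalog with conjunctive facet filters
#'
#' @param catalog A \code{benchmark_catalog}.
#' @param filters Named list of facet filters; keys must be facets of the
#'   catalog. String matching is case-folded; all filters must match
#'   (conjunction). An empty filter returns every project.
#' @return Data frame of project summaries ordered by project ID, one row
#'   per matching project (\code{project_id}, \code{title}, \code{species},
#'   \code{modality}, \code{year}, \code{public}, entity counts).
#' @examples
#' \dontrun{
#' query_catalog(cat, list(species = "Drosophila", year = 2019))
#' }
#' @export
query_catalog <- function(catalog, filters = list()) {
  stopifnot(inherits(catalog, "benchmark_catalog"))
  if (length(filters) > 0L &&
      (is.null(names(filters)) || !all(names(filters) %in% catalog$facets))) {
    stop("unknown facet key(s): ",
         paste(setdiff(names(filters), catalog$facets), collapse = ", "),
         "; valid facets: ", paste(catalog$facets, collapse = ", "),
         call. = FALSE)
  }
  hit <- vapply(catalog$entries, function(e) {
    for (k in names(filters)) {
      want <- filters[[k]]
      got <- e[[k]]
      match_one <- if (k == "year") {
        !is.na(got) && got %in% as.integer(want)
      } else if (k == "public") {
        identical(got, isTRUE(want))
      } else {
        any(normalize_label(as.character(want)) %in% got)
      }
      if (!match_one) return(FALSE)
    }
    TRUE
  }, TRUE)
  rows <- catalog$entries[hit]
  df <- data.frame(
    project_id = vapply(rows, `[[`, "", "project_id"),
    title = vapply(rows, `[[`, "", "title"),
    species = vapply(rows, function(e) paste(e$species, collapse = ";"), ""),
    modality = vapply(rows, function(e) paste(e$modality, collapse = ";"), ""),
    year = vapply(rows, `[[`, 0L, "year"),
    public = vapply(rows, `[[`, TRUE, "public"),
    n_collections = vapply(rows, `[[`, 0L, "n_collections"),
    n_experiments = vapply(rows, `[[`, 0L, "n_experiments"),
    n_channels = vapply(rows, `[[`, 0L, "n_channels"),
    stringsAsFactors = FALSE
  )
  rownames(df) <- NULL
  df[order(df$project_id, method = "radix"), , drop = FALSE]
}

#' @export
print.benchmark_catalog <- function(x, ...) {
  cat("<benchmark_catalog>", length(x$entries), "project(s); facets:",
      paste(x$facets, collapse = ", "), "\n")
  invisible(x)
}

#' Number of projects in a catalog
#' @param catalog A \code{benchmark_catalog}.
#' @return Integer count.
#' @export
catalog_size <- function(catalog) length(catalog$entries)
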