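# Syntax-only checking of persistent identifiers. No network resolution:
# validation stays offline and deterministic.

#' Identifier schemes known to the syntax checker
#'
#' @return Character vector of scheme names accepted by
#'   \code{\link{validate_identifier}}. \code{"GRID"} is accepted as an
#'   alias of \code{"GRDI"} (the registered enum member) and normalized.
#' @export
identifier_schemes <- function() {
  c("GRDI", "GRID", "ISNI", "ORCID", "ROR", "RRID",
    "DOI", "PMID", "arXiv", "ISBN", "Other")
}

#' Check a persistent identifier's syntax
#'
#' Scheme-specific checks: ORCID and ISNI are 16 characters whose last is an
#' ISO 7064 mod 11-2 check character over the first 15 digits; DOI matches
#' \code{10.<registrant>/<suffix>}; ROR is \code{0} followed by 8 Crockford
#' base-32 characters (an optional \code{https://ror.org/} prefix is
#' stripped); RRID requires the \code{RRID:} prefix; PMID is all digits;
#' arXiv accepts the modern \code{YYMM.NNNNN[vN]} and legacy
#' \code{archive/NNNNNNN} forms; ISBN is 10 or 13 characters after removing
#' separators; GRDI uses the \code{grid.<code>.<suffix>} form; Other merely
#' requires a non-blank value.
#'
#' @param scheme One of \code{\link{identifier_schemes}}.
#' @param value Identifier string.
#' @return List with \code{valid} (logical), \code{normalized} (canonical
#'   form, e.g. hyphenated ORCID; \code{NA} when invalid) and \code{message}.
#' @examples
#' validate_identifier("ORCID", "0000-0002-1825-0097")$valid  # TRUE
#' validate_identifier("DOI", "10.1234/abcd")$normalized
#' @export
validate_identifier <- function(scheme, value) {
  if (!is.character(scheme) || length(scheme) != 1L ||
      !scheme %in% identifier_schemes()) {
    stop("unknown identifier scheme '", paste(scheme, collapse = ","),
         "'; known schemes: ", paste(identifier_schemes(), collapse = ", "),
         call. = FALSE)
  }
  stopifnot(is.character(value), length(value) == 1L)
  value <- trimws(value)
  res <- switch(scheme,
    ORCID = check_mod11_2(value, hyphenate = TRUE, label = "ORCID"),
    ISNI  = check_mod11_2(value, hyphenate = FALSE, label = "ISNI"),
    DOI   = check_pattern(value, "^10\\.[0-9]{4,9}/\\S+$", tolower(value),
                          "expected 10.<registrant>/<suffix>"),
    ROR   = check_ror(value),
    RRID  = check_rrid(value),
    PMID  = check_pattern(value, "^[0-9]{1,8}$", value, "expected digits"),
    arXiv = check_arxiv(value),
    ISBN  = check_isbn(value),
    GRDI  = check_grid(value),
    GRID  = check_grid(value),
    Other = if (nzchar(value)) ok(value) else
      bad("identifier must be non-empty")
  )
  res
}

ok <- function(normalized) {
  list(valid = TRUE, normalized = normalized, message = "ok")
}
bad <- function(message) {
  list(valid = FALSE, normalized = NA_character_, message = message)
}

check_pattern <- function(value, pattern, normalized, hint) {
  if (grepl(pattern, value)) ok(normalized) else bad(hint)
}

#' ISO 7064 mod 11-2 check character
#'
#' Computes the check character over a string of base digits using the
#' recurrence total = (total + digit) * 2 and check = (12 - total mod 11)
#' mod 11, with 10 written as \code{"X"}. This is the checksum scheme of
#' ORCID and ISNI identifiers.
#'
#' @param digits String of decimal digits (the identifier without its final
#'   check character).
#' @return Single character: \code{"0"}--\code{"9"} or \code{"X"}.
#' @export
iso7064_mod11_2_check <- function(digits) {
  stopifnot(grepl("^[0-9]+$", digits))
  total <- 0L
  for (d in as.integer(strsplit(digits, "")[[1L]])) {
    total <- ((total + d) * 2L) %% 11L
  }
  r <- (12L - total) %% 11L
  if (r == 10L) "X" else as.character(r)
}

check_mod11_2 <- function(value, hyphenate, label) {
  compact <- toupper(gsub("[- ]", "", value))
  if (!grepl("^[0-9]{15}[0-9X]$", compact)) {
    return(bad(paste("expected 16 characters (15 digits + check), got '",
                     compact, "'")))
  }
  expect <- iso7064_mod11_2_check(substr(compact, 1L, 15L))
  if (substr(compact, 16L, 16L) != expect) {
    return(bad(paste0("check character mismatch: expected ", expect)))
  }
  norm <- if (hyphenate) {
    paste(substring(compact, c(1, 5, 9, 13), c(4, 8, 12, 16)), collapse = "-")
  } else {
    compact
  }
  ok(norm)
}

check_ror <- function(value) {
  id <- tolower(sub("^https?://ror\\.org/", "", value))
  # Crockford base-32: 0-9 a-z excluding i, l, o, u
  check_pattern(id, "^0[0-9a-hj-km-np-tv-z]{8}$", id,
                "expected '0' + 8 base-32 characters")
}

check_rrid <- function(value) {
  if (!grepl("^RRID:\\s*\\S+$", value)) {
    return(bad("expected 'RRID:' prefix followed by a resource identifier"))
  }
  ok(paste0("RRID:", trimws(sub("^RRID:", "", value))))
}

check_arxiv <- function(value) {
  v <- sub("^arXiv:", "", value)
  if (grepl("^[0-9]{4}\\.[0-9]{4,5}(v[0-9]+)?$", v) ||
      grepl("^[a-z-]+(\\.[A-Z]{2})?/[0-9]{7}$", v)) {
    return(ok(v))
  }
  bad("expected YYMM.NNNNN[vN] or archive/NNNNNNN")
}

check_isbn <- function(value) {
  compact <- toupper(gsub("[- ]", "", value))
  if (grepl("^[0-9]{13}$", compact) || grepl("^[0-9]{9}[0-9X]$", compact)) {
    return(ok(compact))
  }
  bad("expected 10 or 13 characters after removing separators")
}

check_grid <- function(value) {
  check_pattern(tolower(value), "^grid\\.[0-9]{4,6}\\.[0-9a-z]{1,3}$",
                tolower(value), "expected grid.<code>.<suffix>")
}
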