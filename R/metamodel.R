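# Core metamodel machinery: prefix maps and CURIE <-> URI conversion, the
# cardinality grammar, the four-element registry, and semantic mappings.

PREFIX_RE <- "^[A-Za-z][A-Za-z0-9_.-]*$"

#' Construct a prefix map
#'
#' A prefix map associates short namespace prefixes (e.g. `ENVO`, `schema`)
#' with URI bases, enabling compact identifiers (CURIEs) of the form
#' `prefix:local` to be expanded to full URIs and contracted back.
#'
#' @param ... Named arguments or a single named list/character vector of
#'   `prefix = base` entries.
#' @return An object of class `prefix_map` (a named character vector).
#' @examples
#' pm <- prefix_map(ex = "https://example.org/")
#' expand_curie("ex:foo", pm)
#' @export
prefix_map <- function(...) {
  args <- list(...)
  if (length(args) == 1L && is.null(names(args)) ||
      (length(args) == 1L && (is.list(args[[1]]) || length(args[[1]]) > 1L) &&
       !is.null(names(args[[1]])))) {
    entries <- unlist(args[[1]])
  } else {
    entries <- unlist(args)
  }
  if (is.null(entries)) entries <- character(0)
  entries <- vapply(entries, as.character, character(1))
  nms <- names(entries)
  if (length(entries) > 0 && (is.null(nms) || any(nms == "")))
    sk_stop("all prefix map entries must be named", "bad_prefix")
  if (anyDuplicated(nms))
    sk_stop(sprintf("duplicate prefix: %s", nms[duplicated(nms)][1]), "bad_prefix")
  bad <- nms[!grepl(PREFIX_RE, nms)]
  if (length(bad) > 0)
    sk_stop(sprintf("invalid prefix name: '%s'", bad[1]), "bad_prefix")
  if (any(!nzchar(entries)))
    sk_stop("prefix base URIs must be non-empty", "bad_prefix")
  structure(entries, class = "prefix_map")
}

#' @export
print.prefix_map <- function(x, ...) {
  cat("<prefix_map> ", length(x), " entries\n", sep = "")
  for (p in names(x)) cat("  ", p, " -> ", x[[p]], "\n", sep = "")
  invisible(x)
}

# a CURIE is prefix ":" local; local may be empty; "://" marks a full URI
is_curie <- function(x) {
  is_string(x) && grepl("^[A-Za-z][A-Za-z0-9_.-]*:", x) && !grepl("://", x, fixed = TRUE)
}

is_full_uri <- function(x) {
  is_string(x) && (grepl("://", x, fixed = TRUE) || grepl("^urn:", x))
}

#' Expand a CURIE to a full URI
#'
#' @param curie A compact identifier `prefix:local`. Full URIs pass through
#'   unchanged.
#' @param prefixes A [prefix_map()].
#' @param strict If `TRUE` (default) an unregistered prefix is an error; if
#'   `FALSE` it is a warning and the CURIE passes through unchanged.
#' @return The expanded URI string.
#' @export
expand_curie <- function(curie, prefixes, strict = TRUE) {
  if (!is_string(curie))
    sk_stop("curie must be a single string", "malformed_curie")
  if (is_full_uri(curie)) return(curie)
  if (!grepl(":", curie, fixed = TRUE))
    sk_stop(sprintf("malformed CURIE (no colon): '%s'", curie), "malformed_curie")
  parts <- regmatches(curie, regexpr(":", curie, fixed = TRUE), invert = TRUE)[[1]]
  prefix <- parts[1]
  local <- parts[2]
  if (!grepl(PREFIX_RE, prefix))
    sk_stop(sprintf("malformed CURIE prefix: '%s'", prefix), "malformed_curie")
  if (!prefix %in% names(prefixes)) {
    if (strict)
      sk_stop(sprintf("unknown prefix: '%s'", prefix), "unknown_prefix")
    sk_warn(sprintf("unknown prefix '%s'; passing CURIE through", prefix), "unknown_prefix")
    return(curie)
  }
  paste0(unname(prefixes[[prefix]]), local)
}

#' Contract a URI to a CURIE
#'
#' The longest matching registered base wins. Total: when no base matches,
#' the input is returned unchanged with `matched = FALSE`.
#'
#' @param uri A URI string.
#' @param prefixes A [prefix_map()].
#' @return A list with elements `value` (CURIE or original URI) and
#'   `matched` (logical).
#' @export
contract_uri <- function(uri, prefixes, strict = TRUE) {
  if (!is_string(uri)) sk_stop("uri must be a single string", "malformed_curie")
  hits <- names(prefixes)[startsWith(uri, unname(unclass(prefixes)))]
  if (length(hits) == 0L) return(list(value = uri, matched = FALSE))
  lens <- nchar(unname(prefixes[hits]))
  best <- hits[order(-lens, hits)][1]
  local <- substring(uri, nchar(prefixes[[best]]) + 1L)
  list(value = paste0(best, ":", local), matched = TRUE)
}

UNBOUNDED <- Inf

#' Parse a cardinality token
#'
#' Multiplicity grammar for tabular schema authoring: `"n"` means exactly n,
#' `"n..m"` a bounded range, `"n..*"` n or more. The typographic two-dot
#' leader (\code{‥}) and horizontal ellipsis (\code{…}) are accepted
#' as separators, as they appear in print.
#'
#' @param token Cardinality string, e.g. `"0..1"`, `"1"`, `"0..*"`.
#' @return A `cardinality` object: list with integer `min` and `max`
#'   (`Inf` when unbounded).
#' @examples
#' parse_cardinality("0..1")  # min 0, max 1
#' parse_cardinality("0..*")  # min 0, max Inf
#' @export
parse_cardinality <- function(token) {
  if (!is_string(token)) sk_stop("cardinality token must be a string", "malformed_cardinality")
  tok <- trimws(token)
  tok <- gsub("‥|…", "..", tok)
  if (!nzchar(tok)) sk_stop("empty cardinality token", "malformed_cardinality")
  if (grepl("^[0-9]+$", tok)) {
    n <- as.integer(tok)
    return(cardinality(n, n))
  }
  m <- regmatches(tok, regexec("^([0-9]+)\\.\\.([0-9]+|\\*)$", tok))[[1]]
  if (length(m) == 0L)
    sk_stop(sprintf("malformed cardinality token: '%s'", token), "malformed_cardinality")
  lo <- as.integer(m[2])
  hi <- if (m[3] == "*") UNBOUNDED else as.integer(m[3])
  if (is.finite(hi) && lo > hi)
    sk_stop(sprintf("cardinality min > max in '%s'", token), "malformed_cardinality")
  cardinality(lo, hi)
}

#' @rdname parse_cardinality
#' @param min,max Bounds; `max = Inf` for unbounded.
#' @export
cardinality <- function(min, max) {
  if (min < 0) sk_stop("cardinality min must be >= 0", "malformed_cardinality")
  if (is.finite(max) && (max < 1 || min > max))
    sk_stop("cardinality max must be >= 1 and >= min", "malformed_cardinality")
  structure(list(min = as.integer(min), max = if (is.finite(max)) as.integer(max) else UNBOUNDED),
            class = "cardinality")
}

#' Render a cardinality back to its token form
#' @param card A `cardinality` object.
#' @export
format_cardinality <- function(card) {
  stopifnot(inherits(card, "cardinality"))
  if (!is.finite(card$max)) return(paste0(card$min, "..*"))
  if (card$min == card$max) return(as.character(card$min))
  paste0(card$min, "..", card$max)
}

#' @export
print.cardinality <- function(x, ...) {
  cat("<cardinality> ", format_cardinality(x), "\n", sep = "")
  invisible(x)
}

#' The four core schema element kinds
#'
#' Schemas are built from exactly four element categories: classes (entity
#' types), slots (attributes), types (scalar value types) and enums
#' (controlled vocabularies).
#'
#' @return Character vector of the four kind names.
#' @export
element_kinds <- function() c("class", "slot", "type", "enum")

MAPPING_PREDICATES <- c("exact", "close", "broad", "narrow", "related")

#' Construct a semantic mapping
#'
#' Aligns a schema element with an external vocabulary term (by CURIE),
#' qualified by a SKOS-style predicate.
#'
#' @param predicate One of `"exact"`, `"close"`, `"broad"`, `"narrow"`,
#'   `"related"`.
#' @param target A syntactically valid CURIE, e.g. `"ENVO:00001998"`.
#' @export
mapping <- function(predicate, target) {
  predicate <- match.arg(predicate, MAPPING_PREDICATES)
  if (!is_curie(target))
    sk_stop(sprintf("mapping target is not a valid CURIE: '%s'", target), "malformed_curie")
  structure(list(predicate = predicate, target = target), class = "sk_mapping")
}
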