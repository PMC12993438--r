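# Reading and writing schema YAML, plus import resolution and merging.
#
# Parsing is tolerant of unknown keys: they are preserved in per-element
# `annotations` and surfaced via attr(schema, "parse_warnings") rather than
# dropped, so round-tripping never silently loses information.

SCHEMA_KEYS <- c("id", "name", "title", "license", "description", "prefixes",
                 "imports", "default_range", "classes", "slots", "enums", "types")
CLASS_KEYS <- c("description", "is_a", "mixins", "abstract", "slots",
                "attributes", "slot_usage", "class_uri")
SLOT_KEYS <- c("description", "range", "required", "multivalued", "identifier",
               "pattern", "slot_uri", "unit",
               "minimum_cardinality", "maximum_cardinality")
ENUM_KEYS <- c("description", "permissible_values", "case_insensitive")
TYPE_KEYS <- c("base", "uri", "pattern", "description")
MAPPING_KEYS <- paste0(MAPPING_PREDICATES, "_mappings")

#' Parse a schema from YAML text
#'
#' @param text A YAML document as a single string or character vector of
#'   lines.
#' @return A `schema_definition`; parse warnings (unrecognized keys) are
#'   attached as `attr(x, "parse_warnings")`.
#' @seealso [read_schema()] to parse from a file, [emit_schema()] for the
#'   inverse.
#' @export
parse_schema <- function(text) {
  if (length(text) > 1L) text <- paste(text, collapse = "\n")
  raw <- tryCatch(
    yaml::yaml.load(text),
    error = function(e) {
      if (grepl("Duplicate map key", conditionMessage(e)))
        sk_stop(conditionMessage(e), "duplicate_element_name")
      sk_stop(paste("YAML syntax error:", conditionMessage(e)), "yaml_error")
    }
  )
  if (!is.list(raw) || is.null(names(raw)))
    sk_stop("schema document root must be a YAML mapping", "yaml_error")
  warnings <- character(0)
  note <- function(msg) warnings[[length(warnings) + 1L]] <<- msg

  if (is.null(raw$id)) sk_stop("schema has no id", "missing_schema_id")

  take_annotations <- function(node, known, where) {
    unknown <- setdiff(names(node), c(known, MAPPING_KEYS))
    if (length(unknown) == 0L) return(list())
    note(sprintf("unrecognized key(s) in %s preserved as annotations: %s",
                 where, paste(unknown, collapse = ", ")))
    node[unknown]
  }
  take_mappings <- function(node) {
    out <- list()
    for (pred in MAPPING_PREDICATES) {
      key <- paste0(pred, "_mappings")
      for (tgt in node[[key]]) out[[length(out) + 1L]] <- mapping(pred, tgt)
    }
    out
  }
  parse_slot <- function(name, node) {
    if (is.null(node)) node <- list()
    s <- slot_definition(
      name = name,
      description = node$description, range = node$range,
      required = if (is.null(node$required)) NA else isTRUE(node$required),
      multivalued = if (is.null(node$multivalued)) NA else isTRUE(node$multivalued),
      identifier = if (is.null(node$identifier)) NA else isTRUE(node$identifier),
      pattern = node$pattern, slot_uri = node$slot_uri, unit = node$unit,
      mappings = take_mappings(node),
      minimum_cardinality = node$minimum_cardinality,
      maximum_cardinality = node$maximum_cardinality
    )
    s$annotations <- take_annotations(node, SLOT_KEYS, sprintf("slot '%s'", name))
    s
  }
  parse_class <- function(name, node) {
    if (is.null(node)) node <- list()
    attrs <- list()
    for (a in names(node$attributes)) attrs[[a]] <- parse_slot(a, node$attributes[[a]])
    usage <- list()
    for (u in names(node$slot_usage)) {
      part <- node$slot_usage[[u]]
      unknown <- setdiff(names(part), SLOT_KEYS)
      if (length(unknown) > 0)
        note(sprintf("unrecognized slot_usage key(s) for '%s' in class '%s': %s",
                     u, name, paste(unknown, collapse = ", ")))
      usage[[u]] <- part
    }
    cl <- class_definition(
      name = name, description = node$description, is_a = node$is_a,
      mixins = as.character(node$mixins %||% character(0)),
      abstract = isTRUE(node$abstract),
      slots = as.character(node$slots %||% character(0)),
      attributes = attrs, slot_usage = usage,
      class_uri = node$class_uri, mappings = take_mappings(node)
    )
    cl$annotations <- take_annotations(node, CLASS_KEYS, sprintf("class '%s'", name))
    cl
  }
  parse_enum <- function(name, node) {
    if (is.null(node)) node <- list()
    pvs <- list()
    for (pv in names(node$permissible_values)) {
      entry <- node$permissible_values[[pv]]
      if (is.null(entry)) entry <- list()
      pvs[[pv]] <- list(description = entry$description, meaning = entry$meaning)
    }
    e <- enum_definition(name, description = node$description,
                         permissible_values = pvs,
                         case_insensitive = isTRUE(node$case_insensitive))
    e$annotations <- take_annotations(node, ENUM_KEYS, sprintf("enum '%s'", name))
    e
  }
  parse_type <- function(name, node) {
    if (is.null(node)) node <- list()
    t <- type_definition(name, base = node$base %||% "string",
                         uri = node$uri, pattern = node$pattern,
                         description = node$description)
    t$annotations <- take_annotations(node, TYPE_KEYS, sprintf("type '%s'", name))
    t
  }
  parse_category <- function(key, fn) {
    out <- list()
    nodes <- raw[[key]]
    if (length(nodes) > 0 && is.null(names(nodes)))
      sk_stop(sprintf("'%s' must be a mapping of name -> definition", key), "yaml_error")
    for (nm in names(nodes)) out[[nm]] <- fn(nm, nodes[[nm]])
    out
  }

  schema <- schema_definition(
    id = as.character(raw$id), name = as.character(raw$name %||% raw$id),
    title = raw$title, license = raw$license, description = raw$description,
    prefixes = prefix_map(raw$prefixes %||% list()),
    imports = as.character(raw$imports %||% character(0)),
    default_range = raw$default_range,
    classes = parse_category("classes", parse_class),
    slots = parse_category("slots", parse_slot),
    enums = parse_category("enums", parse_enum),
    types = parse_category("types", parse_type),
    annotations = take_annotations(raw, SCHEMA_KEYS, "schema")
  )
  attr(schema, "parse_warnings") <- warnings
  schema
}

#' Read a schema from a YAML file
#' @param path Path to a schema YAML file.
#' @export
read_schema <- function(path) {
  if (!file.exists(path)) sk_stop(sprintf("schema file not found: %s", path), "io_error")
  parse_schema(readLines(path, encoding = "UTF-8", warn = FALSE))
}

# -- emission ----------------------------------------------------------------

compact <- function(x) {
  x[!vapply(x, function(v) is.null(v) || (is.logical(v) && length(v) == 1L && is.na(v)) ||
              (is.list(v) && length(v) == 0L) ||
              (is.character(v) && length(v) == 0L), logical(1))]
}

mappings_to_yaml <- function(mappings) {
  out <- list()
  for (pred in MAPPING_PREDICATES) {
    tgts <- vapply(Filter(function(m) m$predicate == pred, mappings),
                   function(m) m$target, character(1))
    if (length(tgts) > 0) out[[paste0(pred, "_mappings")]] <- as.list(tgts)
  }
  out
}

slot_to_yaml <- function(s) {
  base <- compact(list(
    description = s$description, range = s$range,
    required = s$required, multivalued = s$multivalued,
    identifier = s$identifier, pattern = s$pattern, slot_uri = s$slot_uri,
    unit = s$unit,
    minimum_cardinality = s$minimum_cardinality,
    maximum_cardinality = s$maximum_cardinality
  ))
  c(base, mappings_to_yaml(s$mappings), s$annotations)
}

class_to_yaml <- function(cl) {
  attrs <- list()
  for (a in names(cl$attributes)) attrs[[a]] <- slot_to_yaml(cl$attributes[[a]])
  base <- compact(list(
    description = cl$description, is_a = cl$is_a,
    mixins = if (length(cl$mixins) > 0) as.list(cl$mixins),
    abstract = if (cl$abstract) TRUE,
    slots = if (length(cl$slots) > 0) as.list(cl$slots),
    attributes = if (length(attrs) > 0) attrs,
    slot_usage = if (length(cl$slot_usage) > 0) cl$slot_usage,
    class_uri = cl$class_uri
  ))
  c(base, mappings_to_yaml(cl$mappings), cl$annotations)
}

enum_to_yaml <- function(e) {
  # permissible values without description/meaning stay as empty mappings so
  # the key itself survives the round-trip
  pv_out <- stats::setNames(lapply(names(e$permissible_values), function(pv) {
    entry <- compact(e$permissible_values[[pv]])
    if (length(entry) > 0) entry else structure(list(), names = character(0))
  }), names(e$permissible_values))
  compact(c(list(description = e$description,
                 permissible_values = if (length(pv_out) > 0) pv_out,
                 case_insensitive = if (e$case_insensitive) TRUE),
            e$annotations))
}

type_to_yaml <- function(t) {
  compact(c(list(description = t$description, base = t$base, uri = t$uri,
                 pattern = t$pattern), t$annotations))
}

#' Serialize a schema to YAML text
#'
#' Key order is fixed (metadata, prefixes, imports, types, enums, slots,
#' classes) so regenerated output is byte-stable, and
#' `parse_schema(emit_schema(s))` is structurally equal to `s`.
#'
#' @param schema A `schema_definition`.
#' @return A single YAML string.
#' @export
emit_schema <- function(schema) {
  stopifnot(inherits(schema, "schema_definition"))
  doc <- compact(list(
    id = schema$id, name = schema$name, title = schema$title,
    license = schema$license, description = schema$description,
    prefixes = if (length(schema$prefixes) > 0) as.list(unclass(schema$prefixes)),
    imports = if (length(schema$imports) > 0) as.list(schema$imports),
    default_range = schema$default_range,
    types = if (length(schema$types) > 0)
      stats::setNames(lapply(schema$types, type_to_yaml), names(schema$types)),
    enums = if (length(schema$enums) > 0)
      stats::setNames(lapply(schema$enums, enum_to_yaml), names(schema$enums)),
    slots = if (length(schema$slots) > 0)
      stats::setNames(lapply(schema$slots, slot_to_yaml), names(schema$slots)),
    classes = if (length(schema$classes) > 0)
      stats::setNames(lapply(schema$classes, class_to_yaml), names(schema$classes))
  ))
  doc <- c(doc, schema$annotations)
  yaml::as.yaml(doc, indent.mapping.sequence = TRUE,
                handlers = list(logical = function(x) {
                  r <- ifelse(x, "true", "false"); class(r) <- "verbatim"; r
                }))
}

#' Write a schema to a YAML file
#' @param schema A `schema_definition`.
#' @param path Output file path.
#' @export
write_schema <- function(schema, path) {
  writeLines(emit_schema(schema), path, useBytes = TRUE)
  invisible(path)
}

#' Structural equality of two schemas
#'
#' Compares the structural model, ignoring bookkeeping attributes such as
#' parse warnings and the resolved-imports flag.
#' @param a,b `schema_definition`s.
#' @export
schemas_equal <- function(a, b) {
  strip <- function(s) {
    attr(s, "parse_warnings") <- NULL
    attr(s, "imports_resolved") <- NULL
    attr(s, "import_warnings") <- NULL
    attr(s, "audit") <- NULL
    s
  }
  isTRUE(all.equal(strip(a), strip(b)))
}

# -- import resolution -------------------------------------------------------

as_resolver <- function(resolver) {
  if (is.function(resolver)) return(resolver)
  if (is.character(resolver) || is.list(resolver)) {
    tbl <- resolver
    return(function(name) {
      if (!name %in% names(tbl)) return(NULL)
      v <- tbl[[name]]
      if (is_string(v) && file.exists(v) && !grepl("\n", v)) {
        paste(readLines(v, encoding = "UTF-8", warn = FALSE), collapse = "\n")
      } else v
    })
  }
  sk_stop("resolver must be a function or a named list/vector", "unresolvable_import")
}

merge_schemas <- function(base, imp, warn) {
  for (p in names(imp$prefixes)) {
    if (p %in% names(base$prefixes)) {
      if (!identical(unname(base$prefixes[[p]]), unname(imp$prefixes[[p]])))
        sk_stop(sprintf("prefix conflict on '%s': '%s' vs '%s'",
                        p, base$prefixes[[p]], imp$prefixes[[p]]), "prefix_conflict")
    } else {
      base$prefixes <- prefix_map(c(unclass(base$prefixes),
                                    stats::setNames(unname(imp$prefixes[p]), p)))
    }
  }
  for (cat in c("classes", "slots", "enums", "types")) {
    for (nm in names(imp[[cat]])) {
      if (nm %in% names(base[[cat]])) {
        warn(sprintf("local %s '%s' shadows imported definition", sub("s$", "", cat), nm))
      } else {
        base[[cat]][[nm]] <- imp[[cat]][[nm]]
      }
    }
  }
  base$default_range <- base$default_range %||% imp$default_range
  base
}

#' Resolve a schema's imports into a single merged schema
#'
#' The import closure is walked depth-first in listed order; the importing
#' schema's definition wins on a name collision (recorded as a warning in
#' `attr(x, "import_warnings")`). Prefix maps are merged with conflict
#' detection. Resolution is idempotent: the result carries no imports.
#'
#' @param schema A `schema_definition`.
#' @param resolver A function `name -> YAML text` (or `schema_definition`),
#'   or a named list/vector mapping import names to YAML texts or file paths.
#' @return The merged `schema_definition` with `imports` emptied.
#' @export
resolve_imports <- function(schema, resolver = list()) {
  resolve <- as_resolver(resolver)
  warnings <- character(0)
  warn <- function(msg) warnings[[length(warnings) + 1L]] <<- msg
  seen <- new.env(parent = emptyenv())

  walk <- function(s, stack) {
    if (s$name %in% stack)
      sk_stop(sprintf("import cycle: %s", paste(c(stack, s$name), collapse = " -> ")),
              "import_cycle")
    out <- s
    for (imp in s$imports) {
      got <- resolve(imp)
      if (is.null(got))
        sk_stop(sprintf("cannot resolve import '%s'", imp), "unresolvable_import")
      imp_schema <- if (inherits(got, "schema_definition")) got else parse_schema(got)
      imp_schema <- walk(imp_schema, c(stack, s$name))
      out <- merge_schemas(out, imp_schema, warn)
    }
    out$imports <- character(0)
    out
  }
  resolved <- walk(schema, character(0))
  attr(resolved, "imports_resolved") <- TRUE
  attr(resolved, "import_warnings") <- warnings
  attr(resolved, "parse_warnings") <- attr(schema, "parse_warnings")
  resolved
}
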