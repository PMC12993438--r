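# Artifact generation from a materialized schema: JSON Schema (draft
# 2020-12), Markdown documentation with a diagram edge list, and minimal SQL
# DDL. Every generator is deterministic for equal inputs and emits a
# machine-readable loss report enumerating what the target formalism cannot
# express.

JSON_SCHEMA_DRAFT <- "https://json-schema.org/draft/2020-12/schema"

# regexes shared with the native type checker so both validation routes agree
TYPE_JSON_PATTERNS <- list(
  uri = ":",
  uriorcurie = ":",
  date = "^[0-9]{4}-[0-9]{2}-[0-9]{2}$",
  datetime = "^[0-9]{4}-[0-9]{2}-[0-9]{2}[T ][0-9]{2}:[0-9]{2}(:[0-9]{2})?"
)

generated_artifact <- function(kind, files) {
  stopifnot(kind %in% c("json_schema", "markdown_docs", "sql_ddl"))
  if (anyDuplicated(names(files)))
    sk_stop("generated artifact has duplicate filenames", "bad_artifact")
  structure(list(kind = kind, files = files), class = "generated_artifact")
}

#' @export
print.generated_artifact <- function(x, ...) {
  cat("<generated_artifact> ", x$kind, ": ",
      paste(names(x$files), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Write a generated artifact's files to a directory
#' @param artifact A `generated_artifact`.
#' @param dir Output directory (created if needed).
#' @export
write_artifact <- function(artifact, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (f in names(artifact$files))
    writeLines(artifact$files[[f]], file.path(dir, f), useBytes = TRUE)
  invisible(file.path(dir, names(artifact$files)))
}

induced_for <- function(ms, class_name) {
  if (!class_name %in% names(ms$induced))
    sk_stop(sprintf("unknown class: '%s'", class_name), "unknown_class")
  ms$induced[[class_name]]
}

slot_scalar_json <- function(ms, def, loss) {
  schema <- ms$source
  rng <- def$range
  if (rng %in% names(schema$classes))
    return(list(node = list("$ref" = paste0("#/$defs/", rng)), loss = loss))
  if (rng %in% names(schema$enums)) {
    node <- list(type = "string",
                 enum = as.list(names(schema$enums[[rng]]$permissible_values)))
    if (schema$enums[[rng]]$case_insensitive)
      loss <- c(loss, sprintf("case-insensitive matching of enum '%s' not expressed in JSON Schema", rng))
    return(list(node = node, loss = loss))
  }
  tb <- resolve_type_base(schema, rng)
  base <- tb$base %||% "string"
  node <- switch(base,
    integer = list(type = "integer"),
    float = list(type = "number"),
    boolean = list(type = "boolean"),
    list(type = "string"))
  pat <- NULL
  if (!is.null(def$pattern)) {
    pat <- paste0("^(?:", def$pattern, ")$")
    if (!is.null(tb$pattern))
      loss <- c(loss, sprintf("slot pattern overrides type pattern of '%s' in JSON Schema", rng))
  } else if (!is.null(tb$pattern)) {
    pat <- paste0("^(?:", tb$pattern, ")$")
  } else if (base %in% names(TYPE_JSON_PATTERNS)) {
    pat <- TYPE_JSON_PATTERNS[[base]]
  }
  if (!is.null(pat) && identical(node$type, "string")) node$pattern <- pat
  list(node = node, loss = loss)
}

#' Generate a JSON Schema for a schema's classes
#'
#' Every class becomes an object definition under `$defs`, built from its
#' induced slots; the document root references `root_class`. Required slots
#' populate `required`, multivalued slots become arrays (with
#' `minItems`/`maxItems` from explicit cardinalities), enums become
#' enumerated string sets, and `additionalProperties` reflects the
#' closed-world flag.
#'
#' @param ms A `materialized_schema`.
#' @param root_class Name of the class instances will be validated against.
#' @param closed Closed-world flag (emitted as `additionalProperties: false`).
#' @return A `generated_artifact` with the schema document and a loss report.
#' @export
gen_json_schema <- function(ms, root_class, closed = TRUE) {
  stopifnot(inherits(ms, "materialized_schema"))
  induced_for(ms, root_class)  # errors early on unknown class
  schema <- ms$source
  loss <- character(0)
  defs <- list()
  for (cn in names(schema$classes)) {
    slots <- ms$induced[[cn]]
    props <- list()
    req <- character(0)
    for (s in slots) {
      def <- s$definition
      sc <- slot_scalar_json(ms, def, loss)
      loss <- sc$loss
      node <- sc$node
      if (def$multivalued) {
        arr <- list(type = "array", items = node)
        if (!is.null(def$minimum_cardinality)) arr$minItems <- def$minimum_cardinality
        if (def$required && is.null(arr$minItems)) arr$minItems <- 1L
        if (!is.null(def$maximum_cardinality)) arr$maxItems <- def$maximum_cardinality
        node <- arr
      }
      if (!is.null(def$description)) node$description <- def$description
      props[[s$name]] <- node
      if (def$required) req <- c(req, s$name)
      if (def$identifier)
        loss <- c(loss, sprintf(
          "identifier uniqueness of '%s.%s' across a collection is not expressible in JSON Schema",
          cn, s$name))
    }
    obj <- list(type = "object",
                properties = props,
                additionalProperties = !closed)
    if (!is.null(schema$classes[[cn]]$description))
      obj$description <- schema$classes[[cn]]$description
    if (length(req) > 0) obj$required <- as.list(req)
    defs[[cn]] <- obj
  }
  loss <- c(loss, "empty strings are treated as absent by the native validator; JSON Schema sees them as present strings")
  doc <- list("$schema" = JSON_SCHEMA_DRAFT,
              "$id" = paste0(schema$id, "/jsonschema"),
              title = schema$name,
              "$ref" = paste0("#/$defs/", root_class),
              "$defs" = defs)
  files <- stats::setNames(list(
    as.character(jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = 2, digits = NA)),
    as.character(jsonlite::toJSON(
      list(generator = "json_schema", draft = JSON_SCHEMA_DRAFT,
           losses = as.list(unique(loss))),
      auto_unbox = TRUE, pretty = 2))
  ), paste0(schema$name, c(".schema.json", ".loss.json")))
  generated_artifact("json_schema", files)
}

cardinality_label <- function(def) {
  lo <- def$minimum_cardinality %||% (if (def$required) 1L else 0L)
  hi <- def$maximum_cardinality %||% (if (def$multivalued) UNBOUNDED else 1L)
  format_cardinality(cardinality(lo, hi))
}

#' Generate Markdown documentation for a schema
#'
#' One page per class, slot, enum and type plus an index page. Class pages
#' tabulate induced slots with cardinality, range, description and
#' inheritance provenance. A `diagram.txt` file lists the class-relationship
#' edges (`is_a` edges and slot-range edges to classes and enums) in a text
#' graph notation.
#'
#' @param ms A `materialized_schema`.
#' @return A `generated_artifact`.
#' @export
gen_markdown_docs <- function(ms) {
  stopifnot(inherits(ms, "materialized_schema"))
  schema <- ms$source
  files <- list()
  page <- function(name, lines) files[[paste0(name, ".md")]] <<- paste(lines, collapse = "\n")

  # slot pages cover schema-level slots and class attributes once each
  slot_owner <- list()
  for (sn in names(schema$slots)) slot_owner[[sn]] <- "(schema)"
  for (cn in names(schema$classes))
    for (a in names(schema$classes[[cn]]$attributes))
      if (is.null(slot_owner[[a]])) slot_owner[[a]] <- cn

  edges <- character(0)
  for (cn in names(schema$classes)) {
    cl <- schema$classes[[cn]]
    for (p in c(cl$is_a, cl$mixins))
      edges <- c(edges, sprintf("(%s)-[is_a]->(%s)", cn, p))
    lines <- c(paste0("# Class: ", cn), "",
               cl$description %||% "_No description._", "")
    if (!is.null(cl$class_uri)) lines <- c(lines, paste0("URI: `", cl$class_uri, "`"), "")
    anc <- ms$ancestry[[cn]]
    if (length(anc) > 1)
      lines <- c(lines, paste0("Inheritance: ", paste(anc, collapse = " -> ")), "")
    lines <- c(lines, "| Slot | Cardinality | Range | Description | Defined in |",
               "|---|---|---|---|---|")
    for (s in ms$induced[[cn]]) {
      def <- s$definition
      origin <- "(local)"
      for (pr in s$provenance)
        if (pr$field == "range" || pr$field == "description") {
          origin <- if (is.na(pr$class)) "(schema slot)" else pr$class
          break
        }
      lines <- c(lines, sprintf("| %s | %s | %s | %s | %s |",
                                s$name, cardinality_label(def), def$range,
                                def$description %||% "", origin))
      if (def$range %in% names(schema$classes) || def$range %in% names(schema$enums))
        edges <- c(edges, sprintf("(%s)-[%s]->(%s)", cn, s$name, def$range))
    }
    page(cn, lines)
  }
  for (sn in names(slot_owner)) {
    src <- if (identical(slot_owner[[sn]], "(schema)")) schema$slots[[sn]]
           else schema$classes[[slot_owner[[sn]]]]$attributes[[sn]]
    lines <- c(paste0("# Slot: ", sn), "",
               src$description %||% "_No description._", "",
               paste0("Range: `", src$range %||% schema$default_range %||% "string", "`"))
    if (!is.null(src$slot_uri)) lines <- c(lines, paste0("URI: `", src$slot_uri, "`"))
    if (length(src$mappings) > 0)
      lines <- c(lines, "", "Mappings:",
                 vapply(src$mappings, function(m)
                   paste0("- ", m$predicate, ": `", m$target, "`"), character(1)))
    page(sn, lines)
  }
  for (en in names(schema$enums)) {
    e <- schema$enums[[en]]
    lines <- c(paste0("# Enum: ", en), "", e$description %||% "_No description._",
               "", "Permissible values:")
    for (pv in names(e$permissible_values)) {
      m <- e$permissible_values[[pv]]$meaning
      lines <- c(lines, paste0("- `", pv, "`",
                               if (!is.null(m)) paste0(" (", m, ")") else ""))
    }
    page(en, lines)
  }
  for (tn in names(schema$types)) {
    t <- schema$types[[tn]]
    page(tn, c(paste0("# Type: ", tn), "", t$description %||% "_No description._",
               "", paste0("Base: `", t$base, "`")))
  }

  index <- c(paste0("# ", schema$title %||% schema$name), "",
             schema$description %||% "", "", "## Elements", "")
  for (nm in setdiff(names(files), "index.md"))
    index <- c(index, paste0("- [", sub("\\.md$", "", nm), "](", nm, ")"))
  files[["index.md"]] <- paste(index, collapse = "\n")
  files[["diagram.txt"]] <- paste(unique(edges), collapse = "\n")
  generated_artifact("markdown_docs", files)
}

#' Transliterate an element name to a SQL identifier
#' @param x Element name (CamelCase or otherwise).
#' @return snake_case identifier.
#' @export
to_snake_case <- function(x) {
  x <- gsub("[^A-Za-z0-9]+", "_", x)
  x <- gsub("([a-z0-9])([A-Z])", "\\1_\\2", x)
  tolower(x)
}

sql_quote <- function(x) paste0("'", gsub("'", "''", x), "'")

#' Generate minimal SQL DDL for a schema
#'
#' One table per non-abstract class: scalar slots become typed columns
#' (float -> REAL, integer -> INTEGER, boolean -> BOOLEAN, else TEXT), the
#' identifier slot becomes the PRIMARY KEY, required slots NOT NULL,
#' enum ranges get a CHECK over the permissible values, and multivalued
#' slots become auxiliary link tables `(owner_id, value)`. Classes without
#' an identifier receive a synthesized surrogate key (recorded in the loss
#' report).
#'
#' @param ms A `materialized_schema`.
#' @return A `generated_artifact` with the DDL and a loss report (which also
#'   records the element-name to SQL-name mapping).
#' @export
gen_sql_ddl <- function(ms) {
  stopifnot(inherits(ms, "materialized_schema"))
  schema <- ms$source
  loss <- character(0)
  name_map <- list()
  stmts <- character(0)
  sql_type <- function(rng) {
    if (rng %in% names(schema$classes)) return("TEXT")
    if (rng %in% names(schema$enums)) return("TEXT")
    base <- (resolve_type_base(schema, rng) %||% list(base = "string"))$base
    switch(base, integer = "INTEGER", float = "REAL", boolean = "BOOLEAN", "TEXT")
  }
  for (cn in names(schema$classes)) {
    if (schema$classes[[cn]]$abstract) next
    tbl <- to_snake_case(cn)
    name_map[[cn]] <- tbl
    cols <- character(0)
    id_slot <- ms$identifier_slot[[cn]]
    if (is.na(id_slot)) {
      cols <- c(cols, "_row_id INTEGER PRIMARY KEY")
      loss <- c(loss, sprintf("class '%s' has no identifier slot; surrogate key '_row_id' synthesized", cn))
    }
    owner_id_type <- if (is.na(id_slot)) "INTEGER" else
      sql_type(Filter(function(s) s$name == id_slot, ms$induced[[cn]])[[1]]$definition$range)
    for (s in ms$induced[[cn]]) {
      def <- s$definition
      col <- to_snake_case(s$name)
      name_map[[paste0(cn, ".", s$name)]] <- col
      if (def$multivalued) {
        link <- paste0(tbl, "_", col)
        stmts <- c(stmts, paste0(
          "CREATE TABLE ", link, " (\n",
          "  owner_id ", owner_id_type, " NOT NULL,\n",
          "  value ", sql_type(def$range), if (def$required) " NOT NULL" else "", "\n",
          ");"))
        loss <- c(loss, sprintf("multivalued slot '%s.%s' normalized into link table '%s'",
                                cn, s$name, link))
        next
      }
      decl <- paste0(col, " ", sql_type(def$range))
      if (identical(s$name, id_slot)) {
        decl <- paste0(decl, " PRIMARY KEY")
      } else if (def$required) {
        decl <- paste0(decl, " NOT NULL")
      }
      if (def$range %in% names(schema$enums)) {
        pvs <- names(schema$enums[[def$range]]$permissible_values)
        decl <- paste0(decl, " CHECK (", col, " IN (",
                       paste(vapply(pvs, sql_quote, character(1)), collapse = ", "), "))")
      }
      if (def$range %in% names(schema$classes))
        loss <- c(loss, sprintf("class-valued slot '%s.%s' stored as TEXT reference", cn, s$name))
      cols <- c(cols, decl)
    }
    stmts <- c(stmts, paste0("CREATE TABLE ", tbl, " (\n  ",
                             paste(cols, collapse = ",\n  "), "\n);"))
  }
  files <- stats::setNames(list(
    paste(stmts, collapse = "\n\n"),
    as.character(jsonlite::toJSON(
      list(generator = "sql_ddl", losses = as.list(unique(loss)),
           name_map = name_map), auto_unbox = TRUE, pretty = 2))
  ), paste0(schema$name, c(".sql", ".loss.json")))
  generated_artifact("sql_ddl", files)
}
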