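# A small interpreter for the JSON Schema (draft 2020-12) subset emitted by
# gen_json_schema: $ref/$defs, type, properties, required,
# additionalProperties, enum, pattern, items, minItems, maxItems. It backs
# the "json_schema" validation engine, giving a second, representation-level
# route to validity that tests compare against the native engine.

resolve_ref <- function(ref, root) {
  if (!startsWith(ref, "#/"))
    sk_stop(sprintf("only local $refs are supported: '%s'", ref), "json_schema_ref")
  node <- root
  for (part in strsplit(substring(ref, 3), "/", fixed = TRUE)[[1]])
    node <- node[[part]]
  if (is.null(node))
    sk_stop(sprintf("unresolvable $ref: '%s'", ref), "json_schema_ref")
  node
}

js_type_of <- function(v) {
  if (is.null(v)) return("null")
  if (is.list(v)) {
    if (length(v) == 0L) return("empty")          # [] and {} are both empty lists
    if (is.null(names(v))) return("array")
    return("object")
  }
  if (is.logical(v)) return("boolean")
  if (is.numeric(v)) return(if (v == floor(v)) "integer" else "number")
  if (is.character(v)) return("string")
  "unknown"
}

js_type_ok <- function(expected, v) {
  actual <- js_type_of(v)
  if (actual == "empty") return(expected %in% c("array", "object"))
  switch(expected,
    number = actual %in% c("number", "integer"),
    integer = actual == "integer",
    actual == expected)
}

#' Check a value against a generated JSON Schema
#'
#' @param schema The JSON Schema as a parsed R list (e.g. from
#'   `jsonlite::fromJSON(..., simplifyVector = FALSE)`).
#' @param value The value to check: named lists are objects, unnamed lists
#'   arrays, length-1 atomics scalars.
#' @return List of failures, each a list with `path` and `message`; empty
#'   when the value conforms.
#' @export
json_schema_check <- function(schema, value) {
  root <- schema
  fails <- list()
  add <- function(path, message)
    fails[[length(fails) + 1L]] <<- list(path = path, message = message)

  walk <- function(node, v, path) {
    if (!is.null(node[["$ref"]]))
      node <- resolve_ref(node[["$ref"]], root)
    if (!is.null(node$type) && !js_type_ok(node$type, v)) {
      add(path, sprintf("expected type '%s', got '%s'", node$type, js_type_of(v)))
      return(invisible())
    }
    if (!is.null(node$enum)) {
      ok <- any(vapply(node$enum, function(e) identical(as.character(e), as.character(v)),
                       logical(1)))
      if (!ok) add(path, "value not in enumerated set")
    }
    if (!is.null(node$pattern) && is.character(v) && length(v) == 1L) {
      if (!grepl(node$pattern, v, perl = TRUE))
        add(path, sprintf("string does not match pattern '%s'", node$pattern))
    }
    if (identical(node$type, "object") ||
        (!is.null(node$properties) && js_type_of(v) %in% c("object", "empty"))) {
      for (r in node$required) {
        if (is.null(v[[r]])) add(paste0(path, "/", r),
                                 sprintf("required property '%s' is missing", r))
      }
      props <- names(node$properties)
      for (nm in names(v)) {
        if (nm %in% props) {
          walk(node$properties[[nm]], v[[nm]], paste0(path, "/", nm))
        } else if (isFALSE(node$additionalProperties)) {
          add(paste0(path, "/", nm), sprintf("additional property '%s' not allowed", nm))
        }
      }
    }
    if (identical(node$type, "array") && js_type_of(v) %in% c("array", "empty")) {
      n <- length(v)
      if (!is.null(node$minItems) && n < node$minItems)
        add(path, sprintf("array has %d item(s); minItems is %d", n, node$minItems))
      if (!is.null(node$maxItems) && n > node$maxItems)
        add(path, sprintf("array has %d item(s); maxItems is %d", n, node$maxItems))
      if (!is.null(node$items))
        for (k in seq_along(v)) walk(node$items, v[[k]], paste0(path, "/", k))
    }
    invisible()
  }
  walk(root, value, "")
  fails
}
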