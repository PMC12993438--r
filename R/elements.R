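# Constructors for schema elements. Tri-state logicals (NA = unset) let the
# compiler distinguish "explicitly false" from "inherit"; defaults are applied
# when slots are induced, not at parse time.

TYPE_BASES <- c("string", "integer", "float", "boolean", "uri", "uriorcurie",
                "date", "datetime")

#' Define a slot (class attribute)
#'
#' @param name Slot name.
#' @param description Human-readable description.
#' @param range Name of the type, class or enum constraining values.
#' @param required,multivalued,identifier Tri-state logicals (`NA` = unset;
#'   treated as `FALSE` once the slot is induced). `identifier = TRUE`
#'   implies `required = TRUE`.
#' @param pattern Regular expression values must fully match.
#' @param slot_uri CURIE identifying the slot in an external standard.
#' @param unit Unit label for measured quantities (e.g. `"m"`).
#' @param mappings List of [mapping()] objects.
#' @param minimum_cardinality,maximum_cardinality Optional explicit bounds on
#'   the number of values (as carried by tabular multiplicity columns).
#' @return A `slot_definition`.
#' @export
slot_definition <- function(name, description = NULL, range = NULL,
                            required = NA, multivalued = NA, identifier = NA,
                            pattern = NULL, slot_uri = NULL, unit = NULL,
                            mappings = list(),
                            minimum_cardinality = NULL, maximum_cardinality = NULL) {
  if (!is_string(name) || !nzchar(name)) sk_stop("slot name must be a non-empty string", "bad_element")
  if (!is.null(pattern)) {
    ok <- tryCatch({ grepl(pattern, "", perl = TRUE); TRUE }, error = function(e) FALSE)
    if (!ok) sk_stop(sprintf("pattern does not compile: '%s'", pattern), "bad_element")
  }
  if (isTRUE(identifier)) {
    if (isFALSE(required))
      sk_stop(sprintf("identifier slot '%s' cannot be optional", name), "bad_element")
    required <- TRUE
  }
  if (!is.null(minimum_cardinality)) minimum_cardinality <- as.integer(minimum_cardinality)
  if (!is.null(maximum_cardinality)) maximum_cardinality <- as.integer(maximum_cardinality)
  structure(list(
    name = name, description = description, range = range,
    required = required, multivalued = multivalued, identifier = identifier,
    pattern = pattern, slot_uri = slot_uri, unit = unit,
    mappings = norm_list(mappings),
    minimum_cardinality = minimum_cardinality,
    maximum_cardinality = maximum_cardinality,
    annotations = list()
  ), class = "slot_definition")
}

#' Define a class (entity type)
#'
#' @param name Class name.
#' @param description Human-readable description.
#' @param is_a Name of the parent class, if any.
#' @param mixins Character vector of mixin class names.
#' @param abstract Abstract classes get no instances (and no SQL table).
#' @param slots Character vector of names of schema-level slots used by this
#'   class.
#' @param attributes Named list of inline [slot_definition()]s.
#' @param slot_usage Named list of partial slot refinements (each a list of
#'   slot fields to override for this class).
#' @param class_uri CURIE identifying the class in an external standard.
#' @param mappings List of [mapping()] objects.
#' @return A `class_definition`.
#' @export
class_definition <- function(name, description = NULL, is_a = NULL,
                             mixins = character(0), abstract = FALSE,
                             slots = character(0), attributes = list(),
                             slot_usage = list(), class_uri = NULL,
                             mappings = list()) {
  if (!is_string(name) || !nzchar(name)) sk_stop("class name must be a non-empty string", "bad_element")
  for (a in names(attributes)) {
    if (!inherits(attributes[[a]], "slot_definition"))
      sk_stop(sprintf("attribute '%s' of class '%s' is not a slot_definition", a, name), "bad_element")
  }
  structure(list(
    name = name, description = description, is_a = is_a,
    mixins = as.character(mixins), abstract = isTRUE(abstract),
    slots = as.character(slots), attributes = norm_list(attributes),
    slot_usage = norm_list(slot_usage), class_uri = class_uri,
    mappings = norm_list(mappings),
    annotations = list()
  ), class = "class_definition")
}

#' Define an enumeration (controlled vocabulary)
#'
#' @param name Enum name.
#' @param description Human-readable description.
#' @param permissible_values Named list; names are the permitted value texts,
#'   each entry a list with optional `description` and `meaning` (an ontology
#'   CURIE, e.g. an ENVO term).
#' @param case_insensitive If `TRUE`, value matching folds case.
#' @return An `enum_definition`.
#' @export
enum_definition <- function(name, description = NULL,
                            permissible_values = list(),
                            case_insensitive = FALSE) {
  if (!is_string(name) || !nzchar(name)) sk_stop("enum name must be a non-empty string", "bad_element")
  if (length(permissible_values) > 0 && anyDuplicated(names(permissible_values)))
    sk_stop(sprintf("duplicate permissible value in enum '%s'", name), "duplicate_element_name")
  for (pv in names(permissible_values)) {
    m <- permissible_values[[pv]]$meaning
    if (!is.null(m) && !is_curie(m))
      sk_stop(sprintf("meaning of '%s' in enum '%s' is not a valid CURIE: '%s'", pv, name, m),
              "malformed_curie")
  }
  structure(list(
    name = name, description = description,
    permissible_values = norm_list(permissible_values),
    case_insensitive = isTRUE(case_insensitive),
    annotations = list()
  ), class = "enum_definition")
}

#' Define a scalar type
#'
#' @param name Type name.
#' @param base One of the built-in primitive bases: string, integer, float,
#'   boolean, uri, uriorcurie, date, datetime.
#' @param uri Optional CURIE for the type.
#' @param pattern Optional regex constraint.
#' @param description Human-readable description.
#' @return A `type_definition`.
#' @export
type_definition <- function(name, base, uri = NULL, pattern = NULL,
                            description = NULL) {
  if (!is_string(name) || !nzchar(name)) sk_stop("type name must be a non-empty string", "bad_element")
  if (!is_string(base) || !base %in% TYPE_BASES)
    sk_stop(sprintf("type base must be one of: %s", paste(TYPE_BASES, collapse = ", ")),
            "bad_element")
  structure(list(name = name, base = base, uri = uri, pattern = pattern,
                 description = description, annotations = list()),
            class = "type_definition")
}

#' The built-in scalar type library
#'
#' These types are implicitly available to every schema, so tabular and YAML
#' schemas may use ranges like `float` or `uriorcurie` without declaring them.
#'
#' @return Named list of [type_definition()]s.
#' @export
builtin_types <- function() {
  mk <- function(n, uri) type_definition(n, base = n, uri = uri,
                                         description = paste("built-in", n, "type"))
  list(
    string     = mk("string", "xsd:string"),
    integer    = mk("integer", "xsd:integer"),
    float      = mk("float", "xsd:float"),
    boolean    = mk("boolean", "xsd:boolean"),
    uri        = mk("uri", "xsd:anyURI"),
    uriorcurie = mk("uriorcurie", "xsd:anyURI"),
    date       = mk("date", "xsd:date"),
    datetime   = mk("datetime", "xsd:dateTime")
  )
}

#' Construct a schema definition
#'
#' The top-level container: identified by a URI, holding prefixes, imports and
#' the four element categories in declaration order.
#'
#' @param id Schema identifier; must be a URI.
#' @param name Schema name.
#' @param title,license Optional metadata.
#' @param prefixes A [prefix_map()] (or coercible named list).
#' @param imports Character vector of logical schema names to import.
#' @param default_range Range applied to slots that declare none.
#' @param classes,slots,enums,types Named lists of element definitions.
#' @param description Optional schema description.
#' @param annotations Unrecognized-but-preserved key/value pairs.
#' @return A `schema_definition`.
#' @export
schema_definition <- function(id, name, title = NULL, license = NULL,
                              description = NULL,
                              prefixes = prefix_map(), imports = character(0),
                              default_range = NULL,
                              classes = list(), slots = list(),
                              enums = list(), types = list(),
                              annotations = list()) {
  if (!is_string(id) || !nzchar(id))
    sk_stop("schema id is missing", "missing_schema_id")
  if (!is_full_uri(id) && !is_curie(id))
    sk_stop(sprintf("schema id must be a URI: '%s'", id), "missing_schema_id")
  if (!is_string(name) || !nzchar(name))
    sk_stop("schema name is missing", "bad_element")
  if (!inherits(prefixes, "prefix_map")) prefixes <- prefix_map(prefixes)
  for (cat in list(classes, slots, enums, types)) {
    if (length(cat) > 0 && anyDuplicated(names(cat)))
      sk_stop(sprintf("duplicate element name: '%s'", names(cat)[duplicated(names(cat))][1]),
              "duplicate_element_name")
  }
  structure(list(
    id = id, name = name, title = title, license = license,
    description = description,
    prefixes = prefixes, imports = as.character(imports),
    default_range = default_range,
    classes = norm_list(classes), slots = norm_list(slots),
    enums = norm_list(enums), types = norm_list(types),
    annotations = norm_list(annotations)
  ), class = "schema_definition")
}

#' @export
print.schema_definition <- function(x, ...) {
  cat("<schema_definition> ", x$name, "\n", sep = "")
  cat("  id: ", x$id, "\n", sep = "")
  cat("  classes: ", paste(names(x$classes), collapse = ", "), "\n", sep = "")
  cat("  slots: ", length(x$slots), "  enums: ", length(x$enums),
      "  types: ", length(x$types), "  prefixes: ", length(x$prefixes), "\n", sep = "")
  invisible(x)
}

# all declared element names visible to range resolution
schema_element_names <- function(schema) {
  c(names(schema$classes), names(schema$enums), names(schema$types),
    names(builtin_types()))
}
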