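# Schema compilation: inheritance is resolved once, here, into an "induced"
# view (class ancestry + fully resolved slots) that every downstream module
# consumes. Override precedence, nearest first:
#   slot_usage(self) > slot_usage(nearer ancestor) > nearest attribute
#   definition > schema-level slot definition
# Fields merge one by one; unset fields (NULL / NA) inherit.

#' Ordered ancestors of a class
#'
#' The list starts with the class itself, followed by its `is_a` chain, then
#' mixins depth-first left-to-right; duplicates are removed keeping the first
#' occurrence (so the `is_a` backbone wins ties against mixins).
#'
#' @param schema A `schema_definition` (imports already resolved).
#' @param class_name Name of the class.
#' @return Character vector of class names, nearest first.
#' @export
class_ancestors <- function(schema, class_name) {
  if (!class_name %in% names(schema$classes))
    sk_stop(sprintf("unknown class: '%s'", class_name), "unknown_class")
  out <- character(0)
  visit <- function(nm, stack) {
    if (nm %in% stack)
      sk_stop(sprintf("inheritance cycle: %s", paste(c(stack, nm), collapse = " -> ")),
              "cycle_detected")
    if (!nm %in% names(schema$classes))
      sk_stop(sprintf("unknown class in hierarchy: '%s'", nm), "unknown_class")
    if (!nm %in% out) out[[length(out) + 1L]] <<- nm
    cl <- schema$classes[[nm]]
    for (parent in c(cl$is_a, cl$mixins)) visit(parent, c(stack, nm))
  }
  visit(class_name, character(0))
  out
}

slot_fields_mergeable <- c("description", "range", "required", "multivalued",
                           "identifier", "pattern", "slot_uri", "unit",
                           "minimum_cardinality", "maximum_cardinality")

# find where each slot name is declared along the ancestry, nearest first
declaring_sources <- function(schema, ancestors, slot_name) {
  srcs <- list()
  for (anc in ancestors) {
    cl <- schema$classes[[anc]]
    if (slot_name %in% names(cl$slot_usage))
      srcs[[length(srcs) + 1L]] <- list(kind = "slot_usage", class = anc,
                                        fields = cl$slot_usage[[slot_name]])
  }
  for (anc in ancestors) {
    cl <- schema$classes[[anc]]
    if (slot_name %in% names(cl$attributes))
      srcs[[length(srcs) + 1L]] <- list(kind = "attribute", class = anc,
                                        fields = unclass(cl$attributes[[slot_name]]))
  }
  if (slot_name %in% names(schema$slots))
    srcs[[length(srcs) + 1L]] <- list(kind = "schema_slot", class = NA_character_,
                                      fields = unclass(schema$slots[[slot_name]]))
  srcs
}

#' Induced slots of a class
#'
#' Computes the effective slot definitions for a class after inheritance:
#' the union of its own attributes, referenced schema-level slots, and all
#' ancestor slots, with field-wise override resolution. Slot order is
#' ancestor-inherited first (root-most first), then the class's own slots in
#' declaration order.
#'
#' @inheritParams class_ancestors
#' @return List of `induced_slot` objects, each with `name`, `owner`,
#'   `definition` (a fully resolved `slot_definition` with defaults applied)
#'   and `provenance` (one record per resolved field naming its source).
#' @export
induced_slots <- function(schema, class_name) {
  ancestors <- class_ancestors(schema, class_name)
  slot_names <- character(0)
  for (anc in rev(ancestors)) {
    cl <- schema$classes[[anc]]
    for (nm in c(cl$slots, names(cl$attributes)))
      if (!nm %in% slot_names) slot_names[[length(slot_names) + 1L]] <- nm
  }
  out <- vector("list", length(slot_names))
  for (i in seq_along(slot_names)) {
    nm <- slot_names[[i]]
    srcs <- declaring_sources(schema, ancestors, nm)
    if (!any(vapply(srcs, function(s) s$kind != "slot_usage", logical(1))))
      sk_stop(sprintf("class '%s' references slot '%s' with no definition",
                      class_name, nm), "unknown_slot_reference")
    def <- slot_definition(nm)
    prov <- list()
    for (field in slot_fields_mergeable) {
      for (src in srcs) {
        v <- src$fields[[field]]
        if (is_set(v)) {
          def[[field]] <- v
          prov[[length(prov) + 1L]] <- list(class = src$class, field = field,
                                            source = src$kind)
          break
        }
      }
    }
    # collect mappings from every source (metadata accumulates, not overrides)
    for (src in rev(srcs)) {
      for (m in src$fields$mappings) def$mappings[[length(def$mappings) + 1L]] <- m
    }
    # apply defaults for the induced view
    if (!is_set(def$required)) def$required <- FALSE
    if (!is_set(def$multivalued)) def$multivalued <- FALSE
    if (!is_set(def$identifier)) def$identifier <- FALSE
    if (def$identifier) def$required <- TRUE
    if (is.null(def$range)) def$range <- schema$default_range %||% "string"
    out[[i]] <- structure(list(name = nm, owner = class_name,
                               definition = def, provenance = prov),
                          class = "induced_slot")
  }
  ids <- vapply(out, function(s) s$definition$identifier, logical(1))
  if (sum(ids) > 1L)
    sk_stop(sprintf("class '%s' induces multiple identifier slots: %s",
                    class_name, paste(slot_names[ids], collapse = ", ")),
            "conflicting_identifier")
  out
}

check_integrity <- function(schema) {
  problems <- character(0)
  known_ranges <- schema_element_names(schema)
  for (cn in names(schema$classes)) {
    cl <- schema$classes[[cn]]
    for (parent in c(cl$is_a, cl$mixins)) {
      if (!parent %in% names(schema$classes))
        problems <- c(problems, sprintf("class '%s': parent '%s' not defined", cn, parent))
    }
    for (sn in cl$slots) {
      if (!sn %in% names(schema$slots) && !sn %in% names(cl$attributes))
        problems <- c(problems, sprintf("class '%s': slot reference '%s' not defined", cn, sn))
    }
    for (a in names(cl$attributes)) {
      rng <- cl$attributes[[a]]$range
      if (!is.null(rng) && !rng %in% known_ranges)
        problems <- c(problems, sprintf("slot '%s' of class '%s': range '%s' not defined",
                                        a, cn, rng))
    }
  }
  for (sn in names(schema$slots)) {
    rng <- schema$slots[[sn]]$range
    if (!is.null(rng) && !rng %in% known_ranges)
      problems <- c(problems, sprintf("slot '%s': range '%s' not defined", sn, rng))
  }
  dflt <- schema$default_range
  if (!is.null(dflt) && !dflt %in% known_ranges)
    problems <- c(problems, sprintf("default_range '%s' not defined", dflt))
  problems
}

#' Materialize a schema
#'
#' Single compilation entry point: checks referential integrity (reporting
#' every dangling reference at once), then computes ancestry and induced
#' slots for every class.
#'
#' @param schema A `schema_definition` with imports already resolved.
#' @return A `materialized_schema`: list with `source`, `ancestry`,
#'   `induced` and `identifier_slot` (class -> slot name or `NA`).
#' @export
materialize <- function(schema) {
  stopifnot(inherits(schema, "schema_definition"))
  problems <- check_integrity(schema)
  if (length(problems) > 0)
    sk_stop(paste0("schema integrity check failed:\n  ",
                   paste(problems, collapse = "\n  ")), "integrity_error",
            data = list(problems = problems))
  ancestry <- list()
  induced <- list()
  identifier_slot <- list()
  for (cn in names(schema$classes)) {
    ancestry[[cn]] <- class_ancestors(schema, cn)
    induced[[cn]] <- induced_slots(schema, cn)
    ids <- Filter(function(s) s$definition$identifier, induced[[cn]])
    identifier_slot[[cn]] <- if (length(ids) == 1L) ids[[1]]$name else NA_character_
  }
  structure(list(source = schema, ancestry = ancestry, induced = induced,
                 identifier_slot = identifier_slot),
            class = "materialized_schema")
}

#' @export
print.materialized_schema <- function(x, ...) {
  cat("<materialized_schema> ", x$source$name, "\n", sep = "")
  for (cn in names(x$induced)) {
    cat("  ", cn, ": ",
        paste(vapply(x$induced[[cn]], function(s) s$name, character(1)),
              collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Dump the induced view of a materialized schema as YAML
#'
#' @param ms A `materialized_schema`.
#' @return YAML text describing every class's induced slots.
#' @export
dump_induced <- function(ms) {
  stopifnot(inherits(ms, "materialized_schema"))
  doc <- list()
  for (cn in names(ms$induced)) {
    doc[[cn]] <- list(
      ancestors = as.list(ms$ancestry[[cn]]),
      slots = stats::setNames(
        lapply(ms$induced[[cn]], function(s) slot_to_yaml(s$definition)),
        vapply(ms$induced[[cn]], function(s) s$name, character(1)))
    )
  }
  yaml::as.yaml(doc, indent.mapping.sequence = TRUE,
                handlers = list(logical = function(x) {
                  r <- ifelse(x, "true", "false"); class(r) <- "verbatim"; r
                }))
}
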