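# Declarative schema/data transformations: rename, split, merge, retype,
# recardinalize, subset. A transform spec is an ordered list of operations
# applied both to the schema (derive_schema) and to instance data
# (transform_instance), so migrated documents validate against the derived
# schema.
#
# Spec YAML grammar (artifact-defined): a YAML sequence whose items are
# single-key mappings, the key naming the operation kind, e.g.
#   - split:
#       class: Sample
#       source_slot: position
#       targets: [latitude, longitude]
#       delimiter: ","
#       target_ranges: [float, float]
#   - rename:
#       class: Sample
#       old_slot: environment_type
#       new_slot: sample_type

TRANSFORM_KINDS <- c("rename", "split", "merge", "retype", "recardinalize", "subset")

op_required_fields <- list(
  rename = c("class", "old_slot", "new_slot"),
  split = c("class", "source_slot", "targets", "delimiter"),
  merge = c("class", "sources", "target_slot", "delimiter"),
  retype = c("class", "slot", "new_range"),
  recardinalize = c("class", "slot"),
  subset = "keep_classes"
)

#' Construct a transform spec from a list of operations
#' @param ops List of operation records, each a list with a `kind` field and
#'   the kind's parameters.
#' @export
transform_spec <- function(ops = list()) {
  for (i in seq_along(ops)) {
    op <- ops[[i]]
    if (!is_string(op$kind) || !op$kind %in% TRANSFORM_KINDS)
      sk_stop(sprintf("operation %d: unknown operation kind '%s'", i,
                      op$kind %||% "<missing>"), "unknown_operation_kind")
    missing <- setdiff(op_required_fields[[op$kind]], names(op))
    if (length(missing) > 0)
      sk_stop(sprintf("operation %d (%s): missing field(s): %s", i, op$kind,
                      paste(missing, collapse = ", ")), "unknown_operation_kind")
    if (op$kind == "split" && length(op$targets) < 2L)
      sk_stop(sprintf("operation %d: split needs at least 2 targets", i),
              "unknown_operation_kind")
    if (op$kind == "split" && !is.null(op$target_ranges) &&
        length(op$target_ranges) != length(op$targets))
      sk_stop(sprintf("operation %d: target_ranges length must match targets", i),
              "unknown_operation_kind")
  }
  structure(list(ops = ops), class = "transform_spec")
}

#' Parse a transform spec from YAML
#'
#' @param text YAML text (or character vector of lines): a sequence of
#'   single-key mappings, each key an operation kind (`rename`, `split`,
#'   `merge`, `retype`, `recardinalize`, `subset`).
#' @return A `transform_spec` with operation order preserved.
#' @export
parse_transform_spec <- function(text) {
  if (length(text) > 1L) text <- paste(text, collapse = "\n")
  raw <- yaml::yaml.load(text)
  if (is.null(raw)) raw <- list()
  if (!is.list(raw) || (length(raw) > 0 && !is.null(names(raw))))
    sk_stop("transform spec must be a YAML sequence of operations", "unknown_operation_kind")
  ops <- lapply(seq_along(raw), function(i) {
    item <- raw[[i]]
    if (!is.list(item) || length(item) != 1L || is.null(names(item)))
      sk_stop(sprintf("operation %d must be a single-key mapping", i),
              "unknown_operation_kind")
    c(list(kind = names(item)), item[[1]])
  })
  transform_spec(ops)
}

#' Read a transform spec from a YAML file
#' @param path File path.
#' @export
read_transform_spec <- function(path) {
  parse_transform_spec(readLines(path, encoding = "UTF-8", warn = FALSE))
}

op_ref_stop <- function(i, msg) {
  sk_stop(sprintf("operation %d: %s", i, msg), "reference_error")
}

# pull a slot definition into a class's attributes so it can be edited
# locally, regardless of whether it was declared inline or schema-level
localize_slot <- function(schema, class_name, slot_name, i) {
  cl <- schema$classes[[class_name]]
  if (is.null(cl)) op_ref_stop(i, sprintf("class '%s' not found", class_name))
  if (slot_name %in% names(cl$attributes)) return(schema)
  if (slot_name %in% cl$slots && slot_name %in% names(schema$slots)) {
    cl$attributes[[slot_name]] <- schema$slots[[slot_name]]
    cl$slots <- setdiff(cl$slots, slot_name)
    schema$classes[[class_name]] <- cl
    return(schema)
  }
  op_ref_stop(i, sprintf("slot '%s' not found in class '%s'", slot_name, class_name))
}

replace_attr_at <- function(attrs, name, replacement) {
  # drop `name`, splicing `replacement` (a named list of slots) in its place
  idx <- match(name, names(attrs))
  out <- list()
  nms <- names(attrs)
  for (j in seq_along(attrs)) {
    if (j == idx) {
      for (rn in names(replacement)) out[[rn]] <- replacement[[rn]]
    } else {
      out[[nms[j]]] <- attrs[[j]]
    }
  }
  out
}

#' Derive a transformed schema
#'
#' Applies the spec's operations to the schema in order. `split` removes the
#' source slot and inserts the targets at its position; `rename` preserves
#' all other slot fields; `subset` removes unlisted classes and any slot
#' references left dangling, recording each removal in the audit trail
#' (`attr(x, "audit")`).
#'
#' @param schema A `schema_definition`.
#' @param spec A [transform_spec()].
#' @return The derived `schema_definition`.
#' @export
derive_schema <- function(schema, spec) {
  stopifnot(inherits(schema, "schema_definition"), inherits(spec, "transform_spec"))
  audit <- list()
  log <- function(i, kind, detail)
    audit[[length(audit) + 1L]] <<- list(op = i, kind = kind, detail = detail)

  for (i in seq_along(spec$ops)) {
    op <- spec$ops[[i]]
    if (op$kind == "subset") {
      keep <- as.character(op$keep_classes)
      missing <- setdiff(keep, names(schema$classes))
      if (length(missing) > 0)
        op_ref_stop(i, sprintf("keep_classes name unknown class(es): %s",
                               paste(missing, collapse = ", ")))
      dropped <- setdiff(names(schema$classes), keep)
      for (d in dropped) log(i, "subset", sprintf("dropped class '%s'", d))
      schema$classes <- schema$classes[keep]
      for (cn in names(schema$classes)) {
        cl <- schema$classes[[cn]]
        if (!is.null(cl$is_a) && cl$is_a %in% dropped) {
          log(i, "subset", sprintf("cleared is_a '%s' of class '%s'", cl$is_a, cn))
          cl$is_a <- NULL
        }
        cl$mixins <- setdiff(cl$mixins, dropped)
        for (a in names(cl$attributes)) {
          rng <- cl$attributes[[a]]$range
          if (!is.null(rng) && rng %in% dropped) {
            log(i, "subset", sprintf("dropped slot '%s.%s' (range '%s' removed)", cn, a, rng))
            cl$attributes[[a]] <- NULL
          }
        }
        if (!is.null(op$keep_slots[[cn]])) {
          for (a in setdiff(names(cl$attributes), op$keep_slots[[cn]])) {
            log(i, "subset", sprintf("dropped slot '%s.%s' (not in keep_slots)", cn, a))
            cl$attributes[[a]] <- NULL
          }
        }
        schema$classes[[cn]] <- cl
      }
      next
    }
    cls <- op$class
    if (op$kind == "rename") {
      schema <- localize_slot(schema, cls, op$old_slot, i)
      def <- schema$classes[[cls]]$attributes[[op$old_slot]]
      def$name <- op$new_slot
      schema$classes[[cls]]$attributes <- replace_attr_at(
        schema$classes[[cls]]$attributes, op$old_slot,
        stats::setNames(list(def), op$new_slot))
      log(i, "rename", sprintf("%s: '%s' -> '%s'", cls, op$old_slot, op$new_slot))
    } else if (op$kind == "split") {
      schema <- localize_slot(schema, cls, op$source_slot, i)
      src <- schema$classes[[cls]]$attributes[[op$source_slot]]
      ranges <- as.character(op$target_ranges %||% rep("string", length(op$targets)))
      targets <- stats::setNames(lapply(seq_along(op$targets), function(k)
        slot_definition(op$targets[[k]], range = ranges[k],
                        required = src$required,
                        description = sprintf("Split from '%s' (part %d).",
                                              op$source_slot, k))),
        as.character(op$targets))
      schema$classes[[cls]]$attributes <- replace_attr_at(
        schema$classes[[cls]]$attributes, op$source_slot, targets)
      log(i, "split", sprintf("%s: '%s' -> %s", cls, op$source_slot,
                              paste(op$targets, collapse = " + ")))
    } else if (op$kind == "merge") {
      for (s in op$sources) schema <- localize_slot(schema, cls, s, i)
      srcs <- schema$classes[[cls]]$attributes[op$sources]
      req <- all(vapply(srcs, function(s) isTRUE(s$required), logical(1)))
      tgt <- slot_definition(op$target_slot, range = op$target_range %||% "string",
                             required = if (req) TRUE else NA,
                             description = sprintf("Merged from %s.",
                                                   paste(op$sources, collapse = ", ")))
      attrs <- schema$classes[[cls]]$attributes
      attrs <- replace_attr_at(attrs, op$sources[[1]],
                               stats::setNames(list(tgt), op$target_slot))
      attrs[setdiff(op$sources, op$sources[[1]])] <- NULL
      schema$classes[[cls]]$attributes <- attrs
      log(i, "merge", sprintf("%s: %s -> '%s'", cls,
                              paste(op$sources, collapse = " + "), op$target_slot))
    } else if (op$kind == "retype") {
      schema <- localize_slot(schema, cls, op$slot, i)
      old <- schema$classes[[cls]]$attributes[[op$slot]]$range
      schema$classes[[cls]]$attributes[[op$slot]]$range <- op$new_range
      log(i, "retype", sprintf("%s.%s: range '%s' -> '%s'", cls, op$slot,
                               old %||% "<default>", op$new_range))
    } else if (op$kind == "recardinalize") {
      schema <- localize_slot(schema, cls, op$slot, i)
      def <- schema$classes[[cls]]$attributes[[op$slot]]
      if (!is.null(op$required)) def$required <- isTRUE(op$required)
      if (!is.null(op$multivalued)) def$multivalued <- isTRUE(op$multivalued)
      if (!is.null(op$cardinality)) {
        card <- parse_cardinality(op$cardinality)
        def$minimum_cardinality <- card$min
        def$maximum_cardinality <- if (is.finite(card$max)) card$max else NULL
        def$multivalued <- !is.finite(card$max) || card$max > 1L
        if (card$min >= 1L) def$required <- TRUE
      }
      schema$classes[[cls]]$attributes[[op$slot]] <- def
      log(i, "recardinalize", sprintf("%s.%s", cls, op$slot))
    }
  }
  attr(schema, "audit") <- audit
  schema
}

cast_scalar <- function(x, range, path, schema = NULL) {
  base <- range
  if (!is.null(schema)) {
    tb <- resolve_type_base(schema, range)
    if (!is.null(tb)) base <- tb$base
  } else if (range %in% TYPE_BASES) {
    base <- range
  } else {
    base <- "string"
  }
  if (base %in% c("float", "integer")) {
    v <- suppressWarnings(as.numeric(x))
    if (is.na(v))
      sk_stop(sprintf("%s: cannot cast '%s' to %s", path, x, range), "cast_error")
    if (base == "integer") {
      if (v != floor(v))
        sk_stop(sprintf("%s: cannot cast '%s' to integer", path, x), "cast_error")
      v <- as.integer(v)
    }
    return(v)
  }
  if (base == "boolean") {
    lx <- tolower(trimws(as.character(x)))
    if (!lx %in% c("true", "false"))
      sk_stop(sprintf("%s: cannot cast '%s' to boolean", path, x), "cast_error")
    return(lx == "true")
  }
  as.character(x)
}

#' Transform an instance document along a transform spec
#'
#' `split` divides the source string on the delimiter into exactly as many
#' parts as there are targets (trimmed, cast to the target ranges); `merge`
#' joins source values with the delimiter; `rename` relabels keys. Values
#' of untouched slots pass through unchanged, and an absent source under
#' split/merge propagates absence rather than failing.
#'
#' @param doc An [instance_document()].
#' @param spec A [transform_spec()].
#' @param source Optional source `materialized_schema`, used to resolve
#'   custom types when casting.
#' @return The transformed `instance_document`.
#' @export
transform_instance <- function(doc, spec, source = NULL) {
  stopifnot(inherits(doc, "instance_document"), inherits(spec, "transform_spec"))
  src_schema <- if (!is.null(source)) source$source
  values <- doc$values
  for (i in seq_along(spec$ops)) {
    op <- spec$ops[[i]]
    if (!op$kind %in% c("subset") && !is.null(op$class) &&
        !identical(op$class, doc$class_name)) next
    if (op$kind == "rename") {
      idx <- match(op$old_slot, names(values))
      if (!is.na(idx)) names(values)[idx] <- op$new_slot
    } else if (op$kind == "split") {
      v <- values[[op$source_slot]]
      pos <- match(op$source_slot, names(values))
      if (is.na(pos) || value_absent(v)) {
        values[[op$source_slot]] <- NULL
        next
      }
      path <- paste0("/", op$source_slot)
      if (!is_scalar_value(v))
        sk_stop(sprintf("%s: split source must be a scalar string", path), "cast_error")
      parts <- trimws(strsplit(as.character(v), op$delimiter, fixed = TRUE)[[1]])
      if (length(parts) != length(op$targets))
        sk_stop(sprintf("%s: split of '%s' on '%s' yields %d part(s); expected %d",
                        path, v, op$delimiter, length(parts), length(op$targets)),
                "split_arity_mismatch")
      ranges <- as.character(op$target_ranges %||% rep("string", length(op$targets)))
      repl <- stats::setNames(lapply(seq_along(parts), function(k)
        cast_scalar(parts[k], ranges[k], paste0("/", op$targets[[k]]), src_schema)),
        as.character(op$targets))
      # splice targets where the source sat, preserving field order
      out <- list()
      for (j in seq_along(values)) {
        if (j == pos) for (rn in names(repl)) out[[rn]] <- repl[[rn]]
        else out[[names(values)[j]]] <- values[[j]]
      }
      values <- out
    } else if (op$kind == "merge") {
      srcs <- as.character(op$sources)
      vs <- values[srcs]
      if (any(vapply(srcs, function(s) value_absent(values[[s]]), logical(1)))) {
        values[srcs] <- NULL
        next
      }
      joined <- paste(vapply(vs, as.character, character(1)), collapse = op$delimiter)
      pos <- match(srcs[1], names(values))
      out <- list()
      for (j in seq_along(values)) {
        nm <- names(values)[j]
        if (j == pos) out[[op$target_slot]] <- joined
        else if (!nm %in% srcs) out[[nm]] <- values[[j]]
      }
      values <- out
    } else if (op$kind == "retype") {
      v <- values[[op$slot]]
      if (!is.null(v) && is_scalar_value(v) && !value_absent(v))
        values[[op$slot]] <- cast_scalar(v, op$new_range, paste0("/", op$slot), src_schema)
    } else if (op$kind == "recardinalize") {
      v <- values[[op$slot]]
      if (is.null(v)) next
      if (isTRUE(op$multivalued) && is_scalar_value(v)) values[[op$slot]] <- list(v)
      if (isFALSE(op$multivalued) && is_array_value(v) && length(v) == 1L)
        values[[op$slot]] <- v[[1]]
    } else if (op$kind == "subset") {
      if (!doc$class_name %in% as.character(op$keep_classes))
        sk_stop(sprintf("operation %d: document class '%s' removed by subset",
                        i, doc$class_name), "reference_error")
      keep <- op$keep_slots[[doc$class_name]]
      if (!is.null(keep)) values <- values[intersect(names(values), keep)]
    }
  }
  instance_document(doc$class_name, values)
}

#' Apply a transform end to end
#'
#' Convenience wrapper producing the derived schema, a reusable data
#' mapper, and the audit trail.
#'
#' @param schema Source `schema_definition`.
#' @param spec A [transform_spec()].
#' @return A `transform_result`: list with `derived_schema`, `data_mapper`
#'   (a function of one [instance_document()]) and `audit`.
#' @export
apply_transform <- function(schema, spec) {
  derived <- derive_schema(schema, spec)
  src_ms <- tryCatch(materialize(schema), error = function(e) NULL)
  structure(list(
    derived_schema = derived,
    data_mapper = function(doc) transform_instance(doc, spec, src_ms),
    audit = attr(derived, "audit")
  ), class = "transform_result")
}
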