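# Instance validation against a materialized schema.
#
# All data problems become report issues; the only exception raised is
# UnknownClass. Closed-world by default: slots not in the induced view are
# errors (downgraded to warnings in open-world mode). An empty string is
# treated as "value absent" (spreadsheet blank-cell policy) and flagged only
# when the slot is required.

#' Construct an instance document
#'
#' @param class_name Name of the class this document instantiates.
#' @param values Named list of slot values. Scalars are length-1 vectors,
#'   multivalued slots are unnamed lists, nested class instances are named
#'   lists (or `instance_document`s).
#' @export
instance_document <- function(class_name, values = list()) {
  stopifnot(is_string(class_name), is.list(values))
  structure(list(class_name = class_name, values = values),
            class = "instance_document")
}

issue <- function(severity, check, path, message, value = NA_character_) {
  list(severity = severity, check = check, path = path, message = message,
       value = as.character(value)[1])
}

#' Assemble a validation report
#' @param issues List of issue records.
#' @return A `validation_report` with severity counts.
#' @export
validation_report <- function(issues = list()) {
  sev <- vapply(issues, function(i) i$severity, character(1))
  structure(list(issues = issues,
                 n_error = sum(sev == "ERROR"),
                 n_warning = sum(sev == "WARNING")),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report> ", x$n_error, " error(s), ", x$n_warning,
      " warning(s)\n", sep = "")
  for (i in x$issues)
    cat(sprintf("  [%s] %s %s: %s\n", i$severity, i$check, i$path, i$message))
  invisible(x)
}

#' Is a report free of errors?
#' @param report A `validation_report`.
#' @export
report_valid <- function(report) report$n_error == 0L

#' Convert a validation report to a data frame
#' @param x A `validation_report`.
#' @param ... Unused.
#' @export
as.data.frame.validation_report <- function(x, ...) {
  if (length(x$issues) == 0L)
    return(data.frame(severity = character(0), check = character(0),
                      path = character(0), message = character(0),
                      value = character(0), stringsAsFactors = FALSE))
  do.call(rbind, lapply(x$issues, function(i)
    data.frame(severity = i$severity, check = i$check, path = i$path,
               message = i$message, value = i$value, stringsAsFactors = FALSE)))
}

is_scalar_value <- function(v) is.atomic(v) && length(v) == 1L
is_array_value <- function(v) is.list(v) && is.null(names(v))
is_object_value <- function(v) {
  inherits(v, "instance_document") ||
    (is.list(v) && (!is.null(names(v)) || length(v) == 0L))
}
value_absent <- function(v) {
  is.null(v) || (is.character(v) && length(v) == 1L && !is.na(v) && !nzchar(trimws(v)))
}

resolve_type_base <- function(schema, range) {
  pat <- NULL
  seen <- character(0)
  while (TRUE) {
    t <- schema$types[[range]] %||% builtin_types()[[range]]
    if (is.null(t)) return(NULL)
    pat <- pat %||% t$pattern
    if (t$base == t$name || t$name %in% seen) return(list(base = t$base, pattern = pat))
    if (t$base %in% TYPE_BASES && is.null(schema$types[[t$base]]))
      return(list(base = t$base, pattern = pat))
    seen <- c(seen, t$name)
    range <- t$base
  }
}

check_scalar_type <- function(base, v) {
  switch(base,
    integer = (is.numeric(v) && !is.logical(v) && is.finite(v) && v == floor(v)),
    float = (is.numeric(v) && !is.logical(v)),
    boolean = is.logical(v) && !is.na(v),
    string = is.character(v),
    uri = is.character(v) && grepl(":", v, fixed = TRUE),
    uriorcurie = is.character(v) && grepl(":", v, fixed = TRUE),
    date = is.character(v) && grepl("^[0-9]{4}-[0-9]{2}-[0-9]{2}$", v),
    datetime = is.character(v) &&
      grepl("^[0-9]{4}-[0-9]{2}-[0-9]{2}[T ][0-9]{2}:[0-9]{2}(:[0-9]{2})?", v),
    is.character(v))
}

enum_match <- function(enum, v) {
  pvs <- names(enum$permissible_values)
  if (!is.character(v) || length(v) != 1L) return(FALSE)
  if (enum$case_insensitive) tolower(v) %in% tolower(pvs) else v %in% pvs
}

native_check_doc <- function(ms, doc, path_prefix = "", closed = TRUE) {
  schema <- ms$source
  class_name <- doc$class_name
  if (!class_name %in% names(schema$classes))
    sk_stop(sprintf("unknown class: '%s'", class_name), "unknown_class")
  slots <- ms$induced[[class_name]]
  slot_names <- vapply(slots, function(s) s$name, character(1))
  issues <- list()
  add <- function(...) issues[[length(issues) + 1L]] <<- issue(...)
  values <- doc$values

  unknown <- setdiff(names(values), slot_names)
  for (u in unknown)
    add(if (closed) "ERROR" else "WARNING", "unknown_slot",
        paste0(path_prefix, "/", u),
        sprintf("slot '%s' is not defined for class '%s'", u, class_name))

  check_scalar <- function(s, v, path) {
    rng <- s$definition$range
    if (rng %in% names(schema$classes)) {
      if (!is_object_value(v)) {
        add("ERROR", "type", path,
            sprintf("expected a nested '%s' object", rng), v)
        return(invisible())
      }
      sub <- if (inherits(v, "instance_document")) v else instance_document(rng, v)
      issues <<- c(issues, native_check_doc(ms, sub, path, closed))
      return(invisible())
    }
    if (!is_scalar_value(v)) {
      add("ERROR", "shape", path, "expected a single scalar value", "")
      return(invisible())
    }
    if (rng %in% names(schema$enums)) {
      if (!enum_match(schema$enums[[rng]], v))
        add("ERROR", "enum_miss", path,
            sprintf("value not among permissible values of enum '%s'", rng), v)
      return(invisible())
    }
    tb <- resolve_type_base(schema, rng)
    if (is.null(tb)) return(invisible())  # dangling range caught at materialization
    if (!check_scalar_type(tb$base, v)) {
      add("ERROR", "type", path,
          sprintf("value does not conform to type '%s' (base %s)", rng, tb$base), v)
      return(invisible())
    }
    for (pat in c(tb$pattern, s$definition$pattern)) {
      if (!is.null(pat) && is.character(v) &&
          !grepl(paste0("^(?:", pat, ")$"), v, perl = TRUE))
        add("ERROR", "pattern", path,
            sprintf("value does not match pattern '%s'", pat), v)
    }
    invisible()
  }

  for (s in slots) {
    nm <- s$name
    path <- paste0(path_prefix, "/", nm)
    v <- values[[nm]]
    def <- s$definition
    if (value_absent(v) || (is_array_value(v) && length(v) == 0L && def$required)) {
      if (def$required)
        add("ERROR", "required_missing", path,
            sprintf("required slot '%s' is missing", nm))
      next
    }
    if (def$multivalued) {
      if (!is_array_value(v)) {
        add("ERROR", "shape", path,
            sprintf("slot '%s' is multivalued; expected a list of values", nm))
        next
      }
      n <- length(v)
      lo <- def$minimum_cardinality
      hi <- def$maximum_cardinality
      if (!is.null(lo) && n < lo)
        add("ERROR", "cardinality", path,
            sprintf("%d value(s) supplied; at least %d required", n, lo))
      if (!is.null(hi) && n > hi)
        add("ERROR", "cardinality", path,
            sprintf("%d value(s) supplied; at most %d allowed", n, hi))
      for (k in seq_along(v)) check_scalar(s, v[[k]], paste0(path, "/", k))
    } else {
      if (is_array_value(v)) {
        add("ERROR", "shape", path,
            sprintf("slot '%s' is single-valued; got a list", nm))
        next
      }
      check_scalar(s, v, path)
    }
  }
  issues
}

#' Validate one instance document
#'
#' @param ms A `materialized_schema`.
#' @param doc An [instance_document()].
#' @param closed Closed-world flag: if `TRUE` (default) unknown slots are
#'   errors, otherwise warnings.
#' @param engine Validation engine name; see [validation_engines()].
#' @return A `validation_report`.
#' @export
validate_instance <- function(ms, doc, closed = TRUE, engine = "native") {
  stopifnot(inherits(ms, "materialized_schema"), inherits(doc, "instance_document"))
  eng <- validation_engines()[[engine]]
  if (is.null(eng))
    sk_stop(sprintf("unknown validation engine: '%s'", engine), "unknown_engine")
  artifact <- eng$prepare(ms, doc$class_name, closed)
  validation_report(eng$check(artifact, doc))
}

#' Validate a collection of documents
#'
#' Per-document validation (paths prefixed by the 1-based document ordinal),
#' plus duplicate-identifier detection when the shared class declares an
#' identifier slot.
#'
#' @param ms A `materialized_schema`.
#' @param docs List of [instance_document()]s.
#' @inheritParams validate_instance
#' @return A `validation_report`.
#' @export
validate_collection <- function(ms, docs, closed = TRUE) {
  issues <- list()
  for (i in seq_along(docs)) {
    issues <- c(issues, native_check_doc(ms, docs[[i]],
                                         path_prefix = paste0("/", i),
                                         closed = closed))
  }
  classes <- unique(vapply(docs, function(d) d$class_name, character(1)))
  if (length(classes) == 1L && length(docs) > 0L) {
    id_slot <- ms$identifier_slot[[classes]]
    if (!is.null(id_slot) && !is.na(id_slot)) {
      ids <- vapply(docs, function(d) {
        v <- d$values[[id_slot]]
        if (is_scalar_value(v)) as.character(v) else NA_character_
      }, character(1))
      seen_at <- list()
      for (i in seq_along(ids)) {
        if (is.na(ids[i])) next
        if (!is.null(seen_at[[ids[i]]])) {
          issues[[length(issues) + 1L]] <- issue(
            "ERROR", "duplicate_identifier",
            paste0("/", i, "/", id_slot),
            sprintf("identifier '%s' already used by document %d",
                    ids[i], seen_at[[ids[i]]]), ids[i])
        } else seen_at[[ids[i]]] <- i
      }
    }
  }
  validation_report(issues)
}

#' Registered validation engines
#'
#' The validator has a plugin contract: an engine is a list of
#' `name`, `prepare(ms, class_name, closed) -> artifact` and
#' `check(artifact, doc) -> issues`. Two engines ship with the package: the
#' `native` interpreter of the induced view, and `json_schema`, which
#' validates against the JSON Schema produced by [gen_json_schema()].
#'
#' @return Named list of engines.
#' @export
validation_engines <- function() {
  list(
    native = list(
      name = "native",
      prepare = function(ms, class_name, closed = TRUE)
        list(ms = ms, closed = closed),
      check = function(artifact, doc)
        native_check_doc(artifact$ms, doc, closed = artifact$closed)
    ),
    json_schema = list(
      name = "json_schema",
      prepare = function(ms, class_name, closed = TRUE) {
        art <- gen_json_schema(ms, class_name, closed = closed)
        jsonlite::fromJSON(art$files[[grep("schema\\.json$", names(art$files))]],
                           simplifyVector = FALSE)
      },
      check = function(artifact, doc) {
        fails <- json_schema_check(artifact, as_plain_value(doc$values))
        lapply(fails, function(f)
          issue("ERROR", "json_schema", f$path, f$message))
      }
    )
  )
}

# strip instance_document wrappers so values look like parsed JSON
as_plain_value <- function(v) {
  if (inherits(v, "instance_document")) return(as_plain_value(v$values))
  if (is.list(v)) return(lapply(v, as_plain_value))
  v
}

#' Read instance documents from a file
#'
#' JSON and YAML files may hold one document (a mapping) or a list of
#' documents; CSV/TSV rows become flat documents using the header as slot
#' names (blank cells are dropped, honoring the blank-means-absent policy).
#'
#' @param path Input file; format chosen by extension
#'   (`.json`, `.yaml`/`.yml`, `.csv`, `.tsv`).
#' @param class_name Class the documents instantiate.
#' @return List of [instance_document()]s.
#' @export
read_instances <- function(path, class_name) {
  ext <- tolower(tools::file_ext(path))
  to_doc <- function(m) instance_document(class_name, m)
  if (ext == "json") {
    raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  } else if (ext %in% c("yaml", "yml")) {
    raw <- yaml::yaml.load(paste(readLines(path, encoding = "UTF-8", warn = FALSE),
                                 collapse = "\n"))
  } else if (ext %in% c("csv", "tsv")) {
    df <- utils::read.table(path, header = TRUE, sep = if (ext == "csv") "," else "\t",
                            colClasses = "character", check.names = FALSE,
                            stringsAsFactors = FALSE, quote = "\"",
                            encoding = "UTF-8")
    return(lapply(seq_len(nrow(df)), function(i) {
      row <- as.list(df[i, , drop = FALSE])
      row <- row[vapply(row, function(x) nzchar(trimws(x)), logical(1))]
      to_doc(row)
    }))
  } else {
    sk_stop(sprintf("unsupported instance file extension: '%s'", ext), "io_error")
  }
  if (is.list(raw) && is.null(names(raw))) lapply(raw, to_doc) else list(to_doc(raw))
}
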