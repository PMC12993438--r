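# Tabular schema authoring: a spreadsheet whose second row is a
# ">"-prefixed directive row mapping columns to metamodel fields
# (class, slot, cardinality, required, range, is_a, description), plus
# schema bootstrapping from raw data tables.

SHEET_TOKENS <- c("class", "slot", "cardinality", "required", "range",
                  "is_a", "description")

#' Construct a sheet table
#'
#' @param header Character vector of human-readable column labels.
#' @param directive Character vector of metamodel tokens, one per column
#'   (drawn from `class, slot, cardinality, required, range, is_a,
#'   description`).
#' @param rows List of character vectors, one per data row.
#' @export
sheet_table <- function(header, directive, rows = list()) {
  if (length(directive) != length(header))
    sk_stop("directive row length must equal header length", "missing_directive_row")
  unknown <- setdiff(directive[nzchar(directive)], SHEET_TOKENS)
  if (length(unknown) > 0)
    sk_stop(sprintf("unknown directive token(s): %s", paste(unknown, collapse = ", ")),
            "unknown_directive_token")
  if (!"class" %in% directive)
    sk_stop("directive row must include the 'class' (element name) column",
            "missing_directive_row")
  rows <- lapply(rows, function(r) {
    r <- as.character(r)
    length(r) <- length(header)
    r[is.na(r)] <- ""
    r
  })
  structure(list(header = header, directive = directive, rows = rows),
            class = "sheet_table")
}

#' @export
print.sheet_table <- function(x, ...) {
  cat("<sheet_table> ", length(x$rows), " row(s)\n", sep = "")
  cat("  ", paste(x$directive, collapse = " | "), "\n", sep = "")
  invisible(x)
}

#' Read a schema sheet from TSV/CSV
#'
#' Layout: line 1 holds human-readable column labels, line 2 the
#' `>`-prefixed directive row; any further `>`-only rows are skipped.
#'
#' @param path File path, or a character vector of lines via `text`.
#' @param sep Cell delimiter; tab by default, use `","` for CSV.
#' @param text Character vector of lines (alternative to `path`).
#' @export
read_sheet <- function(path = NULL, sep = "\t", text = NULL) {
  lines <- text %||% readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L)
    sk_stop("sheet needs a header row and a directive row", "missing_directive_row")
  split_row <- function(line) {
    if (sep == ",") as.character(utils::read.csv(text = line, header = FALSE,
                                                 colClasses = "character")[1, ])
    else strsplit(line, sep, fixed = TRUE)[[1]]
  }
  header <- trimws(split_row(lines[1]))
  dline <- lines[2]
  if (!startsWith(trimws(dline), ">"))
    sk_stop("second row must be the '>'-prefixed directive row", "missing_directive_row")
  directive <- trimws(sub("^\\s*>\\s*", "", trimws(split_row(dline))))
  body <- lines[-(1:2)]
  body <- body[!startsWith(trimws(body), ">")]
  rows <- lapply(body, split_row)
  length(directive) <- length(header)
  directive[is.na(directive)] <- ""
  sheet_table(header, directive, rows)
}

sheet_col <- function(table, token) match(token, table$directive)

#' Convert a schema sheet to a schema definition
#'
#' A row with a class name and no slot declares the class; a row with both
#' attaches a slot (inline attribute) to that class. The cardinality column
#' is parsed with [parse_cardinality()]; the required column (TRUE/FALSE,
#' case-insensitive, blank = unset) wins for the required flag, while
#' cardinality governs multivaluedness (max > 1) and is retained as
#' `minimum_cardinality`/`maximum_cardinality`. A minimum cardinality of 1
#' or more combined with an explicit `required: FALSE` is a contradiction
#' and rejected.
#'
#' @param table A [sheet_table()].
#' @param id,name Schema metadata for the resulting definition.
#' @return A `schema_definition`.
#' @export
sheet_to_schema <- function(table, id = "https://example.org/sheet-schema",
                            name = "sheet_schema") {
  stopifnot(inherits(table, "sheet_table"))
  col <- function(token) sheet_col(table, token)
  get <- function(row, token) {
    i <- col(token)
    if (is.na(i)) "" else trimws(row[i])
  }
  classes <- list()
  for (k in seq_along(table$rows)) {
    row <- table$rows[[k]]
    cls <- get(row, "class")
    slt <- get(row, "slot")
    if (!nzchar(cls))
      sk_stop(sprintf("row %d: blank element-name cell", k), "blank_element_name")
    if (!cls %in% names(classes))
      classes[[cls]] <- class_definition(cls)
    if (!nzchar(slt)) {
      # class-declaration row: description / is_a apply to the class
      d <- get(row, "description"); p <- get(row, "is_a")
      if (nzchar(d)) classes[[cls]]$description <- d
      if (nzchar(p)) classes[[cls]]$is_a <- p
      next
    }
    card_tok <- get(row, "cardinality")
    req_tok <- toupper(get(row, "required"))
    required <- NA
    if (req_tok %in% c("TRUE", "FALSE")) required <- req_tok == "TRUE"
    else if (nzchar(req_tok))
      sk_stop(sprintf("row %d: required column must be TRUE/FALSE, got '%s'", k, req_tok),
              "unknown_directive_token")
    multivalued <- NA
    min_card <- NULL; max_card <- NULL
    if (nzchar(card_tok)) {
      card <- parse_cardinality(card_tok)
      if (card$min >= 1L && isFALSE(required))
        sk_stop(sprintf(
          "row %d: cardinality '%s' requires at least one value but required is FALSE",
          k, card_tok), "cardinality_required_conflict")
      if (is.na(required) && card$min >= 1L) required <- TRUE
      multivalued <- !is.finite(card$max) || card$max > 1L
      min_card <- card$min
      if (is.finite(card$max)) max_card <- card$max
    }
    rng <- get(row, "range"); dsc <- get(row, "description")
    classes[[cls]]$attributes[[slt]] <- slot_definition(
      slt,
      description = if (nzchar(dsc)) dsc,
      range = if (nzchar(rng)) rng,
      required = required,
      multivalued = multivalued,
      minimum_cardinality = min_card,
      maximum_cardinality = max_card
    )
  }
  schema_definition(id = id, name = name, classes = classes)
}

#' Convert a schema definition to a schema sheet
#'
#' Inverse of [sheet_to_schema()] on the subset of features the directive
#' vocabulary can express. Features outside that subset (enums, prefixes,
#' patterns, slot_usage, ...) are dropped with a warning list attached as
#' `attr(x, "export_warnings")`.
#'
#' @param schema A `schema_definition`.
#' @return A [sheet_table()].
#' @export
schema_to_sheet <- function(schema) {
  stopifnot(inherits(schema, "schema_definition"))
  warnings <- character(0)
  for (cat in c("slots", "enums", "types")) {
    if (length(schema[[cat]]) > 0)
      warnings <- c(warnings, sprintf("schema-level %s not expressible in sheet form; dropped", cat))
  }
  rows <- list()
  for (cn in names(schema$classes)) {
    cl <- schema$classes[[cn]]
    rows[[length(rows) + 1L]] <- c(cn, "", "", "", "", cl$is_a %||% "",
                                   cl$description %||% "")
    if (length(cl$slot_usage) > 0)
      warnings <- c(warnings, sprintf("slot_usage of class '%s' not expressible; dropped", cn))
    for (a in names(cl$attributes)) {
      s <- cl$attributes[[a]]
      lo <- s$minimum_cardinality %||%
        (if (isTRUE(s$required)) 1L else 0L)
      hi <- s$maximum_cardinality %||%
        (if (isTRUE(s$multivalued)) UNBOUNDED else 1L)
      card <- format_cardinality(cardinality(lo, hi))
      req <- if (is.na(s$required)) "" else if (s$required) "TRUE" else "FALSE"
      if (!is.null(s$pattern) || !is.null(s$slot_uri) || length(s$mappings) > 0)
        warnings <- c(warnings, sprintf("slot '%s.%s': pattern/uri/mappings dropped", cn, a))
      rows[[length(rows) + 1L]] <- c(cn, a, card, req, s$range %||% "", "",
                                     s$description %||% "")
    }
  }
  out <- sheet_table(
    header = c("record", "field", "multiplicity", "required", "range",
               "parents", "desc"),
    directive = SHEET_TOKENS,
    rows = rows)
  attr(out, "export_warnings") <- warnings
  out
}

#' Write a schema sheet to a TSV/CSV file
#' @param table A [sheet_table()].
#' @param path Output path.
#' @param sep Cell delimiter.
#' @export
write_sheet <- function(table, path, sep = "\t") {
  join <- function(cells) paste(cells, collapse = sep)
  directive <- table$directive
  directive[1] <- paste(">", directive[1])
  lines <- c(join(table$header), join(directive),
             vapply(table$rows, join, character(1)))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Bootstrap a schema from a raw data table
#'
#' Infers one class with one slot per column. Ranges are inferred by
#' scanning values: all-integer columns become `integer`, all-numeric
#' `float`, all-boolean `boolean`; a column with few distinct, repeating,
#' non-numeric values becomes an enum of those values; everything else is
#' `string`. A column whose blank fraction is below `required_threshold`
#' is marked required.
#'
#' @param data A data frame of character columns, or a list of named
#'   character records.
#' @param class_name Name for the inferred class.
#' @param id,name Schema metadata.
#' @param enum_k Maximum distinct values for enum inference.
#' @param enum_ratio Minimum rows-per-distinct-value ratio for enum
#'   inference.
#' @param required_threshold Maximum blank fraction for a slot to be
#'   considered required.
#' @return A `schema_definition` with one class and one enum per inferred
#'   enum slot.
#' @export
infer_schema_from_table <- function(data, class_name = "Row",
                                    id = "https://example.org/inferred-schema",
                                    name = "inferred_schema",
                                    enum_k = 10L, enum_ratio = 1.5,
                                    required_threshold = 0.1) {
  if (is.data.frame(data)) {
    cols <- stats::setNames(lapply(data, as.character), names(data))
  } else if (is.list(data) && length(data) > 0) {
    nms <- unique(unlist(lapply(data, names)))
    cols <- stats::setNames(lapply(nms, function(nm)
      vapply(data, function(r) as.character(r[[nm]] %||% ""), character(1))), nms)
  } else {
    cols <- list()
  }
  n <- if (length(cols) > 0) length(cols[[1]]) else 0L
  if (n == 0L) sk_stop("cannot infer a schema from an empty table", "empty_table")

  enums <- list()
  attrs <- list()
  for (nm in names(cols)) {
    vals <- trimws(cols[[nm]])
    nonblank <- vals[nzchar(vals)]
    blank_frac <- 1 - length(nonblank) / length(vals)
    rng <- "string"
    if (length(nonblank) > 0) {
      if (all(grepl("^[+-]?[0-9]+$", nonblank))) {
        rng <- "integer"
      } else if (!anyNA(suppressWarnings(as.numeric(nonblank)))) {
        rng <- "float"
      } else if (all(tolower(nonblank) %in% c("true", "false"))) {
        rng <- "boolean"
      } else {
        distinct <- unique(nonblank)
        if (length(distinct) <= enum_k &&
            length(nonblank) / length(distinct) >= enum_ratio) {
          enum_name <- paste0(
            gsub("(^|_)([a-z])", "\\U\\2", to_snake_case(nm), perl = TRUE), "Enum")
          enums[[enum_name]] <- enum_definition(
            enum_name,
            description = sprintf("Values observed in column '%s'.", nm),
            permissible_values = stats::setNames(
              rep(list(list(description = NULL, meaning = NULL)), length(distinct)),
              sort(distinct)))
          rng <- enum_name
        }
      }
    }
    attrs[[nm]] <- slot_definition(
      nm, range = rng,
      description = sprintf("Inferred from column '%s'.", nm),
      required = if (blank_frac < required_threshold) TRUE else NA)
  }
  schema_definition(
    id = id, name = name,
    classes = stats::setNames(list(class_definition(
      class_name, description = "Class inferred from a data table.",
      attributes = attrs)), class_name),
    enums = enums)
}
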