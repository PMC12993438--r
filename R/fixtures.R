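# Worked-example fixtures: the microbiome Sample schema, a synthetic
# messy-spreadsheet generator with recorded ground truth, and the
# harmonization pipeline that turns messy rows into schema-conformant
# documents. The generator emulates the classic failure modes of hand-kept
# sampling sheets: a cryptic "dep" column holding depths in mixed units and
# formats, free-text environment terms with case and synonym noise, a fused
# "position" column holding "lat, lon", and blank cells.

#' Path to the bundled Sample schema fixture
#' @export
sample_schema_file <- function() {
  system.file("extdata", "sample_schema.yaml", package = "schemakit", mustWork = TRUE)
}

#' The bundled microbiome Sample schema
#'
#' A Sample class with an identifier, required latitude/longitude, an
#' optional depth in metres and an environment type constrained to an
#' ENVO-mapped enumeration. The prefix bases (including the MIXS base) are
#' fixture constants.
#'
#' @param materialized If `TRUE`, return the [materialize()]d schema.
#' @export
sample_schema <- function(materialized = FALSE) {
  s <- read_schema(sample_schema_file())
  if (materialized) materialize(s) else s
}

#' A small sample-site hierarchy schema
#'
#' Two classes built in code: a general `SampleSite` (identifier + name) and
#' an `AirSampleSite` specialization adding air-specific measurements
#' (humidity, PM2.5 level), illustrating inheritance.
#' @export
site_hierarchy_schema <- function() {
  schema_definition(
    id = "https://example.org/site-schema", name = "site_schema",
    title = "Sample Site Hierarchy",
    classes = list(
      SampleSite = class_definition(
        "SampleSite", description = "A location samples are collected from.",
        attributes = list(
          site_id = slot_definition("site_id", identifier = TRUE, range = "uriorcurie",
                                    description = "Unique identifier of the site."),
          name = slot_definition("name", range = "string",
                                 description = "Human-readable site name."))),
      AirSampleSite = class_definition(
        "AirSampleSite", is_a = "SampleSite",
        description = "A site where air samples are collected.",
        attributes = list(
          humidity = slot_definition("humidity", range = "float",
                                     description = "Relative humidity in percent.",
                                     unit = "%"),
          pm2_5_level = slot_definition("pm2_5_level", range = "float",
                                        description = "PM2.5 concentration in ug/m3.",
                                        unit = "ug/m3")))))
}

harmonize_config <- function() {
  path <- system.file("extdata", "harmonize_config.yaml", package = "schemakit",
                      mustWork = TRUE)
  yaml::yaml.load(paste(readLines(path, encoding = "UTF-8", warn = FALSE),
                        collapse = "\n"))
}

#' Depth unit table used by the harmonizer
#' @return Named numeric vector: unit label -> factor to metres.
#' @export
default_unit_table <- function() unlist(harmonize_config()$units)

#' Environment-term synonym table used by the harmonizer
#' @return Named character vector: lower-cased free text -> canonical enum
#'   value.
#' @export
default_synonym_table <- function() unlist(harmonize_config()$synonyms)

#' Convert a depth value between units
#' @param value Numeric value.
#' @param from Unit label (must be in `unit_table`).
#' @param unit_table Named vector of factors to metres.
#' @return Value in metres.
#' @export
convert_depth <- function(value, from, unit_table = default_unit_table()) {
  if (!from %in% names(unit_table))
    sk_stop(sprintf("unknown depth unit: '%s'", from), "unknown_unit")
  value * unname(unit_table[[from]])
}

#' Parse a free-form depth string to metres
#'
#' Accepts `"<x> <unit>"`, `"<x><unit>"` and bare numbers (interpreted as
#' metres).
#'
#' @param text Depth cell text.
#' @param unit_table Named vector of factors to metres.
#' @return Depth in metres, or `NA` when unparseable.
#' @export
parse_depth <- function(text, unit_table = default_unit_table()) {
  m <- regmatches(text, regexec("^\\s*([0-9]*\\.?[0-9]+)\\s*([A-Za-z]*)\\s*$",
                                text))[[1]]
  if (length(m) == 0L) return(NA_real_)
  unit <- if (nzchar(m[3])) tolower(m[3]) else "m"
  if (!unit %in% names(unit_table)) return(NA_real_)
  convert_depth(as.numeric(m[2]), unit, unit_table)
}

#' Format a depth in metres as a full-precision cell string
#'
#' Inverse of [parse_depth()]: rendering a converted value and reparsing it
#' recovers the value (to well under 1e-9), so unit conversion is closed
#' under a format/parse round-trip.
#'
#' @param value_m Depth in metres.
#' @export
format_depth <- function(value_m) {
  paste0(format(value_m, scientific = FALSE, trim = TRUE, digits = 15), " m")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic messy sampling table
#'
#' Produces rows with depth values in randomly chosen unit dialects
#' (`"30 cm"`, `"30cm"`, `"0.5 meters"`, bare numbers meaning metres),
#' free-text environment terms with case and synonym noise, and a fused
#' `position` cell (`"lat, lon"`). All of those are recoverable formatting
#' variation. Unrecoverable faults are injected at the given rates and
#' recorded in a ground-truth fault inventory; at most one fault is applied
#' per cell so each injected fault is observable.
#'
#' @param seed Integer seed; the same seed yields the identical table.
#' @param n_rows Number of rows (>= 1).
#' @param fault_rates Named list of per-cell probabilities:
#'   `blank` (cell emptied), `bad_depth` (depth replaced by free text),
#'   `bad_environment` (environment replaced by an unmatched term).
#' @return A `messy_table`: list with `header`, `rows`,
#'   `ground_truth` (data frame of the clean values each row encodes) and
#'   `faults` (data frame `row`, `column`, `kind`).
#' @export
generate_messy_samples <- function(seed, n_rows,
                                   fault_rates = list(blank = 0, bad_depth = 0,
                                                      bad_environment = 0)) {
  if (n_rows < 1) sk_stop("n_rows must be >= 1", "bad_argument")
  rates <- list(blank = fault_rates$blank %||% 0,
                bad_depth = fault_rates$bad_depth %||% 0,
                bad_environment = fault_rates$bad_environment %||% 0)
  for (r in names(rates))
    if (rates[[r]] < 0 || rates[[r]] > 1)
      sk_stop(sprintf("fault rate '%s' must be in [0, 1]", r), "bad_argument")

  units <- default_unit_table()
  synonyms <- default_synonym_table()
  enum_values <- names(sample_schema()$enums$EnvironmentTypeEnum$permissible_values)

  with_seed(seed, {
    depth_units <- sample(c("m", "cm", "mm", "ft", "in"), n_rows, replace = TRUE)
    depth_raw <- vapply(depth_units, function(u) {
      switch(u,
        m = round(stats::runif(1, 0.1, 50), 2),
        cm = round(stats::runif(1, 1, 500), 1),
        mm = round(stats::runif(1, 10, 5000), 0),
        ft = round(stats::runif(1, 0.5, 150), 1),
        `in` = round(stats::runif(1, 4, 2000), 0))
    }, numeric(1))
    depth_style <- sample(c("spaced", "fused", "word", "bare"), n_rows, replace = TRUE)
    dep_cells <- vapply(seq_len(n_rows), function(i) {
      u <- depth_units[i]; v <- format(depth_raw[i], scientific = FALSE, trim = TRUE)
      switch(depth_style[i],
        spaced = paste0(v, " ", u),
        fused = paste0(v, u),
        word = if (u == "m") paste0(v, " meters") else paste0(v, " ", u),
        bare = if (u == "m") v else paste0(v, " ", u))
    }, character(1))
    depth_m <- round(vapply(seq_len(n_rows), function(i)
      convert_depth(depth_raw[i], depth_units[i], units), numeric(1)), 3)

    latitude <- round(stats::runif(n_rows, -60, 70), 2)
    longitude <- round(stats::runif(n_rows, -180, 180), 2)
    pos_cells <- paste0(latitude, ", ", longitude)

    env_true <- sample(enum_values, n_rows, replace = TRUE)
    env_cells <- vapply(seq_len(n_rows), function(i) {
      ct <- env_true[i]
      forms <- c(ct, toupper(ct),
                 paste0(toupper(substring(ct, 1, 1)), substring(ct, 2)))
      syns <- names(synonyms)[synonyms == ct]
      if (length(syns) > 0) forms <- c(forms, syns)
      sample(forms, 1)
    }, character(1))

    rows <- lapply(seq_len(n_rows), function(i) c(dep_cells[i], pos_cells[i], env_cells[i]))
    faults <- list()
    bad_depth_texts <- c("deep", "shallow", "n/a", "surface?")
    bad_env_texts <- c("???", "unknown habitat", "misc")
    columns <- c("dep", "position", "env")
    for (i in seq_len(n_rows)) {
      for (j in seq_along(columns)) {
        u <- stats::runif(1)
        if (u < rates$blank) {
          rows[[i]][j] <- ""
          faults[[length(faults) + 1L]] <- data.frame(
            row = i, column = columns[j], kind = "blank", stringsAsFactors = FALSE)
        } else if (columns[j] == "dep" && u < rates$blank + rates$bad_depth) {
          rows[[i]][j] <- sample(bad_depth_texts, 1)
          faults[[length(faults) + 1L]] <- data.frame(
            row = i, column = "dep", kind = "bad_depth", stringsAsFactors = FALSE)
        } else if (columns[j] == "env" && u < rates$blank + rates$bad_environment) {
          rows[[i]][j] <- sample(bad_env_texts, 1)
          faults[[length(faults) + 1L]] <- data.frame(
            row = i, column = "env", kind = "bad_environment", stringsAsFactors = FALSE)
        }
      }
    }
    structure(list(
      header = columns,
      rows = rows,
      ground_truth = data.frame(
        row = seq_len(n_rows), depth_m = depth_m, latitude = latitude,
        longitude = longitude, environment_type = env_true,
        stringsAsFactors = FALSE),
      faults = if (length(faults) > 0) do.call(rbind, faults) else
        data.frame(row = integer(0), column = character(0), kind = character(0),
                   stringsAsFactors = FALSE)
    ), class = "messy_table")
  })
}

#' @export
print.messy_table <- function(x, ...) {
  cat("<messy_table> ", length(x$rows), " row(s), ", nrow(x$faults),
      " injected fault(s)\n", sep = "")
  invisible(x)
}

#' Harmonize a messy sampling table against the Sample schema
#'
#' Depth strings are parsed against the unit table and converted to metres
#' (rounded to 3 decimals); the fused position cell is split via the
#' declarative transform engine; environment text is matched to the enum's
#' permissible values after case folding and synonym lookup; CURIE
#' identifiers are minted as `<prefix>:<zero-padded ordinal>`. Unparseable
#' or blank cells become report issues and the affected slot is left
#' absent; a row whose resulting document fails validation is rejected.
#'
#' @param table A [generate_messy_samples()] table (or any `messy_table`).
#' @param ms A materialized Sample schema; default [sample_schema()].
#' @param unit_table,synonyms Harmonization configuration.
#' @param id_prefix Prefix for minted identifiers.
#' @return A `harmonization_result`: `clean_docs` (validating
#'   [instance_document()]s), `report` (a `validation_report` of
#'   harmonization issues), `provenance` (per-cell data frame of raw value,
#'   parsed value, action) and `rejected_rows`.
#' @export
harmonize_samples <- function(table, ms = sample_schema(materialized = TRUE),
                              unit_table = default_unit_table(),
                              synonyms = default_synonym_table(),
                              id_prefix = "ex") {
  stopifnot(inherits(table, "messy_table"))
  enum <- ms$source$enums$EnvironmentTypeEnum
  pvs <- names(enum$permissible_values)
  split_spec <- transform_spec(list(list(
    kind = "split", class = "Sample", source_slot = "position",
    targets = c("latitude", "longitude"), delimiter = ",",
    target_ranges = c("float", "float"))))

  issues <- list()
  prov <- list()
  note <- function(row, column, raw, parsed, action)
    prov[[length(prov) + 1L]] <<- data.frame(
      row = row, column = column, raw = as.character(raw),
      parsed = as.character(parsed), action = action, stringsAsFactors = FALSE)
  flag <- function(severity, check, row, slot, msg, value)
    issues[[length(issues) + 1L]] <<- issue(severity, check,
                                            paste0("/", row, "/", slot), msg, value)

  clean_docs <- list()
  rejected <- integer(0)
  for (i in seq_along(table$rows)) {
    cells <- stats::setNames(as.list(table$rows[[i]]), table$header)
    values <- list(id = paste0(id_prefix, ":", sprintf("%04d", i)))
    note(i, "id", "", values$id, "minted")

    dep <- cells$dep %||% ""
    if (!nzchar(trimws(dep))) {
      note(i, "dep", dep, NA, "blank")
      flag("WARNING", "blank_cell", i, "depth", "blank depth cell", dep)
    } else {
      d <- parse_depth(dep, unit_table)
      if (is.na(d)) {
        note(i, "dep", dep, NA, "rejected")
        flag("ERROR", "unparseable_unit", i, "depth",
             "cannot parse depth value/unit", dep)
      } else {
        values$depth <- round(d, 3)
        note(i, "dep", dep, values$depth, "converted_to_m")
      }
    }

    pos <- cells$position %||% ""
    if (!nzchar(trimws(pos))) {
      note(i, "position", pos, NA, "blank")
      flag("WARNING", "blank_cell", i, "position", "blank position cell", pos)
    } else {
      split_doc <- tryCatch(
        transform_instance(instance_document("Sample", list(position = pos)),
                           split_spec),
        schemakit_error = function(e) NULL)
      if (is.null(split_doc)) {
        note(i, "position", pos, NA, "rejected")
        flag("ERROR", "unparseable_position", i, "position",
             "cannot split position into latitude, longitude", pos)
      } else {
        values$latitude <- split_doc$values$latitude
        values$longitude <- split_doc$values$longitude
        note(i, "position", pos,
             paste(values$latitude, values$longitude, sep = "|"), "split")
      }
    }

    env <- cells$env %||% ""
    if (!nzchar(trimws(env))) {
      note(i, "env", env, NA, "blank")
      flag("WARNING", "blank_cell", i, "environment_type", "blank environment cell", env)
    } else {
      folded <- tolower(trimws(env))
      hit <- if (folded %in% tolower(pvs)) pvs[match(folded, tolower(pvs))]
             else if (folded %in% names(synonyms)) unname(synonyms[[folded]])
             else NA_character_
      if (is.na(hit)) {
        note(i, "env", env, NA, "rejected")
        flag("ERROR", "enum_unmatched", i, "environment_type",
             "environment term matches no permissible value or synonym", env)
      } else {
        values$environment_type <- hit
        note(i, "env", env, hit,
             if (identical(env, hit)) "exact" else "normalized")
      }
    }

    doc <- instance_document("Sample", values)
    if (report_valid(validate_instance(ms, doc))) {
      clean_docs[[length(clean_docs) + 1L]] <- doc
    } else {
      rejected <- c(rejected, i)
    }
  }
  structure(list(
    clean_docs = clean_docs,
    report = validation_report(issues),
    provenance = do.call(rbind, prov),
    rejected_rows = rejected
  ), class = "harmonization_result")
}

#' @export
print.harmonization_result <- function(x, ...) {
  cat("<harmonization_result> ", length(x$clean_docs), " clean doc(s), ",
      length(x$rejected_rows), " rejected row(s), ",
      x$report$n_error, " error issue(s), ", x$report$n_warning,
      " warning issue(s)\n", sep = "")
  invisible(x)
}
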