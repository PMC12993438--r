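# Best-practice linting. Rules are pure functions over the schema; the
# configuration can disable rules, change severities, or pass parameters.
# Default severity is WARNING for every rule: schema style is advisory.

CLASS_NAME_RE <- "^[A-Z][A-Za-z0-9]*$"
SLOT_NAME_RE <- "^[a-z][a-z0-9_]*$"

lint_rule_set <- function() {
  list(
    no_description = function(schema, params) {
      out <- list()
      miss <- function(kind, nm)
        out[[length(out) + 1L]] <<- list(element = nm,
                                         message = sprintf("%s '%s' has no description", kind, nm))
      for (nm in names(schema$classes)) {
        cl <- schema$classes[[nm]]
        if (is.null(cl$description)) miss("class", nm)
        for (a in names(cl$attributes))
          if (is.null(cl$attributes[[a]]$description)) miss("slot", a)
      }
      for (nm in names(schema$slots))
        if (is.null(schema$slots[[nm]]$description)) miss("slot", nm)
      for (nm in names(schema$enums))
        if (is.null(schema$enums[[nm]]$description)) miss("enum", nm)
      out
    },
    class_name_style = function(schema, params) {
      re <- params$pattern %||% CLASS_NAME_RE
      out <- list()
      for (nm in names(schema$classes))
        if (!grepl(re, nm))
          out[[length(out) + 1L]] <- list(element = nm,
                                          message = sprintf("class '%s' is not CamelCase", nm))
      out
    },
    slot_name_style = function(schema, params) {
      re <- params$pattern %||% SLOT_NAME_RE
      out <- list()
      nms <- c(names(schema$slots),
               unlist(lapply(schema$classes, function(cl) names(cl$attributes))))
      for (nm in unique(nms))
        if (!grepl(re, nm))
          out[[length(out) + 1L]] <- list(element = nm,
                                          message = sprintf("slot '%s' is not snake_case", nm))
      out
    },
    range_missing = function(schema, params) {
      out <- list()
      check <- function(nm, s) {
        if (is.null(s$range) && is.null(schema$default_range))
          out[[length(out) + 1L]] <<- list(element = nm,
                                           message = sprintf("slot '%s' has no range and the schema has no default_range", nm))
      }
      for (nm in names(schema$slots)) check(nm, schema$slots[[nm]])
      for (cl in schema$classes)
        for (a in names(cl$attributes)) check(a, cl$attributes[[a]])
      out
    },
    enum_empty = function(schema, params) {
      out <- list()
      for (nm in names(schema$enums))
        if (length(schema$enums[[nm]]$permissible_values) == 0L)
          out[[length(out) + 1L]] <- list(element = nm,
                                          message = sprintf("enum '%s' defines no permissible values", nm))
      out
    }
  )
}

#' Names of the built-in lint rules
#' @export
lint_rules <- function() names(lint_rule_set())

#' Lint a schema against best-practice rules
#'
#' Built-in rules: `no_description` (classes/slots/enums should be
#' documented), `class_name_style` (CamelCase), `slot_name_style`
#' (snake_case), `range_missing` (every slot needs a range or a schema
#' default), `enum_empty` (enums need permissible values).
#'
#' @param schema A `schema_definition`.
#' @param config Optional named list keyed by rule id, each entry a list
#'   with any of `enabled` (logical), `severity` (`ERROR`/`WARNING`/`INFO`)
#'   and `params` (rule-specific, e.g. a replacement `pattern` for the
#'   naming rules).
#' @return A `lint_report`: data frame of findings `(rule, element,
#'   severity, message)`, sorted by element then rule.
#' @export
lint_schema <- function(schema, config = list()) {
  stopifnot(inherits(schema, "schema_definition"))
  rules <- lint_rule_set()
  unknown <- setdiff(names(config), names(rules))
  if (length(unknown) > 0)
    sk_stop(sprintf("unknown lint rule id(s): %s", paste(unknown, collapse = ", ")),
            "unknown_rule_id")
  findings <- list()
  for (rid in names(rules)) {
    cfg <- config[[rid]] %||% list()
    if (isFALSE(cfg$enabled)) next
    sev <- toupper(cfg$severity %||% "WARNING")
    if (!sev %in% c("ERROR", "WARNING", "INFO"))
      sk_stop(sprintf("invalid severity for rule '%s': %s", rid, sev), "unknown_rule_id")
    for (f in rules[[rid]](schema, cfg$params %||% list()))
      findings[[length(findings) + 1L]] <- data.frame(
        rule = rid, element = f$element, severity = sev, message = f$message,
        stringsAsFactors = FALSE)
  }
  out <- if (length(findings) > 0) do.call(rbind, findings) else
    data.frame(rule = character(0), element = character(0),
               severity = character(0), message = character(0),
               stringsAsFactors = FALSE)
  out <- out[order(out$element, out$rule), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("lint_report", "data.frame")
  out
}

#' @export
print.lint_report <- function(x, ...) {
  cat("<lint_report> ", nrow(x), " finding(s)\n", sep = "")
  if (nrow(x) > 0) print.data.frame(x)
  invisible(x)
}

#' Load a lint configuration from YAML
#' @param path YAML file mapping rule ids to `enabled`/`severity`/`params`.
#' @export
read_lint_config <- function(path) {
  cfg <- yaml::yaml.load(paste(readLines(path, encoding = "UTF-8", warn = FALSE),
                               collapse = "\n"))
  cfg %||% list()
}
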