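# Shared test fixtures: programmatic schema builders, random generators for
# property-style tests, and independent brute-force oracles.

two_class_schema <- function() {
  # SampleSite / AirSampleSite pair with a slot_usage override in the child
  s <- site_hierarchy_schema()
  s$classes$AirSampleSite$slot_usage <- list(name = list(required = TRUE))
  s
}

# -- random schema generator (YAML-expressible features) ---------------------

rand_name <- function(prefix, i) paste0(prefix, i)

rand_word <- function() paste(sample(letters, sample(3:8, 1), replace = TRUE),
                              collapse = "")

rand_schema <- function() {
  n_enum <- sample(0:2, 1)
  enums <- list()
  for (e in seq_len(n_enum)) {
    nm <- rand_name("Enum", e)
    n_pv <- sample(0:4, 1)
    pvs <- stats::setNames(
      lapply(seq_len(n_pv), function(k) list(
        description = if (stats::runif(1) < 0.5) rand_word(),
        meaning = if (stats::runif(1) < 0.5) paste0("ENVO:", sprintf("%08d", k)))),
      vapply(seq_len(n_pv), function(k) paste0("val_", e, "_", k), character(1)))
    enums[[nm]] <- enum_definition(nm, description = rand_word(),
                                   permissible_values = pvs,
                                   case_insensitive = stats::runif(1) < 0.2)
  }
  ranges <- c("string", "integer", "float", "boolean", "uriorcurie", names(enums))
  rand_slot <- function(nm) {
    slot_definition(
      nm,
      description = if (stats::runif(1) < 0.7) rand_word(),
      range = sample(ranges, 1),
      required = sample(c(NA, TRUE, FALSE), 1),
      multivalued = sample(c(NA, TRUE, FALSE), 1),
      pattern = if (stats::runif(1) < 0.2) "[a-z]+",
      slot_uri = if (stats::runif(1) < 0.3) paste0("ex:", rand_word()),
      unit = if (stats::runif(1) < 0.2) "m")
  }
  n_gslot <- sample(0:3, 1)
  gslots <- stats::setNames(lapply(seq_len(n_gslot), function(k)
    rand_slot(rand_name("gslot", k))),
    vapply(seq_len(n_gslot), function(k) rand_name("gslot", k), character(1)))
  n_class <- sample(1:3, 1)
  classes <- list()
  for (ci in seq_len(n_class)) {
    nm <- rand_name("Class", ci)
    n_attr <- sample(0:3, 1)
    attrs <- stats::setNames(lapply(seq_len(n_attr), function(k)
      rand_slot(paste0("attr_", ci, "_", k))),
      vapply(seq_len(n_attr), function(k) paste0("attr_", ci, "_", k), character(1)))
    classes[[nm]] <- class_definition(
      nm,
      description = if (stats::runif(1) < 0.7) rand_word(),
      is_a = if (ci > 1 && stats::runif(1) < 0.5) rand_name("Class", sample(ci - 1, 1)),
      abstract = stats::runif(1) < 0.15,
      slots = if (n_gslot > 0 && stats::runif(1) < 0.5)
        sample(names(gslots), sample(n_gslot, 1)) else character(0),
      attributes = attrs)
  }
  schema_definition(
    id = paste0("https://example.org/", rand_word()),
    name = rand_word(), title = if (stats::runif(1) < 0.5) rand_word(),
    license = if (stats::runif(1) < 0.3) "https://creativecommons.org/publicdomain/zero/1.0/",
    prefixes = prefix_map(ex = "https://example.org/",
                          ENVO = "http://purl.obolibrary.org/obo/ENVO_"),
    default_range = "string",
    classes = classes, slots = gslots, enums = enums)
}

# restricted generator: only features the sheet directive vocabulary carries,
# with explicit cardinalities coherent with required/multivalued
rand_sheet_schema <- function() {
  n_class <- sample(1:3, 1)
  classes <- list()
  for (ci in seq_len(n_class)) {
    nm <- rand_name("Class", ci)
    n_attr <- sample(0:3, 1)
    attrs <- list()
    for (k in seq_len(n_attr)) {
      lo <- sample(0:1, 1)
      hi <- sample(c(1L, 3L, NA), 1)  # NA = unbounded
      if (!is.na(hi) && hi < max(lo, 1L)) hi <- max(lo, 1L)
      required <- if (lo >= 1L) TRUE else sample(c(NA, TRUE, FALSE), 1)
      anm <- paste0("attr_", ci, "_", k)
      attrs[[anm]] <- slot_definition(
        anm, range = sample(c("string", "integer", "float"), 1),
        description = if (stats::runif(1) < 0.6) rand_word(),
        required = required,
        multivalued = is.na(hi) || hi > 1L,
        minimum_cardinality = lo,
        maximum_cardinality = if (!is.na(hi)) hi)
    }
    classes[[nm]] <- class_definition(
      nm, description = if (stats::runif(1) < 0.6) rand_word(),
      is_a = if (ci > 1 && stats::runif(1) < 0.4) rand_name("Class", sample(ci - 1, 1)),
      attributes = attrs)
  }
  schema_definition(id = "https://example.org/sheet-schema", name = "sheet_schema",
                    classes = classes)
}

# -- random hierarchy + brute-force ancestry oracle --------------------------

rand_hierarchy <- function(n = sample(2:8, 1)) {
  classes <- list()
  for (i in seq_len(n)) {
    nm <- rand_name("C", i)
    parents <- if (i > 1) sample(seq_len(i - 1), min(i - 1, sample(0:2, 1))) else integer(0)
    is_a <- if (length(parents) > 0 && stats::runif(1) < 0.8)
      rand_name("C", parents[1]) else NULL
    mixins <- if (length(parents) > 1) vapply(parents[-1], function(p)
      rand_name("C", p), character(1)) else character(0)
    attrs <- list()
    if (stats::runif(1) < 0.8) {
      anm <- paste0("slot_", i)
      attrs[[anm]] <- slot_definition(anm, range = "string")
    }
    classes[[nm]] <- class_definition(nm, is_a = is_a, mixins = mixins,
                                      attributes = attrs)
  }
  schema_definition(id = "https://example.org/h", name = "hierarchy",
                    classes = classes)
}

# independent oracle: full pre-order expansion with duplicates, then
# first-occurrence dedup
oracle_ancestors <- function(schema, class_name) {
  expand <- function(nm) {
    cl <- schema$classes[[nm]]
    out <- nm
    for (p in c(cl$is_a, cl$mixins)) out <- c(out, expand(p))
    out
  }
  seq <- expand(class_name)
  seq[!duplicated(seq)]
}

# independent oracle for induced slots: naive precedence walk per field
oracle_induced <- function(schema, class_name) {
  ancs <- oracle_ancestors(schema, class_name)
  nms <- character(0)
  for (a in rev(ancs)) {
    cl <- schema$classes[[a]]
    for (s in c(cl$slots, names(cl$attributes))) if (!s %in% nms) nms <- c(nms, s)
  }
  fields <- c("description", "range", "required", "multivalued", "identifier",
              "pattern", "slot_uri", "unit",
              "minimum_cardinality", "maximum_cardinality")
  lapply(nms, function(sn) {
    sources <- list()
    for (a in ancs) {
      u <- schema$classes[[a]]$slot_usage[[sn]]
      if (!is.null(u)) sources[[length(sources) + 1L]] <- u
    }
    for (a in ancs) {
      d <- schema$classes[[a]]$attributes[[sn]]
      if (!is.null(d)) sources[[length(sources) + 1L]] <- unclass(d)
    }
    g <- schema$slots[[sn]]
    if (!is.null(g)) sources[[length(sources) + 1L]] <- unclass(g)
    out <- list(name = sn)
    for (f in fields) {
      for (src in sources) {
        v <- src[[f]]
        set <- !is.null(v) && !(is.logical(v) && length(v) == 1L && is.na(v))
        if (set) { out[[f]] <- v; break }
      }
    }
    if (is.null(out$required)) out$required <- FALSE
    if (is.null(out$multivalued)) out$multivalued <- FALSE
    if (is.null(out$identifier)) out$identifier <- FALSE
    if (out$identifier) out$required <- TRUE
    if (is.null(out$range)) out$range <- schema$default_range %||% "string"
    out
  })
}

# -- random documents for a materialized schema ------------------------------

rand_scalar_for <- function(ms, def) {
  schema <- ms$source
  rng <- def$range
  if (rng %in% names(schema$enums)) {
    pvs <- names(schema$enums[[rng]]$permissible_values)
    if (length(pvs) == 0) return("x")
    return(sample(pvs, 1))
  }
  if (rng %in% names(schema$classes)) {
    return(rand_doc(ms, rng, nested = TRUE)$values)
  }
  base <- rng
  switch(base,
    integer = sample.int(100, 1),
    float = round(stats::runif(1, -50, 50), 2),
    boolean = sample(c(TRUE, FALSE), 1),
    uriorcurie = paste0("ex:", rand_word()),
    uri = paste0("https://example.org/", rand_word()),
    date = "2024-05-01",
    datetime = "2024-05-01T10:00:00",
    rand_word())
}

rand_doc <- function(ms, class_name, nested = FALSE) {
  values <- list()
  for (s in ms$induced[[class_name]]) {
    def <- s$definition
    if (!def$required && stats::runif(1) < 0.3) next
    if (def$multivalued) {
      lo <- max(def$minimum_cardinality %||% 0L, if (def$required) 1L else 0L)
      hi <- min(def$maximum_cardinality %||% 3L, 3L)
      n <- sample(seq(max(lo, 1L), max(hi, lo, 1L)), 1)
      values[[s$name]] <- lapply(seq_len(n), function(k) rand_scalar_for(ms, def))
    } else {
      values[[s$name]] <- rand_scalar_for(ms, def)
    }
  }
  instance_document(class_name, values)
}

# corrupt one slot of a doc; returns list(doc, slot). Corruptions stay inside
# the subset where the native and JSON-Schema routes are equally expressive.
corrupt_doc <- function(ms, doc) {
  class_name <- doc$class_name
  slots <- ms$induced[[class_name]]
  defs <- stats::setNames(lapply(slots, function(s) s$definition),
                          vapply(slots, function(s) s$name, character(1)))
  candidates <- names(defs)
  target <- sample(candidates, 1)
  def <- defs[[target]]
  v <- doc$values[[target]]
  schema <- ms$source
  corrupted <- if (def$required && !is.null(v) && stats::runif(1) < 0.4) {
    NULL                                   # drop a required value
  } else if (def$multivalued) {
    rand_scalar_for(ms, def)               # scalar where a list is expected
  } else if (def$range %in% names(schema$enums)) {
    "definitely_not_a_permitted_value"
  } else if (def$range %in% c("integer", "float")) {
    rand_word()                            # string where a number is expected
  } else if (def$range %in% c("uriorcurie", "uri")) {
    "nocolonhere"
  } else if (def$range == "boolean") {
    "yes"
  } else if (def$range %in% names(schema$classes)) {
    "not_an_object"
  } else {
    list(rand_word())                      # list where a scalar is expected
  }
  doc$values[[target]] <- corrupted
  if (is.null(corrupted)) doc$values[[target]] <- NULL
  list(doc = doc, slot = target, removed = is.null(corrupted) && def$required)
}
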