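# JSON Schema, Markdown docs, SQL DDL generation.

ms_fix <- sample_schema(materialized = TRUE)

test_that("the generated JSON Schema reflects properties, required and enums", {
  art <- gen_json_schema(ms_fix, "Sample")
  expect_s3_class(art, "generated_artifact")
  js <- jsonlite::fromJSON(art$files[["sample_schema.schema.json"]],
                           simplifyVector = FALSE)
  expect_equal(js[["$schema"]], "https://json-schema.org/draft/2020-12/schema")
  def <- js[["$defs"]]$Sample
  expect_true(all(c("latitude", "longitude", "environment_type")
                  %in% names(def$properties)))
  expect_true(all(c("latitude", "longitude") %in% unlist(def$required)))
  expect_false("environment_type" %in% unlist(def$required))
  expect_equal(def$properties$latitude$type, "number")
  expect_setequal(unlist(def$properties$environment_type$enum),
                  c("soil", "water", "air", "sediment", "sand"))
  expect_false(isTRUE(def$additionalProperties))
  # the loss report names the identifier-uniqueness expressiveness gap
  loss <- jsonlite::fromJSON(art$files[["sample_schema.loss.json"]])
  expect_match(loss$losses, "identifier uniqueness", all = FALSE)
})

test_that("an empty class yields an object schema with no properties", {
  s <- schema_definition(id = "https://example.org/e", name = "empty_class",
                         classes = list(Bare = class_definition("Bare")))
  js <- jsonlite::fromJSON(
    gen_json_schema(materialize(s), "Bare")$files[[1]], simplifyVector = FALSE)
  expect_equal(js[["$defs"]]$Bare$type, "object")
  expect_length(js[["$defs"]]$Bare$properties, 0)
  expect_error(gen_json_schema(ms_fix, "Nope"), class = "schemakit_unknown_class")
})

test_that("native and JSON-Schema validation classify random documents identically", {
  set.seed(71)
  for (fixture in list(ms_fix, materialize(two_class_schema()))) {
    for (cls in names(fixture$source$classes)) {
      for (i in 1:60) {
        doc <- rand_doc(fixture, cls)
        if (i %% 2 == 0) doc <- corrupt_doc(fixture, doc)$doc
        native <- report_valid(validate_instance(fixture, doc))
        via_js <- report_valid(validate_instance(fixture, doc, engine = "json_schema"))
        expect_equal(via_js, native,
                     label = sprintf("%s doc %d (native %s)", cls, i, native))
      }
    }
  }
})

test_that("the reference jsonschema library agrees with the generated schema", {
  # independent oracle: Python's jsonschema evaluates the generated document
  set.seed(73)
  docs <- list()
  native <- logical(0)
  for (i in 1:30) {
    doc <- rand_doc(ms_fix, "Sample")
    if (i %% 2 == 0) doc <- corrupt_doc(ms_fix, doc)$doc
    docs[[i]] <- doc
    native[i] <- report_valid(validate_instance(ms_fix, doc))
  }
  tmp <- withr::local_tempdir()
  schema_path <- file.path(tmp, "schema.json")
  docs_path <- file.path(tmp, "docs.json")
  writeLines(gen_json_schema(ms_fix, "Sample")$files[[1]], schema_path)
  writeLines(as.character(jsonlite::toJSON(
    lapply(docs, function(d) schemakit:::as_plain_value(d$values)),
    auto_unbox = TRUE, digits = NA)), docs_path)
  script <- paste(
    "import json, sys",
    "import jsonschema",
    "schema = json.load(open(sys.argv[1]))",
    "docs = json.load(open(sys.argv[2]))",
    "v = jsonschema.Draft202012Validator(schema)",
    "print('\\n'.join('1' if v.is_valid(d) else '0' for d in docs))",
    sep = "\n")
  script_path <- file.path(tmp, "check.py")
  writeLines(script, script_path)
  out <- suppressWarnings(system2("python", c(script_path, schema_path, docs_path),
                                  stdout = TRUE, stderr = TRUE))
  skip_if(is.null(attr(out, "status")) == FALSE && attr(out, "status") != 0,
          "python jsonschema unavailable")
  expect_equal(out == "1", native)
})

test_that("docs cover every element exactly once and list the range edges", {
  art <- gen_markdown_docs(ms_fix)
  pages <- names(art$files)
  elements <- c("Sample", "id", "latitude", "longitude", "depth",
                "environment_type", "EnvironmentTypeEnum")
  for (el in elements)
    expect_equal(sum(pages == paste0(el, ".md")), 1L, label = el)
  index <- art$files[["index.md"]]
  for (el in elements) expect_match(index, paste0("(", el, ".md)"), fixed = TRUE)
  edges <- strsplit(art$files[["diagram.txt"]], "\n")[[1]]
  expect_true("(Sample)-[environment_type]->(EnvironmentTypeEnum)" %in% edges)
  # inheritance edges appear for the hierarchy fixture
  hier <- gen_markdown_docs(materialize(site_hierarchy_schema()))
  hedges <- strsplit(hier$files[["diagram.txt"]], "\n")[[1]]
  expect_true("(AirSampleSite)-[is_a]->(SampleSite)" %in% hedges)
  # cardinalities rendered on the class page: required single-valued is "1",
  # optional single-valued is "0..1"
  expect_match(art$files[["Sample.md"]], "| latitude | 1 |", fixed = TRUE)
  expect_match(art$files[["Sample.md"]], "| depth | 0..1 |", fixed = TRUE)
})

test_that("an empty schema documents to an index page only", {
  s <- schema_definition(id = "https://example.org/none", name = "nothing")
  art <- gen_markdown_docs(materialize(s))
  expect_setequal(names(art$files), c("index.md", "diagram.txt"))
})

test_that("generators are byte-identical across runs", {
  for (gen in list(function() gen_json_schema(ms_fix, "Sample"),
                   function() gen_markdown_docs(ms_fix),
                   function() gen_sql_ddl(ms_fix))) {
    expect_identical(gen()$files, gen()$files)
  }
})

test_that("SQL DDL maps identifiers, requiredness, types and enums", {
  ddl <- gen_sql_ddl(ms_fix)$files[["sample_schema.sql"]]
  expect_match(ddl, "CREATE TABLE sample")
  expect_match(ddl, "id TEXT PRIMARY KEY")
  expect_match(ddl, "latitude REAL NOT NULL")
  expect_match(ddl, "environment_type TEXT CHECK \\(environment_type IN \\('soil'")
  # abstract classes get no table
  s <- site_hierarchy_schema()
  s$classes$SampleSite$abstract <- TRUE
  ddl2 <- gen_sql_ddl(materialize(s))$files[["site_schema.sql"]]
  expect_false(grepl("CREATE TABLE sample_site ", ddl2))
  expect_match(ddl2, "CREATE TABLE air_sample_site")
})

test_that("multivalued slots become link tables and no identifier means a surrogate key", {
  s <- parse_schema(paste(
    "id: https://example.org/mv", "name: mv",
    "classes:",
    "  Study:",
    "    attributes:",
    "      analyses: {range: string, multivalued: true}",
    "      n_samples: {range: integer}",
    sep = "\n"))
  art <- gen_sql_ddl(materialize(s))
  ddl <- art$files[["mv.sql"]]
  expect_match(ddl, "CREATE TABLE study_analyses")
  expect_match(ddl, "_row_id INTEGER PRIMARY KEY")
  expect_match(ddl, "n_samples INTEGER")
  loss <- jsonlite::fromJSON(art$files[["mv.loss.json"]])
  expect_match(loss$losses, "surrogate key", all = FALSE)
})

test_that("the DDL loads into an embedded database and round-trips a record", {
  skip_if_not_installed("RSQLite")
  con <- DBI::dbConnect(RSQLite::SQLite(), ":memory:")
  withr::defer(DBI::dbDisconnect(con))
  ddl <- gen_sql_ddl(ms_fix)$files[["sample_schema.sql"]]
  for (stmt in strsplit(ddl, ";\\s*\n")[[1]]) {
    if (nzchar(trimws(stmt))) DBI::dbExecute(con, stmt)
  }
  DBI::dbExecute(con, paste(
    "INSERT INTO sample (id, latitude, longitude, depth, environment_type)",
    "VALUES ('ex:0001', 37.87, -122.27, 0.3, 'soil')"))
  row <- DBI::dbGetQuery(con, "SELECT * FROM sample")
  expect_equal(row$id, "ex:0001")
  expect_equal(row$latitude, 37.87)
  expect_equal(row$environment_type, "soil")
  # the enum CHECK constraint is live
  expect_error(DBI::dbExecute(con, paste(
    "INSERT INTO sample (id, latitude, longitude, environment_type)",
    "VALUES ('ex:0002', 0, 0, 'lava')")))
})
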