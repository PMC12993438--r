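# Instance validation: per-check behavior, collections, determinism,
# fault injection.

ms_sample <- sample_schema(materialized = TRUE)

good_sample <- function(id = "ex:0001") {
  instance_document("Sample", list(
    id = id, latitude = 37.87, longitude = -122.27,
    depth = 0.3, environment_type = "soil"))
}

test_that("a conformant document yields an empty report", {
  r <- validate_instance(ms_sample, good_sample())
  expect_length(r$issues, 0)
  expect_true(report_valid(r))
})

test_that("a missing required slot is reported at its path", {
  doc <- good_sample()
  doc$values$latitude <- NULL
  r <- validate_instance(ms_sample, doc)
  expect_equal(r$n_error, 1L)
  expect_equal(r$issues[[1]]$check, "required_missing")
  expect_equal(r$issues[[1]]$path, "/latitude")
})

test_that("an unlisted enum value is an enum_miss error", {
  doc <- good_sample()
  doc$values$environment_type <- "volcano"
  r <- validate_instance(ms_sample, doc)
  expect_equal(vapply(r$issues, function(i) i$check, character(1)), "enum_miss")
  expect_equal(r$issues[[1]]$path, "/environment_type")
})

test_that("enum matching is exact unless the enum folds case", {
  doc <- good_sample()
  doc$values$environment_type <- "Soil"
  expect_false(report_valid(validate_instance(ms_sample, doc)))
  folded <- sample_schema()
  folded$enums$EnvironmentTypeEnum$case_insensitive <- TRUE
  expect_true(report_valid(validate_instance(materialize(folded), doc)))
})

test_that("value shape must match multivaluedness", {
  s <- parse_schema(paste(
    "id: https://example.org/mv", "name: mv",
    "classes:",
    "  Study:",
    "    attributes:",
    "      analyses: {range: string, multivalued: true}",
    "      title: {range: string}",
    sep = "\n"))
  ms <- materialize(s)
  r <- validate_instance(ms, instance_document("Study", list(analyses = "one")))
  expect_equal(r$issues[[1]]$check, "shape")
  r2 <- validate_instance(ms, instance_document("Study", list(title = list("a", "b"))))
  expect_equal(r2$issues[[1]]$check, "shape")
  r3 <- validate_instance(ms, instance_document("Study",
                                                list(analyses = list("a", "b"))))
  expect_true(report_valid(r3))
})

test_that("type conformance is strict except integers for float ranges", {
  doc <- good_sample()
  doc$values$latitude <- 37L
  expect_true(report_valid(validate_instance(ms_sample, doc)))
  doc$values$latitude <- "37.87"
  r <- validate_instance(ms_sample, doc)
  expect_equal(r$issues[[1]]$check, "type")
  expect_equal(r$issues[[1]]$path, "/latitude")
})

test_that("pattern constraints are anchored full matches", {
  s <- parse_schema(paste(
    "id: https://example.org/p", "name: p",
    "classes:",
    "  C:",
    "    attributes:",
    "      code: {range: string, pattern: '[A-Z]{3}[0-9]+'}",
    sep = "\n"))
  ms <- materialize(s)
  expect_true(report_valid(validate_instance(ms, instance_document("C", list(code = "ABC12")))))
  r <- validate_instance(ms, instance_document("C", list(code = "xABC12x")))
  expect_equal(r$issues[[1]]$check, "pattern")
})

test_that("empty strings count as absent and are flagged only when required", {
  doc <- good_sample()
  doc$values$depth <- ""            # optional: silently absent
  expect_true(report_valid(validate_instance(ms_sample, doc)))
  doc$values$latitude <- ""         # required: missing
  r <- validate_instance(ms_sample, doc)
  expect_equal(r$issues[[1]]$check, "required_missing")
})

test_that("unknown slots are errors closed-world, warnings open-world", {
  doc <- good_sample()
  doc$values$color <- "red"
  closed <- validate_instance(ms_sample, doc)
  expect_equal(closed$n_error, 1L)
  expect_equal(closed$issues[[1]]$check, "unknown_slot")
  open <- validate_instance(ms_sample, doc, closed = FALSE)
  expect_equal(open$n_error, 0L)
  expect_equal(open$n_warning, 1L)
})

test_that("nested class ranges recurse with path accumulation", {
  s <- parse_schema(paste(
    "id: https://example.org/n", "name: n",
    "classes:",
    "  Site:",
    "    attributes:",
    "      name: {range: string, required: true}",
    "  Sample:",
    "    attributes:",
    "      site: {range: Site}",
    sep = "\n"))
  ms <- materialize(s)
  ok <- instance_document("Sample", list(site = list(name = "beach")))
  expect_true(report_valid(validate_instance(ms, ok)))
  bad <- instance_document("Sample", list(site = list(label = "beach")))
  r <- validate_instance(ms, bad)
  paths <- vapply(r$issues, function(i) i$path, character(1))
  expect_true("/site/name" %in% paths)    # required missing inside the nested doc
  expect_true("/site/label" %in% paths)   # unknown nested slot
})

test_that("duplicate identifiers across a collection are flagged once per repeat", {
  docs <- list(good_sample("ex:s1"), good_sample("ex:s2"), good_sample("ex:s1"))
  r <- validate_collection(ms_sample, docs)
  dups <- Filter(function(i) i$check == "duplicate_identifier", r$issues)
  expect_length(dups, 1)
  expect_equal(dups[[1]]$path, "/3/id")
  expect_match(dups[[1]]$message, "document 1")
  expect_length(validate_collection(ms_sample, list())$issues, 0)
})

test_that("collections degrade to per-doc validation without an identifier", {
  s <- site_hierarchy_schema()
  s$classes$SampleSite$attributes$site_id$identifier <- NA
  ms <- materialize(s)
  docs <- list(instance_document("SampleSite", list(site_id = "ex:1")),
               instance_document("SampleSite", list(site_id = "ex:1")))
  expect_true(report_valid(validate_collection(ms, docs)))
})

test_that("corrupting one field produces an issue addressing that field", {
  set.seed(53)
  for (i in 1:50) {
    doc <- rand_doc(ms_sample, "Sample")
    res <- corrupt_doc(ms_sample, doc)
    r <- validate_instance(ms_sample, res$doc)
    expect_gt(r$n_error, 0)
    paths <- vapply(r$issues, function(x) x$path, character(1))
    expect_true(any(startsWith(paths, paste0("/", res$slot))),
                label = sprintf("iteration %d, corrupted %s, paths: %s",
                                i, res$slot, paste(paths, collapse = ",")))
  }
})

test_that("validation reports are deterministic including ordering", {
  doc <- instance_document("Sample", list(
    longitude = "east", environment_type = "lava", junk = 1))
  r1 <- validate_instance(ms_sample, doc)
  r2 <- validate_instance(ms_sample, doc)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  expect_equal(nrow(as.data.frame(r1)), length(r1$issues))
})

test_that("unknown classes raise rather than report", {
  expect_error(validate_instance(ms_sample, instance_document("Nope", list())),
               class = "schemakit_unknown_class")
})

test_that("instances load from JSON, YAML and TSV with blank cells dropped", {
  tmp <- withr::local_tempdir()
  json <- file.path(tmp, "docs.json")
  writeLines(jsonlite::toJSON(list(
    list(id = "ex:1", latitude = 1.5, longitude = 2.5),
    list(id = "ex:2", latitude = 3.5, longitude = 4.5)),
    auto_unbox = TRUE), json)
  docs <- read_instances(json, "Sample")
  expect_length(docs, 2)
  expect_equal(docs[[2]]$values$latitude, 3.5)
  tsv <- file.path(tmp, "docs.tsv")
  writeLines(c("id\tlatitude\tlongitude\tenvironment_type",
               "ex:1\t1.5\t2.5\tsoil",
               "ex:2\t3.5\t4.5\t"), tsv)
  rows <- read_instances(tsv, "Sample")
  expect_length(rows, 2)
  expect_false("environment_type" %in% names(rows[[2]]$values))
  expect_equal(rows[[1]]$values$environment_type, "soil")
})
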