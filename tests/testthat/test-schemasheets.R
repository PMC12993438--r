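# Tabular schema syntax: sheet -> schema, schema -> sheet, inference.

sheet_path <- system.file("extdata", "sample_study_sheet.tsv", package = "schemakit")

test_that("the bundled multiplicity table converts to the expected schema", {
  sch <- sheet_to_schema(read_sheet(sheet_path))
  expect_setequal(names(sch$classes), c("Sample", "Study"))
  sample_attrs <- sch$classes$Sample$attributes
  study_attrs <- sch$classes$Study$attributes
  expect_setequal(names(sample_attrs), c("latitude", "longitude", "environment_type"))
  expect_named(study_attrs, "id")
  # 2 classes, 4 slots in total
  expect_equal(length(sample_attrs) + length(study_attrs), 4L)
  # requiredness: the required column wins; environment_type stays unset
  expect_true(sample_attrs$latitude$required)
  expect_true(sample_attrs$longitude$required)
  expect_true(is.na(sample_attrs$environment_type$required))
  expect_true(study_attrs$id$required)
  # cardinalities as printed: 0..1 for the Sample fields, 1 for Study id
  expect_equal(sample_attrs$latitude$minimum_cardinality, 0L)
  expect_equal(sample_attrs$latitude$maximum_cardinality, 1L)
  expect_equal(sample_attrs$environment_type$minimum_cardinality, 0L)
  expect_equal(study_attrs$id$minimum_cardinality, 1L)
  expect_equal(study_attrs$id$maximum_cardinality, 1L)
  # ranges and descriptions carried over
  expect_equal(sample_attrs$latitude$range, "float")
  expect_equal(study_attrs$id$range, "uriorcurie")
  expect_match(sample_attrs$latitude$description, "latitude")
  # none of the printed slots is multivalued
  expect_false(any(vapply(c(sample_attrs, study_attrs),
                          function(s) isTRUE(s$multivalued), logical(1))))
})

test_that("sheet -> schema -> sheet is a fixpoint on the bundled table", {
  sch <- sheet_to_schema(read_sheet(sheet_path))
  sheet <- schema_to_sheet(sch)
  expect_length(sheet$rows, 6L)   # 2 class rows + 4 slot rows
  back <- sheet_to_schema(sheet)
  expect_true(schemas_equal(sch, back))
})

test_that("a header-only table yields an empty schema", {
  tbl <- sheet_table(header = c("record", "field"), directive = c("class", "slot"))
  sch <- sheet_to_schema(tbl)
  expect_length(sch$classes, 0)
})

test_that("a mandatory cardinality contradicted by required FALSE is rejected", {
  tbl <- sheet_table(
    header = c("record", "field", "multiplicity", "required"),
    directive = c("class", "slot", "cardinality", "required"),
    rows = list(c("Study", "id", "1", "FALSE")))
  expect_error(sheet_to_schema(tbl),
               class = "schemakit_cardinality_required_conflict")
  # but the printed 0..1 + TRUE pairing is legal: required wins
  ok <- sheet_to_schema(sheet_table(
    header = c("record", "field", "multiplicity", "required"),
    directive = c("class", "slot", "cardinality", "required"),
    rows = list(c("Study", "id", "0..1", "TRUE"))))
  expect_true(ok$classes$Study$attributes$id$required)
})

test_that("directive rows are mandatory and tokens validated", {
  tmp <- withr::local_tempfile(lines = c("a\tb", "x\ty"))
  expect_error(read_sheet(tmp), class = "schemakit_missing_directive_row")
  expect_error(sheet_table(header = "a", directive = "frobnicate"),
               class = "schemakit_unknown_directive_token")
  expect_error(sheet_to_schema(sheet_table(
    header = c("record", "field"), directive = c("class", "slot"),
    rows = list(c("", "orphan")))),
    class = "schemakit_blank_element_name")
})

test_that("unbounded cardinality marks a slot multivalued", {
  sch <- sheet_to_schema(sheet_table(
    header = c("record", "field", "multiplicity"),
    directive = c("class", "slot", "cardinality"),
    rows = list(c("Study", "analyses", "0..*"))))
  s <- sch$classes$Study$attributes$analyses
  expect_true(s$multivalued)
  expect_equal(s$minimum_cardinality, 0L)
  expect_null(s$maximum_cardinality)
})

test_that("expressible schemas round-trip through sheet form", {
  set.seed(83)
  for (i in 1:60) {
    s <- rand_sheet_schema()
    back <- sheet_to_schema(schema_to_sheet(s))
    expect_true(schemas_equal(s, back), label = sprintf("sheet schema %d", i))
  }
})

test_that("sheets survive a write/read cycle including non-ASCII separators", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  sch <- sheet_to_schema(read_sheet(sheet_path))
  write_sheet(schema_to_sheet(sch), tmp)
  reread <- sheet_to_schema(read_sheet(tmp))
  expect_true(schemas_equal(sch, reread))
})

test_that("range inference follows the value-scanning rules", {
  df <- data.frame(
    count = c("30", "45", "12"),
    depth = c("0.5", "2", "13.25"),
    flag = c("true", "false", "TRUE"),
    texture = c("sand", "clay", "sand"),
    note = c("one off", "another note", "third remark"),
    stringsAsFactors = FALSE)
  sch <- infer_schema_from_table(df, class_name = "Obs")
  attrs <- sch$classes$Obs$attributes
  expect_equal(attrs$count$range, "integer")
  expect_equal(attrs$depth$range, "float")
  expect_equal(attrs$flag$range, "boolean")
  expect_equal(attrs$texture$range, "TextureEnum")
  expect_setequal(names(sch$enums$TextureEnum$permissible_values),
                  c("sand", "clay"))
  expect_equal(attrs$note$range, "string")
})

test_that("enum inference respects the distinct-count oracle", {
  vals <- c("sand", "clay", "sand", "loam")
  df <- data.frame(soil = vals, stringsAsFactors = FALSE)
  sch <- infer_schema_from_table(df, enum_k = 10, enum_ratio = 1.0)
  # oracle: distinct count by hand
  expect_length(sch$enums$SoilEnum$permissible_values, length(unique(vals)))
  # too many distinct values: stays a string
  many <- data.frame(x = paste0("v", 1:30), stringsAsFactors = FALSE)
  expect_equal(infer_schema_from_table(many)$classes$Row$attributes$x$range,
               "string")
})

test_that("blank fraction drives requiredness against the threshold", {
  df <- data.frame(x = c("a", "", "b", "", "c", "d", "e", "f", "g", "h"),
                   stringsAsFactors = FALSE)   # 20% blank
  sch <- infer_schema_from_table(df, required_threshold = 0.1)
  expect_true(is.na(sch$classes$Row$attributes$x$required))
  sch2 <- infer_schema_from_table(df, required_threshold = 0.5)
  expect_true(sch2$classes$Row$attributes$x$required)
  expect_error(infer_schema_from_table(data.frame()), class = "schemakit_empty_table")
})

test_that("inference is invariant under row permutation", {
  set.seed(89)
  df <- data.frame(
    n = as.character(sample.int(50, 40, replace = TRUE)),
    cat = sample(c("a", "b", "c"), 40, replace = TRUE),
    stringsAsFactors = FALSE)
  s1 <- infer_schema_from_table(df)
  s2 <- infer_schema_from_table(df[sample(nrow(df)), , drop = FALSE])
  expect_true(schemas_equal(s1, s2))
})
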