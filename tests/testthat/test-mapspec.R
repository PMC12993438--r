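# Declarative schema/data transformations.

legacy_schema <- function() {
  read_schema(system.file("extdata", "legacy_sample_schema.yaml",
                          package = "schemakit"))
}
migration_spec <- function() {
  read_transform_spec(system.file("extdata", "position_split_spec.yaml",
                                  package = "schemakit"))
}

test_that("transform specs parse with order preserved and kinds validated", {
  spec <- migration_spec()
  expect_length(spec$ops, 2)
  expect_equal(vapply(spec$ops, function(o) o$kind, character(1)),
               c("split", "rename"))
  one <- parse_transform_spec(
    "- rename: {class: Sample, old_slot: a, new_slot: b}")
  expect_length(one$ops, 1)
  expect_error(parse_transform_spec("- frobnicate: {class: Sample}"),
               class = "schemakit_unknown_operation_kind")
  expect_error(parse_transform_spec("- rename: {class: Sample}"),
               class = "schemakit_unknown_operation_kind")
  expect_error(parse_transform_spec(
    "- split: {class: S, source_slot: x, targets: [only_one], delimiter: ','}"),
    class = "schemakit_unknown_operation_kind")
})

test_that("the position-split migration derives the expected schema", {
  derived <- derive_schema(legacy_schema(), migration_spec())
  attrs <- names(derived$classes$Sample$attributes)
  expect_true(all(c("latitude", "longitude", "sample_type") %in% attrs))
  expect_false("position" %in% attrs)
  expect_false("environment_type" %in% attrs)
  expect_equal(derived$classes$Sample$attributes$latitude$range, "float")
  # rename preserved all other fields of the slot
  expect_equal(derived$classes$Sample$attributes$sample_type$range,
               "EnvironmentTypeEnum")
  expect_match(vapply(attr(derived, "audit"), function(a) a$kind, character(1)),
               "split", all = FALSE)
})

test_that("an empty spec leaves the schema unchanged", {
  s <- legacy_schema()
  expect_true(schemas_equal(s, derive_schema(s, transform_spec())))
})

test_that("subset keeps listed classes and audits removals", {
  s <- schema_definition(
    id = "https://example.org/two", name = "two",
    classes = list(
      Sample = class_definition("Sample", attributes = list(
        study = slot_definition("study", range = "Study"))),
      Study = class_definition("Study")))
  sub <- derive_schema(s, transform_spec(list(
    list(kind = "subset", keep_classes = list("Sample")))))
  expect_named(sub$classes, "Sample")
  # the slot whose range was dropped is removed too, with an audit record
  expect_false("study" %in% names(sub$classes$Sample$attributes))
  details <- vapply(attr(sub, "audit"), function(a) a$detail, character(1))
  expect_match(details, "dropped class 'Study'", all = FALSE)
  expect_match(details, "study", all = FALSE)
})

test_that("operations referencing missing elements fail with the op index", {
  err <- tryCatch(
    derive_schema(legacy_schema(), transform_spec(list(
      list(kind = "rename", class = "Sample", old_slot = "ghost",
           new_slot = "x")))),
    schemakit_reference_error = function(e) e)
  expect_s3_class(err, "schemakit_reference_error")
  expect_match(conditionMessage(err), "operation 1")
  expect_match(conditionMessage(err), "ghost")
})

test_that("instances split, rename and pass untouched values through", {
  doc <- instance_document("Sample", list(
    id = "ex:1", position = "37.87, -122.27", environment_type = "soil"))
  out <- transform_instance(doc, migration_spec())
  expect_equal(out$values$latitude, 37.87)
  expect_equal(out$values$longitude, -122.27)
  expect_equal(out$values$sample_type, "soil")
  expect_equal(out$values$id, "ex:1")
  expect_false("position" %in% names(out$values))
})

test_that("split arity and cast failures carry the document path", {
  spec <- migration_spec()
  short <- instance_document("Sample", list(position = "37.87"))
  expect_error(transform_instance(short, spec),
               class = "schemakit_split_arity_mismatch")
  bad <- instance_document("Sample", list(position = "north, east"))
  err <- tryCatch(transform_instance(bad, spec),
                  schemakit_cast_error = function(e) e)
  expect_match(conditionMessage(err), "/latitude")
})

test_that("absent split/merge sources propagate absence", {
  spec <- migration_spec()
  doc <- instance_document("Sample", list(id = "ex:2", environment_type = "air"))
  out <- transform_instance(doc, spec)
  expect_false(any(c("latitude", "longitude", "position") %in% names(out$values)))
  mspec <- transform_spec(list(list(
    kind = "merge", class = "Sample", sources = list("a", "b"),
    target_slot = "ab", delimiter = "|")))
  half <- transform_instance(instance_document("Sample", list(a = "x")), mspec)
  expect_false("ab" %in% names(half$values))
})

test_that("split followed by the matching merge recovers the document", {
  set.seed(97)
  split_spec <- transform_spec(list(list(
    kind = "split", class = "C", source_slot = "joint",
    targets = c("p1", "p2", "p3"), delimiter = ";")))
  merge_spec <- transform_spec(list(list(
    kind = "merge", class = "C", sources = list("p1", "p2", "p3"),
    target_slot = "joint", delimiter = ";")))
  for (i in 1:60) {
    parts <- replicate(3, rand_word())
    doc <- instance_document("C", list(joint = paste(parts, collapse = ";")))
    back <- transform_instance(transform_instance(doc, split_spec), merge_spec)
    expect_equal(back$values$joint, doc$values$joint)
  }
})

test_that("transformed conformant documents validate against the derived schema", {
  set.seed(103)
  src <- resolve_imports(legacy_schema(), list())
  src_ms <- materialize(src)
  res <- apply_transform(src, migration_spec())
  derived_ms <- materialize(res$derived_schema)
  envs <- names(src$enums$EnvironmentTypeEnum$permissible_values)
  for (i in 1:100) {
    doc <- instance_document("Sample", list(
      id = paste0("ex:", i),
      position = paste0(round(runif(1, -90, 90), 3), ", ",
                        round(runif(1, -180, 180), 3)),
      environment_type = sample(envs, 1)))
    expect_true(report_valid(validate_instance(src_ms, doc)))
    out <- res$data_mapper(doc)
    expect_true(report_valid(validate_instance(derived_ms, out)),
                label = sprintf("transformed doc %d", i))
  }
})

test_that("operation order matters when ops touch the same slot", {
  s <- schema_definition(
    id = "https://example.org/o", name = "order",
    classes = list(C = class_definition("C", attributes = list(
      pos = slot_definition("pos", range = "string")))))
  rename_then_split <- transform_spec(list(
    list(kind = "rename", class = "C", old_slot = "pos", new_slot = "position"),
    list(kind = "split", class = "C", source_slot = "position",
         targets = c("x", "y"), delimiter = ",")))
  split_then_rename <- transform_spec(list(
    list(kind = "split", class = "C", source_slot = "pos",
         targets = c("x", "y"), delimiter = ","),
    list(kind = "rename", class = "C", old_slot = "pos", new_slot = "position")))
  d1 <- derive_schema(s, rename_then_split)
  expect_named(d1$classes$C$attributes, c("x", "y"))
  # after splitting, "pos" no longer exists for the rename to find
  expect_error(derive_schema(s, split_then_rename),
               class = "schemakit_reference_error")
})

test_that("retype and recardinalize adjust slot constraints and data", {
  s <- schema_definition(
    id = "https://example.org/r", name = "retype",
    classes = list(C = class_definition("C", attributes = list(
      n = slot_definition("n", range = "string")))))
  spec <- transform_spec(list(
    list(kind = "retype", class = "C", slot = "n", new_range = "integer"),
    list(kind = "recardinalize", class = "C", slot = "n", required = TRUE)))
  d <- derive_schema(s, spec)
  expect_equal(d$classes$C$attributes$n$range, "integer")
  expect_true(d$classes$C$attributes$n$required)
  out <- transform_instance(instance_document("C", list(n = "42")), spec)
  expect_identical(out$values$n, 42L)
  expect_true(report_valid(validate_instance(materialize(d), out)))
})
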