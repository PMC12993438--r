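# schemakit

A schema-modeling kernel for FAIR scientific metadata, written in R and
demonstrated end-to-end on microbiome sample metadata.

Field spreadsheets of sampling data are rarely comparable: a cryptic `dep`
column mixes `30 cm`, `0.5 meters` and bare numbers; environment terms are
free text (`Sand`, `sea water`, `dirt`); latitude and longitude are fused
into one `position` cell; and nothing says which columns are mandatory.
`schemakit` attacks this by making the **schema** the single source of
truth. Schemas are built from four element kinds — **classes** (entity
types), **slots** (attributes with a *range*, cardinality and metadata),
**types** (scalar value spaces) and **enums** (controlled vocabularies,
optionally mapped to ontology terms such as ENVO CURIEs) — plus prefix
maps for CURIE ↔ URI conversion, imports, and class inheritance with
slot-level overrides.

Around that metamodel the package provides the full modeling lifecycle:

| Stage | Functions |
|---|---|
| Author | `parse_schema()` / `emit_schema()` (YAML), `read_sheet()` + `sheet_to_schema()` (tabular syntax with a `>`-directive row), `infer_schema_from_table()` (bootstrap from raw data) |
| Compile | `materialize()` — resolves inheritance into *induced slots*; `class_ancestors()`, `induced_slots()`, `dump_induced()` |
| Check style | `lint_schema()` — descriptions, CamelCase classes, snake_case slots, ranges, non-empty enums |
| Validate data | `validate_instance()` / `validate_collection()` with a pluggable engine contract (`native` and `json_schema` engines) |
| Generate | `gen_json_schema()` (draft 2020-12), `gen_markdown_docs()` (+ diagram edge list), `gen_sql_ddl()` — each with a machine-readable loss report |
| Evolve | `parse_transform_spec()`, `derive_schema()`, `transform_instance()` — declarative rename / split / merge / retype / recardinalize / subset |
| Demonstrate | `generate_messy_samples()` + `harmonize_samples()` — a synthetic messy spreadsheet with recorded ground truth, harmonized against the bundled Sample schema |

The induced view is compiled once and consumed everywhere: for each class,
ancestry is the `is_a` chain followed by mixins (depth-first, first
occurrence kept), and each slot's fields are resolved nearest-first —
`slot_usage` of the class, then ancestor `slot_usage`, then the nearest
attribute definition, then the schema-level slot — with unset fields
inheriting. Cardinality is carried both as `required`/`multivalued` flags
and as explicit `minimum_cardinality`/`maximum_cardinality` bounds parsed
from multiplicity tokens (`0..1`, `1`, `0..*`).

## Worked example

Validate a document against the bundled Sample schema:

```r
library(schemakit)
ms <- sample_schema(materialized = TRUE)
doc <- instance_document("Sample", list(
  id = "ex:0001", longitude = -122.27, environment_type = "Soil"))
validate_instance(ms, doc)
#> <validation_report> 2 error(s), 0 warning(s)
#>   [ERROR] required_missing /latitude: required slot 'latitude' is missing
#>   [ERROR] enum_miss /environment_type: value not among permissible values of enum 'EnvironmentTypeEnum'
```

`latitude` is required by the schema, and enum matching is case-sensitive
exact text (`"Soil"` is not the permissible value `"soil"`).

Harmonize a synthetic messy spreadsheet (mixed units, fused positions,
free-text environments):

```r
tbl <- generate_messy_samples(seed = 1, n_rows = 3)
# row cells:  "10.16 meters | -33.22, -41.72 | sea water"
#             "134.8ft      | -37.05, 97.14  | soil"
#             "47.24m       | 29.31, -0.83   | sand"
res <- harmonize_samples(tbl)
res
#> <harmonization_result> 3 clean doc(s), 0 rejected row(s), 0 error issue(s), 0 warning issue(s)
str(res$clean_docs[[1]]$values)
#> List of 5
#>  $ id              : chr "ex:0001"
#>  $ depth           : num 10.2
#>  $ latitude        : num -33.2
#>  $ longitude       : num -41.7
#>  $ environment_type: chr "water"
```

Depths are converted to metres (rounded to 3 decimals), positions split
into typed latitude/longitude, `sea water` resolved through the synonym
table to the canonical enum value `water`, and a CURIE identifier minted
per row. With zero injected faults, harmonization reproduces the
generator's ground truth exactly.

Convert a multiplicity table to a schema:

```r
sheet <- read_sheet(system.file("extdata", "sample_study_sheet.tsv", package = "schemakit"))
schema <- sheet_to_schema(sheet)
schema$classes$Study$attributes$id$minimum_cardinality
#> [1] 1
schema$classes$Sample$attributes$latitude$minimum_cardinality
#> [1] 0
```

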