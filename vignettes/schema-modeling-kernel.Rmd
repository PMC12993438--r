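---
title: "The schemakit schema-modeling kernel: model, design choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The schemakit schema-modeling kernel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(schemakit)
```

## The metamodel

`schemakit` models data with exactly four element kinds: **classes**
(entity types whose instances are documents), **slots** (named attributes
with a range, cardinality and metadata), **types** (scalar value spaces
over the closed primitive set `string, integer, float, boolean, uri,
uriorcurie, date, datetime`) and **enums** (controlled vocabularies whose
permissible values may carry a `meaning` CURIE pointing at an ontology
term, e.g. `ENVO:00001998` for soil). A schema is identified by a URI and
carries a prefix map; `expand_curie()`/`contract_uri()` convert between
compact and full identifiers, with contraction choosing the longest
matching base so nested namespaces resolve deterministically. The built-in
type library is implicitly imported: tabular and YAML schemas may use
`float` or `uriorcurie` without declaring them.

Cardinality lives in two redundant encodings that the package keeps
coherent: boolean `required`/`multivalued` flags (the YAML idiom) and
explicit `minimum_cardinality`/`maximum_cardinality` bounds parsed from
multiplicity tokens (`"0..1"`, `"1"`, `"0..*"`; the grammar also accepts
the typographic separators `‥` and `…` because tables set in print often
use them). When both appear, the explicit `required` flag wins for
requiredness and the bounds govern multivaluedness (`max > 1`); the only
hard contradiction is a minimum of 1 or more against an explicit
`required: FALSE`. Boolean slot fields are tri-state: `NA` means "unset"
and is distinct from an explicit `FALSE`, which matters for inheritance.

## Compilation: the induced view

Inheritance is resolved exactly once, by `materialize()`, into an induced
view consumed by the validator and all generators. Ancestry starts at the
class, follows the `is_a` chain, then mixins depth-first left-to-right,
keeping the first occurrence — so the single-inheritance backbone wins
ties against mixins. Mixin semantics are an extension point: the design
commits only to this linearization.

Induced slot resolution is field-wise, nearest-first:

1. `slot_usage` of the class itself,
2. `slot_usage` of nearer ancestors,
3. the nearest attribute (or schema-level slot) definition.

Unset fields (`NULL`/`NA`) inherit from the next source; every resolved
field records its winning source in a provenance list, which the
documentation generator surfaces as "defined in". Defaults are applied at
this point only (`required = FALSE`, `multivalued = FALSE`, range falls
back to the schema's `default_range`, else `string`). A class may induce
at most one identifier slot; inheriting a second is an error, because
identifier minting and uniqueness checking need an unambiguous key.
Integrity checking aggregates *all* dangling references into a single
error rather than stopping at the first, which is what you want when
repairing a hand-written schema.

## Validation policy

All data problems become report issues with a slash-delimited path;
exceptions are reserved for misuse (unknown class, unknown engine).
Closed-world is the default — validation exists to check conformance — and
open-world mode downgrades unknown slots to warnings. Deliberate policy
choices:

* **Empty string means absent.** Spreadsheet blanks are ambiguous; the
  validator treats `""` as "not specified" and flags it only when the slot
  is required.
* **Integers are accepted for float ranges** (spreadsheets store `30` for
  `30.0`); every other cross-type coercion is rejected, because silent
  string-to-number coercion hides data errors.
* **Enum matching is case-sensitive exact text**, with an opt-in per-enum
  `case_insensitive` flag; permissible values are controlled vocabulary,
  not free text.
* **Patterns are anchored full matches**, both natively and in generated
  JSON Schema (emitted as `^(?:pat)$`), so the two routes agree.

The validator is a plugin contract — an engine is `(name, prepare(ms,
class, closed) → artifact, check(artifact, doc) → issues)` — with two
shipped engines: `native` interprets the induced view directly, and
`json_schema` validates against the document produced by
`gen_json_schema()`, interpreted by a small checker for the exact draft
2020-12 subset the generator emits (`$ref`/`$defs`, `type`, `properties`,
`required`, `additionalProperties`, `enum`, `pattern`, `items`,
`minItems`/`maxItems`). That checker is in-package because the generated
subset is small and closed; the test suite additionally cross-checks it
against an external JSON Schema implementation. Two expressiveness gaps
are excluded from native-vs-JSON-Schema comparisons and enumerated in the
generators' loss reports: identifier uniqueness across a collection
(inexpressible in per-document JSON Schema) and the empty-string-as-absent
policy.

## Generators and loss reports

Every generator is a pure function of the materialized schema and
deterministic byte-for-byte, which makes goldens and diffs meaningful.
Conversions lose information, so each artifact ships with a
machine-readable loss report saying exactly what was dropped: JSON Schema
cannot express collection-level identifier uniqueness; SQL DDL normalizes
multivalued slots into `(owner_id, value)` link tables, synthesizes a
surrogate `_row_id` key for classes without an identifier, and stores
class-valued slots as TEXT references; table and column names are
snake_case transliterations with the mapping recorded. JSON Schema is
pinned to draft 2020-12 so output is stable. Markdown docs give one page
per element, an index, and a `diagram.txt` edge list
(`(Sample)-[environment_type]->(EnvironmentTypeEnum)`,
`(AirSampleSite)-[is_a]->(SampleSite)`) as a text graph notation that
downstream diagram tools can consume.

## Tabular authoring and inference

The sheet dialect puts human labels on line 1 and a `>`-prefixed directive
row on line 2 mapping columns to metamodel fields (`class, slot,
cardinality, required, range, is_a, description`). A row with only a class
name declares the class; a row with class and slot attaches an inline
attribute. A printed table may pair `0..1` with `required TRUE`; the
parser accepts this deliberately (required column wins, bounds retained)
rather than rejecting real-world tables. The reverse conversion restricts
itself to the directive vocabulary and reports everything it must drop.

`infer_schema_from_table()` bootstraps a schema from raw data: all-integer
columns → `integer`, all-numeric → `float`, all `true/false` → `boolean`;
a non-numeric column becomes an enum when it has at most `enum_k = 10`
distinct values repeating at `enum_ratio ≥ 1.5` rows per value (both
configurable — there is no canonical heuristic, so the defaults are chosen
to catch obvious vocabularies without enum-ifying free text); a column is
marked required when its blank fraction is below `required_threshold =
0.1`. Inference is deterministic and invariant under row permutation
(enum values are sorted).

## Transformations

Transform specs are ordered YAML operation lists (`rename`, `split`,
`merge`, `retype`, `recardinalize`, `subset`) applied identically to the
schema and to instance data, so a document that validated against the
source validates against the derived schema after mapping. Split is
exact-arity with trimming and no regex delimiters — dirty cells should
fail loudly, not partially parse. A missing source under split or merge
propagates absence instead of erroring, matching the validator's
blank-cell policy. Specs are schema-level only (no per-row conditionals);
that is an extension point. Operation order is significant and verified by
construction: renaming then splitting a slot is not the same program as
splitting then renaming it.

## The synthetic messy table and harmonization

`generate_messy_samples()` emulates a hand-kept sampling sheet: a `dep`
column rendered in mixed unit dialects (`"30 cm"`, `"30cm"`,
`"0.5 meters"`, bare numbers meaning metres), a fused `position` cell, and
environment terms with case and synonym noise. Those are *recoverable*
formatting variations and are always present; *unrecoverable* faults —
blank cells, free-text depths, unmatched environment terms — are injected
at caller-specified per-cell rates, at most one fault per cell so every
injected fault stays observable, and recorded in a ground-truth inventory.
Value ranges are chosen as plausible field values (depths up to 50 m,
latitudes −60..70°); the unit table (m, cm, mm, ft, in), synonym table and
the identifier-minting scheme (`prefix:0001` zero-padded ordinals) are
explicit configuration shipped as fixture constants.

`harmonize_samples()` converts depths to metres (rounded to 3 decimals;
`format_depth()`/`parse_depth()` round-trip to well under 1e-9), splits
positions through the transform engine, folds case and applies the
synonym table for environments, and mints identifiers. Every unrecovered
cell becomes exactly one report issue, so on a zero-noise table
harmonization equals ground truth with an empty report, and under fault
injection the issue count equals the injected-fault count while
`rows in = clean documents + rejected rows`.

What passing these tests shows — and does not show — about real data: the
generator's dialect and synonym inventories are finite and known to the
harmonizer, so recovery here demonstrates the pipeline's bookkeeping
(nothing silently lost, everything accounted), not robustness to
arbitrary field spreadsheets, which contain misspellings, locale number
formats and semantic ambiguities this fixture deliberately excludes.

## Numerical and procedural choices

* Depth rounding to 3 decimals (millimetre precision) at harmonization;
  ground truth is defined through the same rounding, so recovery is exact
  equality, not tolerance comparison.
* Determinism everywhere: generators and reports are ordered; the messy
  generator takes an explicit seed and restores the caller's RNG state.
* Import resolution is depth-first in listed order; a local definition
  shadows an imported one with a recorded warning (modular-schema
  convention); identical prefixes merge, conflicting bases are an error.
  Resolution empties the import list, making it idempotent.
* Unknown YAML keys are preserved in per-element `annotations` and
  re-emitted, so round-tripping a schema authored against a richer
  metamodel is lossless rather than destructive.
* Emission uses a fixed key order (metadata, prefixes, imports, types,
  enums, slots, classes), making output byte-stable across runs.

## Test problem sizes

Property suites use 60–100 random cases per law (schema round-trips,
ancestry against a brute-force traversal oracle on hierarchies of up to 8
classes, dual-route validation on 100 documents per fixture class,
split/merge and CURIE round-trips at 100 cases); the binomial check of
blank-injection rates uses 1000 rows, and the fault-accounting checks use
200–300 rows. These sizes give the properties room to fail while keeping
the default suite fast.

## Known limitations

* No RDF/OWL/ShEx/SHACL or native-code emission; no live ontology lookup —
  enum meanings are static CURIEs.
* Prefix maps are local and explicit; nothing resolves against a registry.
* No cross-document referential integrity beyond identifier uniqueness.
* Slot logic is limited to the fields of the slot definition — no boolean
  expression ranges.
* The JSON-Schema checker interprets only the subset the generator emits;
  it is not a general-purpose validator.
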