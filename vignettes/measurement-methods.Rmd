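---
title: "Measurement methods for clinical data quality: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measurement methods for clinical data quality: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dqmm)
```

## The problem

Secondary use of electronic health records — research, quality management,
data integration — stands or falls with data quality (DQ): completeness,
plausibility, conformance to the constraints the data should satisfy.
In practice DQ assessment is often re-implemented per project as ad-hoc
scripts: the knowledge of *what* to measure (which variables, which ranges,
which value sets, which cardinalities) is locked into single-use code and
cannot be reviewed, versioned, or reused across sites.

`dqmm` addresses this by making the unit of DQ knowledge an explicit,
portable object: the **measurement method (MM)**. An MM quantifies one
characteristic of a dataset and is fully described by five parts:

1. **tags** — descriptive keywords (what the MM does, and optionally its
   domain/task context). Tags are also the *interface* for composition:
   multi-layered MMs select their inputs by tag predicates, never by id.
2. **domain paths** — named, typed input bindings `item0, item1, …`.
   A binding either addresses a dataset variable by a slash-separated
   archetype-style path (`dataset-row/composition/…`), or — for
   multi-layered MMs — selects *other MMs' results* via a tag filter.
3. an optional **check**: a Boolean rule applied to each input row
   (e.g. a range or value-set constraint).
4. an optional **grouping**: an expression assigning each row to a group
   (per site, per patient, per month, …). Without it, all rows form one
   group labelled `ALL`.
5. a **characterization**: the summary computed per group — a count, a
   distribution measure, a frequency table, a histogram, or (for check
   MMs) typically the mean of the Boolean check vector, i.e. the pass
   fraction.

Because variables are addressed by paths rather than by source-system
column names, an MM written against a shared clinical information model
applies unchanged to any dataset exposing the same paths; compilations of
MMs ("knowledge bases") become reviewable, diffable artifacts.

## Datasets and paths

A dataset is an ordered collection of *compositions*: nested records, one
per row. Nodes carry either a scalar payload (optionally with a unit
attribute) or ordered children, never both. Two on-disk encodings are
supported — newline-delimited JSON records, and a flat CSV whose headers
are paths — and both resolve identically for leaf paths.

The path dialect is deliberately small: a `dataset-row/` prefix, segments
`name`, `name[id]`, `name[id,'display']` or `[id]`, an optional trailing
attribute projection (`.value`, `.magnitude`, `.unit`, `.code`), and the
instruction `.countChildnodes(only_child|all)`, which asks for the number
of child nodes rather than contents — the primitive behind cardinality
checks (a mandatory variable whose container has zero children is absent).
Full archetype-path semantics (ADL predicates, arbitrary axes) are out of
scope; the constructs above are the ones DQ rules actually use.

Two readings were genuinely open here:

* **`only_child`** is interpreted as *the unique matched parent*: if the
  path matches more than one parent node, counting raises an ambiguity
  error rather than silently using the first match. Fail-loud is the only
  safe reading for a construct whose intent is a cardinality assertion.
* **Multi-match paths** (repeated elements such as several lab panels per
  composition) produce one input row per matched node, with the original
  row index kept as provenance — each repeated element must be checked,
  not only the first.

Missing values: a value is missing iff the node is absent from the tree or
its text form is one of the dataset's *missing tokens*. The default token
set is `{"", "NA", "ND"}` and is configurable at load time, because real
feeds use source-specific null flavors — an `"ND"` slipping through a
pipeline that only knows `"NA"` is precisely the class of defect a DQ tool
must be robust to.

## The expression dialect

Checks, groupings and custom characterizations are written in a closed,
sandboxed expression language (arithmetic, comparisons, `and`/`or`/`not`,
`if/else`, list membership `in_list`, string `concat`/`format`, regex
`matches`/`extract_match`, date parts `year`/`month`/`quarter`/`day`/
`weekday`, and a fixed set of aggregate functions). There is no I/O, no
loop, no user-defined function, and no host-language escape hatch. The
alternative — executing fragments of a general statistical language inside
MMs — maximizes expressiveness but makes knowledge bases unreviewable and
unsafe to run when they come from third parties; a closed dialect keeps
MMs "plain" enough to audit line by line. `extract_match(x, pattern)` is
the one operation added beyond the obvious core: the TDConstraints
aggregation (below) uses it to pull the variable-path tag out of a
contributing MM's tag list.

Missing propagation is total: *any* missing operand makes a check or
grouping result missing, including `false and missing`. This is stricter
than three-valued logic on purpose — a check result of `FALSE` must mean
"observed and violated", never "not observed", so that correctness
measures stay orthogonal to completeness measures. Characterization
builtins skip missing values, except `count_total`/`count_missing`, which
are the completeness bookkeeping. Group labels are ordered
lexicographically (byte order, locale-independent), and rows whose
grouping value is missing are pooled under the label `MISSING`.

Numeric details worth knowing: comparisons require operands of one type
(numbers with numbers, text with text — ISO-8601 date strings order
correctly as text); type mismatches are evaluation errors, not silent
coercions. `histogram` and `barplot` return data structures (break points,
labels, counts) rather than images; rendering is a reporting-layer
concern, so results stay comparable and serializable.

## Execution

`execute_all()` resolves the dependency graph first: an edge runs from MM
*x* to MM *y* whenever *y*'s filter matches *x*'s tags. Execution follows
a stable topological order (independent MMs keep their input order), and a
cycle is an error naming the MMs involved. Filter-bound inputs are
assembled in canonical order (by MM id), so every valid topological order
yields bit-identical results. Execution is fail-soft: one MM's error is
recorded as a failed result and never aborts the batch — a DQ report that
dies on the first defective rule would be useless exactly when it is
needed. An MM's domain paths must be all dataset bindings or all filter
bindings; mixing the two would leave row alignment undefined and is
rejected.

When a check is present, the characterization consumes the check vector
(the Fig.-style "mean compliance per site" pattern); otherwise it consumes
`item0`, with further items serving grouping and conditions.

## Automatic generation

Two generators turn existing knowledge into MMs:

* **Type-based profiling.** Every dataset variable, by reference model
  type, yields a fixed set of profiling MMs. The pinned generation matrix
  is: NUMERIC/COUNT → count_present, min, max, mean, median, sd,
  histogram; TEXT/CODED_TEXT → count_present, frequency_table,
  relative_frequency_table, barplot; DATE_TIME → count_present, min, max;
  BOOLEAN → count_present, frequency_table, relative_frequency_table.
  There is no canonical mapping to recover from prior art, so the matrix
  is a package constant, documented and overridable — reproducibility
  requires *a* pinned matrix more than it requires any particular one.
* **Constraint-based checks.** A constraint schema — the information
  content of a clinical information model: per variable a reference type,
  mandatory flag/occurrence bounds, numeric range (optionally per unit
  code), value set, regex pattern — yields one check MM per constraint,
  each reporting its pass fraction. Unit-conditional ranges compile to a
  single conditional rule over the companion unit item; cardinalities
  compile to a child-node count on the variable's parent container
  compared against the occurrence bounds.

Generation is deterministic; MM identity is a content hash of the rendered
5-tuple, so identical MMs share ids across knowledge-base round-trips and
version-control history. Grouped ("dimension") variants are separate MMs
carrying a `per_<dimension>` tag — which is what lets aggregate layers
exclude them with `lacks_tag('per_*')` — and the originals are retained.

## The HDQF measures

Three measures adapted from a harmonized DQ framework are built as
ordinary MMs, which is the point: the assessment layer needs no special
machinery.

* **RepresentationComplete** — per variable, the fraction of non-missing
  entries, computed as `count_present(item0) / count_total(item0)`. The
  denominator is the dataset row count: an absent subtree counts as
  missing, because "fraction complete" is meaningless without a fixed
  denominator.
* **TaskComplete** — per *mandatory* variable, the count of rows whose
  mandatory value is missing or absent (via the cardinality primitive);
  0 is the all-good value. The heatmap reports both the raw count and a
  normalized goodness score `1 − count/rows` (whether such counts are
  better reported raw or normalized is a presentation question; emitting
  both costs nothing).
* **TDConstraints** — one multi-layered MM over all executed ungrouped
  check MMs (`has_tag('check') and lacks_tag('per_*')`), reporting per
  variable the **unweighted mean** of that variable's check pass
  fractions. The aggregation rule had to be pinned by design decision:
  unweighted averaging over checks treats each declared constraint as one
  unit of evidence regardless of how many rows it touched, which matches
  how the contributing pass fractions are themselves already normalized.
  Because the filter speaks only about tags, the same TDConstraints MM
  applies unchanged to checks generated from any schema.

The heatmap assembles one row per variable and one column per measure;
cells without contributing results are not-applicable and rendered white
(masking irrelevant cells rather than scoring them follows established
heatmap practice in the DQ literature). The color scale is continuous
green (1.0) → yellow (0.8) → red (0.0); the yellow knee at 0.8 marks the
zone where a variable deserves a look without being catastrophic. Cells
are pure functions of the MM results — re-rendering never changes values.

## The synthetic study fixture

The patient data the surrounding method was applied to is restricted, so
the package ships a generator instead of data. `make_study_fixture()`
emulates the *structure* of a two-site transplant study: a mandatory
healthcare facility name, patient identifiers, gender with the three-code
value set (Weiblich/Männlich/Divers), recipient and donor ages with
plausibility ranges, a weight with unit-conditional ranges (kg: 0–1000,
g: 0–1,000,000), transplant and biopsy dates drawn from a 2020–2022
window, and months since transplantation. Defaults are clean (no injected
defects), mirroring a dataset whose mandatory fields are all filled; tests
inject defect rates explicitly.

Injection semantics are chosen for unambiguous ground truth: per cell,
missingness (Bernoulli, per-variable rate) is drawn first; only non-missing
cells can be flipped to a violating value (per-constraint rate) — a cell is
never both. Missing cells and cardinality violations both manifest as an
absent subtree (that is what the cardinality primitive detects); the
ground-truth log distinguishes them. Missing cells additionally carry a
null-flavor token (`NA`/`ND`/empty, with mixture weights) that surfaces in
the flat-table encoding, reproducing the non-standard-null-flavor failure
mode. With rates *m* and *v*, the expected pass fraction of a range check
is (1−m)(1−v)/(1−m) = 1−v among observed values, and tests verify recovery
within 3-sigma binomial bounds at n = 1000.

What the generator deliberately does **not** emulate: clinical
correlations between variables, longitudinal structure, site-specific
distribution shifts, or realistic free text. Passing tests therefore
demonstrate that the *measurement machinery* is correct — that injected
defect rates are recovered and identities hold — not that the package's
default constraints are clinically adequate for any real dataset.

## Problem sizes and numerical choices

The test suite and the acceptance script run at deliberately desk-sized
scales: 1000 rows for rate-recovery checks (3-sigma binomial bounds are
then ±3.6 percentage points at p = 0.9), 100–300 rows for identity and
round-trip checks, 1000 random vectors for characterization-oracle
equivalence at tolerance 1e-9. Floating-point determinism is achieved by
fixing every iteration order (lexicographic group labels, canonical
filter-input order, stable topological sort) rather than by rounding.
The fixture generator saves and restores the session RNG state, so
`--seed`-style reproducibility composes with user code.

## Limitations

* The path dialect is a pragmatic subset; real openEHR canonical
  serializations and ADL/OPT files are not parsed.
* The constraint schema is a purpose-built document format, not a CIM
  parser: it captures the information content (paths, types, constraints),
  not the modeling formalism.
* Terminology-bound value sets are represented as literal code lists.
* Knowledge bases are version-control *friendly* (one MM per file, stable
  bytes, content-hash manifest) but the package performs no VCS
  operations itself.
* The expression dialect trades power for auditability; a characterization
  that needs more than the registry and the dialect offers does not belong
  in a portable knowledge base.
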