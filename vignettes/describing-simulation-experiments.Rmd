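---
title: "Describing, indexing and sharing biomolecular simulation experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Describing, indexing and sharing biomolecular simulation experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(simdex)
```

## The problem

A molecular dynamics (MD) or quantum chemistry (QM) study is not one file
but a directory of dependent artifacts: a topology defining the molecular
system, per-stage input and output files (minimization, heating,
production), trajectory segments, and derived analysis tables. Repositories
that want to index such studies — so that someone can ask "all explicit-
solvent simulations run with AMBER FF99SB under a Langevin thermostat" —
need three things: a *logical model* of what a study is, a *controlled
vocabulary* for the values that recur across laboratories, and a flat
*annotation form* (attribute–value–unit triplets) that file catalogues and
search engines can store. simdex implements all three, plus the
serializers (XML, HTML, relational DDL) that move descriptions between
systems, and a deterministic fixture generator so the whole pipeline can be
exercised without any real simulation data.

## The logical model

The central object is the **virtual experiment**: the full set of
computational tasks and files constituting one study. It decomposes into

* **process groups** — all tasks targeting the same molecular system; each
  simulated copy of a system, and each separately studied subsystem
  (ligand vs. receptor), is its own group;
* **processes** — consecutive runs of similar tasks (a minimization
  process, a heating process, a production-MD process); and
* **tasks** — single computational runs (one program execution), typed as
  minimization, MD, QM, or QM/MM.

Method settings live in reusable **parameter sets** referenced by id from
tasks: an MD set carries force fields, barostat/thermostat, ensemble,
constraints and restraints, the electrostatics model, step count and step
length (the collision frequency is meaningful only for stochastic
dynamics); a QM set carries the method and basis-set names plus the
standard approximations (frozen core, pseudopotentials, plane-wave
cutoff); a QM/MM task references an MD set, a QM set and a QM/MM set
describing the boundary treatment. Because several tasks can share one
set (replica-exchange replicas, for instance), sets live in a
per-experiment registry and tasks hold references — this also keeps the
XML serialization an exact inverse.

The molecular system stores composition as *occurrence counts* rather than
atom instances: water is one hydrogen entry with count 2 and one oxygen
entry with count 1, plus the number of water molecules in the system.
Biomolecule chains are kept twice: the *specific chain* exactly as the
topology spells it, and a *normalized chain* of one-letter codes obtained
through the residue dictionary (unknown residues become `X`), which makes
sequences comparable across software.

Dependencies between tasks, between processes, and between process groups
are recorded as same-kind, acyclic edges; `validate_experiment()` reports
every breached invariant (containment, cycles, parameter-set arity,
misplaced topology files, negative conditions) as data rather than
exceptions, so callers can present complete reports.

Anything the model does not represent natively can be attached to any
entity as an **extended attribute** — an attribute–value–unit triplet with
an optional concept identifier (e.g. "PME interpolation order" = 4 on an
MD parameter set). Extended attributes are multi-valued: attaching the
same name twice keeps two triplets. Units are opaque strings copied
verbatim; simdex never converts them, on the assumption that a repository
settles units at publication time.

## Dictionaries

Twenty controlled vocabularies ship as CSV files (one per dictionary, with
mandatory `ID`, `TERM`, `DESCRIPTION` columns; extra columns hold scalars,
boolean flags, or `<TARGET>_ID` links into other dictionaries declared in
`_schema.csv`). Matching is case-insensitive and whitespace-normalized.
Search ranks exact matches before raw-prefix matches before token matches,
with ties broken lexicographically, so results are a deterministic subset
of a linear scan with the same predicate.

Two link chains matter most. Force fields link to a *type* (classical,
polarizable, reactive), so "AMBER FF99SB" implies "classical" without
storing it. QM methods link to a *class* (Hartree-Fock, Møller-Plesset,
DFT, ...) which links to a *family* (ab initio, semi-empirical,
empirical), so "MP2" implies Møller-Plesset and ab initio:

```{r classify}
dicts <- load_dictionary_set()
classify_method("MP2", dicts)[c("method_class", "method_family")]
```

Specific names are always retained even when no dictionary entry matches —
an unmapped basis set such as `LANL2DZ` is stored verbatim with no link,
and data carrying it remains publishable and queryable. Synonyms are a
known limitation of this design; the schema leaves room for a per-
dictionary synonym file but none is implemented. Dictionary entries beyond
the handful of published examples are provisional content chosen to cover
the fixtures and common practice.

## Triplets, the CDE catalogue, and completeness

`flatten_to_triplets()` projects a valid experiment onto
attribute–value–unit triplets over experiment, system, task and file
subjects, following the versioned field-to-attribute map in
`avu_attribute_map()`. Derived attributes (force-field type, QM method
class/family, basis-set type) are materialized at flattening time when the
dictionaries resolve them — they are never stored on entities, so model
content and vocabulary stay independent. We chose materialization over
query-time derivation because flat triplet stores (file catalogues,
full-text indexes) cannot follow links at query time.

The packaged **common data element (CDE) catalogue** names 32 data
elements with 72 attributes across the seven survey groups (authorship,
platform, molecular system, methods, molecules, molecular dynamics,
quantum mechanics); the published description of the catalogue gives its
totals and its scoring rule rather than the full table, so the packaged
CSV is a synthetic reconstruction assembled from the attributes the text
names, constrained to those totals. An attribute is *recommended* when its
mean community importance score on the 1–5 Likert scale is strictly
greater than 4.0; N/A responses are excluded from the mean (a mean of
exactly 4.0 is optional), and an element is recommended if any of its
attributes is. `validate_annotations()` reports the fraction of
recommended attributes present in a triplet set — a quality criterion for
a data publication — and lists unknown attributes as user-specific
extensions, not errors. The seven-versus-six group discrepancy in the
source description is preserved as seven groups rather than resolved.

## File parsing and the fixture dialects

Real engine grammars are out of scope: the contribution is the model, not
parsers for every output format. Instead simdex documents three
line-oriented dialects (`?fixture-dialects`): a topology dialect
(`%SIMDEX_TOP`, `%SECTION` blocks with `RESIDUE`/`ATOM` occurrence lines
whose sums must match the declared totals), and MD/QM output dialects
(`KEY = value` lines with a `FOOTER: <status>` line; a missing footer
means the run died and is recorded as termination status `incomplete`).
Parsers never invent values: absent keys yield absent fields. Executable
strings of the form `<ARCH>-<PRODUCT>Rev<REVISION>` (e.g.
`EM64L-G09RevC.01`) are decomposed into build information; known engine
names (`SANDER`, `PMEMD`) yield a product; anything else degrades to the
raw string. `detect_format()` keys on content (magic first lines, `ATOM`
records for PDB), never on file extension.

## Assembly and trajectory ordering

Trajectory segments are ordered by name, and a straight string sort ranks
`10.traj` before `2.traj`. `order_task_files()` implements a natural
order: names split into digit and non-digit runs, digit runs compared
numerically and text runs bytewise, digits before text, shorter token
sequences first. Two tie-break decisions were open and are fixed here:
leading zeros compare equal numerically with the shorter spelling first
(`2` before `02`), and names without any digit fall back to lexicographic
order with an `all_lexicographic` flag so callers can warn instead of
trusting the inference. The implementation builds radix-sortable keys;
tests hold it against an independent pairwise comparator over thousands of
random name sets (total order, idempotent, permutation-invariant).

`assemble_experiment()` builds the tree from parsed records: one process
group per (system, copy) — the copy comes from directory structure or an
explicit output key, never from content hashing — one process per
consecutive stage, chained dependencies following task order, inputs and
naturally-ordered trajectories attached to their stage's task, and the
topology attached to the system. Replica sets (e.g. a 4-replica REMD run)
are legally representable either as one process holding all replica tasks
or as one process per replica; both modes are exposed and
`single_process` is the default, treating the exchange run as one logical
unit.

## Serialization

`to_xml()` writes the experiment tree with entities as elements, scalars
as attributes, and dependencies/parameter-set usage as id references so
the document stays a tree; `from_xml()` is its exact inverse
(`identical()` on the R objects) and rejects any element outside the
schema with its path. The schema is authored in this package; no public
document vocabulary exists for these trees, so fidelity is to the model,
not to any external file. `render_html()` turns the XML into a collapsible
`details`/`summary` tree with exactly one node per entity — a template
transformation playing the role an XSLT stylesheet would.

`generate_ddl()` emits a portable SQL baseline: one table per entity and
per dictionary, foreign keys for every link, and one
`<table>_extended_attribute` companion table per extension-enabled entity
(a single shared attribute table would force table-name injection into
queries). Tables are created in dependency order and dropped in reverse,
making the script idempotent. The suite executes the DDL and loads every
packaged dictionary row on SQLite — through RSQLite when installed,
otherwise through the system python's sqlite3 module — with foreign keys
enforced.

## Analysis descriptors

Derived datasets are described by named dimensions and variables (rank 0 =
scalar, 1 = series, 2 = matrix), plus a provenance record: method name and
description, program and version, the exact command, timestamp, and
optional reference system. Optional filters list file dependencies, a time
window, and an opaque program-tagged atom selection (translating selection
syntaxes to a common form is explicitly not attempted, and filters are
never inferred from the command). `check_currency()` flags an analysis as
`needs_update` when any dependency is newer than the artifact, comparing
whole seconds with ties counted as current, and returns `unknown` when a
dependency timestamp is unavailable. Descriptors persist as JSON sidecars
(`write_descriptor()`/`read_descriptor()`) next to the analysis file —
delimited tables dominate in practice, so the description travels beside
the data rather than inside it.

## The synthetic fixture generator

`generate_md_study()`, `generate_remd_study()` and `generate_qm_study()`
write complete study directories in the documented dialects together with
a ground-truth JSON manifest. All randomness flows from the single seed
and timestamps are config-supplied, so regeneration at equal (seed,
config) is byte-identical. Defaults emulate a small nucleic-acid MD study:
a 6–12-residue RNA chain, explicit water (500–2000 molecules) under
AMBER-style force fields (FF99bsc0 + TIP3P), minimization–heating–
production staging with SHAKE, PME and an NPT production run at 300 K and
1 bar, 10 production trajectory segments (so the `2`/`10` natural-ordering
collision is always present), REMD ladders of 1–8 replicas with ~4%
temperature spacing, and Gaussian-style QM runs (MP2/B3LYP/HF/AM1 with
atomic basis sets including the deliberately unmapped `LANL2DZ`).

What the fixtures do *not* emulate matters for interpreting green tests:
payloads are placeholders (no physics), the dialects are cleaner than any
real engine output, and values are drawn from well-formed ranges. Passing
the generator↔parser recovery and round-trip checks therefore
demonstrates the correctness of the model, assembly, indexing and
serialization machinery — not robustness to the formatting quirks of real
AMBER or Gaussian files, which would require the software-specific parsers
this package intentionally leaves out.

## Numerical and scale choices

Entity identifiers, when not supplied by input, are derived
deterministically from content and position so fixtures and assembly are
reproducible. Value canonicalization writes numbers without exponent
padding and trims strings; comparisons in queries are exact on the
canonical form (equality) or case-insensitive substring. The test suite
and acceptance script exercise 1000 random name sets against the ordering
oracle, 1000 random triplet stores against a linear-scan oracle, ≥50
fixture round trips and a 20-cell seed×config recovery matrix — sizes
chosen to run the whole suite in well under a minute while leaving the
property space densely sampled. Multi-level (ONIOM-style) QM tasks are
sketched in the model's extension story but not implemented.
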